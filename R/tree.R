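#' Build a pressure-support indicator
#'
#' An indicator is one matched pressure/support pair: the support value is
#' the threshold the pressure is judged against, and both carry the same
#' units. Indicators are leaves of the assessment tree built with
#' [cc_factor()], [cc_dimension()] and [cc_tree()].
#'
#' @param id short identifier, unique within its factor.
#' @param pressure non-negative pressure value.
#' @param support positive support value (same units as `pressure`).
#' @param name human-readable name; defaults to `id`.
#' @param units units tag shared by the pair (e.g. `"km2"`, `"t/a"`).
#' @param weight positive aggregation weight relative to siblings
#'   (default 1, i.e. equal weights).
#' @return an object of class `cc_indicator`.
#' @examples
#' cc_indicator("land", pressure = 0.08, support = 0.13, units = "km2")
#' @export
cc_indicator <- function(id, pressure, support, name = id, units = "",
                         weight = 1) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(name), length(name) == 1L,
            is.character(units), length(units) == 1L,
            is.numeric(weight), length(weight) == 1L, weight > 0)
  if (!is.numeric(support) || length(support) != 1L ||
      !is.finite(support) || support <= 0) {
    stop("invalid indicator [", id, "]: support must be a positive number",
         call. = FALSE)
  }
  if (!is.numeric(pressure) || length(pressure) != 1L ||
      !is.finite(pressure) || pressure < 0) {
    stop("invalid indicator [", id, "]: pressure must be non-negative",
         call. = FALSE)
  }
  structure(list(id = id, name = name, pressure = as.numeric(pressure),
                 support = as.numeric(support), units = units,
                 weight = as.numeric(weight)),
            class = "cc_indicator")
}

#' Group indicators into a core factor
#'
#' @param id short identifier, unique within its dimension.
#' @param ... one or more [cc_indicator()] objects.
#' @param name human-readable name; defaults to `id`.
#' @param weight positive aggregation weight relative to sibling factors.
#' @return an object of class `cc_factor`.
#' @export
cc_factor <- function(id, ..., name = id, weight = 1) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.numeric(weight), length(weight) == 1L, weight > 0)
  kids <- list(...)
  if (length(kids) == 0L) {
    stop("structural error: factor [", id, "] has no indicators",
         call. = FALSE)
  }
  if (!all(vapply(kids, inherits, logical(1), "cc_indicator"))) {
    stop("factor [", id, "] children must be cc_indicator objects",
         call. = FALSE)
  }
  ids <- vapply(kids, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("factor [", id, "] has duplicated indicator ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  structure(list(id = id, name = name, weight = as.numeric(weight),
                 indicators = kids),
            class = "cc_factor")
}

#' Group core factors into a dimension
#'
#' A dimension aggregates in one of two modes. In `"flat"` mode all
#' indicators of all its factors are pooled and aggregated once; the
#' factor grouping is descriptive only. In `"nested"` mode each factor's
#' indicators are aggregated first and the dimension then aggregates the
#' factor ratios, so a factor with many indicators counts once, not once
#' per indicator.
#'
#' @param id short identifier, unique within the tree.
#' @param ... one or more [cc_factor()] objects (bare [cc_indicator()]s
#'   are accepted and wrapped in a single-indicator factor of the same id).
#' @param name human-readable name; defaults to `id`.
#' @param mode aggregation mode, `"flat"` (default) or `"nested"`.
#' @param weight positive aggregation weight relative to sibling dimensions.
#' @return an object of class `cc_dimension`.
#' @export
cc_dimension <- function(id, ..., name = id, mode = c("flat", "nested"),
                         weight = 1) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.numeric(weight), length(weight) == 1L, weight > 0)
  mode <- match.arg(mode)
  kids <- lapply(list(...), function(k) {
    if (inherits(k, "cc_indicator")) cc_factor(k$id, k, name = k$name) else k
  })
  if (length(kids) == 0L) {
    stop("structural error: dimension [", id, "] has no factors",
         call. = FALSE)
  }
  if (!all(vapply(kids, inherits, logical(1), "cc_factor"))) {
    stop("dimension [", id, "] children must be cc_factor or cc_indicator",
         call. = FALSE)
  }
  ids <- vapply(kids, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("dimension [", id, "] has duplicated factor ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  structure(list(id = id, name = name, mode = mode,
                 weight = as.numeric(weight), factors = kids),
            class = "cc_dimension")
}

#' Assemble the assessment tree
#'
#' @param ... one or more [cc_dimension()] objects.
#' @param name name of the assessed system.
#' @return an object of class `cc_tree`.
#' @seealso [corecc()] to run the assessment, [zsi_tree()] for the
#'   bundled Zhaoshu Island 2017 case study.
#' @export
cc_tree <- function(..., name = "CORE-CC") {
  kids <- list(...)
  if (length(kids) == 0L) {
    stop("structural error: tree has no dimensions", call. = FALSE)
  }
  if (!all(vapply(kids, inherits, logical(1), "cc_dimension"))) {
    stop("tree children must be cc_dimension objects", call. = FALSE)
  }
  ids <- vapply(kids, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("tree has duplicated dimension ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  structure(list(name = name, dimensions = kids), class = "cc_tree")
}

#' @export
print.cc_tree <- function(x, ...) {
  cat("<cc_tree> ", x$name, "\n", sep = "")
  for (dm in x$dimensions) {
    cat("  ", dm$name, " [", dm$mode, "]\n", sep = "")
    for (fc in dm$factors) {
      cat("    ", fc$name, "\n", sep = "")
      for (ind in fc$indicators) {
        cat(sprintf("      %s: p = %g, s = %g %s\n",
                    ind$name, ind$pressure, ind$support, ind$units))
      }
    }
  }
  invisible(x)
}

#' Flatten an assessment tree to a data frame of indicators
#'
#' @param x a `cc_tree`.
#' @param row.names,optional,... ignored; present for method consistency.
#' @return data frame with one row per indicator: dimension, factor and
#'   indicator ids/names, mode, pressure, support, units, weight.
#' @export
as.data.frame.cc_tree <- function(x, row.names = NULL, optional = FALSE, ...) {
  rows <- list()
  for (dm in x$dimensions) {
    for (fc in dm$factors) {
      for (ind in fc$indicators) {
        rows[[length(rows) + 1L]] <- data.frame(
          dimension = dm$id, dimension_name = dm$name, mode = dm$mode,
          factor = fc$id, factor_name = fc$name,
          indicator = ind$id, indicator_name = ind$name,
          pressure = ind$pressure, support = ind$support,
          units = ind$units, weight = ind$weight,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
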