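#' Assess the carrying state of an indicator tree
#'
#' Runs the full hierarchical assessment: a surplus ratio
#' \eqn{d = 1 - p/s} for every indicator, vector (RMS) aggregation
#' ([aggregate_ratios()]) up through factors and dimensions to the
#' overall index, and a carrying state for every node under the
#' configured warning buffer.
#'
#' Dimensions in `"flat"` mode pool all their indicators into one
#' aggregation; `"nested"` dimensions aggregate each factor first and
#' then the factor ratios. All stored values are full precision; the
#' `print` and `summary` methods round for display (ratios to two
#' decimals, degrees to whole percent).
#'
#' @param tree a [cc_tree()].
#' @param warning_width warning-buffer width in `[0, 1)`; positive
#'   ratios below it are flagged `"warning"`. Default `0.10`.
#' @return an object of class `corecc`: a list with `report` (one row
#'   per node: `level`, `path`, `id`, `name`, `ratio`, `degree`,
#'   `state`), `overall`, `dimensions` (named ratio vector),
#'   `warning_width`, `tree` and `timestamp`.
#' @examples
#' fit <- corecc(zsi_tree())
#' fit
#' coef(fit)
#' summary(fit)
#' @seealso [zsi_tree()], [render_report()]
#' @export
corecc <- function(tree, warning_width = 0.10) {
  if (!inherits(tree, "cc_tree")) {
    stop("tree must be a cc_tree object", call. = FALSE)
  }
  # validate width before any computation
  classify_state(0, warning_width)

  rows <- list()
  add <- function(level, path, id, name, ratio) {
    rows[[length(rows) + 1L]] <<- data.frame(
      level = level, path = path, id = id, name = name,
      ratio = ratio, degree = abs(ratio) * 100,
      state = classify_state(ratio, warning_width),
      stringsAsFactors = FALSE)
    ratio
  }

  dim_ratio <- numeric(0)
  dim_w <- numeric(0)
  for (dm in tree$dimensions) {
    ind_d <- numeric(0)   # all indicator ratios in this dimension
    ind_w <- numeric(0)
    fac_D <- numeric(0)
    fac_w <- numeric(0)
    for (fc in dm$factors) {
      d <- vapply(fc$indicators, function(ind) {
        r <- tryCatch(
          surplus_ratio(ind$pressure, ind$support, id = ind$id),
          error = function(e) {
            stop("at ", dm$id, "/", fc$id, "/", ind$id, ": ",
                 conditionMessage(e), call. = FALSE)
          })
        add("indicator", paste(dm$id, fc$id, ind$id, sep = "/"),
            ind$id, ind$name, r)
      }, numeric(1))
      w <- vapply(fc$indicators, `[[`, numeric(1), "weight")
      fr <- aggregate_ratios(d, w)
      add("factor", paste(dm$id, fc$id, sep = "/"), fc$id, fc$name, fr)
      ind_d <- c(ind_d, d); ind_w <- c(ind_w, w)
      fac_D <- c(fac_D, fr); fac_w <- c(fac_w, fc$weight)
    }
    Dr <- if (dm$mode == "nested") aggregate_ratios(fac_D, fac_w)
          else aggregate_ratios(ind_d, ind_w)
    add("dimension", dm$id, dm$id, dm$name, Dr)
    dim_ratio <- c(dim_ratio, Dr)
    dim_w <- c(dim_w, dm$weight)
  }
  names(dim_ratio) <- vapply(tree$dimensions, `[[`, character(1), "id")
  overall <- aggregate_ratios(dim_ratio, dim_w)
  add("overall", "overall", "overall", tree$name, overall)

  structure(list(report = do.call(rbind, rows),
                 overall = overall,
                 dimensions = dim_ratio,
                 warning_width = warning_width,
                 tree = tree,
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
            class = "corecc")
}

#' @export
print.corecc <- function(x, ...) {
  cat("Carrying-capacity assessment:", x$tree$name, "\n")
  cat(sprintf("Overall surplus ratio: %.2f (%s, degree %d%%)\n",
              x$overall, classify_state(x$overall, x$warning_width),
              round(abs(x$overall) * 100)))
  dd <- x$report[x$report$level == "dimension", , drop = FALSE]
  cat("\nDimensions:\n")
  print(data.frame(name = dd$name,
                   ratio = sprintf("%.2f", dd$ratio),
                   state = dd$state,
                   `degree %` = round(dd$degree),
                   check.names = FALSE, row.names = NULL))
  cat(sprintf("\nWarning buffer width: %.2f\n", x$warning_width))
  invisible(x)
}

#' @export
coef.corecc <- function(object, ...) {
  c(object$dimensions, overall = object$overall)
}

#' @export
as.data.frame.corecc <- function(x, row.names = NULL, optional = FALSE, ...) {
  x$report
}

#' @rdname corecc
#' @param object,x a fitted `corecc` object.
#' @param ... unused.
#' @export
summary.corecc <- function(object, ...) {
  rep <- object$report
  ind <- rep[rep$level == "indicator", , drop = FALSE]
  ind$dimension <- vapply(strsplit(ind$path, "/"), `[[`, character(1), 1L)
  binding <- do.call(rbind, lapply(split(ind, ind$dimension), function(g) {
    g[which.min(g$ratio), c("dimension", "id", "name", "ratio", "state")]
  }))
  structure(list(fit = object, binding = binding), class = "summary.corecc")
}

#' @export
print.summary.corecc <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat("\nAll nodes:\n")
  rep <- fit$report
  print(data.frame(path = rep$path,
                   ratio = sprintf("%.2f", rep$ratio),
                   state = rep$state,
                   `degree %` = round(rep$degree),
                   check.names = FALSE, row.names = NULL))
  cat("\nMost binding indicator per dimension:\n")
  b <- x$binding
  for (i in seq_len(nrow(b))) {
    cat(sprintf("  %s: %s (ratio %.2f, %s)\n",
                b$dimension[i], b$name[i], b$ratio[i], b$state[i]))
  }
  invisible(x)
}

#' @rdname corecc
#' @export
plot.corecc <- function(x, ...) {
  dd <- x$report[x$report$level == "dimension", , drop = FALSE]
  cols <- c("over-loaded" = "#d73027", "full-loaded" = "#fdae61",
            "warning" = "#fee090", "surplus" = "#4575b4")
  op <- graphics::par(mar = c(7, 4, 3, 1))
  on.exit(graphics::par(op))
  graphics::barplot(dd$ratio, names.arg = dd$name, las = 2,
                    col = cols[dd$state],
                    ylab = "surplus ratio",
                    main = sprintf("%s (overall %.2f, %s)", x$tree$name,
                                   x$overall,
                                   classify_state(x$overall, x$warning_width)),
                    ...)
  graphics::abline(h = 0, lwd = 1)
  graphics::abline(h = x$warning_width, lty = 3)
  invisible(x)
}
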