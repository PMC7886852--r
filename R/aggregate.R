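#' Surplus ratio of a pressure-support indicator pair
#'
#' The surplus ratio compares the pressure exerted on an indicator with the
#' support the system provides: \eqn{d = (s - p)/s = 1 - p/s}. Positive
#' values mean the support exceeds the pressure (surplus), zero means the
#' pressure has exactly reached the support threshold (full load), and
#' negative values mean overload. Since pressure is non-negative and
#' support positive, \eqn{d \le 1} always; there is no lower bound (an
#' indicator loaded at double its support scores \eqn{-1}).
#'
#' @param pressure numeric vector of non-negative pressure values.
#' @param support numeric vector of positive support values, recycled
#'   against `pressure`; same units as `pressure`.
#' @param id optional indicator identifier(s) used in error messages.
#' @return numeric vector of surplus ratios, each \eqn{\le 1}.
#' @examples
#' surplus_ratio(5, 5)    # full load -> 0
#' surplus_ratio(0, 5)    # no pressure -> 1
#' surplus_ratio(10, 5)   # double the support -> -1
#' @seealso [classify_state()], [aggregate_ratios()]
#' @export
surplus_ratio <- function(pressure, support, id = NULL) {
  stopifnot(is.numeric(pressure), is.numeric(support))
  bad <- !is.finite(support) | support <= 0
  if (any(bad)) {
    lab <- if (is.null(id)) which(bad) else id[bad]
    stop("invalid indicator [", paste(lab, collapse = ", "),
         "]: support must be positive and finite", call. = FALSE)
  }
  bad <- !is.finite(pressure) | pressure < 0
  if (any(bad)) {
    lab <- if (is.null(id)) which(bad) else id[bad]
    stop("invalid indicator [", paste(lab, collapse = ", "),
         "]: pressure must be non-negative and finite", call. = FALSE)
  }
  1 - pressure / support
}

#' Classify a surplus ratio into a carrying state
#'
#' Maps surplus ratios onto the four carrying states. Negative ratios are
#' `"over-loaded"`, exactly zero is `"full-loaded"`, and positive ratios
#' are `"surplus"` unless they fall inside the warning buffer
#' `(0, warning_width)`, in which case they are `"warning"`: a small
#' positive surplus is treated as too close to the critical point to be
#' called safe, given the uncertainty of estimated indicator values.
#'
#' @param d numeric vector of surplus ratios (each \eqn{\le 1}).
#' @param warning_width half-open buffer width in `[0, 1)`; ratios in
#'   `(0, warning_width)` classify as `"warning"`. `0` disables the
#'   buffer. Default `0.10`.
#' @return character vector over
#'   `c("over-loaded", "full-loaded", "warning", "surplus")`.
#' @examples
#' classify_state(c(-0.04, 0, 0.05, 0.38))
#' classify_state(0.05, warning_width = 0)  # buffer off -> "surplus"
#' @export
classify_state <- function(d, warning_width = 0.10) {
  if (!is.numeric(warning_width) || length(warning_width) != 1L ||
      is.na(warning_width) || warning_width < 0 || warning_width >= 1) {
    stop("configuration error: warning_width must be a single value in [0, 1)",
         call. = FALSE)
  }
  stopifnot(is.numeric(d))
  if (any(d > 1 + 1e-12, na.rm = TRUE)) {
    stop("surplus ratio exceeds 1; check pressure/support signs", call. = FALSE)
  }
  out <- character(length(d))
  out[d < 0] <- "over-loaded"
  out[d == 0] <- "full-loaded"
  out[d > 0 & d < warning_width] <- "warning"
  out[d >= warning_width & d > 0] <- "surplus"
  out[is.na(d)] <- NA_character_
  out
}

#' Carrying-state names in display order
#' @return character vector of the four states, worst first.
#' @export
carrying_states <- function() {
  c("over-loaded", "full-loaded", "warning", "surplus")
}

#' Vector (RMS) aggregation of surplus ratios
#'
#' Combines the surplus ratios of sibling nodes into the ratio of their
#' parent by the vector-modulus rule
#' \deqn{D = 1 - \sqrt{\sum_j w_j (1 - d_j)^2}, \qquad \sum_j w_j = 1,}
#' with equal weights \eqn{w_j = 1/n} by default. Each child's load factor
#' \eqn{1 - d_j} enters quadratically, so a single heavily overloaded
#' child drags the parent down more than an arithmetic mean would. The
#' same rule applies at every level: indicators into a factor, factors or
#' indicators into a dimension, and dimensions into the overall index.
#'
#' Properties: the aggregate of a single child is the child itself; of
#' identical children, that common value; the result never exceeds the
#' maximum child; and it is invariant under permutation and strictly
#' increasing in every child.
#'
#' @param d numeric vector of child surplus ratios, each \eqn{\le 1}.
#' @param weights optional positive weights, recycled and normalised to
#'   sum to one. Default equal.
#' @return the aggregated surplus ratio (single number, \eqn{\le 1}).
#' @examples
#' aggregate_ratios(c(0.38, 0.44))        # ~ 0.409
#' aggregate_ratios(0.87)                 # singleton -> 0.87
#' aggregate_ratios(c(0.04, 0.08, -0.6))  # ~ -0.201
#' @export
aggregate_ratios <- function(d, weights = NULL) {
  if (length(d) == 0L) {
    stop("structural error: cannot aggregate an empty set of ratios",
         call. = FALSE)
  }
  stopifnot(is.numeric(d), all(is.finite(d)))
  if (any(d > 1 + 1e-12)) {
    stop("surplus ratios must not exceed 1", call. = FALSE)
  }
  if (is.null(weights)) {
    w <- rep(1 / length(d), length(d))
  } else {
    stopifnot(is.numeric(weights), all(is.finite(weights)), all(weights > 0))
    w <- rep_len(weights, length(d))
    w <- w / sum(w)
  }
  1 - sqrt(sum(w * (1 - d)^2))
}
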