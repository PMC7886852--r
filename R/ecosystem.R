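#' Reference mean leaf-area index by land-cover type
#'
#' Empirical mean LAI (m2/m2) for the seven land-cover classes used in
#' the terrestrial ecosystem-service indicator.
#'
#' @return named numeric vector of mean LAI values.
#' @export
default_lai_table <- function() {
  c("Farmland" = 3.0, "Garden" = 3.0, "Woodland" = 5.0,
    "Grassland" = 2.0, "Wetland" = 6.5, "Construction land" = 0.5,
    "Other land" = 1.0)
}

#' Area-weighted mean leaf-area index (Sum LAI)
#'
#' The terrestrial ecosystem-service level of an island is summarised by
#' the Sum LAI: the mean LAI of its land-cover types weighted by their
#' area shares, \eqn{L_S = \sum_i L_i A_i / A_{total}}. This is the
#' support value of the Sum-LAI indicator; the pressure is a target value
#' set by the island's functional planning.
#'
#' @param areas named non-negative areas by cover type (any common unit);
#'   at least one must be positive.
#' @param lai named mean-LAI lookup covering every type in `areas`;
#'   default [default_lai_table()].
#' @return the area-weighted mean LAI (m2/m2).
#' @examples
#' sum_lai(c(Wetland = 10))                       # 6.5
#' sum_lai(c("Construction land" = 2, Woodland = 2))
#' @export
sum_lai <- function(areas, lai = default_lai_table()) {
  stopifnot(is.numeric(areas), is.numeric(lai))
  if (is.null(names(areas)) || any(!nzchar(names(areas)))) {
    stop("land-cover areas must be named by cover type", call. = FALSE)
  }
  if (any(!is.finite(areas) | areas < 0)) {
    stop("land-cover areas must be non-negative and finite", call. = FALSE)
  }
  total <- sum(areas)
  if (total <= 0) stop("total land-cover area is zero", call. = FALSE)
  miss <- setdiff(names(areas), names(lai))
  if (length(miss)) {
    stop("cover type(s) missing from the LAI table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  sum(lai[names(areas)] * areas) / total
}

#' Hard-coral coverage from a point-intercept transect
#'
#' On a point-intercept transect the substrate is recorded at `M` fixed
#' points along the line; the hard-coral coverage is the percentage of
#' points that intercept live hard coral, \eqn{100\, n / M}.
#'
#' @param n hard-coral point count(s), `0 <= n <= M`.
#' @param M total points per transect, `> 0`; recycled against `n`.
#' @return coverage in percent, in `[0, 100]`.
#' @examples
#' hard_coral_coverage(25, 100)  # 25
#' @export
hard_coral_coverage <- function(n, M) {
  stopifnot(is.numeric(n), is.numeric(M))
  M <- rep_len(M, length(n))
  if (any(!is.finite(M) | M <= 0)) {
    stop("total point count M must be positive", call. = FALSE)
  }
  if (any(!is.finite(n) | n < 0 | n > M)) {
    stop("hard-coral count n must satisfy 0 <= n <= M", call. = FALSE)
  }
  100 * n / M
}

#' Reef-fish density from a belt transect
#'
#' A belt transect of length `L` surveys a strip of width `W` on each
#' side of the line, so the swept area is `2 L W` and the density is
#' \eqn{D_f = N / (2 L W)} fish per square metre.
#'
#' @param N fish count(s), non-negative.
#' @param L transect length in metres, `> 0`; recycled.
#' @param W one-side strip width in metres, `> 0`; recycled.
#' @return density in fish per square metre.
#' @examples
#' fish_density(100, 50, 1)    # 1
#' fish_density(30, 30, 2.5)   # 0.2
#' @export
fish_density <- function(N, L, W) {
  stopifnot(is.numeric(N), is.numeric(L), is.numeric(W))
  L <- rep_len(L, length(N)); W <- rep_len(W, length(N))
  if (any(!is.finite(L) | L <= 0) || any(!is.finite(W) | W <= 0)) {
    stop("transect length and width must be positive", call. = FALSE)
  }
  if (any(!is.finite(N) | N < 0)) {
    stop("fish count must be non-negative", call. = FALSE)
  }
  N / (2 * L * W)
}

#' Pool per-transect estimates into one support value
#'
#' Combines per-transect coverage or density estimates into the single
#' value entering the indicator pair, as an effort-weighted mean (equal
#' weights by default).
#'
#' @param values per-transect estimates, non-empty.
#' @param weights optional positive survey-effort weights, recycled.
#' @return the pooled estimate.
#' @examples
#' pool_transects(c(20, 30))                    # 25
#' pool_transects(c(10, 20, 30), c(1, 1, 2))    # 22.5
#' @export
pool_transects <- function(values, weights = NULL) {
  stopifnot(is.numeric(values))
  if (length(values) == 0L) {
    stop("cannot pool an empty set of transects", call. = FALSE)
  }
  if (is.null(weights)) return(mean(values))
  stopifnot(is.numeric(weights), all(is.finite(weights)), all(weights > 0))
  w <- rep_len(weights, length(values))
  sum(w * values) / sum(w)
}
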