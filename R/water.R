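#' Total available water resource
#'
#' Sums the named components of an island's annual water budget into the
#' total available water resource, the support value of the water
#' indicator (the matching pressure is the population's annual water
#' consumption). The canonical components are available ground water,
#' water transferred in, reclaimed wastewater and desalinated sea water,
#' but the component list is open: every named non-negative entry is
#' included, so an "available surface water" term can simply be added
#' where an island has one.
#'
#' @param components named numeric vector or list of non-negative
#'   volumes, all in one unit (conventionally m3/a).
#' @return the component sum.
#' @examples
#' available_water(c(ground = 1, transferred = 2,
#'                   reclaimed = 3, desalinated = 4))  # 10
#' @export
available_water <- function(components) {
  components <- unlist(components)
  stopifnot(length(components) >= 1L, is.numeric(components))
  if (is.null(names(components)) || any(!nzchar(names(components)))) {
    stop("water-budget components must be named", call. = FALSE)
  }
  bad <- !is.finite(components) | components < 0
  if (any(bad)) {
    stop("invalid water-budget component [",
         paste(names(components)[bad], collapse = ", "),
         "]: values must be non-negative and finite", call. = FALSE)
  }
  sum(components)
}
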