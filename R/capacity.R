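#' Seawater assimilative capacity by load optimisation
#'
#' Estimates the assimilative capacity of the water body around an
#' island as the maximum total pollutant load that still meets the
#' water-quality standard in every monitored sea area, following the
#' total-maximum-daily-load (TMDL) approach. Given a response field
#' `P` — the concentration increment in sea area `i` per unit annual
#' load from point source `j`, precomputed by a hydrodynamic
#' water-quality model — the capacity is the linear program
#' \deqn{AC = \max \sum_j Q_j \quad \mathrm{s.t.}\quad
#'   \sum_j P_{ij} Q_j \le C^s_i - b_i,\;\; Q^l_j \le Q_j \le Q^u_j,}
#' solved with the simplex method. `b` is an optional per-area ambient
#' background concentration (default 0), subtracted from the standard.
#'
#' When several optimal load allocations exist only the total `AC` is
#' well-defined; the reported `loads` vector is the vertex the solver
#' returns.
#'
#' @param P numeric matrix, sea areas x sources, all entries finite and
#'   non-negative, in (mg/L)/(t/a).
#' @param limits per-area water-quality standards \eqn{C^s_i > 0} (mg/L).
#' @param lower,upper per-source load bounds (t/a),
#'   \eqn{0 \le Q^l \le Q^u}; scalars are recycled.
#' @param background per-area ambient concentration, each
#'   `< limits` (mg/L); default 0.
#' @return a list of class `cc_capacity`: `status` (`"optimal"` or
#'   `"infeasible"`), `loads` (t/a), `capacity` (`AC`, t/a),
#'   `binding` (labels of active constraints) and, when infeasible,
#'   `violated` (areas whose standard is exceeded already at the lower
#'   bounds).
#' @examples
#' solve_capacity(matrix(0.5, 1, 1), limits = 1, lower = 0, upper = 10)
#' @export
solve_capacity <- function(P, limits, lower = 0, upper, background = 0) {
  P <- as.matrix(P)
  stopifnot(is.numeric(P), all(is.finite(P)), all(P >= 0),
            nrow(P) >= 1L, ncol(P) >= 1L)
  n_area <- nrow(P); n_src <- ncol(P)
  stopifnot(length(limits) == n_area, all(is.finite(limits)),
            all(limits > 0))
  background <- rep_len(background, n_area)
  stopifnot(all(is.finite(background)), all(background >= 0))
  if (any(background >= limits)) {
    stop("background concentration at or above the quality standard in ",
         "area(s) ", paste(which(background >= limits), collapse = ", "),
         call. = FALSE)
  }
  lower <- rep_len(lower, n_src)
  upper <- rep_len(upper, n_src)
  stopifnot(all(is.finite(lower)), all(is.finite(upper)),
            all(lower >= 0))
  if (any(upper < lower)) {
    stop("upper load bounds below lower bounds for source(s) ",
         paste(which(upper < lower), collapse = ", "), call. = FALSE)
  }
  cap <- limits - background

  # lower bounds alone may already break a standard: report, don't solve
  base <- drop(P %*% lower)
  viol <- which(base > cap + 1e-12)
  area_ids <- rownames(P) %||% as.character(seq_len(n_area))
  src_ids <- colnames(P) %||% as.character(seq_len(n_src))
  if (length(viol)) {
    return(structure(list(status = "infeasible", loads = NULL,
                          capacity = NA_real_, binding = character(0),
                          violated = area_ids[viol]),
                     class = "cc_capacity"))
  }

  # shift to x = Q - lower >= 0 for the simplex tableau
  b1 <- c(cap - base, upper - lower)
  sol <- boot::simplex(a = rep(1, n_src),
                       A1 = rbind(P, diag(n_src)), b1 = b1,
                       maxi = TRUE)
  if (sol$solved != 1) {
    return(structure(list(status = "infeasible", loads = NULL,
                          capacity = NA_real_, binding = character(0),
                          violated = character(0)),
                     class = "cc_capacity"))
  }
  Q <- as.numeric(sol$soln) + lower
  names(Q) <- src_ids
  conc <- drop(P %*% Q) + background
  tol <- 1e-9 * pmax(1, abs(limits))
  binding <- c(paste0("area:", area_ids[abs(conc - limits) <= tol]),
               paste0("source-upper:", src_ids[abs(Q - upper) <= 1e-9 * pmax(1, upper)]),
               paste0("source-lower:", src_ids[lower > 0 & abs(Q - lower) <= 1e-9 * pmax(1, lower)]))
  structure(list(status = "optimal", loads = Q, capacity = sum(Q),
                 binding = binding, violated = character(0)),
            class = "cc_capacity")
}

#' @export
print.cc_capacity <- function(x, ...) {
  cat("<cc_capacity> status:", x$status, "\n")
  if (x$status == "optimal") {
    cat("  total capacity AC =", format(x$capacity), "t/a\n")
    cat("  loads:", paste(sprintf("%s=%.4g", names(x$loads), x$loads),
                          collapse = ", "), "\n")
    if (length(x$binding)) {
      cat("  binding:", paste(x$binding, collapse = ", "), "\n")
    }
  } else {
    cat("  standards violated already at the lower load bounds in:",
        paste(x$violated, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Water-assimilation surplus ratio across pollutants
#'
#' Turns per-pollutant assimilative capacities and actual discharges into
#' the single water-assimilation surplus ratio: per pollutant
#' \eqn{d = 1 - \mathrm{discharge}/AC}, combined across pollutants either
#' by the minimum (the most binding pollutant; default) or by the RMS
#' vector rule of [aggregate_ratios()].
#'
#' @param capacity named vector of assimilative capacities `AC > 0`
#'   (t/a), or a named list of [solve_capacity()] results.
#' @param discharge named vector of actual annual loads (t/a); names
#'   must match `capacity`.
#' @param combine `"min"` (default) or `"rms"`.
#' @return the combined surplus ratio.
#' @examples
#' assimilation_surplus(c(IN = 100, IP = 10), c(IN = 13, IP = 5))
#' @export
assimilation_surplus <- function(capacity, discharge,
                                 combine = c("min", "rms")) {
  combine <- match.arg(combine)
  if (is.list(capacity)) {
    capacity <- vapply(capacity, function(r) {
      if (inherits(r, "cc_capacity")) {
        if (r$status != "optimal") {
          stop("capacity result is not optimal", call. = FALSE)
        }
        r$capacity
      } else as.numeric(r)
    }, numeric(1))
  }
  stopifnot(is.numeric(capacity), is.numeric(discharge))
  if (is.null(names(capacity)) || is.null(names(discharge))) {
    stop("capacity and discharge must be named by pollutant", call. = FALSE)
  }
  miss <- c(setdiff(names(capacity), names(discharge)),
            setdiff(names(discharge), names(capacity)))
  if (length(miss)) {
    stop("pollutant(s) present on one side only: ",
         paste(unique(miss), collapse = ", "), call. = FALSE)
  }
  if (any(capacity <= 0)) {
    stop("assimilative capacity must be positive", call. = FALSE)
  }
  d <- 1 - discharge[names(capacity)] / capacity
  if (combine == "min") unname(min(d)) else aggregate_ratios(unname(d))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
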