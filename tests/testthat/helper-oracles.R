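# Independent brute-force oracles used to cross-check the implementation.

# Direct re-evaluation of the surplus-ratio / RMS aggregation chain on a
# cc_tree, written as plain loops with no shared code with corecc().
oracle_assess <- function(tree) {
  rms_up <- function(d) 1 - sqrt(mean((1 - d)^2))
  dims <- numeric(0)
  for (dm in tree$dimensions) {
    if (dm$mode == "nested") {
      fr <- numeric(0)
      for (fc in dm$factors) {
        d <- sapply(fc$indicators, function(i) 1 - i$pressure / i$support)
        fr <- c(fr, rms_up(d))
      }
      dims <- c(dims, rms_up(fr))
    } else {
      d <- numeric(0)
      for (fc in dm$factors) {
        d <- c(d, sapply(fc$indicators,
                         function(i) 1 - i$pressure / i$support))
      }
      dims <- c(dims, rms_up(d))
    }
  }
  list(dimensions = dims, overall = rms_up(dims))
}

# Brute-force LP oracle: enumerate all basic feasible solutions (vertices)
# of {P Q <= b, l <= Q <= u} and take the best objective. Only sensible
# for a handful of sources.
oracle_lp <- function(P, limits, lower, upper, background = 0) {
  n <- ncol(P)
  A <- rbind(P, diag(n), -diag(n))
  b <- c(limits - rep_len(background, nrow(P)),
         rep_len(upper, n), -rep_len(lower, n))
  m <- nrow(A)
  best <- -Inf
  bestx <- NULL
  for (idx in utils::combn(m, n, simplify = FALSE)) {
    Aa <- A[idx, , drop = FALSE]
    if (abs(det(Aa)) < 1e-12) next
    x <- solve(Aa, b[idx])
    if (all(A %*% x <= b + 1e-9)) {
      if (sum(x) > best) { best <- sum(x); bestx <- x }
    }
  }
  list(capacity = best, loads = bestx)
}

# Random assessment tree with known ratios, built from (p, s) = (1 - d, 1).
random_tree <- function(seed) {
  set.seed(seed)
  ndim <- sample(1:4, 1)
  dims <- lapply(seq_len(ndim), function(i) {
    nfac <- sample(1:3, 1)
    facs <- lapply(seq_len(nfac), function(j) {
      nind <- sample(1:3, 1)
      inds <- lapply(seq_len(nind), function(k) {
        d <- stats::runif(1, -2, 1)
        cc_indicator(sprintf("i%d_%d_%d", i, j, k),
                     pressure = 1 - d, support = 1)
      })
      do.call(cc_factor, c(list(sprintf("f%d_%d", i, j)), inds))
    })
    do.call(cc_dimension,
            c(list(sprintf("d%d", i)), facs,
              list(mode = sample(c("flat", "nested"), 1))))
  })
  do.call(cc_tree, dims)
}
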