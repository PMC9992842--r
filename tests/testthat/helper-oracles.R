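# Brute-force grid oracle for the constrained solve, and shared generators.

# Exact minimum of ||M f - L||^2 over the grid {0, step, ..., 1}^k.
# The outer k-1 coordinates are enumerated on the grid; the innermost
# coordinate is a univariate convex quadratic, whose grid minimum sits at
# floor/ceil of the clamped continuous argmin, so it is resolved
# analytically. This evaluates the full grid exactly without enumerating
# all (1/step + 1)^k points.
grid_nnls_min <- function(M, L, step = 1e-3) {
  M <- as.matrix(M)
  k <- ncol(M)
  g <- seq(0, 1, by = step)
  a <- M[, 1]
  aa <- sum(a * a)
  min_over_f1 <- function(R) {
    # R: residual targets, one column per outer-grid combo
    rr <- .colSums(R * R, nrow(R), ncol(R))
    if (aa == 0) return(min(rr))
    ar <- drop(crossprod(a, R))
    t <- pmin(1, pmax(0, ar / aa))
    lo <- pmax(0, floor(t / step) * step)
    hi <- pmin(1, ceiling(t / step) * step)
    min(pmin(aa * lo^2 - 2 * lo * ar, aa * hi^2 - 2 * hi * ar) + rr)
  }
  if (k == 1) {
    min_over_f1(matrix(L, ncol = 1))
  } else if (k == 2) {
    min_over_f1(L - outer(M[, 2], g))
  } else if (k == 3) {
    G <- grid_pairs(length(g))
    R <- L - M[, 2:3] %*% rbind(g[G$i], g[G$j])
    min_over_f1(R)
  } else {
    stop("grid oracle supports k <= 3")
  }
}

# cache the (f2, f3) index grid; ~1e6 pairs for step 1e-3
grid_pairs <- local({
  cache <- NULL
  cache_n <- 0L
  function(n) {
    if (is.null(cache) || cache_n != n) {
      cache <<- list(i = rep(seq_len(n), times = n),
                     j = rep(seq_len(n), each = n))
      cache_n <<- n
    }
    cache
  }
})

nnls_objective <- function(M, L, f) sum((as.matrix(M) %*% f - L)^2)

random_system <- function(k) {
  list(M = matrix(stats::runif(k * k), k, k), L = stats::runif(k))
}

random_fraction_spectrum <- function(C) {
  x <- stats::runif(C + 1)
  isotopologue_spectrum("random", x / sum(x), carbon_count = C,
                        is_fraction = TRUE)
}

# normalized-labeling table for a hand-specified 3-substrate system
toy_normalized <- function(M, L, se_M = 0, se_L = 0,
                           substrates = c("lactate", "glycerol", "alanine"),
                           product = "glucose") {
  rows <- list()
  for (t in seq_along(substrates)) {
    for (s in seq_along(substrates)) {
      if (s == t) next
      rows[[length(rows) + 1L]] <- data.frame(
        metabolite = substrates[s], tracer = substrates[t],
        value = M[t, s], se = if (length(se_M) == 1) se_M else se_M[t, s])
    }
    rows[[length(rows) + 1L]] <- data.frame(
      metabolite = product, tracer = substrates[t],
      value = L[t], se = if (length(se_L) == 1) se_L else se_L[t])
  }
  do.call(rbind, rows)
}
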