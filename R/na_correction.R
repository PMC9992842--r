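#' Natural-abundance correction matrix for carbon
#'
#' Builds the lower-triangular convolution matrix A relating a true
#' (tracer-derived) mass isotopomer distribution to the observed one under
#' natural 13C abundance. With `i` carbons truly labeled, each of the
#' remaining `C - i` carbons is independently 13C with probability `p`, so
#' `A[j, i] = choose(C - i, j - i) * p^(j - i) * (1 - p)^(C - j)` for
#' `j >= i` (0-based isotopologue indices). Columns are binomial
#' distributions and sum to 1. Only carbon is corrected; H/N/O isotopes are
#' ignored, which dominates for the small gluconeogenic metabolites
#' considered here.
#'
#' @param carbon_count integer number of carbons C >= 1.
#' @param p natural 13C abundance fraction, default 0.0107 (standard
#'   terrestrial value).
#' @return A `(C+1) x (C+1)` matrix of class `"correction_matrix"` with
#'   attributes `carbon_count` and `p`.
#' @examples
#' correction_matrix(2, 0.0107)[, 1]  # 0.97871449 0.02117102 0.00011449
#' @export
correction_matrix <- function(carbon_count, p = 0.0107) {
  C <- as.integer(carbon_count)
  if (C < 1L) stop("carbon_count must be >= 1", call. = FALSE)
  if (!is.finite(p) || p < 0 || p >= 1)
    stop("natural abundance p must satisfy 0 <= p < 1", call. = FALSE)
  A <- matrix(0, C + 1L, C + 1L)
  for (i in 0:C) {
    # column i: observed M+j for true label count i
    A[(i:C) + 1L, i + 1L] <- stats::dbinom((i:C) - i, size = C - i, prob = p)
  }
  dimnames(A) <- list(paste0("M+", 0:C), paste0("M+", 0:C))
  structure(A, carbon_count = C, p = p, class = c("correction_matrix", "matrix"))
}

#' Forward-apply natural abundance to a true spectrum
#'
#' Convolves a tracer-derived mass isotopomer distribution with the natural
#' 13C background: returns `A %*% x` where A is [correction_matrix()].
#' This is the simulation counterpart of [correct_spectrum()]; the two
#' compose to the identity (round trip).
#'
#' @param spec an [isotopologue_spectrum()] of fractions.
#' @param p natural 13C abundance fraction.
#' @return A fractional spectrum summing to 1.
#' @export
convolve_natural_abundance <- function(spec, p = 0.0107) {
  stopifnot(inherits(spec, "isotopologue_spectrum"))
  if (!spec$is_fraction)
    stop("convolve_natural_abundance expects a fractional spectrum", call. = FALSE)
  A <- correction_matrix(spec$carbon_count, p)
  spec$values <- unname(drop(A %*% spec$values))
  spec
}

#' Correct an observed spectrum for natural 13C abundance
#'
#' Removes the natural-abundance background from an observed mass isotopomer
#' distribution so the fractions reflect tracer-derived labeling only.
#' The default solves the non-negatively constrained least-squares problem
#' min ||A x - observed|| over x >= 0 and renormalizes x to sum 1; plain
#' inversion of A can produce negative fractions under measurement noise,
#' while the constrained solve is deterministic and stable. The
#' unconstrained inverse with clipping is available as
#' `mode = "inverse_clip"` for comparison.
#'
#' @param spec an [isotopologue_spectrum()] of fractions (observed MID).
#' @param p natural 13C abundance fraction.
#' @param mode `"constrained"` (NNLS, default) or `"inverse_clip"`
#'   (solve then clip negatives).
#' @return The corrected fractional spectrum (sums to 1).
#' @examples
#' s <- isotopologue_spectrum("x", c(0.97871449, 0.02117102, 0.00011449),
#'                            is_fraction = TRUE)
#' correct_spectrum(s, 0.0107)$values  # ~ c(1, 0, 0)
#' @export
correct_spectrum <- function(spec, p = 0.0107,
                             mode = c("constrained", "inverse_clip")) {
  stopifnot(inherits(spec, "isotopologue_spectrum"))
  mode <- match.arg(mode)
  if (!spec$is_fraction)
    stop("correct_spectrum expects a fractional spectrum; call to_fractions() first",
         call. = FALSE)
  if (sum(spec$values) <= 0)
    stop("observed spectrum sums to 0", call. = FALSE)
  A <- correction_matrix(spec$carbon_count, p)
  x <- switch(mode,
    constrained = nnls_fit(unclass(A), spec$values)$x,
    inverse_clip = pmax(unname(drop(solve(unclass(A), spec$values))), 0))
  tot <- sum(x)
  if (tot <= 0)
    stop("natural-abundance correction produced an all-zero spectrum",
         call. = FALSE)
  spec$values <- x / tot
  spec
}
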