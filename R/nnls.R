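#' Non-negative least squares by the active-set method
#'
#' Solves min ||A x - b||_2 subject to x >= 0 with the Lawson-Hanson
#' active-set algorithm. For the small dense systems arising here (k <= 3
#' substrates, correction matrices up to ~7x7) the solve is exact and
#' deterministic. Rank-deficient passive sets are handled by dropping the
#' undetermined coordinates (minimum-norm behaviour on the degenerate
#' directions).
#'
#' @param A numeric matrix (m x n).
#' @param b numeric vector of length m.
#' @param tol non-negativity / optimality tolerance, scaled internally by
#'   the problem magnitude.
#' @return A list with `x` (the solution, length n), `residual`
#'   (`||A x - b||_2`) and `deficient` (TRUE if a rank-deficient passive
#'   set was encountered).
#' @examples
#' A <- matrix(c(1, 0.9, 0.9, 1), 2, 2)
#' nnls_fit(A, c(0.1, 0.5))$x  # first coordinate pinned at 0
#' @export
nnls_fit <- function(A, b, tol = 1e-12) {
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  b <- as.numeric(b)
  if (nrow(A) != length(b))
    stop("nrow(A) must equal length(b)", call. = FALSE)
  if (anyNA(A) || any(!is.finite(A)) || anyNA(b) || any(!is.finite(b)))
    stop("non-finite entries in NNLS system", call. = FALSE)
  n <- ncol(A)
  scale <- max(abs(crossprod(A, b)), 1)
  eps <- tol * scale
  x <- numeric(n)
  passive <- logical(n)
  deficient <- FALSE

  ls_on <- function(P) {
    # least squares restricted to passive set P; NA coefs (rank deficiency)
    # are dropped to zero
    z <- numeric(n)
    if (length(P)) {
      cf <- qr.coef(qr(A[, P, drop = FALSE]), b)
      if (anyNA(cf)) {
        deficient <<- TRUE
        cf[is.na(cf)] <- 0
      }
      z[P] <- cf
    }
    z
  }

  outer_iter <- 0L
  max_outer <- 10L * (n + 1L)
  repeat {
    w <- drop(crossprod(A, b - A %*% x))
    free <- which(!passive)
    if (!length(free) || max(w[free]) <= eps) break
    outer_iter <- outer_iter + 1L
    if (outer_iter > max_outer) break
    j <- free[which.max(w[free])]
    passive[j] <- TRUE
    repeat {
      P <- which(passive)
      z <- ls_on(P)
      if (all(z[P] > eps)) {
        x <- z
        break
      }
      Q <- P[z[P] <= eps]
      denom <- x[Q] - z[Q]
      alpha <- suppressWarnings(min(x[Q][denom > 0] / denom[denom > 0]))
      if (!is.finite(alpha)) alpha <- 0
      x <- x + alpha * (z - x)
      passive <- passive & x > eps
      x[!passive] <- 0
      if (!any(passive)) break
    }
  }
  x[x < 0] <- 0
  list(x = x, residual = sqrt(sum((A %*% x - b)^2)), deficient = deficient)
}
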