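#' Assemble the substrate interconversion system
#'
#' Builds the linear system relating direct contribution fractions to
#' observed tracer-normalized labelings. Row t corresponds to the
#' experiment infusing substrate t: `M[t, s]` is the normalized labeling of
#' substrate s under tracer t (`L_s<-t`, unit diagonal since a tracer is
#' fully exchanged with itself), and `L[t]` is the normalized labeling of
#' the product (glucose) under tracer t. Standard errors are carried
#' alongside for Monte Carlo resampling.
#'
#' @param normalized a data frame of normalized labelings with columns
#'   `metabolite`, `tracer`, `value`, `se` (see [normalized_labelings()]).
#' @param substrates ordered substrate names; default
#'   `c("lactate", "glycerol", "alanine")`.
#' @param product product metabolite name; default `"glucose"`.
#' @return A list of class `"contribution_system"` with fields `substrates`,
#'   `product`, `M`, `M_se`, `L`, `L_se`, `n`.
#' @examples
#' nl <- data.frame(
#'   metabolite = c("glycerol", "alanine", "lactate", "alanine", "lactate",
#'                  "glycerol", "glucose", "glucose", "glucose"),
#'   tracer = c("lactate", "lactate", "glycerol", "glycerol", "alanine",
#'              "alanine", "lactate", "glycerol", "alanine"),
#'   value = c(0.5, 0, 0.2, 0, 0, 0, 0.4, 0.3, 0.1), se = 0)
#' build_system(nl)$M
#' @export
build_system <- function(normalized,
                         substrates = c("lactate", "glycerol", "alanine"),
                         product = "glucose") {
  stopifnot(is.data.frame(normalized),
            all(c("metabolite", "tracer", "value", "se") %in% names(normalized)))
  k <- length(substrates)
  look <- function(met, tr) {
    row <- normalized[normalized$metabolite == met & normalized$tracer == tr, ,
                      drop = FALSE]
    if (nrow(row) == 0L)
      stop(sprintf("missing normalized labeling of %s under %s tracer",
                   met, tr), call. = FALSE)
    if (nrow(row) > 1L)
      stop(sprintf("multiple normalized labelings of %s under %s tracer",
                   met, tr), call. = FALSE)
    row
  }
  M <- diag(1, k)
  M_se <- matrix(0, k, k)
  L <- numeric(k)
  L_se <- numeric(k)
  n <- rep(NA_integer_, k)
  dimnames(M) <- dimnames(M_se) <- list(tracer = substrates,
                                        substrate = substrates)
  for (t in seq_len(k)) {
    for (s in seq_len(k)) {
      if (s == t) next
      row <- look(substrates[s], substrates[t])
      M[t, s] <- row$value
      M_se[t, s] <- row$se
    }
    row <- look(product, substrates[t])
    L[t] <- row$value
    L_se[t] <- row$se
    if ("n" %in% names(row)) n[t] <- row$n
  }
  if (any(M < 0) || any(L < 0))
    stop("normalized labelings must be non-negative", call. = FALSE)
  structure(list(substrates = substrates, product = product, M = M,
                 M_se = M_se, L = L, L_se = L_se, n = n),
            class = "contribution_system")
}

#' Solve for non-negative direct contribution fractions
#'
#' Point estimate of the direct contribution fractions f: the minimizer of
#' `||M f - L||_2` subject to `f >= 0` (exact non-negative least squares,
#' active-set method). f is deliberately not constrained to sum to 1: the
#' un-attributed remainder (e.g. glycogenolysis) is meaningful, and the sum
#' is reported alongside.
#'
#' @param system a `"contribution_system"` (see [build_system()]), or a
#'   plain list with fields `M`, `L`, `substrates`.
#' @return A list of class `"contribution_result"` with fields `substrates`,
#'   `f` (non-negative fractions), `f_se` (zeros here; see
#'   [monte_carlo_errors()]), `residual` (`||M f - L||_2`), `n_mc`, `seed`.
#' @examples
#' M <- rbind(c(1, 0.5, 0), c(0.2, 1, 0), c(0, 0, 1))
#' L <- c(0.4, 0.3, 0.1)
#' solve_contributions(list(M = M, L = L,
#'                          substrates = c("lactate", "glycerol", "alanine")))$f
#' @export
solve_contributions <- function(system) {
  M <- as.matrix(system$M)
  L <- as.numeric(system$L)
  substrates <- if (!is.null(system$substrates)) system$substrates
                else paste0("s", seq_len(ncol(M)))
  if (anyNA(M) || any(!is.finite(M)) || anyNA(L) || any(!is.finite(L)))
    stop("non-finite entries in contribution system", call. = FALSE)
  fit <- nnls_fit(M, L)
  if (fit$deficient || (nrow(M) == ncol(M) &&
                        abs(det(M)) < 1e-8 * max(abs(M), 1)))
    warning("interconversion matrix is (near-)singular; returning a feasible minimizer",
            call. = FALSE)
  f <- fit$x
  names(f) <- substrates
  structure(list(substrates = substrates, product = system$product,
                 f = f, f_se = stats::setNames(numeric(length(f)), substrates),
                 f_mc = NULL, residual = fit$residual,
                 n_mc = 1L, seed = NA_integer_),
            class = "contribution_result")
}

#' Monte Carlo error propagation for contribution fractions
#'
#' Propagates the standard errors of the normalized labelings into the
#' contribution fractions by resampling: in each replicate every
#' off-diagonal entry of M and every entry of L is redrawn independently
#' from Normal(mean, SE) (negative draws clamped to 0, labelings being
#' fractions; the diagonal stays at 1), the constrained solve is repeated,
#' and the replicate solutions are pooled. The reported central estimate
#' `f` is the point solve on the mean system; the replicate mean (`f_mc`)
#' and SD (`f_se`) are exported alongside.
#'
#' @param system a `"contribution_system"` with SE fields `M_se`, `L_se`.
#' @param n_mc number of Monte Carlo replicates (default 100).
#' @param seed integer RNG seed; the run is deterministic given the seed.
#' @return A `"contribution_result"` with `f` (point solve), `f_mc`
#'   (replicate mean), `f_se` (replicate SD), `replicates` (n_mc x k
#'   matrix), `residual`, `n_mc`, `seed`.
#' @export
monte_carlo_errors <- function(system, n_mc = 100L, seed = 0L) {
  stopifnot(n_mc >= 1L)
  M <- as.matrix(system$M)
  M_se <- as.matrix(system$M_se)
  L <- as.numeric(system$L)
  L_se <- as.numeric(system$L_se)
  if (anyNA(M_se) || any(!is.finite(M_se)) || anyNA(L_se) || any(!is.finite(L_se)))
    stop("non-finite standard errors in contribution system", call. = FALSE)
  k <- ncol(M)
  point <- solve_contributions(system)
  off <- which(row(M) != col(M))
  reps <- matrix(NA_real_, n_mc, k, dimnames = list(NULL, point$substrates))
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit(restore_rng(old_seed), add = TRUE)
  for (r in seq_len(n_mc)) {
    Mr <- M
    Mr[off] <- pmax(stats::rnorm(length(off), M[off], M_se[off]), 0)
    Lr <- pmax(stats::rnorm(k, L, L_se), 0)
    reps[r, ] <- nnls_fit(Mr, Lr)$x
  }
  out <- point
  out$f_mc <- colMeans(reps)
  out$f_se <- if (n_mc == 1L) stats::setNames(numeric(k), point$substrates)
              else apply(reps, 2, stats::sd)
  out$replicates <- reps
  out$n_mc <- as.integer(n_mc)
  out$seed <- as.integer(seed)
  out
}

restore_rng <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

#' Contributions to an arbitrary product metabolite
#'
#' The mutual-interconversion extension: the same machinery as
#' [build_system()] plus [monte_carlo_errors()] with the product swapped to
#' any measured metabolite (e.g. pyruvate, lactate). When the product is
#' itself one of the substrates, it is removed from the substrate set
#' first, so e.g. contributions to circulating lactate are resolved over
#' \{glycerol, alanine\}.
#'
#' @param normalized data frame of normalized labelings (see
#'   [normalized_labelings()]).
#' @param substrates candidate source substrates.
#' @param product product metabolite.
#' @param n_mc,seed passed to [monte_carlo_errors()].
#' @return A `"contribution_result"`.
#' @export
interconversion_contributions <- function(normalized,
                                          substrates = c("lactate", "glycerol",
                                                         "alanine"),
                                          product = "glucose",
                                          n_mc = 100L, seed = 0L) {
  subs <- setdiff(substrates, product)
  if (!length(subs))
    stop("no substrates left after removing the product", call. = FALSE)
  if (!product %in% normalized$metabolite)
    stop(sprintf("product %s not among measured metabolites", product),
         call. = FALSE)
  system <- build_system(normalized, substrates = subs, product = product)
  monte_carlo_errors(system, n_mc = n_mc, seed = seed)
}

#' @export
print.contribution_result <- function(x, digits = 4, ...) {
  cat(sprintf("Direct contributions to %s (NNLS",
              if (is.null(x$product) || is.na(x$product)) "product" else x$product))
  if (x$n_mc > 1L)
    cat(sprintf(", %d Monte Carlo replicates, seed %d", x$n_mc, x$seed))
  cat(")\n")
  tab <- data.frame(fraction = x$f, se = x$f_se)
  print(round(tab, digits))
  cat(sprintf("sum(f) = %.*f   residual ||Mf - L|| = %.3g\n",
              digits, sum(x$f), x$residual))
  invisible(x)
}
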