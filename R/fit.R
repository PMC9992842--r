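#' Fit direct contribution fractions from tracer infusion data
#'
#' The full analysis for a steady-state U-13C tracer infusion study: from
#' raw serum isotopologue intensities and tracer metadata to the
#' non-negative direct contribution fractions of circulating substrates
#' (by default lactate, glycerol, alanine) to a product metabolite (by
#' default glucose), with Monte Carlo standard errors.
#'
#' The pipeline is: (i) convert each measured spectrum to fractions and
#' correct for natural 13C abundance ([correct_spectrum()]); (ii) reduce
#' each corrected spectrum to its atom-labeling fraction
#' ([atom_labeling()]); (iii) normalize by the serum labeling of the
#' infused tracer and aggregate animals ([normalized_labelings()]);
#' (iv) assemble the interconversion system M, L ([build_system()]) and
#' solve min ||M f - L|| subject to f >= 0, propagating the labeling SEs by
#' Monte Carlo resampling ([monte_carlo_errors()]).
#'
#' @param measurements isotopologue intensity table: a CSV path, data
#'   frame, or `"isotopologue_set"` (see [read_isotopologue_table()]).
#' @param tracers tracer metadata: CSV path or data frame (see
#'   [read_tracer_metadata()]).
#' @param substrates ordered substrate names.
#' @param product product metabolite name.
#' @param p natural 13C abundance fraction (default 0.0107).
#' @param correction natural-abundance correction mode,
#'   `"constrained"` or `"inverse_clip"`.
#' @param order replicate aggregation order for normalized labelings,
#'   `"per_animal"` or `"pooled"` (see [normalized_labelings()]).
#' @param n_mc Monte Carlo replicates for error propagation (default 100).
#' @param seed integer RNG seed for the Monte Carlo draws (default 0).
#' @return An object of class `"gng_contrib"`: a list with the fitted
#'   result (`f`, `f_se`, `f_mc`, `residual`), the assembled `system`, the
#'   `normalized` labeling table, and the call. Methods: [print()],
#'   [summary()], [coef()], [residuals()], [plot()], [simulate()].
#' @examples
#' truth <- synthetic_truth(seed = 1)
#' sim <- generate_experiment(truth)
#' fit <- gng_contrib(sim$measurements, sim$tracers, seed = 1)
#' coef(fit)
#' @export
gng_contrib <- function(measurements, tracers,
                        substrates = c("lactate", "glycerol", "alanine"),
                        product = "glucose", p = 0.0107,
                        correction = c("constrained", "inverse_clip"),
                        order = c("per_animal", "pooled"),
                        n_mc = 100L, seed = 0L) {
  correction <- match.arg(correction)
  order <- match.arg(order)
  normalized <- normalized_labelings(measurements, tracers, p = p,
                                     correction = correction, order = order)
  subs <- setdiff(substrates, product)
  system <- build_system(normalized, substrates = subs, product = product)
  result <- monte_carlo_errors(system, n_mc = n_mc, seed = seed)
  structure(list(call = match.call(), substrates = subs, product = product,
                 f = result$f, f_se = result$f_se, f_mc = result$f_mc,
                 replicates = result$replicates, residual = result$residual,
                 n_mc = result$n_mc, seed = result$seed,
                 system = system, normalized = normalized,
                 p = p, correction = correction, order = order),
            class = "gng_contrib")
}

#' @export
print.gng_contrib <- function(x, digits = 4, ...) {
  cat("Direct contribution of circulating substrates to", x$product, "\n\n")
  tab <- data.frame(fraction = x$f, se = x$f_se)
  print(round(tab, digits))
  cat(sprintf("\nsum(f) = %.*f (unattributed remainder %.*f)\n",
              digits, sum(x$f), digits, 1 - sum(x$f)))
  cat(sprintf("residual ||Mf - L|| = %.3g; %d Monte Carlo replicates (seed %d)\n",
              x$residual, x$n_mc, x$seed))
  invisible(x)
}

#' @export
summary.gng_contrib <- function(object, ...) {
  structure(list(fit = object), class = "summary.gng_contrib")
}

#' @export
print.summary.gng_contrib <- function(x, digits = 4, ...) {
  fit <- x$fit
  print(fit, digits = digits)
  cat("\nInterconversion matrix M (rows = tracer experiments):\n")
  print(round(fit$system$M, digits))
  cat("\nProduct normalized labeling L:\n")
  L <- fit$system$L
  names(L) <- fit$substrates
  print(round(L, digits))
  cat("\nMonte Carlo replicate mean of f:\n")
  print(round(fit$f_mc, digits))
  invisible(x)
}

#' @export
coef.gng_contrib <- function(object, ...) object$f

#' Residuals of the interconversion system at the fitted fractions
#'
#' Returns `M %*% f - L` per tracer experiment: how far each observed
#' product labeling is from the value implied by the fitted fractions.
#'
#' @param object a fitted `"gng_contrib"`.
#' @param ... unused.
#' @export
residuals.gng_contrib <- function(object, ...) {
  r <- drop(object$system$M %*% object$f) - object$system$L
  names(r) <- object$substrates
  r
}

#' Draw Monte Carlo replicates of the contribution fractions
#'
#' Redraws the system entries from Normal(mean, SE) and re-solves, exactly
#' as in the fitted object's error propagation, returning the replicate
#' solutions.
#'
#' @param object a fitted `"gng_contrib"`.
#' @param nsim number of replicates.
#' @param seed RNG seed; defaults to the fit's own seed.
#' @param ... unused.
#' @return An `nsim` x k matrix of non-negative fraction vectors.
#' @export
simulate.gng_contrib <- function(object, nsim = object$n_mc,
                                 seed = object$seed, ...) {
  monte_carlo_errors(object$system, n_mc = nsim, seed = seed)$replicates
}

#' Plot fitted contribution fractions
#'
#' Bar plot of the fractions with +/- 1 SE error bars.
#'
#' @param x a fitted `"gng_contrib"`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.gng_contrib <- function(x, ...) {
  up <- x$f + x$f_se
  mids <- graphics::barplot(x$f, ylim = c(0, max(up) * 1.15),
                            ylab = sprintf("direct contribution to %s",
                                           x$product),
                            ...)
  has_se <- x$f_se > 0
  if (any(has_se))
    graphics::arrows(mids[has_se], (x$f - x$f_se)[has_se],
                     mids[has_se], up[has_se],
                     angle = 90, code = 3, length = 0.06)
  invisible(mids)
}
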