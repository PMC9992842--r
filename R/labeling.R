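#' Atom labeling fraction of a corrected spectrum
#'
#' The overall 13C labeling of a metabolite: the weighted average of
#' atomized labeling over all isotopologues,
#' `L = sum_i (i / C) * L[M+i]`, i.e. the fraction of the metabolite's
#' carbon atoms that are 13C. Expects fractions already corrected for
#' natural abundance.
#'
#' @param spec an [isotopologue_spectrum()] of (corrected) fractions.
#' @return A number in \[0, 1\].
#' @examples
#' s <- isotopologue_spectrum("x", c(0.4, 0.3, 0.2, 0.1), is_fraction = TRUE)
#' atom_labeling(s)  # 1/3
#' @export
atom_labeling <- function(spec) {
  stopifnot(inherits(spec, "isotopologue_spectrum"))
  if (!spec$is_fraction)
    stop("atom_labeling expects a fractional spectrum", call. = FALSE)
  C <- spec$carbon_count
  sum((0:C) / C * spec$values)
}

#' Aggregate replicate labeling values
#'
#' Mean and standard error (sample SD / sqrt(n)) of per-animal atom-labeling
#' fractions. A single replicate yields SE = 0 with a warning.
#'
#' @param values numeric vector of labeling fractions, one per replicate.
#' @param metabolite,experiment optional labels carried into the estimate.
#' @return A list of class `"labeling_estimate"` with fields `metabolite`,
#'   `experiment`, `mean_L`, `se_L`, `n`.
#' @examples
#' aggregate_replicates(c(0.2, 0.3, 0.4))  # mean 0.3, se 0.1/sqrt(3)
#' @export
aggregate_replicates <- function(values, metabolite = NA_character_,
                                 experiment = NA_character_) {
  values <- as.numeric(values)
  if (!length(values)) stop("no replicate values", call. = FALSE)
  if (anyNA(values)) stop("NA replicate values", call. = FALSE)
  n <- length(values)
  if (n == 1L) {
    warning("single replicate: SE set to 0", call. = FALSE)
    se <- 0
  } else {
    se <- stats::sd(values) / sqrt(n)
  }
  structure(list(metabolite = as.character(metabolite),
                 experiment = as.character(experiment),
                 mean_L = mean(values), se_L = se, n = n),
            class = "labeling_estimate")
}

#' Tracer-normalized labeling
#'
#' The labeling of a metabolite normalized by the serum labeling of the
#' infused tracer: `L_metabolite_from_tracer = L_metabolite / L_tracer`.
#' A value near 1 means full exchange with the tracer pool. The SE is
#' propagated by the first-order delta method for a ratio,
#' `se = value * sqrt((se_p / mean_p)^2 + (se_t / mean_t)^2)`, with the
#' product term dropped when the numerator mean is 0. Values above 1
#' (possible under noise) are retained, not clipped, so downstream solves
#' see unbiased inputs; values above 1.05 raise a warning.
#'
#' @param product a `"labeling_estimate"` for the downstream metabolite.
#' @param tracer_serum a `"labeling_estimate"` for the infused tracer
#'   measured in serum.
#' @return A list of class `"normalized_labeling"` with fields `metabolite`,
#'   `tracer`, `value`, `se`, `n`.
#' @export
normalized_labeling <- function(product, tracer_serum) {
  stopifnot(inherits(product, "labeling_estimate"),
            inherits(tracer_serum, "labeling_estimate"))
  if (tracer_serum$mean_L <= 0)
    stop("tracer serum labeling <= 0: tracer did not circulate", call. = FALSE)
  value <- product$mean_L / tracer_serum$mean_L
  rel_t <- tracer_serum$se_L / tracer_serum$mean_L
  se <- if (product$mean_L == 0) {
    # delta-method limit at zero numerator: the term carrying the product
    # mean vanishes and only the numerator SE propagates
    product$se_L / tracer_serum$mean_L
  } else {
    value * sqrt((product$se_L / product$mean_L)^2 + rel_t^2)
  }
  if (value > 1.05)
    warning(sprintf("normalized labeling %.4g > 1.05 for %s under %s tracer",
                    value, product$metabolite, tracer_serum$metabolite),
            call. = FALSE)
  structure(list(metabolite = product$metabolite,
                 tracer = tracer_serum$metabolite,
                 value = value, se = se,
                 n = min(product$n, tracer_serum$n)),
            class = "normalized_labeling")
}

#' Per-experiment normalized labelings from measured spectra
#'
#' The full measurement-to-labeling path for a set of tracer experiments:
#' raw spectra are converted to fractions, corrected for natural abundance,
#' reduced to atom-labeling fractions, normalized by the serum labeling of
#' the infused tracer, and aggregated over animals.
#'
#' Two aggregation orders are supported. `"per_animal"` (default) forms the
#' ratio within each animal (tracer and product measured in the same serum
#' sample) and then averages the ratios, so animal-level variation in
#' tracer enrichment cancels. `"pooled"` averages labelings across animals
#' first and takes one ratio of means, with a delta-method SE.
#'
#' @param measurements an `"isotopologue_set"` (see
#'   [read_isotopologue_table()]), a data frame, or a CSV path.
#' @param tracers tracer metadata (see [read_tracer_metadata()]), a data
#'   frame, or a CSV path.
#' @param p natural 13C abundance used for correction.
#' @param correction correction mode passed to [correct_spectrum()].
#' @param order `"per_animal"` or `"pooled"` (see Details).
#' @return A data frame with one row per (metabolite, tracer experiment):
#'   columns `metabolite`, `tracer`, `experiment`, `value`, `se`, `n`.
#' @export
normalized_labelings <- function(measurements, tracers, p = 0.0107,
                                 correction = c("constrained", "inverse_clip"),
                                 order = c("per_animal", "pooled")) {
  correction <- match.arg(correction)
  order <- match.arg(order)
  if (!inherits(measurements, "isotopologue_set"))
    measurements <- read_isotopologue_table(measurements)
  tracers <- read_tracer_metadata(tracers)

  # atom labeling per (sample, metabolite) after correction
  lab <- vapply(measurements, function(s) {
    atom_labeling(correct_spectrum(to_fractions(s), p = p, mode = correction))
  }, numeric(1))
  samp <- vapply(measurements, `[[`, character(1), "sample")
  met <- vapply(measurements, `[[`, character(1), "metabolite")

  out <- list()
  for (exp_id in unique(tracers$experiment)) {
    meta <- tracers[tracers$experiment == exp_id, , drop = FALSE]
    tr <- unique(meta$tracer_metabolite)
    if (length(tr) != 1L)
      stop(sprintf("experiment %s names multiple tracers", exp_id), call. = FALSE)
    animals <- meta$sample
    in_exp <- samp %in% animals
    if (!all(animals %in% samp[in_exp & met == tr]))
      stop(sprintf(
        "tracer %s not measured in every sample of experiment %s", tr, exp_id),
        call. = FALSE)
    tr_lab <- lab[in_exp & met == tr]
    names(tr_lab) <- samp[in_exp & met == tr]
    for (m in unique(met[in_exp])) {
      sel <- in_exp & met == m
      m_lab <- lab[sel]
      names(m_lab) <- samp[sel]
      common <- intersect(names(m_lab), names(tr_lab))
      if (order == "per_animal") {
        if (any(tr_lab[common] <= 0))
          stop(sprintf(
            "tracer %s shows zero serum labeling in experiment %s", tr, exp_id),
            call. = FALSE)
        est <- aggregate_replicates(m_lab[common] / tr_lab[common],
                                    metabolite = m, experiment = exp_id)
        nl <- structure(list(metabolite = m, tracer = tr, value = est$mean_L,
                             se = est$se_L, n = est$n),
                        class = "normalized_labeling")
        if (nl$value > 1.05)
          warning(sprintf(
            "normalized labeling %.4g > 1.05 for %s under %s tracer",
            nl$value, m, tr), call. = FALSE)
      } else {
        nl <- normalized_labeling(
          aggregate_replicates(m_lab[common], metabolite = m, experiment = exp_id),
          aggregate_replicates(tr_lab[common], metabolite = tr, experiment = exp_id))
      }
      out[[length(out) + 1L]] <- data.frame(
        metabolite = m, tracer = tr, experiment = exp_id,
        value = nl$value, se = nl$se, n = nl$n, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
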