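#' Ground truth for a synthetic tracer infusion study
#'
#' Full parameterization of the forward simulator: the study design it
#' emulates is a set of steady-state U-13C infusions (one tracer per
#' experiment, n animals each) with serum sampled during the infusion, plus
#' measurement of all substrates and the product in every sample.
#'
#' Defaults describe three substrate tracers (lactate, glycerol, alanine;
#' all C3) plus a glucose (C6) tracer experiment, n = 6 animals per tracer,
#' true direct contributions f = (0.5, 0.3, 0.1), lactate-alanine
#' interconversion via the shared pyruvate pool (cross-labelings 0.30 and
#' 0.25), a nearly inert glycerol pool, serum tracer enrichments of
#' 0.25-0.45, 5% multiplicative measurement noise per isotopologue, and
#' natural 13C abundance 0.0107.
#'
#' @param f_true named non-negative contribution fractions, sum <= 1.
#' @param cross_labeling k x k matrix of normalized cross-labelings
#'   `L_s<-t` (rows = tracer experiment, cols = substrate), unit diagonal,
#'   off-diagonals in \[0, 1).
#' @param tracer_serum_enrichment named serum atom-labeling of each infused
#'   tracer, in (0, 1].
#' @param product_cross normalized labeling of each substrate under the
#'   product (glucose) tracer, used only when `include_product_tracer`.
#' @param carbon_counts named integer carbon counts for all metabolites.
#' @param product product metabolite name.
#' @param include_product_tracer also simulate the product-tracer infusion
#'   (not needed to fit f, but part of the four-tracer design).
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   measurement noise applied per isotopologue.
#' @param n_animals animals per tracer experiment.
#' @param group group label recorded in the tracer metadata.
#' @param p natural 13C abundance.
#' @param seed master integer seed; per-(tracer, animal) streams are
#'   derived from it by fixed offsets so adding animals does not reshuffle
#'   existing ones.
#' @return A list of class `"synthetic_truth"`.
#' @export
synthetic_truth <- function(f_true = c(lactate = 0.5, glycerol = 0.3,
                                       alanine = 0.1),
                            cross_labeling = default_cross_labeling(names(f_true)),
                            tracer_serum_enrichment = c(lactate = 0.35,
                                                        glycerol = 0.25,
                                                        alanine = 0.30,
                                                        glucose = 0.45),
                            product_cross = c(lactate = 0.15, glycerol = 0.01,
                                              alanine = 0.10),
                            carbon_counts = c(lactate = 3, glycerol = 3,
                                              alanine = 3, glucose = 6,
                                              pyruvate = 3),
                            product = "glucose",
                            include_product_tracer = TRUE,
                            noise_cv = 0.05, n_animals = 6L,
                            group = "control", p = 0.0107, seed = 0L) {
  substrates <- names(f_true)
  k <- length(substrates)
  stopifnot(k >= 1L, !is.null(substrates))
  if (any(f_true < 0) || sum(f_true) > 1 + 1e-12)
    stop("f_true must be non-negative with sum <= 1", call. = FALSE)
  cross_labeling <- as.matrix(cross_labeling)
  stopifnot(identical(dim(cross_labeling), c(k, k)))
  if (any(abs(diag(cross_labeling) - 1) > 1e-12))
    stop("cross_labeling must have a unit diagonal", call. = FALSE)
  off <- cross_labeling[row(cross_labeling) != col(cross_labeling)]
  if (any(off < 0) || any(off >= 1))
    stop("off-diagonal cross-labelings must lie in [0, 1)", call. = FALSE)
  need_tr <- c(substrates, if (include_product_tracer) product)
  if (!all(need_tr %in% names(tracer_serum_enrichment)))
    stop("tracer_serum_enrichment must name every infused tracer", call. = FALSE)
  e <- tracer_serum_enrichment[need_tr]
  if (any(e <= 0 | e > 1))
    stop("tracer serum enrichments must lie in (0, 1]", call. = FALSE)
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  if (isTRUE(include_product_tracer)) {
    if (!all(substrates %in% names(product_cross)))
      stop("product_cross must name every substrate", call. = FALSE)
    if (any(product_cross < 0 | product_cross >= 1))
      stop("product_cross values must lie in [0, 1)", call. = FALSE)
  }
  if (!all(c(substrates, product) %in% names(carbon_counts)))
    stop("carbon_counts must name every metabolite", call. = FALSE)
  dimnames(cross_labeling) <- list(tracer = substrates, substrate = substrates)
  structure(list(substrates = substrates, product = product,
                 f_true = f_true, cross_labeling = cross_labeling,
                 tracer_serum_enrichment = tracer_serum_enrichment,
                 product_cross = product_cross,
                 carbon_counts = carbon_counts,
                 include_product_tracer = isTRUE(include_product_tracer),
                 noise_cv = noise_cv, n_animals = as.integer(n_animals),
                 group = group, p = p, seed = as.integer(seed)),
            class = "synthetic_truth")
}

# lactate and alanine exchange via the shared pyruvate pool; glycerol is
# nearly inert
default_cross_labeling <- function(substrates) {
  k <- length(substrates)
  M <- diag(1, k)
  dimnames(M) <- list(substrates, substrates)
  set_if <- function(t, s, v) {
    if (all(c(t, s) %in% substrates)) M[t, s] <<- v
  }
  set_if("lactate", "alanine", 0.30)
  set_if("lactate", "glycerol", 0.02)
  set_if("glycerol", "lactate", 0.05)
  set_if("glycerol", "alanine", 0.03)
  set_if("alanine", "lactate", 0.25)
  set_if("alanine", "glycerol", 0.02)
  M
}

#' Exact normalized labelings implied by a ground truth
#'
#' The noiseless normalized-labeling table the simulator targets: the
#' cross-labelings themselves for substrate pairs, and for the product the
#' consistency value `L_product<-t = sum_s M[t, s] f_s`, so that solving
#' the assembled system recovers `f_true` exactly (when M is well
#' conditioned; a near-singular M triggers a warning).
#'
#' @param truth a [synthetic_truth()].
#' @return A data frame with columns `metabolite`, `tracer`, `value`,
#'   `se` (0), `n`.
#' @export
forward_labelings <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  M <- truth$cross_labeling
  if (abs(det(M)) < 1e-8)
    warning("cross-labeling matrix is near-singular (|det M| < 1e-8)",
            call. = FALSE)
  Lprod <- drop(M %*% truth$f_true)
  rows <- list()
  add <- function(met, tr, value)
    rows[[length(rows) + 1L]] <<- data.frame(
      metabolite = met, tracer = tr, value = value, se = 0,
      n = truth$n_animals, stringsAsFactors = FALSE)
  for (t in truth$substrates) {
    for (s in truth$substrates) add(s, t, M[t, s])
    add(truth$product, t, Lprod[[t]])
  }
  if (truth$include_product_tracer) {
    for (s in truth$substrates) add(s, truth$product,
                                    truth$product_cross[[s]])
    add(truth$product, truth$product, 1)
  }
  do.call(rbind, rows)
}

#' Binomial mass isotopomer distribution for a given atom labeling
#'
#' The generative MID model of the simulator: each of the C carbon atoms is
#' independently 13C with probability L, so
#' `L[M+i] = choose(C, i) L^i (1-L)^(C-i)`. Real metabolism produces
#' non-binomial MIDs, but the inference pipeline consumes only the atom
#' labeling, which this model preserves exactly:
#' `atom_labeling(spectrum_from_labeling(L, C)) == L`.
#'
#' @param L atom labeling fraction in \[0, 1\].
#' @param C integer carbon count.
#' @param metabolite,sample labels for the resulting spectrum.
#' @return An [isotopologue_spectrum()] of fractions.
#' @examples
#' spectrum_from_labeling(0.3, 3)$values  # 0.343 0.441 0.189 0.027
#' @export
spectrum_from_labeling <- function(L, C, metabolite = "synthetic",
                                   sample = NA_character_) {
  stopifnot(L >= 0, L <= 1)
  isotopologue_spectrum(metabolite, stats::dbinom(0:C, C, L),
                        carbon_count = C, is_fraction = TRUE, sample = sample)
}

#' Simulate a full tracer infusion study
#'
#' Generates the measurement tables of a synthetic study: for each tracer
#' experiment and animal, the exact atom labelings from
#' [forward_labelings()] are turned into binomial spectra, convolved with
#' natural abundance at `truth$p`, perturbed by multiplicative lognormal
#' noise per isotopologue (CV `truth$noise_cv`, unit mean), and scaled to
#' raw-intensity magnitude. Deterministic given `truth$seed`; the RNG
#' stream of each (tracer, animal) pair is derived from the master seed by
#' fixed offsets.
#'
#' @param truth a [synthetic_truth()].
#' @param out_dir if non-NULL, also write `measurements.csv` and
#'   `tracers.csv` there (floats at 12 significant digits; byte-identical
#'   across runs with the same seed).
#' @return A list with `measurements` (isotopologue intensity table),
#'   `tracers` (metadata table), `labelings` (the exact noiseless
#'   normalized labelings), and `truth`.
#' @export
generate_experiment <- function(truth, out_dir = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  exact <- forward_labelings(truth)
  tracers_run <- c(truth$substrates,
                   if (truth$include_product_tracer) truth$product)
  measured <- unique(c(truth$substrates, truth$product))
  base_intensity <- 1e6
  sdlog <- sqrt(log(1 + truth$noise_cv^2))

  meas <- list()
  meta <- list()
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old_seed), add = TRUE)
  for (it in seq_along(tracers_run)) {
    tr <- tracers_run[it]
    e_t <- truth$tracer_serum_enrichment[[tr]]
    exp_id <- paste0("U13C_", tr)
    # atom labeling of each measured metabolite in this experiment
    lab <- vapply(measured, function(m) {
      nl <- exact$value[exact$metabolite == m & exact$tracer == tr]
      nl * e_t
    }, numeric(1))
    for (a in seq_len(truth$n_animals)) {
      sub_seed <- (truth$seed %% 1000L) * 1000003 + it * 131071 + a * 7919
      set.seed(as.integer(sub_seed %% 2147483647))
      samp <- sprintf("%s_m%02d", tr, a)
      for (m in measured) {
        C <- as.integer(truth$carbon_counts[[m]])
        mid <- spectrum_from_labeling(lab[[m]], C, metabolite = m,
                                      sample = samp)
        obs <- convolve_natural_abundance(mid, p = truth$p)$values
        if (truth$noise_cv > 0)
          obs <- obs * stats::rlnorm(C + 1L, meanlog = -sdlog^2 / 2,
                                     sdlog = sdlog)
        meas[[length(meas) + 1L]] <- data.frame(
          sample = samp, metabolite = m, carbon_count = C,
          isotopologue_index = 0:C, intensity = base_intensity * obs,
          stringsAsFactors = FALSE)
      }
      meta[[length(meta) + 1L]] <- data.frame(
        experiment = exp_id, tracer_metabolite = tr,
        tracer_carbons = as.integer(truth$carbon_counts[[tr]]),
        sample = samp, group = truth$group, stringsAsFactors = FALSE)
    }
  }
  measurements <- do.call(rbind, meas)
  tracers <- do.call(rbind, meta)
  rownames(measurements) <- rownames(tracers) <- NULL
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    mtxt <- measurements
    mtxt$intensity <- format_sig(mtxt$intensity)
    utils::write.csv(mtxt, file.path(out_dir, "measurements.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(tracers, file.path(out_dir, "tracers.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  list(measurements = measurements, tracers = tracers, labelings = exact,
       truth = truth)
}
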