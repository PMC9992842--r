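#' Percent 13C enrichment of a corrected spectrum
#'
#' `100 * atom_labeling(spec)`: the percentage of a metabolite's carbon
#' atoms that are 13C, computed from natural-abundance-corrected fractions.
#' Shares the [atom_labeling()] code path exactly.
#'
#' @param spec an [isotopologue_spectrum()] of corrected fractions.
#' @return A percentage in \[0, 100\].
#' @export
percent_enrichment <- function(spec) {
  100 * atom_labeling(spec)
}

#' Protein-normalized 13C-labeled pool size
#'
#' The relative size of the tracer-derived pool of a metabolite in an
#' isolated-mitochondria incubation:
#' `(total_intensity * atom_labeling) / protein_conc`. Used to compare the
#' flux of 13C-pyruvate carbon into TCA intermediates across genotypes on a
#' per-mitochondrial-protein basis.
#'
#' @param spec an [isotopologue_spectrum()] of corrected fractions.
#' @param total_intensity summed raw intensity of the metabolite's
#'   isotopologues (arbitrary units).
#' @param protein_conc mitochondrial protein concentration (ug/mL), > 0.
#' @return Labeled pool size in intensity units per (ug/mL).
#' @export
labeled_pool_per_protein <- function(spec, total_intensity, protein_conc) {
  if (!is.finite(protein_conc) || protein_conc <= 0)
    stop("protein_conc must be > 0", call. = FALSE)
  total_intensity * atom_labeling(spec) / protein_conc
}

#' Enrichment summaries for isolated-mitochondria tracer incubations
#'
#' For each (sample, metabolite) in a U-13C-pyruvate incubation of isolated
#' mitochondria, computes the natural-abundance-corrected percent 13C
#' enrichment, the protein-normalized labeled pool size, and the fraction
#' of the fully labeled M+3 species (for 3-carbon intermediates the species
#' arriving intact from U-13C pyruvate). Both the atom-enrichment and the
#' species-specific summary are emitted since either may be the quantity of
#' interest.
#'
#' @param measurements isotopologue intensity table (CSV path, data frame,
#'   or `"isotopologue_set"`).
#' @param protein data frame or CSV path with columns `sample`,
#'   `protein_conc` (ug/mL).
#' @param p natural 13C abundance fraction.
#' @return A data frame with columns `sample`, `metabolite`,
#'   `percent_enrichment`, `labeled_pool`, `m3_percent`.
#' @export
mito_enrichment <- function(measurements, protein, p = 0.0107) {
  if (!inherits(measurements, "isotopologue_set"))
    measurements <- read_isotopologue_table(measurements)
  if (!is.data.frame(protein))
    protein <- utils::read.csv(protein, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "protein_conc") %in% names(protein)))
  if (any(protein$protein_conc <= 0))
    stop("protein_conc must be > 0 for every sample", call. = FALSE)
  pc <- stats::setNames(protein$protein_conc, protein$sample)
  rows <- lapply(measurements, function(s) {
    if (!s$sample %in% names(pc))
      stop(sprintf("no protein concentration for sample %s", s$sample),
           call. = FALSE)
    total <- sum(s$values)
    corr <- correct_spectrum(to_fractions(s), p = p)
    m3 <- if (corr$carbon_count >= 3L) 100 * corr$values[4L] else NA_real_
    data.frame(sample = s$sample, metabolite = s$metabolite,
               percent_enrichment = percent_enrichment(corr),
               labeled_pool = labeled_pool_per_protein(corr, total,
                                                       pc[[s$sample]]),
               m3_percent = m3, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
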