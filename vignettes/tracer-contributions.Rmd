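---
title: "Estimating direct substrate contributions to glucose from 13C tracer infusions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating direct substrate contributions to glucose from 13C tracer infusions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(gngtrace)
```

## The problem

Fasting glucose is produced largely by hepatic gluconeogenesis from
circulating precursors: lactate, glycerol and alanine. A steady-state
infusion study measures, for each U-¹³C tracer in turn, the serum mass
isotopomer distributions (MIDs) of all substrates and of glucose. The
quantity of interest is the *direct* contribution fraction of each
substrate to glucose carbon — what remains after the indirect routes
(label passing through another substrate first, e.g. lactate → alanine →
glucose) are removed algebraically.

`gngtrace` implements that computation end to end: natural-abundance
correction of MIDs, atom-labeling and tracer-normalized labeling,
assembly and constrained solution of the interconversion system, Monte
Carlo error propagation, and a forward simulator used to validate the
pipeline by parameter recovery.

## Model and assumptions

**Atom labeling.** For a metabolite with C carbons and corrected
isotopologue fractions `L[M+i]`, the overall labeling is the weighted
average `L = Σ (i/C) L[M+i]` — the fraction of the molecule's carbon atoms
that are ¹³C. This discards positional information deliberately; the whole
pipeline operates on whole-molecule carbon fractions.

**Normalization.** Labelings are divided by the *serum* labeling of the
infused tracer (not the infusate's nominal enrichment), so a value of 1
means full exchange with the circulating tracer pool. Normalized labelings
slightly above 1 can arise from noise; they are retained unclipped so the
solver sees unbiased inputs (a warning fires above 1.05).

**The matrix equation.** With substrates ordered as rows/columns, row t of
the k×k matrix M holds the normalized labelings of each substrate under
tracer t (unit diagonal); L holds the product's normalized labelings. The
direct fractions solve `min ‖Mf − L‖₂, f ≥ 0`. Key assumptions: isotopic
and metabolic steady state during the infusion; one well-mixed circulating
pool per metabolite (no compartments, no kinetics); linearity of label
transfer. The fractions are *not* constrained to sum to 1 — the shortfall
is the share not attributed to the measured substrates (glycogenolysis,
other precursors) and is reported as such.

**Error propagation.** Every off-diagonal entry of M and every entry of L
carries a standard error from the between-animal spread. Each Monte Carlo
replicate redraws all entries independently from Normal(mean, SE), clamps
negative draws to 0 (labelings are fractions), keeps the diagonal at 1,
and re-solves. Entries are sampled independently because the per-animal
pairing needed to estimate covariances is generally not available at this
stage. The reported central estimate is the point solve on the mean
system; the replicate mean and SD are exported alongside (`f_mc`, `f_se`).
With 100 replicates (the default) component SEs are reproducible to
roughly ±15% relative, which the calibration tests verify against
10,000-replicate runs.

## Natural-abundance correction

Each carbon that is not tracer-derived is ¹³C with probability
p = 0.0107 (standard terrestrial abundance; `natural_abundance_p` is a
parameter since instrument-calibrated values differ in the third decimal).
The observed MID is therefore the true MID convolved with a binomial
background: `A[j, i] = choose(C−i, j−i) p^(j−i) (1−p)^(C−j)`, a
column-stochastic lower-triangular matrix. Correction inverts this.

Two modes are provided. The default solves the non-negatively constrained
least-squares problem and renormalizes, because plain inversion of A can
produce negative fractions under measurement noise; `"inverse_clip"`
(invert, clip, renormalize) is kept for comparison — on noiseless data the
two agree to machine precision. Only carbon is corrected: for the small
gluconeogenic metabolites considered here the ¹³C term dominates the
H/N/O isotope effects, and tracer isotopic impurity is not modeled.

## The solver

The core solve is exact non-negative least squares via the Lawson–Hanson
active-set method (`nnls_fit()`). The systems are tiny (k ≤ 3 for the
contribution problem, up to ~7×7 for MID correction), so the active-set
iteration terminates in a handful of steps and is fully deterministic.
Rank-deficient passive sets (a structurally singular M) are handled by
dropping undetermined coordinates, returning a feasible minimizer with a
warning. Optimality is tested two ways: against `pracma::lsqnonneg` as an
independent implementation, and against a brute-force evaluation of the
objective on the grid {0, 10⁻³, …, 1}ᵏ. The grid oracle enumerates the
outer k−1 coordinates and resolves the innermost analytically — a
univariate convex quadratic on a uniform grid attains its minimum at the
floor/ceil neighbors of the clamped continuous argmin — so it evaluates
the full grid exactly without touching all 10⁹ points at k = 3.

## Mutual interconversions and mitochondrial enrichment

`interconversion_contributions()` re-targets the same machinery at any
measured product (pyruvate, lactate, …). When the product is itself a
substrate it is removed from the substrate set first, so contributions to
circulating lactate are resolved over {glycerol, alanine}. The tracer's
contribution to its own pool is thus reported from the reduced system, not
fixed at a conventional value of 1 — the reduced solve is the convention
here, stated explicitly since either reading is defensible.

For isolated-mitochondria U-¹³C-pyruvate incubations,
`mito_enrichment()` reports, per sample and metabolite, (i) percent
enrichment (100 × atom labeling, sharing the same code path), which is
invariant to uniform intensity rescaling, and (ii) the protein-normalized
labeled pool, `total intensity × labeling / protein concentration`
(units: intensity per µg/mL), for genotype comparisons of absolute label
uptake. Both are emitted — together with the M+3 species percentage —
because "relative contribution to a metabolite" can reasonably mean
either the atom-enrichment or the species-specific summary.

## What the simulator emulates — and what it does not

`synthetic_truth()` describes a four-tracer design: U-¹³C infusions of
lactate, glycerol, alanine and glucose with n = 6 animals per tracer and
serum sampling at steady state, matching the infusion-study layout the
package targets. Defaults, chosen once as physiologically plausible:

- `f_true = (0.5, 0.3, 0.1)` for lactate, glycerol, alanine — lactate the
  dominant precursor, ~10% unattributed;
- cross-labelings: lactate ↔ alanine 0.30/0.25 (both exchange through the
  pyruvate pool), glycerol nearly inert (0.02–0.05). Real magnitudes are
  not established quantities; these are documented placeholders with the
  qualitative structure right;
- serum tracer enrichments 0.25–0.45 — the range typical of primed
  continuous infusions;
- `noise_cv = 0.05`: 5% multiplicative lognormal noise per isotopologue,
  applied at the *measurement* stage (to intensities, before correction)
  so correction and aggregation are genuinely exercised;
- `p = 0.0107`, applied by forward convolution before noise.

MIDs are generated by the positional-binomial model
(`spectrum_from_labeling()`): each carbon independently labeled with
probability L. Real metabolism produces distinctly non-binomial MIDs
(e.g. glucose made from two labeled trioses is enriched in M+3/M+6), but
the inference pipeline consumes only atom labeling, which the binomial
model preserves *exactly* — so parameter recovery is a valid test of
everything downstream of peak integration. What passing tests therefore
do **not** show: robustness to non-binomial MID shapes (irrelevant to
atom-labeling-based inference), to drift from steady state, to
time-course effects over the infusion, or to LC–MS artifacts beyond
multiplicative noise.

Seeding: one master seed; each (tracer, animal) RNG stream is derived by
fixed integer offsets, so enlarging `n_animals` extends the study without
reshuffling existing animals, and equal seeds give byte-identical output
files (floats written at 12 significant digits).

## Numerical choices and degenerate inputs

- NNLS optimality/feasibility tolerance 10⁻¹² scaled by the problem
  magnitude; iteration caps guard pathological cycling.
- All-zero spectra, non-positive protein concentrations, tracers with
  zero serum labeling, and missing system entries are hard errors naming
  the offending sample/measurement; missing isotopologue rows are
  zero-filled with a warning (LC–MS exports omit undetected species).
- A single replicate yields SE 0 with a warning rather than NA, keeping
  downstream Monte Carlo well-defined.
- Replicate aggregation defaults to forming tracer-normalized ratios
  within each animal and averaging those (`order = "per_animal"`), so
  animal-level variation in tracer enrichment cancels; `"pooled"`
  (ratio of means with a delta-method SE) is provided because the
  opposite order is also seen in practice. Both recover noiseless
  labelings exactly.

## Validation surface and problem sizes

The test suite checks, among others: solver objective ≤ the 10⁻³-grid
minimum on 1,000 random k ≤ 3 systems; the hand-worked interior solution
(0.277778, 0.244444, 0.1); convolve→correct round trips below 10⁻⁹ for
C ∈ [2,6], p ∈ [0, 0.05]; zero-SE inputs giving exactly zero output SEs
and 100-replicate SEs within 30% of 10,000-replicate values; recovery of
`f_true` within ±0.05 per component in ≥95% of 200 simulated studies at
the default design; and byte-level determinism. These sizes keep the whole
suite around a minute on one CPU while leaving each property statistically
meaningful.

## Limitations

Fractional contributions only — no absolute fluxes (µmol/min/kg), no
multi-compartment or time-resolved modeling, no positional isotopomer
analysis, no vendor raw-file parsing (peak integration is assumed done
upstream). The Monte Carlo treats system entries as independent Gaussians;
with strong between-entry correlation the reported SEs will be
conservative or optimistic depending on the correlation sign.
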