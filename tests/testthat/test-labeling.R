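test_that("atom labeling is the carbon-weighted isotopologue average", {
  mk <- function(v) isotopologue_spectrum("x", v, is_fraction = TRUE)
  expect_equal(atom_labeling(mk(c(1, 0, 0, 0))), 0)
  expect_equal(atom_labeling(mk(c(0, 0, 0, 1))), 1)
  expect_equal(atom_labeling(mk(c(0.4, 0.3, 0.2, 0.1))), 1 / 3,
               tolerance = 1e-12)
  # fully labeled gives 1 for every carbon count
  for (C in 1:6)
    expect_equal(atom_labeling(mk(c(rep(0, C), 1))), 1)
})

test_that("atom labeling is linear in the spectrum", {
  set.seed(7)
  for (rep in 1:10) {
    C <- sample(2:6, 1)
    x <- random_fraction_spectrum(C)
    y <- random_fraction_spectrum(C)
    a <- stats::runif(1)
    mix <- isotopologue_spectrum("mix", a * x$values + (1 - a) * y$values,
                                 is_fraction = TRUE)
    expect_equal(atom_labeling(mix),
                 a * atom_labeling(x) + (1 - a) * atom_labeling(y),
                 tolerance = 1e-12)
  }
})

test_that("replicate aggregation gives mean and SD/sqrt(n)", {
  est <- aggregate_replicates(c(0.2, 0.3, 0.4))
  expect_equal(est$mean_L, 0.3)
  expect_equal(est$se_L, 0.1 / sqrt(3), tolerance = 1e-9)
  expect_equal(est$n, 3L)
  expect_warning(one <- aggregate_replicates(0.5), "single replicate")
  expect_equal(one$se_L, 0)
  flat <- aggregate_replicates(rep(0.25, 4))
  expect_equal(flat$mean_L, 0.25)
  expect_equal(flat$se_L, 0)
  expect_error(aggregate_replicates(numeric(0)), "no replicate")
})

test_that("tracer normalization divides by serum tracer labeling", {
  est <- function(m, s, met = "x") structure(
    list(metabolite = met, experiment = "e", mean_L = m, se_L = s, n = 6L),
    class = "labeling_estimate")
  nl <- normalized_labeling(est(0.12, 0.01), est(0.4, 0.02, "tracer"))
  expect_equal(nl$value, 0.3)
  expect_equal(nl$se, 0.3 * sqrt((0.01 / 0.12)^2 + (0.02 / 0.4)^2),
               tolerance = 1e-12)
  # unit tracer labeling is the identity normalization
  expect_equal(normalized_labeling(est(0.12, 0), est(1, 0))$value, 0.12)
  # zero numerator: only the numerator SE propagates
  z <- normalized_labeling(est(0, 0.05), est(0.4, 0.02))
  expect_equal(z$value, 0)
  expect_equal(z$se, 0.05 / 0.4)
  # self-normalization is exactly 1
  tr <- est(0.37, 0.02, "lactate")
  expect_identical(normalized_labeling(tr, tr)$value, 1)
  expect_error(normalized_labeling(est(0.1, 0), est(0, 0)),
               "did not circulate")
  expect_warning(normalized_labeling(est(0.9, 0), est(0.4, 0)), "> 1.05")
})

test_that("both replicate-aggregation orders recover noiseless labelings", {
  truth <- synthetic_truth(noise_cv = 0, n_animals = 3L, seed = 5L)
  sim <- generate_experiment(truth)
  for (ord in c("per_animal", "pooled")) {
    nl <- normalized_labelings(sim$measurements, sim$tracers, order = ord)
    merged <- merge(nl, sim$labelings, by = c("metabolite", "tracer"),
                    suffixes = c("", "_true"))
    expect_equal(nrow(merged), nrow(sim$labelings))
    expect_equal(merged$value, merged$value_true, tolerance = 1e-6)
    # tracer normalized against itself is 1 by construction
    self <- nl[nl$metabolite == nl$tracer, "value"]
    expect_equal(self, rep(1, length(self)), tolerance = 1e-12)
  }
})
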