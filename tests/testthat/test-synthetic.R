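test_that("forward labelings are consistent with the matrix equation", {
  # identity interconversion: product labelings are f_true itself
  t0 <- synthetic_truth(cross_labeling = diag(3))
  fl <- forward_labelings(t0)
  glu <- fl[fl$metabolite == "glucose" & fl$tracer != "glucose", ]
  expect_equal(glu$value[match(names(t0$f_true), glu$tracer)],
               unname(t0$f_true))
  # forward product of the solver's worked example
  M <- rbind(c(1, 0.5, 0), c(0.2, 1, 0), c(0, 0, 1))
  dimnames(M) <- list(c("lactate", "glycerol", "alanine"),
                      c("lactate", "glycerol", "alanine"))
  tw <- synthetic_truth(f_true = c(lactate = 0.277778, glycerol = 0.244444,
                                   alanine = 0.1),
                        cross_labeling = M)
  flw <- forward_labelings(tw)
  gluw <- flw[flw$metabolite == "glucose" & flw$tracer != "glucose", ]
  expect_equal(gluw$value[match(c("lactate", "glycerol", "alanine"),
                                gluw$tracer)],
               c(0.4, 0.3, 0.1), tolerance = 1e-5)
  # inverse consistency: solving the forward system returns f_true
  set.seed(3)
  for (rep in 1:10) {
    X <- diag(3)
    X[row(X) != col(X)] <- stats::runif(6, 0, 0.3)
    dimnames(X) <- dimnames(M)
    f <- stats::runif(3, 0, 0.3)
    names(f) <- rownames(M)
    tr <- synthetic_truth(f_true = f, cross_labeling = X)
    sys <- build_system(forward_labelings(tr))
    expect_equal(solve_contributions(sys)$f, f, tolerance = 1e-9)
  }
  # near-singular cross-labeling warns
  bad <- matrix(c(1, 1 - 1e-9, 1 - 1e-9, 1), 2)
  expect_warning(
    forward_labelings(synthetic_truth(
      f_true = c(lactate = 0.2, alanine = 0.1), cross_labeling = bad,
      include_product_tracer = FALSE)),
    "near-singular")
})

test_that("binomial MID preserves atom labeling exactly", {
  expect_equal(spectrum_from_labeling(0, 3)$values, c(1, 0, 0, 0))
  expect_equal(spectrum_from_labeling(1, 3)$values, c(0, 0, 0, 1))
  expect_equal(spectrum_from_labeling(0.3, 3)$values,
               c(0.343, 0.441, 0.189, 0.027), tolerance = 1e-12)
  for (C in 1:6)
    for (L in c(0, 0.1, 0.3, 0.5, 0.77, 1))
      expect_equal(atom_labeling(spectrum_from_labeling(L, C)), L,
                   tolerance = 1e-12)
})

test_that("the noiseless pipeline is an identity up to solver tolerance", {
  # no noise, no natural abundance
  t0 <- synthetic_truth(noise_cv = 0, p = 0, seed = 4L)
  s0 <- generate_experiment(t0)
  f0 <- gng_contrib(s0$measurements, s0$tracers, p = 0, n_mc = 1)
  expect_equal(f0$f, t0$f_true, tolerance = 1e-9)
  # no noise, natural abundance on and corrected for
  t1 <- synthetic_truth(noise_cv = 0, seed = 4L)
  s1 <- generate_experiment(t1)
  f1 <- gng_contrib(s1$measurements, s1$tracers, n_mc = 1)
  expect_equal(f1$f, t1$f_true, tolerance = 1e-6)
})

test_that("simulation output is byte-identical for a fixed seed", {
  truth <- synthetic_truth(n_animals = 2L, seed = 8L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_experiment(truth, out_dir = d1)
  generate_experiment(synthetic_truth(n_animals = 2L, seed = 8L),
                      out_dir = d2)
  for (f in c("measurements.csv", "tracers.csv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  # a different seed changes the measurements
  d3 <- withr::local_tempdir()
  generate_experiment(synthetic_truth(n_animals = 2L, seed = 9L),
                      out_dir = d3)
  expect_false(identical(readLines(file.path(d1, "measurements.csv")),
                         readLines(file.path(d3, "measurements.csv"))))
})

test_that("adding animals does not reshuffle existing ones", {
  small <- generate_experiment(synthetic_truth(n_animals = 3L, seed = 6L))
  big <- generate_experiment(synthetic_truth(n_animals = 5L, seed = 6L))
  shared <- merge(small$measurements, big$measurements,
                  by = c("sample", "metabolite", "isotopologue_index"))
  expect_equal(nrow(shared), nrow(small$measurements))
  expect_identical(shared$intensity.x, shared$intensity.y)
})
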