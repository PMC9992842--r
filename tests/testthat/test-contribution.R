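test_that("system assembly places labelings per tracer row", {
  # no interconversion: M is the identity
  nl0 <- toy_normalized(diag(3), c(0.3, 0.1, 0.05))
  sys0 <- build_system(nl0)
  expect_equal(unname(unclass(sys0$M)), diag(3))
  expect_equal(sys0$L, c(0.3, 0.1, 0.05))
  # direct placement of cross-labelings, unit diagonal
  M <- rbind(c(1, 0.5, 0), c(0.2, 1, 0), c(0, 0, 1))
  sys <- build_system(toy_normalized(M, c(0.4, 0.3, 0.1)))
  expect_equal(unname(unclass(sys$M)), M)
  expect_equal(unname(diag(sys$M)), c(1, 1, 1))
  expect_equal(unname(diag(sys$M_se)), c(0, 0, 0))
  # a missing measurement is named in the error
  nl_miss <- nl0[!(nl0$metabolite == "glycerol" & nl0$tracer == "lactate"), ]
  expect_error(build_system(nl_miss), "glycerol under lactate")
})

test_that("the constrained solve reproduces hand-worked systems", {
  sys <- list(M = diag(3), L = c(0.3, 0.1, 0.05),
              substrates = c("a", "b", "c"))
  expect_equal(unname(solve_contributions(sys)$f), c(0.3, 0.1, 0.05),
               tolerance = 1e-9)
  # interior solution: matches exact elimination
  M <- rbind(c(1, 0.5, 0), c(0.2, 1, 0), c(0, 0, 1))
  res <- solve_contributions(list(M = M, L = c(0.4, 0.3, 0.1),
                                  substrates = c("lactate", "glycerol",
                                                 "alanine")))
  expect_lt(max(abs(unname(res$f) - c(0.277778, 0.244444, 0.1))), 1e-6)
  expect_lt(res$residual, 1e-12)
  # active constraint: matches the brute-force grid oracle
  M2 <- rbind(c(1, 0.9), c(0.9, 1))
  L2 <- c(0.1, 0.5)
  f2 <- nnls_fit(M2, L2)$x
  expect_true(any(f2 == 0))
  expect_lte(nnls_objective(M2, L2, f2), grid_nnls_min(M2, L2) + 1e-6)
})

test_that("solver agrees with unconstrained least squares when feasible and with lsqnonneg otherwise", {
  set.seed(31)
  for (rep in 1:50) {
    k <- sample(1:3, 1)
    sys <- random_system(k)
    f <- nnls_fit(sys$M, sys$L)$x
    ols <- qr.coef(qr(sys$M), sys$L)
    if (!anyNA(ols) && all(ols >= 0))
      expect_equal(f, unname(ols), tolerance = 1e-9)
    ref <- pracma::lsqnonneg(sys$M, sys$L)$x
    expect_equal(nnls_objective(sys$M, sys$L, f),
                 nnls_objective(sys$M, sys$L, ref), tolerance = 1e-8)
  }
})

test_that("permuting substrate order permutes the solution identically", {
  set.seed(13)
  M <- rbind(c(1, 0.3, 0.1), c(0.25, 1, 0.05), c(0.2, 0.02, 1))
  L <- c(0.45, 0.32, 0.12)
  subs <- c("lactate", "glycerol", "alanine")
  base <- solve_contributions(build_system(toy_normalized(M, L)))
  perm <- c(3, 1, 2)
  res_p <- solve_contributions(
    build_system(toy_normalized(M, L), substrates = subs[perm]))
  expect_equal(res_p$f, base$f[perm], tolerance = 1e-10)
})

test_that("a singular system warns but returns a feasible minimizer", {
  M <- matrix(1, 2, 2)
  expect_warning(
    res <- solve_contributions(list(M = M, L = c(0.4, 0.4),
                                    substrates = c("a", "b"))),
    "singular")
  expect_true(all(res$f >= 0))
  expect_lt(res$residual, 1e-9)
  expect_error(solve_contributions(list(M = matrix(c(1, NA, 0, 1), 2),
                                        L = c(0.1, 0.2),
                                        substrates = c("a", "b"))),
               "non-finite")
})

test_that("Monte Carlo resampling propagates input SEs deterministically", {
  M <- rbind(c(1, 0.3, 0.05), c(0.25, 1, 0.04), c(0.1, 0.02, 1))
  L <- c(0.45, 0.32, 0.12)
  sys <- build_system(toy_normalized(M, L, se_M = 0.02, se_L = 0.02))
  a <- monte_carlo_errors(sys, n_mc = 100, seed = 9)
  b <- monte_carlo_errors(sys, n_mc = 100, seed = 9)
  expect_identical(a$f_se, b$f_se)
  expect_identical(a$replicates, b$replicates)
  expect_true(all(a$f_se > 0))
  # the reported central estimate is the point solve on the mean system
  expect_equal(a$f, solve_contributions(sys)$f)
  # degenerate noise: every replicate identical, SEs exactly zero
  sys0 <- build_system(toy_normalized(M, L))
  z <- monte_carlo_errors(sys0, n_mc = 50, seed = 1)
  expect_identical(unname(z$f_se), c(0, 0, 0))
  expect_equal(unname(z$f_mc), unname(z$f), tolerance = 1e-12)
})

test_that("doubling input SEs approximately doubles Monte Carlo SEs", {
  M <- rbind(c(1, 0.3, 0.05), c(0.25, 1, 0.04), c(0.1, 0.02, 1))
  L <- c(0.45, 0.32, 0.12)
  s1 <- build_system(toy_normalized(M, L, se_M = 0.01, se_L = 0.01))
  s2 <- build_system(toy_normalized(M, L, se_M = 0.02, se_L = 0.02))
  se1 <- monte_carlo_errors(s1, n_mc = 10000, seed = 2)$f_se
  se2 <- monte_carlo_errors(s2, n_mc = 10000, seed = 3)$f_se
  expect_equal(unname(se2 / se1), rep(2, 3), tolerance = 0.1)
})

test_that("interconversion extension swaps the product and reduces substrates", {
  M <- rbind(c(1, 0.3, 0.05), c(0.25, 1, 0.04), c(0.1, 0.02, 1))
  L <- c(0.45, 0.32, 0.12)
  nl <- toy_normalized(M, L)
  # default product reproduces the plain solve exactly
  res <- interconversion_contributions(nl, n_mc = 1, seed = 0)
  expect_equal(res$f, solve_contributions(build_system(nl))$f)
  # product = pyruvate with identity M: f equals the product labelings
  nl_pyr <- rbind(toy_normalized(diag(3), c(0.2, 0.1, 0.3)),
                  data.frame(metabolite = "pyruvate",
                             tracer = c("lactate", "glycerol", "alanine"),
                             value = c(0.6, 0.05, 0.4), se = 0))
  res_pyr <- interconversion_contributions(nl_pyr, product = "pyruvate",
                                           n_mc = 1)
  expect_equal(unname(res_pyr$f), c(0.6, 0.05, 0.4), tolerance = 1e-9)
  # product = lactate: reduced 2x2 over {glycerol, alanine}, vs grid oracle
  res_lac <- interconversion_contributions(nl, product = "lactate", n_mc = 1)
  expect_identical(res_lac$substrates, c("glycerol", "alanine"))
  M2 <- M[2:3, 2:3]
  L2 <- c(M[2, 1], M[3, 1])  # lactate labeling under glycerol/alanine tracers
  expect_lte(nnls_objective(M2, L2, unname(res_lac$f)),
             grid_nnls_min(M2, L2) + 1e-6)
  expect_error(interconversion_contributions(nl, product = "pyruvate"),
               "not among measured")
})
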