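test_that("SIF equals exactly 1 under independence", {
  for (psiA in seq(0.05, 0.95, by = 0.1))
    for (x in seq(0.1, 1, by = 0.1))
      expect_identical(sif(psiA, x, x), 1)
})

test_that("SIF hand values and algebraic limits", {
  # psiB = 0.36 + 0.19 * 0.01 = 0.3619; phi = 0.37 / 0.3619
  expect_equal(sif(0.19, 0.37, 0.36), 0.37 / 0.3619, tolerance = 1e-12)
  # subordinate never occurs without the dominant: phi = 1 / psiA
  for (psiA in c(0.2, 0.5, 0.8))
    expect_equal(sif(psiA, 0.6, 0), 1 / psiA, tolerance = 1e-12)
  # avoidance and co-occurrence sides of 1
  expect_lt(sif(0.5, 0.2, 0.6), 1)
  expect_gt(sif(0.5, 0.6, 0.2), 1)
  expect_error(sif(0.5, 0, 0), "zero marginal")
})

test_that("the conditional-denominator variant reproduces the ratio it defines", {
  expect_equal(sif(0.19, 0.37, 0.36, denominator = "conditional"),
               0.19 * 0.37 / (0.37 * 0.36))
  # it is not independence-normalized: equal conditionals do not give 1
  expect_false(isTRUE(all.equal(sif(0.19, 0.37, 0.37,
                                    denominator = "conditional"), 1)))
})

test_that("averaged SIF from an SP fit is exactly 1 with zero delta-method SE", {
  d <- sim_pair(400, psiA = 0.4, psiBA = 0.5, psiBa = 0.5, p = 0.5, seed = 6)
  fit <- occu_pair(d, interaction = FALSE, n_starts = 3, seed = 1)
  s <- sif_estimate(fit)
  expect_equal(unique(s$phi_site), 1)
  expect_equal(s$phi_mean, 1)
  expect_equal(s$se, 0)
  expect_false(s$significant)
})

test_that("intercept-only SP+INT averaged SIF equals the scalar evaluation", {
  d <- sim_pair(1500, psiA = 0.5, psiBA = 0.7, psiBa = 0.3, p = 0.6, seed = 12)
  fit <- occu_pair(d, n_starts = 3, seed = 1)
  s <- sif_estimate(fit)
  expect_equal(s$phi_mean,
               sif(fit$psiA_hat[[1]], fit$psiBA_hat[[1]], fit$psiBa_hat[[1]]),
               tolerance = 1e-10)
  expect_gt(s$se, 0)
  expect_equal(s$ci95, s$phi_mean + c(-1.96, 1.96) * s$se)
  expect_error(sif_estimate(occu_pair(
    detection_data(list(A = rbind(c(1, 0), c(0, 0)), B = matrix(0, 2, 2))),
    n_starts = 2, seed = 1)), "did not converge")
})

# helper: a converged fit with hand-set coefficients for profile checks
profile_fixture <- function(beta) {
  d <- sim_pair(60, psiA = 0.5, psiBA = 0.5, psiBa = 0.5, p = 0.5,
                beta_psiBa = c(x = 0.5), seed = 21)
  fit <- occu_pair(d, psiA_formula = ~1, psiBA_formula = ~1,
                   psiBa_formula = ~x, n_starts = 2, seed = 1)
  fit$coefficients[] <- beta
  fit$vcov <- NULL
  fit$converged <- TRUE
  fit
}

test_that("SIF profiles respond to covariate slopes as the algebra dictates", {
  grid <- seq(-2, 2, length.out = 9)
  # zero slope everywhere: flat profile
  flat <- sif_profile(profile_fixture(c(0, 0.4, 0.2, 0, 0, 0)), "x", grid = grid)
  expect_lt(diff(range(flat$phi)), 1e-12)
  # positive slope on psiBa only: phi strictly decreasing along the grid
  dec <- sif_profile(profile_fixture(c(0, 0.4, 0.2, 0.9, 0, 0)), "x", grid = grid)
  expect_true(all(diff(dec$phi) < 0))
  # at the covariate mean (z = 0) the profile equals the scalar evaluation
  at0 <- sif_profile(profile_fixture(c(0, 0.4, 0.2, 0, 0, 0)), "x", grid = 0)
  expect_equal(at0$phi, sif(0.5, plogis(0.4), plogis(0.2)), tolerance = 1e-12)
  expect_error(sif_profile(profile_fixture(c(0, 0.4, 0.2, 0, 0, 0)), "nope"),
               "absent from every occupancy predictor")
})

test_that("profiles report delta-method SEs and back-transformed grids", {
  set.seed(33)
  d <- sim_pair(1200, psiA = 0.5, psiBA = 0.65, psiBa = 0.35, p = 0.6,
                beta_psiBa = c(x = 0.6),
                site_covariates = data.frame(x = rnorm(1200, 100, 15)),
                seed = 33)
  d <- standardize_covariates(d, "x")
  fit <- occu_pair(d, psiBA_formula = ~x, psiBa_formula = ~x,
                   n_starts = 3, seed = 1)
  prof <- sif_profile(fit, "x", length.out = 5)
  expect_equal(nrow(prof), 5)
  expect_true(all(is.finite(prof$se) & prof$se >= 0))
  # original-scale grid is the z grid un-standardized
  sc <- d$scaling$x
  expect_equal(prof$covariate, prof$z * sc[["scale"]] + sc[["center"]])
})
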