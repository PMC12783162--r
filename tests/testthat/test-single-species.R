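test_that("site likelihood matches hand-computed values", {
  expect_equal(site_lik_single(0.5, c(0.5, 0.5), c(1, 0)), 0.125)
  expect_equal(site_lik_single(0.5, c(0.5, 0.5), c(0, 0)), 0.625)
  expect_equal(site_lik_single(1, c(1, 1), c(1, 1)), 1)
  # missing occasions are skipped
  expect_equal(site_lik_single(0.5, c(0.5, 0.9), c(1, NA)), 0.25)
  expect_error(site_lik_single(0.5, c(0.5, 0.5), c(NA, NA)), "all-missing")
})

test_that("site likelihood normalizes and matches latent-state enumeration", {
  set.seed(101)
  for (K in 2:3) {
    H <- all_histories(K)
    for (rep in 1:5) {
      psi <- runif(1, 0.05, 0.95)
      p <- runif(K, 0.05, 0.95)
      liks <- apply(H, 1, function(h) site_lik_single(psi, p, h))
      expect_lt(abs(sum(liks) - 1), 1e-12)
      oracle <- apply(H, 1, function(h) enum_lik_single(psi, p, h))
      expect_lt(max(abs(liks - oracle)), 1e-14)
    }
  }
})

test_that("negative log-likelihood at beta = 0 matches the hand-summed value", {
  d <- detection_data(rbind(c(1, 0), c(0, 0)))
  des <- occupair:::build_designs(d, ~1, ~1)
  nll <- occupair:::negloglik_single_factory(des$X, des$W, d$histories[[1]])
  expect_equal(nll(c(0, 0)), -log(0.125) - log(0.625), tolerance = 1e-12)
  # logit-inverse of 0 is 0.5, so beta = 0 equals the (psi=0.5, p=0.5) value
  expect_equal(nll(c(0, 0)), 2.549445, tolerance = 1e-6)
})

test_that("intercept-only MLE matches a brute-force grid search", {
  d <- detection_data(rbind(c(1, 0), c(0, 0)))
  fit <- occu_single(d, n_starts = 5, seed = 1)
  # independent grid oracle over (psi, p) with closed-form site products
  psi <- p <- seq(0.001, 0.999, by = 0.001)
  nll_grid <- outer(psi, p, function(psi, p)
    -log(psi * p * (1 - p)) - log(psi * (1 - p)^2 + 1 - psi))
  expect_lt(fit$neg2loglik / 2 - min(nll_grid), 1e-4)
  idx <- which(nll_grid == min(nll_grid), arr.ind = TRUE)[1, ]
  expect_equal(plogis(fit$beta_psi[[1]]), psi[idx[1]], tolerance = 2e-3)
  expect_equal(plogis(fit$beta_p[[1]]), p[idx[2]], tolerance = 2e-3)
})

test_that("parameters are recovered from simulated data", {
  d <- sim_single(3000, psi = 0.6, p = 0.7, seed = 2)
  fit <- occu_single(d, n_starts = 3, seed = 1)
  expect_true(fit$converged)
  expect_lt(abs(plogis(fit$beta_psi[[1]]) - 0.6), 0.05)
  expect_lt(abs(plogis(fit$beta_p[[1]]) - 0.7), 0.05)
  expect_true(all(fit$psi_hat > 0 & fit$psi_hat < 1))
  expect_equal(fit$K, 2)
  # vcov symmetric positive semi-definite at an interior optimum
  expect_lt(max(abs(fit$vcov - t(fit$vcov))), 1e-6)
  expect_true(all(eigen(fit$vcov, symmetric = TRUE)$values > -1e-10))
})

test_that("fits are invariant to covariate standardization", {
  set.seed(9)
  x <- rnorm(600, 5, 2)
  d <- sim_single(600, psi = 0.5, p = 0.6,
                  beta_psi = c(x = 0.3),
                  site_covariates = data.frame(x = x - mean(x)),
                  seed = 9)
  d$site_covariates$x <- x   # fit on the raw, uncentered scale
  raw <- occu_single(d, psi_formula = ~x, n_starts = 3, seed = 1)
  std <- occu_single(standardize_covariates(d, "x"), psi_formula = ~x,
                     n_starts = 3, seed = 1)
  expect_equal(raw$neg2loglik, std$neg2loglik, tolerance = 1e-6)
  expect_equal(raw$psi_hat, std$psi_hat, tolerance = 1e-6)
})

test_that("degenerate datasets flag non-convergence instead of erroring", {
  all_ones <- detection_data(matrix(1, 30, 2))
  f1 <- occu_single(all_ones, n_starts = 2, seed = 1)
  expect_false(f1$converged)
  expect_true(f1$boundary)
  expect_gt(mean(f1$psi_hat), 0.99)

  none <- detection_data(matrix(0, 30, 2))
  f0 <- occu_single(none, n_starts = 2, seed = 1)
  expect_false(f0$converged)
  expect_true(f0$no_detections)
})

test_that("occupancy predictions report per-site psi with mean and range", {
  set.seed(3)
  d <- sim_single(800, psi = 0.5, p = 0.6, beta_psi = c(x = 1), seed = 3)
  fit <- occu_single(d, psi_formula = ~x, n_starts = 3, seed = 1)
  pr <- predict(fit, type = "psi")
  expect_length(pr, 800)
  expect_equal(attr(pr, "mean"), mean(as.numeric(pr)))
  expect_equal(attr(pr, "range"), range(as.numeric(pr)))
  # positive slope: psi monotone increasing in the covariate
  o <- order(d$site_covariates$x)
  expect_true(all(diff(as.numeric(pr)[o]) >= 0))
  # mean psi-hat close to the simulation's average true psi
  expect_lt(abs(attr(pr, "mean") - mean(attr(d, "truth")$psi)), 0.05)

  # intercept-only: all sites equal, zero-width range
  fit0 <- occu_single(d, n_starts = 3, seed = 1)
  pr0 <- predict(fit0, type = "psi")
  expect_equal(diff(attr(pr0, "range")), 0)
})

test_that("history-conditioned occupancy follows Bayes rule", {
  d <- detection_data(rbind(c(0, 0), c(1, 0), c(0, 1)))
  fit <- occu_single(d, n_starts = 2, seed = 1)
  # force known parameter values through the fitted object
  fit$psi_hat[] <- 0.5
  fit$p_hat[] <- 0.5
  cond <- conditional_occupancy(fit)
  expect_equal(cond[1], 0.125 / 0.625)   # = 0.2
  expect_equal(cond[2], 1)               # any detection implies presence
  expect_equal(cond[3], 1)
  # perfect-detection limit: an all-zero history implies absence
  fit$p_hat[] <- 1 - 1e-12
  expect_lt(conditional_occupancy(fit)[1], 1e-11)
})
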