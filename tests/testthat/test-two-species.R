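test_that("joint state probabilities follow the conditional parameterization", {
  pr <- joint_state_probs(0.18, 0.08, 0.01)
  expect_equal(unname(drop(pr)), c(0.0144, 0.1656, 0.0082, 0.8118))
  expect_equal(sum(pr), 1)
  # A certain: states without A have probability 0
  pr1 <- joint_state_probs(1, 0.3, 0.7)
  expect_equal(unname(pr1[, c("aB", "ab")]), c(0, 0))
  # normalization for random inputs
  set.seed(5)
  for (i in 1:20) {
    v <- runif(3)
    expect_equal(sum(joint_state_probs(v[1], v[2], v[3])), 1)
  }
})

test_that("two-species site likelihood matches hand values and handles errors", {
  pr <- as.list(setNames(rep(0.5, 8),
                         c("psiA", "psiBA", "psiBa", "pA", "pB", "rA", "rBA", "rBa")))
  expect_equal(site_lik_two(pr, c(0, 0), c(0, 0)), 0.390625)
  # B never present: reduces to A's detection term
  prb <- pr; prb$psiBA <- 0; prb$psiBa <- 0; prb$psiA <- 0.4
  expect_equal(site_lik_two(prb, c(1, 0), c(0, 0)), 0.4 * 0.5 * 0.5)
  expect_error(site_lik_two(pr, c(1, 0), c(0)), "same number of occasions")
})

test_that("two-species likelihood normalizes and matches 4-state enumeration", {
  set.seed(202)
  for (K in 2:3) {
    H <- all_histories(K)
    joint <- expand.grid(a = seq_len(nrow(H)), b = seq_len(nrow(H)))
    for (rep in 1:5) {
      pr <- random_pair_params()
      liks <- mapply(function(i, j) site_lik_two(pr, H[i, ], H[j, ]),
                     joint$a, joint$b)
      expect_lt(abs(sum(liks) - 1), 1e-12)
      oracle <- mapply(function(i, j) enum_lik_two(pr, H[i, ], H[j, ]),
                       joint$a, joint$b)
      expect_lt(max(abs(liks - oracle)), 1e-14)
    }
  }
})

test_that("with no interaction and shared B detection the B-marginal equals the single-species likelihood", {
  set.seed(303)
  H <- all_histories(2)
  for (rep in 1:10) {
    pr <- random_pair_params()
    pr$psiBa <- pr$psiBA        # psiBA = psiBa
    pr$rBA <- pr$pB; pr$rBa <- pr$pB  # B detection unaffected by A
    psiB <- pr$psiBA
    for (j in seq_len(nrow(H))) {
      marg <- sum(vapply(seq_len(nrow(H)), function(i)
        site_lik_two(pr, H[i, ], H[j, ]), 0))
      expect_lt(abs(marg - site_lik_single(psiB, rep(pr$pB, 2), H[j, ])),
                1e-10)
    }
  }
})

test_that("intercept-only SP+INT fit matches a refined grid search on a toy dataset", {
  hA <- rbind(c(1, 0), c(1, 1), c(0, 0), c(0, 0), c(1, 0),
              c(0, 0), c(1, 0), c(1, 1), c(0, 0), c(0, 0))
  hB <- rbind(c(1, 0), c(0, 1), c(1, 1), c(0, 0), c(0, 0),
              c(0, 1), c(0, 0), c(0, 0), c(0, 0), c(0, 0))
  d <- detection_data(list(A = hA, B = hB))
  fit <- occu_pair(d, n_starts = 8, seed = 1)
  expect_true(fit$converged)

  # closed-form likelihood under the shared detection constraint: each
  # species' detections are Bernoulli in its own occupancy, so only the
  # per-site detection counts matter; vectorized over grid rows
  aA <- rowSums(hA); aB <- rowSums(hB); K <- 2
  nll_vec <- function(psiA, psiBA, psiBa, pA, pB) {
    f <- function(a, p) p^a * (1 - p)^(K - a)
    tot <- 0
    for (i in seq_along(aA)) {
      L <- psiA * psiBA * f(aA[i], pA) * f(aB[i], pB) +
        psiA * (1 - psiBA) * f(aA[i], pA) * (aB[i] == 0) +
        (1 - psiA) * psiBa * (aA[i] == 0) * f(aB[i], pB) +
        (1 - psiA) * (1 - psiBa) * (aA[i] == 0) * (aB[i] == 0)
      tot <- tot - log(L)
    }
    tot
  }
  # coarse-to-fine grid over (psiA, psiBA, psiBa, pA, pB)
  lo <- rep(0.01, 5); hi <- rep(0.99, 5)
  for (pass in 1:4) {
    grids <- Map(function(l, h) seq(l, h, length.out = 9), lo, hi)
    G <- do.call(expand.grid, grids)
    vals <- nll_vec(G[[1]], G[[2]], G[[3]], G[[4]], G[[5]])
    best <- unlist(G[which.min(vals), ])
    step <- vapply(grids, function(g) diff(g[1:2]), 0)
    lo <- pmax(0.001, best - step); hi <- pmin(0.999, best + step)
  }
  expect_lt(abs(fit$neg2loglik / 2 - min(vals)), 1e-3)
  # grid argmin agrees with the fitted probabilities
  est <- plogis(fit$coefficients)
  expect_equal(unname(best), unname(est), tolerance = 0.02)
})

test_that("fitting recovers two-species generating parameters", {
  d <- sim_pair(3000, psiA = 0.5, psiBA = 0.7, psiBa = 0.3, p = 0.6, seed = 3)
  fit <- occu_pair(d, n_starts = 3, seed = 1)
  expect_true(fit$converged)
  expect_gt(mean(fit$psiBA_hat), mean(fit$psiBa_hat))
  expect_lt(abs(mean(fit$psiA_hat) - 0.5), 0.07)
  expect_lt(abs(mean(fit$psiBA_hat) - 0.7), 0.07)
  expect_lt(abs(mean(fit$psiBa_hat) - 0.3), 0.07)
  expect_equal(fit$K, 5)  # psiA, psiBA, psiBa + 2 shared detection blocks
})

test_that("SP is preferred over SP+INT when the species are truly independent", {
  wins <- 0
  for (r in 1:20) {
    d <- sim_pair(500, psiA = 0.5, psiBA = 0.5, psiBa = 0.5, p = 0.5,
                  seed = 1000 + r)
    sp <- occu_pair(d, interaction = FALSE, n_starts = 2, seed = 1)
    int <- occu_pair(d, interaction = TRUE, n_starts = 2, seed = 1)
    if (aic(sp$neg2loglik, sp$K) <= aic(int$neg2loglik, int$K)) wins <- wins + 1
  }
  expect_gt(wins, 10)
})

test_that("free detection parameterization nests the shared one", {
  d <- sim_pair(800, psiA = 0.5, psiBA = 0.6, psiBa = 0.4, p = 0.5, seed = 8)
  shared <- occu_pair(d, detection_constraint = "shared", n_starts = 3, seed = 1)
  free <- occu_pair(d, detection_constraint = "free", n_starts = 5, seed = 1)
  expect_equal(free$K, shared$K + 3)
  expect_lte(free$neg2loglik, shared$neg2loglik + 1e-4)
})

test_that("a species without detections yields a flagged, not crashed, fit", {
  d <- detection_data(list(A = rbind(c(1, 0), c(0, 1), c(0, 0)),
                           B = matrix(0, 3, 2)))
  fit <- occu_pair(d, n_starts = 2, seed = 1)
  expect_s3_class(fit, "occu_pair")
  expect_false(fit$converged)
  expect_true(fit$no_detections)
})
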