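test_that("single-species generator hits the closed-form naive occupancy", {
  d <- sim_single(10000, psi = 0.5, p = 0.5, seed = 17)
  naive <- mean(rowSums(d$histories[[1]]) > 0)
  expected <- 0.5 * (1 - 0.25)   # psi * (1 - (1-p)^2) = 0.375
  se <- sqrt(expected * (1 - expected) / 10000)
  expect_lt(abs(naive - expected), 3 * se)

  sure <- sim_single(50, psi = 1, p = 1, seed = 1)
  expect_true(all(sure$histories[[1]] == 1))
})

test_that("generators are pure functions of the seed", {
  expect_identical(sim_single(200, seed = 5), sim_single(200, seed = 5))
  expect_identical(sim_pair(200, seed = 5), sim_pair(200, seed = 5))
  expect_false(identical(sim_single(200, seed = 5)$histories,
                         sim_single(200, seed = 6)$histories))
})

test_that("two-species generator respects the latent coupling", {
  d <- sim_pair(5000, psiA = 0.5, psiBA = 0.6, psiBa = 0, p = 0.5, seed = 9)
  tr <- attr(d, "truth")
  expect_true(all(tr$zB[tr$zA == 0] == 0))  # B never occurs without A

  # independence: empirical phi of latent states near 1 at large n
  di <- sim_pair(50000, psiA = 0.4, psiBA = 0.55, psiBa = 0.55, p = 0.5,
                 seed = 10)
  ti <- attr(di, "truth")
  pA <- mean(ti$zA); pB <- mean(ti$zB); pAB <- mean(ti$zA & ti$zB)
  expect_lt(abs(pAB / (pA * pB) - 1), 0.03)
})

test_that("simulated joint-history frequencies match the likelihood", {
  pr <- list(psiA = 0.45, psiBA = 0.7, psiBa = 0.25,
             pA = 0.55, pB = 0.4, rA = 0.55, rBA = 0.4, rBa = 0.4)
  n <- 100000
  d <- sim_pair(n, psiA = pr$psiA, psiBA = pr$psiBA, psiBa = pr$psiBa,
                pA = pr$pA, pB = pr$pB, rA = pr$rA, rBA = pr$rBA,
                rBa = pr$rBa, seed = 14)
  hA <- d$histories[[1]]; hB <- d$histories[[2]]
  key <- paste(hA[, 1], hA[, 2], hB[, 1], hB[, 2])
  H <- all_histories(2)
  for (i in seq_len(nrow(H))) {
    for (j in seq_len(nrow(H))) {
      prob <- site_lik_two(pr, H[i, ], H[j, ])
      obs <- mean(key == paste(H[i, 1], H[i, 2], H[j, 1], H[j, 2]))
      se <- sqrt(prob * (1 - prob) / n)
      expect_lt(abs(obs - prob), 4 * se + 1e-12)
    }
  }
})

test_that("study emulation reproduces the two-park design", {
  d <- sim_study(seed = 4)
  expect_equal(nrow(d$histories$lion), 768)
  expect_equal(unname(table(d$area)[c("Kruger", "Limpopo")]), c(269L, 499L),
               ignore_attr = TRUE)
  expect_equal(ncol(d$histories$lion), 2)
  expect_true(all(d$occasion_covariates$substrate %in% 1:3))
  expect_setequal(names(d$histories),
                  c("buffalo", "impala", "kudu", "cattle", "poaching", "lion",
                    "cheetah", "leopard", "spotted_hyena", "wild_dog"))

  # wild dog is the rarest carnivore; spotted hyena the most detected
  naive <- vapply(d$histories, function(h) sum(rowSums(h) > 0), 0L)
  carn <- naive[c("lion", "cheetah", "leopard", "spotted_hyena", "wild_dog")]
  expect_equal(names(which.min(carn)), "wild_dog")
  expect_equal(names(which.max(carn)), "spotted_hyena")

  # same seed gives a byte-identical CSV
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_detection_data(sim_study(seed = 4), f1)
  write_detection_data(sim_study(seed = 4), f2)
  expect_identical(readLines(f1), readLines(f2))
})
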