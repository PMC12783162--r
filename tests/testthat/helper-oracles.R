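# Independent brute-force oracles used across tests.  These deliberately
# avoid the package's likelihood code paths: they enumerate latent states
# and multiply Bernoulli terms directly.

# single-species likelihood by explicit enumeration over z in {0, 1}
enum_lik_single <- function(psi, p, h) {
  keep <- !is.na(h)
  h <- h[keep]; p <- p[keep]
  by_state <- function(z) {
    pz <- if (z == 1) psi else 1 - psi
    cond <- if (z == 1) prod(p^h * (1 - p)^(1 - h)) else as.numeric(all(h == 0))
    pz * cond
  }
  by_state(1) + by_state(0)
}

# two-species likelihood by explicit enumeration over the 4 latent states
enum_lik_two <- function(pr, hA, hB) {
  keep <- !is.na(hA) | !is.na(hB)
  states <- list(c(1, 1), c(1, 0), c(0, 1), c(0, 0))
  total <- 0
  for (st in states) {
    zA <- st[1]; zB <- st[2]
    pz <- (if (zA == 1) pr$psiA else 1 - pr$psiA) *
      (if (zA == 1) {
        if (zB == 1) pr$psiBA else 1 - pr$psiBA
      } else {
        if (zB == 1) pr$psiBa else 1 - pr$psiBa
      })
    condA <- 1; condB <- 1
    for (k in seq_along(hA)) {
      if (!is.na(hA[k])) {
        pa <- if (zA == 1) (if (zB == 1) pr$rA else pr$pA) else 0
        condA <- condA * ifelse(hA[k] == 1, pa, 1 - pa)
      }
      if (!is.na(hB[k])) {
        pb <- if (zB == 1) {
          if (zA == 1) {
            if (!is.na(hA[k]) && hA[k] == 1) pr$rBA else pr$rBa
          } else pr$pB
        } else 0
        condB <- condB * ifelse(hB[k] == 1, pb, 1 - pb)
      }
    }
    total <- total + pz * condA * condB
  }
  total
}

# all 0/1 histories of length K as rows
all_histories <- function(K) {
  as.matrix(expand.grid(rep(list(c(0, 1)), K)))
}

random_pair_params <- function() {
  p <- as.list(stats::runif(8, 0.05, 0.95))
  names(p) <- c("psiA", "psiBA", "psiBa", "pA", "pB", "rA", "rBA", "rBa")
  p
}
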