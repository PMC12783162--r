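## Occasion-level detection probability on the logit scale:
## base + substrate effect (higher quality substrate = class 1 detects
## better) + recapture (lag-1 detection) effect.
det_logit <- function(base_p, substrate, substrate_effect, prev, recap_effect) {
  qlogis(base_p) + substrate_effect * (2 - substrate) + recap_effect * prev
}

draw_substrate <- function(n, K, probs = c(0.4, 0.4, 0.2)) {
  matrix(sample(1:3, n * K, replace = TRUE, prob = probs), n, K)
}

## Sequential detection draw with a lag-1 recapture effect: occasion k's
## probability may depend on the realized detection at k - 1.
draw_history <- function(z, base_p, substrate, substrate_effect, recap_effect) {
  n <- length(z); K <- ncol(substrate)
  h <- matrix(0, n, K)
  prev <- numeric(n)
  for (k in seq_len(K)) {
    pk <- plogis(det_logit(base_p, substrate[, k], substrate_effect,
                           prev, recap_effect))
    h[, k] <- stats::rbinom(n, 1, z * pk)
    prev <- h[, k]
  }
  h
}

#' Simulate a single-species detection/non-detection survey
#'
#' Draws site covariates, latent occupancy `z_i ~ Bernoulli(psi_i)` and
#' detections `h_ik ~ Bernoulli(z_i p_ik)`.  Occupancy is logit-linear:
#' `logit(psi_i) = qlogis(psi) + x_i' beta_psi`, so `psi` is the occupancy
#' at covariate 0 (the mean, for z-scaled covariates).  Detection can
#' include a 3-level substrate covariate and a lag-1 recapture effect on
#' the logit scale.
#'
#' @param n_sites number of sites.
#' @param n_occasions occasions per site (default 2: two consecutive 1-km
#'   walks of a 2-km transect site).
#' @param psi,p baseline occupancy and detection probabilities.
#' @param beta_psi optional named vector of occupancy slopes; covariates
#'   named here and absent from `site_covariates` are drawn N(0, 1).
#' @param site_covariates optional data frame of site covariates.
#' @param substrate include the substrate occasion covariate?
#' @param substrate_probs frequencies of substrate classes 1-3.
#' @param substrate_effect logit-scale effect per substrate class away
#'   from class 2 (positive = better detection on class 1).
#' @param recapture_effect logit-scale effect of a detection on the
#'   previous occasion.
#' @param seed RNG seed; the dataset is a pure function of the arguments.
#' @return A [detection_data] object; attribute `truth` holds the latent
#'   occupancy states and the generating `psi_i`.
#' @examples
#' d <- sim_single(500, psi = 0.5, p = 0.5, seed = 7)
#' mean(rowSums(d$histories[[1]]) > 0)  # naive occupancy, about 0.375
#' @export
sim_single <- function(n_sites, n_occasions = 2, psi = 0.5, p = 0.5,
                       beta_psi = NULL, site_covariates = NULL,
                       substrate = FALSE, substrate_probs = c(0.4, 0.4, 0.2),
                       substrate_effect = 0, recapture_effect = 0, seed = 1) {
  set.seed(seed)
  covs <- as.data.frame(site_covariates %||%
                          data.frame(row.names = seq_len(n_sites)))
  for (nm in setdiff(names(beta_psi), names(covs)))
    covs[[nm]] <- stats::rnorm(n_sites)
  eta <- qlogis(psi)
  for (nm in names(beta_psi)) eta <- eta + beta_psi[[nm]] * covs[[nm]]
  psi_i <- plogis(eta)
  z <- stats::rbinom(n_sites, 1, psi_i)
  sub <- if (substrate) draw_substrate(n_sites, n_occasions, substrate_probs)
         else matrix(2, n_sites, n_occasions)
  h <- draw_history(z, p, sub, substrate_effect, recapture_effect)
  occ <- list()
  if (substrate) occ$substrate <- sub
  if (recapture_effect != 0 || n_occasions > 1)
    occ$recap <- make_recapture_covariate(h)
  out <- detection_data(list(species = h),
                        site_covariates = if (ncol(covs)) covs,
                        occasion_covariates = if (length(occ)) occ)
  attr(out, "truth") <- list(z = z, psi = psi_i)
  out
}

#' Simulate a two-species detection/non-detection survey
#'
#' Generative mirror of the conditional two-species likelihood: the
#' dominant species A occupies with probability `psiA_i`, the subordinate
#' B with `psiBA_i` where A is present and `psiBa_i` where it is absent.
#' Detections are drawn per occasion with `pA`/`rA` for A and, for B at
#' co-occupied sites, `rBA` or `rBa` according to A's realized detection
#' on the same occasion.
#'
#' @inheritParams sim_single
#' @param psiA,psiBA,psiBa baseline occupancy parameters.
#' @param p shared baseline detection probability; the five block-specific
#'   probabilities default to it.
#' @param pA,pB,rA,rBA,rBa detection probabilities per block.
#' @param beta_psiA,beta_psiBA,beta_psiBa optional named slope vectors on
#'   the logit scale (covariates drawn N(0, 1) unless supplied).
#' @param species_names names for the two history slots.
#' @return A [detection_data] object with two histories; attribute
#'   `truth` holds the latent states `zA`, `zB` and generating parameters.
#' @examples
#' d <- sim_pair(1000, psiA = 0.5, psiBA = 0.7, psiBa = 0.3, p = 0.6, seed = 3)
#' attr(d, "truth")$phi   # latent-state interaction factor
#' @export
sim_pair <- function(n_sites, n_occasions = 2,
                     psiA = 0.5, psiBA = 0.5, psiBa = 0.5, p = 0.5,
                     pA = p, pB = p, rA = pA, rBA = pB, rBa = pB,
                     beta_psiA = NULL, beta_psiBA = NULL, beta_psiBa = NULL,
                     site_covariates = NULL,
                     substrate = FALSE, substrate_probs = c(0.4, 0.4, 0.2),
                     substrate_effect = 0, seed = 1,
                     species_names = c("A", "B")) {
  set.seed(seed)
  covs <- as.data.frame(site_covariates %||%
                          data.frame(row.names = seq_len(n_sites)))
  all_beta <- c(names(beta_psiA), names(beta_psiBA), names(beta_psiBa))
  for (nm in setdiff(all_beta, names(covs))) covs[[nm]] <- stats::rnorm(n_sites)
  lin <- function(base, beta) {
    eta <- qlogis(base)
    for (nm in names(beta)) eta <- eta + beta[[nm]] * covs[[nm]]
    plogis(eta)
  }
  psiA_i <- lin(psiA, beta_psiA)
  psiBA_i <- lin(psiBA, beta_psiBA)
  psiBa_i <- lin(psiBa, beta_psiBa)
  zA <- stats::rbinom(n_sites, 1, psiA_i)
  zB <- stats::rbinom(n_sites, 1, ifelse(zA == 1, psiBA_i, psiBa_i))
  sub <- if (substrate) draw_substrate(n_sites, n_occasions, substrate_probs)
         else matrix(2, n_sites, n_occasions)
  hA <- matrix(0, n_sites, n_occasions)
  hB <- matrix(0, n_sites, n_occasions)
  for (k in seq_len(n_occasions)) {
    pAk <- plogis(det_logit(ifelse(zB == 1, rA, pA), sub[, k],
                            substrate_effect, 0, 0))
    hA[, k] <- stats::rbinom(n_sites, 1, zA * pAk)
    pBk_both <- ifelse(hA[, k] == 1, rBA, rBa)
    pBk <- plogis(det_logit(ifelse(zA == 1, pBk_both, pB), sub[, k],
                            substrate_effect, 0, 0))
    hB[, k] <- stats::rbinom(n_sites, 1, zB * pBk)
  }
  hist <- list(hA, hB)
  names(hist) <- species_names
  occ <- if (substrate) list(substrate = sub) else NULL
  out <- detection_data(hist, site_covariates = if (ncol(covs)) covs,
                        occasion_covariates = occ)
  attr(out, "truth") <- list(zA = zA, zB = zB, psiA = psiA_i,
                             psiBA = psiBA_i, psiBa = psiBa_i,
                             phi = sif(mean(psiA_i), mean(psiBA_i), mean(psiBa_i)))
  out
}

## Per-area generating values for the study-design emulation.  Chosen to
## reproduce the qualitative structure of a two-park spoor survey: a
## water-associated dominant carnivore in the well-protected park, a
## prey-associated one in the pastoralist park, subordinate carnivores
## coupled to the dominant with co-occurrence (cheetah, leopard),
## near-independence (spotted hyena) or avoidance (wild dog), and the
## wild dog rarest throughout.
study_config <- function() {
  list(
    areas = c(Kruger = 269, Limpopo = 499),
    landscape = c("water", "bushlands", "grasslands", "thicket", "settlement"),
    substrate_probs = c(0.4, 0.4, 0.2),
    substrate_effect = 0.4,
    recapture_effect = 0.8,
    prey = list(
      buffalo = list(psi = c(Kruger = 0.65, Limpopo = 0.60), p = 0.55,
                     beta = c(water = 0.8)),
      impala  = list(psi = c(Kruger = 0.55, Limpopo = 0.50), p = 0.60,
                     beta = c(water = 0.6)),
      kudu    = list(psi = c(Kruger = 0.70, Limpopo = 0.65), p = 0.55,
                     beta = c(bushlands = 0.5)),
      cattle  = list(psi = c(Kruger = 0.02, Limpopo = 0.30), p = 0.60,
                     beta = c(settlement = -0.8)),
      poaching = list(psi = c(Kruger = 0.05, Limpopo = 0.25), p = 0.45,
                      beta = c(settlement = -0.6))),
    lion = list(p = 0.35,
                psi = c(Kruger = 0.30, Limpopo = 0.15),
                beta = list(Kruger = c(water = 0.8),
                            Limpopo = c(buffalo_psi = 1.2))),
    subordinates = list(
      cheetah = list(p = 0.30,
                     psiBA = c(Kruger = 0.30, Limpopo = 0.25),
                     psiBa = c(Kruger = 0.08, Limpopo = 0.08),
                     beta_BA = list(Kruger = c(water = -0.5),
                                    Limpopo = c(buffalo_psi = -0.5))),
      leopard = list(p = 0.35,
                     psiBA = c(Kruger = 0.45, Limpopo = 0.60),
                     psiBa = c(Kruger = 0.25, Limpopo = 0.35),
                     beta_BA = list(Kruger = c(water = -0.4),
                                    Limpopo = c(buffalo_psi = -0.4))),
      spotted_hyena = list(p = 0.60,
                           psiBA = c(Kruger = 0.55, Limpopo = 0.50),
                           psiBa = c(Kruger = 0.53, Limpopo = 0.30),
                           beta_BA = list(Kruger = NULL, Limpopo = NULL)),
      wild_dog = list(p = 0.15,
                      psiBA = c(Kruger = 0.08, Limpopo = 0.18),
                      psiBa = c(Kruger = 0.20, Limpopo = 0.08),
                      beta_BA = list(Kruger = c(bushlands = -0.4),
                                     Limpopo = NULL))))
}

#' Simulate the full two-park study design
#'
#' Generates a 768-site survey emulating a two-area spoor-transect design:
#' 269 sites in "Kruger" and 499 in "Limpopo", two consecutive occasions
#' per site, a 3-level substrate detection covariate, continuous landscape
#' covariates (water, bushlands, grasslands, thicket, settlement),
#' covariate-driven prey and threat species (buffalo, impala, kudu,
#' cattle, poaching), and five carnivores in which each subordinate's
#' occupancy is coupled to the dominant (lion) latent state.  Generating
#' values reproduce qualitative effect directions (e.g. lion follows water
#' in Kruger and buffalo in Limpopo; wild dog avoids lion in Kruger; wild
#' dog is the rarest carnivore), not any particular field estimate.
#'
#' @param seed RNG seed; output is a pure function of it.
#' @return A [detection_data] object with ten species histories, area
#'   labels, landscape site covariates and substrate/recapture occasion
#'   covariates.  Attribute `truth` records latent states and the
#'   generating configuration.
#' @export
sim_study <- function(seed = 1) {
  set.seed(seed)
  cfg <- study_config()
  n <- sum(cfg$areas); K <- 2
  area <- rep(names(cfg$areas), cfg$areas)
  covs <- as.data.frame(lapply(setNames(cfg$landscape, cfg$landscape),
                               function(nm) stats::rnorm(n)))
  sub <- draw_substrate(n, K, cfg$substrate_probs)
  truth <- list(config = cfg)

  area_prob <- function(base_by_area, beta = NULL) {
    eta <- qlogis(base_by_area[area])
    for (nm in names(beta)) eta <- eta + beta[[nm]] * covs[[nm]]
    unname(plogis(eta))
  }
  histories <- list()
  prey_psi <- list()
  for (sp in names(cfg$prey)) {
    ps <- cfg$prey[[sp]]
    psi_i <- area_prob(ps$psi, ps$beta)
    z <- stats::rbinom(n, 1, psi_i)
    histories[[sp]] <- draw_history(z, ps$p, sub, cfg$substrate_effect,
                                    cfg$recapture_effect)
    prey_psi[[sp]] <- psi_i
    truth[[paste0("z_", sp)]] <- z
  }
  ## prey occupancy probabilities act as carnivore covariates, mirroring
  ## the pipeline's use of estimated psi-hat
  covs$buffalo_psi_true <- prey_psi$buffalo

  lion_eta <- qlogis(cfg$lion$psi[area])
  lion_eta <- lion_eta + ifelse(area == "Kruger",
                                cfg$lion$beta$Kruger[["water"]] * covs$water,
                                cfg$lion$beta$Limpopo[["buffalo_psi"]] *
                                  (prey_psi$buffalo - mean(prey_psi$buffalo)))
  psiA_i <- unname(plogis(lion_eta))
  zA <- stats::rbinom(n, 1, psiA_i)
  histories$lion <- draw_history(zA, cfg$lion$p, sub, cfg$substrate_effect,
                                 cfg$recapture_effect)
  truth$z_lion <- zA; truth$psi_lion <- psiA_i

  cond_prob <- function(base_by_area, beta_by_area) {
    eta <- qlogis(base_by_area[area])
    for (ar in names(cfg$areas)) {
      b <- beta_by_area[[ar]]
      for (nm in names(b)) {
        x <- if (nm == "buffalo_psi")
          prey_psi$buffalo - mean(prey_psi$buffalo) else covs[[nm]]
        eta <- eta + ifelse(area == ar, b[[nm]] * x, 0)
      }
    }
    unname(plogis(eta))
  }
  for (sp in names(cfg$subordinates)) {
    ss <- cfg$subordinates[[sp]]
    psiBA_i <- cond_prob(ss$psiBA, ss$beta_BA)
    psiBa_i <- cond_prob(ss$psiBa, ss$beta_BA)
    zB <- stats::rbinom(n, 1, ifelse(zA == 1, psiBA_i, psiBa_i))
    histories[[sp]] <- draw_history(zB, ss$p, sub, cfg$substrate_effect,
                                    cfg$recapture_effect)
    truth[[paste0("z_", sp)]] <- zB
  }
  covs$buffalo_psi_true <- NULL
  occ <- list(substrate = sub)
  for (sp in c("lion", names(cfg$subordinates)))
    occ[[paste0("recap_", sp)]] <- make_recapture_covariate(histories[[sp]])
  out <- detection_data(histories, site_covariates = covs,
                        occasion_covariates = occ,
                        site_id = sprintf("site_%03d", seq_len(n)),
                        area = area)
  attr(out, "truth") <- truth
  out
}
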