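#' Species interaction factor
#'
#' Ratio of the joint occupancy of two species to its expectation under
#' independence: `phi = psiAB / (psiA * psiB)` with `psiAB = psiA * psiBA`
#' and `psiB = psiA * psiBA + (1 - psiA) * psiBa`.  `phi < 1` indicates
#' avoidance of the dominant species A by the subordinate B, `phi = 1`
#' independence, `phi > 1` co-occurrence beyond independence.
#'
#' The alternative `denominator = "conditional"` evaluates
#' `psiAB / (psiBA * psiBa)` instead; it is provided for comparison with
#' formulations that normalize by the conditional occupancies rather than
#' the unconditional product, and does not equal 1 under independence.
#'
#' @param psiA,psiBA,psiBa occupancy parameters (scalars or vectors):
#'   P(A), P(B | A present), P(B | A absent).
#' @param denominator `"product"` (default; independence-normalized) or
#'   `"conditional"`.
#' @return The interaction factor(s) `phi > 0`.
#' @examples
#' sif(0.3, 0.4, 0.4)        # independence: exactly 1
#' sif(0.19, 0.37, 0.36)     # weak co-occurrence, ~1.02
#' @export
sif <- function(psiA, psiBA, psiBa,
                denominator = c("product", "conditional")) {
  denominator <- match.arg(denominator)
  stopifnot(all(psiA > 0 & psiA < 1), all(psiBA >= 0 & psiBA <= 1),
            all(psiBa >= 0 & psiBa <= 1))
  psiAB <- psiA * psiBA
  ## written so that psiB == psiBA exactly when psiBA == psiBa, making
  ## the independence identity phi = 1 exact in floating point
  psiB <- psiBa + psiA * (psiBA - psiBa)
  if (denominator == "product") {
    if (any(psiB == 0))
      stop("subordinate species has zero marginal occupancy; SIF undefined")
    psiAB / (psiA * psiB)
  } else {
    if (any(psiBA * psiBa == 0))
      stop("conditional denominator is zero; SIF undefined")
    psiAB / (psiBA * psiBa)
  }
}

#' Averaged species interaction factor with delta-method CI
#'
#' Site-level interaction factors `phi_i = sif(psiA_i, psiBA_i, psiBa_i)`
#' from a fitted two-species model, their arithmetic mean, and a
#' delta-method standard error obtained by propagating the coefficient
#' covariance through the mean-phi map.  The association is flagged
#' significant when the 95% CI (`phi_mean +/- 1.96 se`) excludes 1.
#'
#' @param fit a converged [occu_pair] fit.
#' @param denominator passed to [sif()].
#' @return An object of class `sif_estimate` with `phi_site`, `phi_mean`,
#'   `se`, `ci95`, `significant`.
#' @export
sif_estimate <- function(fit, denominator = c("product", "conditional")) {
  stopifnot(inherits(fit, "occu_pair"))
  denominator <- match.arg(denominator)
  if (!fit$converged)
    stop("two-species fit did not converge; SIF unavailable")
  phi_site <- sif(fit$psiA_hat, fit$psiBA_hat, fit$psiBa_hat,
                  denominator = denominator)
  newdata <- fit$data$site_covariates
  if (!nrow(newdata) || !ncol(newdata))
    newdata <- data.frame(row.names = seq_len(fit$n_sites))
  mean_phi <- function(beta) {
    pr <- pair_probs_newdata(fit, beta, newdata)
    mean(sif(pr$psiA, pr$psiBA, pr$psiBa, denominator = denominator))
  }
  se <- NA_real_
  if (!is.null(fit$vcov)) {
    g <- num_grad(mean_phi, fit$coefficients)
    se <- sqrt(max(0, drop(t(g) %*% fit$vcov %*% g)))
  }
  phi_mean <- mean(phi_site)
  ci <- phi_mean + c(-1.96, 1.96) * se
  structure(list(phi_site = phi_site, phi_mean = phi_mean, se = se,
                 ci95 = ci,
                 significant = is.finite(se) && (ci[1] > 1 || ci[2] < 1),
                 denominator = denominator,
                 pair = paste(fit$speciesA, fit$speciesB, sep = "-")),
            class = "sif_estimate")
}

#' @export
print.sif_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("SIF %s: phi = %.*f +/- %.*f (95%% CI %.3f-%.3f)%s\n",
              x$pair, digits, x$phi_mean, digits, x$se,
              x$ci95[1], x$ci95[2],
              if (isTRUE(x$significant)) " *" else ""))
  cat("Interpretation:",
      if (x$phi_mean < 1) "phi < 1, avoidance"
      else if (x$phi_mean > 1) "phi > 1, co-occurrence"
      else "independence",
      if (isTRUE(x$significant)) "(CI excludes 1)" else "(CI overlaps 1)", "\n")
  invisible(x)
}

#' SIF and conditional-occupancy profile along a covariate
#'
#' Evaluates `psiA`, `psiBA`, `psiBa` and the interaction factor along a
#' grid of one covariate, holding every other site covariate at its mean
#' (0 on the z-scale), with delta-method standard errors for phi at each
#' grid point.  Grid values are interpreted on the standardized scale used
#' in the fit; if the covariate was standardized with
#' [standardize_covariates()], the returned table also reports the grid
#' back-transformed to the original scale.
#'
#' @param fit a converged [occu_pair] fit.
#' @param covariate name of a site covariate appearing in at least one
#'   occupancy predictor.
#' @param grid numeric grid on the (standardized) covariate scale;
#'   default an even grid over the observed range.
#' @param length.out grid size when `grid` is NULL.
#' @param denominator passed to [sif()].
#' @return A data frame with columns `covariate` (original scale when a
#'   scaling is recorded), `z` (model scale), `psiA`, `psiBA`, `psiBa`,
#'   `phi`, `se`.
#' @export
sif_profile <- function(fit, covariate, grid = NULL, length.out = 25,
                        denominator = c("product", "conditional")) {
  stopifnot(inherits(fit, "occu_pair"))
  denominator <- match.arg(denominator)
  if (!fit$converged) stop("fit did not converge; profile unavailable")
  vars <- unique(unlist(lapply(fit$formulas[c("psiA", "psiBA", "psiBa")],
                               all.vars)))
  if (!covariate %in% vars)
    stop("covariate '", covariate, "' is absent from every occupancy predictor")
  x_obs <- fit$data$site_covariates[[covariate]]
  if (is.null(x_obs)) stop("covariate '", covariate, "' not in the dataset")
  grid <- grid %||% seq(min(x_obs), max(x_obs), length.out = length.out)
  base <- as.data.frame(lapply(fit$data$site_covariates, function(v)
    if (is.numeric(v)) mean(v) else v[[1]]))
  if (!ncol(base)) base <- data.frame(row.names = 1)
  newdata <- base[rep(1, length(grid)), , drop = FALSE]
  newdata[[covariate]] <- grid
  rownames(newdata) <- NULL

  pr <- pair_probs_newdata(fit, fit$coefficients, newdata)
  phi <- sif(pr$psiA, pr$psiBA, pr$psiBa, denominator = denominator)
  se <- rep(NA_real_, length(grid))
  if (!is.null(fit$vcov)) {
    for (j in seq_along(grid)) {
      gj <- num_grad(function(beta) {
        prj <- pair_probs_newdata(fit, beta, newdata[j, , drop = FALSE])
        sif(prj$psiA, prj$psiBA, prj$psiBa, denominator = denominator)
      }, fit$coefficients)
      se[j] <- sqrt(max(0, drop(t(gj) %*% fit$vcov %*% gj)))
    }
  }
  sc <- fit$data$scaling[[covariate]]
  orig <- if (!is.null(sc)) grid * sc[["scale"]] + sc[["center"]] else grid
  data.frame(covariate = orig, z = grid, psiA = pr$psiA, psiBA = pr$psiBA,
             psiBa = pr$psiBa, phi = phi, se = se)
}
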