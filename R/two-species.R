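#' Latent joint-state probabilities for a species pair
#'
#' Probabilities of the four occupancy states \{AB, Ab, aB, ab\} of a
#' dominant species A and subordinate species B under the conditional
#' parameterization: `psiBA = P(B | A present)`, `psiBa = P(B | A absent)`.
#'
#' @param psiA,psiBA,psiBa probabilities in \[0, 1\] (scalars or vectors).
#' @return A 4-column matrix with columns `AB`, `Ab`, `aB`, `ab`;
#'   rows sum to 1.
#' @examples
#' joint_state_probs(0.18, 0.08, 0.01)
#' @export
joint_state_probs <- function(psiA, psiBA, psiBa) {
  stopifnot(all(psiA >= 0 & psiA <= 1), all(psiBA >= 0 & psiBA <= 1),
            all(psiBa >= 0 & psiBa <= 1))
  cbind(AB = psiA * psiBA, Ab = psiA * (1 - psiBA),
        aB = (1 - psiA) * psiBa, ab = (1 - psiA) * (1 - psiBa))
}

## Vectorized two-species site likelihood.  All detection arguments are
## sites x occasions matrices; psiA/psiBA/psiBa are per-site vectors.
## B's detection under co-occurrence is conditioned on A's *observed*
## same-occasion detection (rBA if A was detected that occasion, rBa
## otherwise; a missing A occasion counts as not detected).
lik_two_vec <- function(psiA, psiBA, psiBa, pA, pB, rA, rBA, rBa, hA, hB) {
  a_det <- !is.na(hA) & hA == 1
  Q <- ifelse(a_det, rBA, rBa)
  lAB <- bern_logsum(hA, rA) + bern_logsum(hB, Q)
  lAb <- bern_logsum(hA, pA)
  laB <- bern_logsum(hB, pB)
  noA <- rowSums(hA == 1, na.rm = TRUE) == 0
  noB <- rowSums(hB == 1, na.rm = TRUE) == 0
  psiA * psiBA * exp(lAB) +
    psiA * (1 - psiBA) * exp(lAb) * noB +
    (1 - psiA) * psiBa * exp(laB) * noA +
    (1 - psiA) * (1 - psiBa) * noA * noB
}

#' Two-species site likelihood
#'
#' Probability of a pair of detection histories at one site, mixing over
#' the four latent occupancy states.  Detection parameters: `pA`, `pB`
#' apply when only one species is present; `rA`, `rBA`, `rBa` when both
#' are present, with B's occasion-level detection probability `rBA` when A
#' was detected that occasion and `rBa` when it was not.  Missing
#' occasions are skipped.
#'
#' @param params a named list with elements `psiA`, `psiBA`, `psiBa`
#'   (scalars) and `pA`, `pB`, `rA`, `rBA`, `rBa` (scalars or length-K
#'   vectors).
#' @param historyA,historyB 0/1/NA vectors of equal length K.
#' @return The likelihood of the joint history.
#' @examples
#' pr <- as.list(setNames(rep(0.5, 8),
#'   c("psiA", "psiBA", "psiBa", "pA", "pB", "rA", "rBA", "rBa")))
#' site_lik_two(pr, c(0, 0), c(0, 0))  # 0.390625
#' @export
site_lik_two <- function(params, historyA, historyB) {
  if (length(historyA) != length(historyB))
    stop("historyA and historyB must have the same number of occasions")
  K <- length(historyA)
  as_row <- function(x) matrix(rep_len(x, K), nrow = 1)
  drop(lik_two_vec(params$psiA, params$psiBA, params$psiBa,
                   as_row(params$pA), as_row(params$pB), as_row(params$rA),
                   as_row(params$rBA), as_row(params$rBa),
                   matrix(historyA, 1), matrix(historyB, 1)))
}

## Coefficient layout for the two-species model.  Occupancy blocks:
## psiA always; psiBA and psiBa separate under interaction (SP+INT), a
## single shared psiB block otherwise (SP).  Detection blocks: under the
## "shared" constraint pA = rA and pB = rBA = rBa (2 blocks); "free"
## estimates all five.
pair_layout <- function(kA, kBA, kBa, kp, interaction, constraint) {
  blocks <- list(psiA = kA, psiBA = kBA)
  if (interaction) blocks$psiBa <- kBa
  if (constraint == "shared") {
    blocks$pA <- kp; blocks$pB <- kp
  } else {
    blocks$pA <- kp; blocks$pB <- kp
    blocks$rA <- kp; blocks$rBA <- kp; blocks$rBa <- kp
  }
  ends <- cumsum(unlist(blocks))
  starts <- c(1, utils::head(ends, -1) + 1)
  idx <- Map(seq, starts, ends)
  names(idx) <- names(blocks)
  idx
}

pair_probs <- function(beta, idx, XA, XBA, XBa, W, interaction, constraint) {
  n <- nrow(XA)
  psiA <- plogis(drop(XA %*% beta[idx$psiA]))
  psiBA <- plogis(drop(XBA %*% beta[idx$psiBA]))
  psiBa <- if (interaction) plogis(drop(XBa %*% beta[idx$psiBa])) else psiBA
  pmat <- function(ix) {
    P <- vapply(W, function(w) plogis(drop(w %*% beta[ix])), numeric(n))
    if (n == 1) matrix(P, nrow = 1) else P
  }
  pA <- pmat(idx$pA); pB <- pmat(idx$pB)
  if (constraint == "shared") {
    rA <- pA; rBA <- pB; rBa <- pB
  } else {
    rA <- pmat(idx$rA); rBA <- pmat(idx$rBA); rBa <- pmat(idx$rBa)
  }
  list(psiA = psiA, psiBA = psiBA, psiBa = psiBa,
       pA = pA, pB = pB, rA = rA, rBA = rBA, rBa = rBa)
}

#' Fit a conditional two-species occupancy model
#'
#' Maximum-likelihood fit for a dominant species A and subordinate B.
#' `interaction = TRUE` fits the SP+INT parameterization with separate
#' logit-linear predictors for `psiBA` (B given A present) and `psiBa`
#' (B given A absent); `interaction = FALSE` fits the SP constraint
#' `psiBA = psiBa` with one shared predictor.  `detection_constraint =
#' "shared"` (default) sets `pA = rA` and `pB = rBA = rBa`, i.e. neither
#' species alters the other's detectability; `"free"` estimates all five
#' detection blocks.  Non-convergence is reported via the `converged`
#' flag, never an error.
#'
#' @param data a [detection_data] object holding both species.
#' @param speciesA,speciesB names or indices of the dominant and
#'   subordinate species histories.
#' @param psiA_formula,psiBA_formula,psiBa_formula RHS-only formulas for
#'   the occupancy predictors; `psiBa_formula` defaults to
#'   `psiBA_formula` and is ignored when `interaction = FALSE`.
#' @param p_formula RHS-only formula for every detection predictor.
#' @param interaction fit SP+INT (`TRUE`) or SP (`FALSE`).
#' @param detection_constraint `"shared"` or `"free"` (see above).
#' @param n_starts,seed multi-start optimizer controls.
#' @return An object of class `occu_pair` with the coefficient vector,
#'   `vcov`, `neg2loglik`, `K`, `converged`, and per-site `psiA_hat`,
#'   `psiBA_hat`, `psiBa_hat` plus detection matrices.
#' @examples
#' d <- sim_pair(n_sites = 300, psiA = 0.5, psiBA = 0.7, psiBa = 0.3,
#'               p = 0.6, seed = 1)
#' fit <- occu_pair(d, n_starts = 3, seed = 1)
#' fit
#' @export
occu_pair <- function(data, speciesA = 1, speciesB = 2,
                      psiA_formula = ~1, psiBA_formula = ~1,
                      psiBa_formula = psiBA_formula, p_formula = ~1,
                      interaction = TRUE,
                      detection_constraint = c("shared", "free"),
                      n_starts = 10, seed = 1) {
  stopifnot(inherits(data, "detection_data"))
  detection_constraint <- match.arg(detection_constraint)
  hA <- data$histories[[speciesA]]
  hB <- data$histories[[speciesB]]
  if (is.null(hA) || is.null(hB)) stop("species not found in data")

  dA <- build_designs(data, psiA_formula, p_formula)
  dBA <- build_designs(data, psiBA_formula, p_formula)
  dBa <- build_designs(data, psiBa_formula, p_formula)
  XA <- dA$X; XBA <- dBA$X; XBa <- dBa$X; W <- dA$W
  idx <- pair_layout(ncol(XA), ncol(XBA), ncol(XBa), ncol(W[[1]]),
                     interaction, detection_constraint)
  npar <- max(unlist(idx))
  no_detections <- !any(hA == 1, na.rm = TRUE) || !any(hB == 1, na.rm = TRUE)

  key <- do.call(paste, c(lapply(seq_len(ncol(XA)), function(j) XA[, j]),
                          lapply(seq_len(ncol(XBA)), function(j) XBA[, j]),
                          lapply(seq_len(ncol(XBa)), function(j) XBa[, j]),
                          lapply(W, function(w) apply(w, 1, paste, collapse = ",")),
                          lapply(seq_len(ncol(hA)), function(k) hA[, k]),
                          lapply(seq_len(ncol(hB)), function(k) hB[, k]),
                          sep = "|"))
  cp <- collapse_patterns(key)
  cXA <- XA[cp$idx, , drop = FALSE]; cXBA <- XBA[cp$idx, , drop = FALSE]
  cXBa <- XBa[cp$idx, , drop = FALSE]
  cW <- lapply(W, function(w) w[cp$idx, , drop = FALSE])
  chA <- hA[cp$idx, , drop = FALSE]; chB <- hB[cp$idx, , drop = FALSE]
  w8 <- cp$weight

  nll <- function(beta) {
    pr <- pair_probs(beta, idx, cXA, cXBA, cXBa, cW,
                     interaction, detection_constraint)
    L <- lik_two_vec(pr$psiA, pr$psiBA, pr$psiBa, pr$pA, pr$pB,
                     pr$rA, pr$rBA, pr$rBa, chA, chB)
    v <- -sum(w8 * log(L))
    if (!is.finite(v)) 1e10 else v
  }
  res <- mle_optim(nll, npar, n_starts, seed)

  beta <- res$par
  nm <- character(npar)
  nm[idx$psiA] <- paste0("psiA_", colnames(XA))
  nm[idx$psiBA] <- paste0(if (interaction) "psiBA_" else "psiB_", colnames(XBA))
  if (interaction) nm[idx$psiBa] <- paste0("psiBa_", colnames(XBa))
  for (blk in intersect(c("pA", "pB", "rA", "rBA", "rBa"), names(idx)))
    nm[idx[[blk]]] <- paste0(blk, "_", colnames(W[[1]]))
  names(beta) <- nm

  pr <- pair_probs(beta, idx, XA, XBA, XBa, W, interaction, detection_constraint)
  boundary <- is.finite(beta[1]) &&
    boundary_flag(beta, c(pr$psiA, pr$psiBA, pr$psiBa,
                          pr$pA, pr$pB, pr$rA, pr$rBA, pr$rBa))
  if (!is.null(res$vcov)) dimnames(res$vcov) <- list(nm, nm)
  structure(list(coefficients = beta, vcov = res$vcov,
                 neg2loglik = 2 * res$value, K = npar,
                 converged = res$ok && !boundary && !no_detections,
                 boundary = isTRUE(boundary), no_detections = no_detections,
                 psiA_hat = pr$psiA, psiBA_hat = pr$psiBA, psiBa_hat = pr$psiBa,
                 pA_hat = pr$pA, pB_hat = pr$pB, rA_hat = pr$rA,
                 rBA_hat = pr$rBA, rBa_hat = pr$rBa,
                 interaction = interaction,
                 detection_constraint = detection_constraint,
                 layout = idx,
                 formulas = list(psiA = psiA_formula, psiBA = psiBA_formula,
                                 psiBa = psiBa_formula, p = p_formula),
                 speciesA = if (is.character(speciesA)) speciesA
                            else names(data$histories)[speciesA],
                 speciesB = if (is.character(speciesB)) speciesB
                            else names(data$histories)[speciesB],
                 data = data, n_sites = n_sites(data)),
            class = "occu_pair")
}

## Re-evaluate all parameter blocks at (possibly new) site covariates.
## newdata: data frame of site covariates; occasion covariates are held
## at the dataset's first-occasion column means.
pair_probs_newdata <- function(fit, beta, newdata) {
  data <- fit$data
  if (!is.null(data$area) && is.null(newdata$area))
    newdata$area <- factor(names(which.max(table(data$area))),
                           levels = levels(factor(data$area)))
  mm <- function(f) stats::model.matrix(f, newdata)
  XA <- mm(fit$formulas$psiA); XBA <- mm(fit$formulas$psiBA)
  XBa <- mm(fit$formulas$psiBa)
  pd <- newdata
  for (nmv in names(data$occasion_covariates))
    pd[[nmv]] <- mean(data$occasion_covariates[[nmv]][, 1])
  pd$occasion <- factor(1, levels = seq_len(n_occasions(data)))
  Wn <- list(stats::model.matrix(fit$formulas$p, pd))
  pair_probs(beta, fit$layout, XA, XBA, XBa, Wn,
             fit$interaction, fit$detection_constraint)
}

#' @export
print.occu_pair <- function(x, digits = 4, ...) {
  cat("Two-species occupancy model:", x$speciesA, "(dominant) /",
      x$speciesB, "(subordinate)\n")
  cat("Parameterization:", if (x$interaction) "SP+INT (psiBA != psiBa)"
      else "SP (psiBA = psiBa)",
      "| detection:", x$detection_constraint, "\n")
  if (!x$converged)
    cat("** did not converge",
        if (x$no_detections) "(a species has no detections)"
        else if (x$boundary) "(boundary estimate)", "**\n")
  cat("Coefficients:\n")
  print(round(x$coefficients, digits))
  cat(sprintf("-2l = %.2f, K = %d, AIC = %.2f\n", x$neg2loglik, x$K,
              x$neg2loglik + 2 * x$K))
  cat(sprintf("mean psiA = %.3f, psiBA = %.3f, psiBa = %.3f\n",
              mean(x$psiA_hat), mean(x$psiBA_hat), mean(x$psiBa_hat)))
  invisible(x)
}

#' @export
coef.occu_pair <- function(object, ...) object$coefficients

#' @export
vcov.occu_pair <- function(object, ...) object$vcov

#' @export
logLik.occu_pair <- function(object, ...)
  structure(-object$neg2loglik / 2, df = object$K, nobs = object$n_sites,
            class = "logLik")

#' @export
summary.occu_pair <- function(object, ...) {
  se <- if (!is.null(object$vcov)) sqrt(pmax(0, diag(object$vcov)))
        else rep(NA_real_, object$K)
  tab <- data.frame(estimate = object$coefficients, se = se,
                    row.names = names(object$coefficients))
  avg <- c(psiA = mean(object$psiA_hat), psiBA = mean(object$psiBA_hat),
           psiBa = mean(object$psiBa_hat), rA = mean(object$rA_hat),
           pA = mean(object$pA_hat), pB = mean(object$pB_hat),
           rBA = mean(object$rBA_hat), rBa = mean(object$rBa_hat))
  out <- list(pair = paste(object$speciesA, object$speciesB, sep = "-"),
              coefficients = tab, averages = avg,
              neg2loglik = object$neg2loglik, K = object$K,
              aic = object$neg2loglik + 2 * object$K,
              converged = object$converged, interaction = object$interaction)
  class(out) <- "summary.occu_pair"
  out
}

#' @export
print.summary.occu_pair <- function(x, digits = 4, ...) {
  cat("Two-species occupancy fit:", x$pair,
      if (!x$converged) "(NOT CONVERGED)", "\n")
  print(round(x$coefficients, digits))
  cat("Site-averaged parameters:\n")
  print(round(x$averages, 3))
  cat(sprintf("-2l = %.2f, K = %d, AIC = %.2f\n", x$neg2loglik, x$K, x$aic))
  invisible(x)
}
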