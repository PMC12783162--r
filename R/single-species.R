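#' Single-species site likelihood
#'
#' Probability of a detection history at one site under the single-season
#' occupancy model: `psi * prod_k p_k^h_k (1-p_k)^(1-h_k)` plus, when no
#' detection was made, `(1 - psi)` for the site being unoccupied.  Missing
#' occasions are skipped.
#'
#' @param psi occupancy probability (scalar, or vector over sites).
#' @param p detection probability per occasion: a vector of length K, or a
#'   sites x occasions matrix.
#' @param history detection history (0/1/NA), a vector of length K or a
#'   sites x occasions matrix conformable with `p`.
#' @return Likelihood value(s), one per site.
#' @examples
#' site_lik_single(0.5, c(0.5, 0.5), c(1, 0))  # 0.125
#' site_lik_single(0.5, c(0.5, 0.5), c(0, 0))  # 0.625
#' @export
site_lik_single <- function(psi, p, history) {
  if (!is.matrix(history)) history <- matrix(history, nrow = 1)
  if (!is.matrix(p)) p <- matrix(p, nrow = nrow(history),
                                 ncol = ncol(history), byrow = TRUE)
  stopifnot(all(dim(p) == dim(history)),
            all(psi >= 0 & psi <= 1), all(p >= 0 & p <= 1))
  if (any(rowSums(!is.na(history)) == 0))
    stop("site with all-missing history is uninformative; drop it")
  detected <- rowSums(history == 1, na.rm = TRUE) > 0
  cond <- exp(bern_logsum(history, p))     # P(history | occupied)
  psi * cond + (1 - psi) * ifelse(detected, 0, 1)
}

## Build psi and p design matrices for one species.
## Returns X (n x kpsi), W (list of K matrices n x kp), and column names.
build_designs <- function(data, psi_formula, p_formula) {
  n <- n_sites(data); K <- n_occasions(data)
  site_df <- data$site_covariates
  if (!is.null(data$area)) site_df$area <- factor(data$area)
  X <- stats::model.matrix(psi_formula, site_df)
  long <- site_df[rep(seq_len(n), K), , drop = FALSE]
  for (nm in names(data$occasion_covariates))
    long[[nm]] <- as.vector(data$occasion_covariates[[nm]])
  long$occasion <- factor(rep(seq_len(K), each = n))
  MM <- stats::model.matrix(p_formula, long)
  W <- lapply(seq_len(K), function(k) MM[(k - 1) * n + seq_len(n), , drop = FALSE])
  list(X = X, W = W)
}

## Collapse sites sharing an identical (design row, history) pattern into
## one weighted row.  Exact, and reduces intercept-only fits to a handful
## of unique detection histories.
collapse_patterns <- function(key) {
  u <- !duplicated(key)
  idx <- which(u)
  map <- match(key, key[u])
  list(idx = idx, weight = as.numeric(tabulate(map, nbins = length(idx))),
       map = map)
}

negloglik_single_factory <- function(X, W, h, weight = NULL) {
  n <- nrow(h); K <- ncol(h)
  weight <- weight %||% rep(1, n)
  detected <- rowSums(h == 1, na.rm = TRUE) > 0
  kpsi <- ncol(X)
  kp <- ncol(W[[1]])
  function(beta) {
    psi <- plogis(drop(X %*% beta[seq_len(kpsi)]))
    bp <- beta[kpsi + seq_len(kp)]
    P <- vapply(W, function(w) plogis(drop(w %*% bp)), numeric(n))
    if (n == 1) P <- matrix(P, nrow = 1)
    lcond <- bern_logsum(h, P)
    ll <- numeric(n)
    ll[detected] <- log(psi[detected]) + lcond[detected]
    if (any(!detected)) {
      i <- !detected
      ll[i] <- log(psi[i] * exp(lcond[i]) + (1 - psi[i]))
    }
    v <- -sum(weight * ll)
    if (!is.finite(v)) 1e10 else v
  }
}

## Shared multi-start BFGS driver.  First start is beta = 0; the rest are
## seeded dispersed initials.  Ties broken by first-found.
mle_optim <- function(nll, npar, n_starts, seed, maxit = 500) {
  set.seed(seed)
  starts <- rbind(rep(0, npar),
                  if (n_starts > 1)
                    matrix(stats::runif((n_starts - 1) * npar, -2, 2),
                           ncol = npar))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    opt <- tryCatch(stats::optim(starts[s, ], nll, method = "BFGS",
                                 control = list(maxit = maxit,
                                                reltol = 1e-12)),
                    error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value)) next
    if (is.null(best) || opt$value < best$value - 1e-9) best <- opt
  }
  if (is.null(best)) return(list(par = rep(NA_real_, npar), value = NA_real_,
                                 ok = FALSE, vcov = NULL))
  ## Newton polish: BFGS stops on objective change, which can leave the
  ## parameters ~1e-5 off in ill-conditioned parameterizations
  for (step in 1:2) {
    g <- num_grad(nll, best$par)
    H <- tryCatch(stats::optimHess(best$par, nll), error = function(e) NULL)
    if (is.null(H) || !all(is.finite(H))) break
    delta <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(delta) || !all(is.finite(delta)) || max(abs(delta)) > 1) break
    cand <- best$par - delta
    vc <- nll(cand)
    if (is.finite(vc) && vc <= best$value + 1e-10) {
      best$par <- cand; best$value <- min(vc, best$value)
    } else break
  }
  H <- tryCatch(stats::optimHess(best$par, nll), error = function(e) NULL)
  V <- if (!is.null(H) && all(is.finite(H)))
    tryCatch(solve(H), error = function(e) NULL)
  ok <- best$convergence == 0 && !is.null(V) && all(diag(V) >= -1e-8)
  list(par = best$par, value = best$value, ok = ok, vcov = V)
}

boundary_flag <- function(beta, probs, limit = 15) {
  any(abs(beta) > limit) || any(probs < 1e-6 | probs > 1 - 1e-6)
}

#' Fit a single-season single-species occupancy model
#'
#' Maximum-likelihood fit of the occupancy model with logit-linked linear
#' predictors for occupancy (`psi`) and detection (`p`).  Site covariates
#' may appear in either formula; occasion-level covariates (entries of
#' `occasion_covariates` such as substrate or the recapture indicator) and
#' the factor `occasion` may appear in the detection formula.  Optimization
#' uses multi-start BFGS; standard errors come from the inverse observed
#' information.  Non-convergence (optimizer failure, singular Hessian, or a
#' boundary estimate with |logit| > 15) is reported via the `converged`
#' flag, never an error, mirroring how sparse-detection datasets behave.
#'
#' @param data a [detection_data] object.
#' @param species species name or index within `data$histories`.
#' @param psi_formula RHS-only formula for the occupancy predictor.
#' @param p_formula RHS-only formula for the detection predictor.
#' @param n_starts number of optimizer starts (first is always beta = 0).
#' @param seed seed for the dispersed starting values.
#' @return An object of class `occu_single` with components `beta_psi`,
#'   `beta_p`, `vcov`, `neg2loglik`, `K` (parameter count), `converged`,
#'   `psi_hat` (per-site occupancy), `p_hat` (site x occasion detection).
#' @examples
#' d <- sim_single(n_sites = 200, psi = 0.6, p = 0.7, seed = 1)
#' fit <- occu_single(d, n_starts = 3, seed = 1)
#' fit
#' @export
occu_single <- function(data, species = 1, psi_formula = ~1, p_formula = ~1,
                        n_starts = 10, seed = 1) {
  stopifnot(inherits(data, "detection_data"))
  h <- data$histories[[species]]
  if (is.null(h)) stop("species '", species, "' not found")
  des <- build_designs(data, psi_formula, p_formula)
  no_detections <- !any(h == 1, na.rm = TRUE)

  key <- do.call(paste, c(lapply(seq_len(ncol(des$X)), function(j) des$X[, j]),
                          lapply(des$W, function(w) apply(w, 1, paste, collapse = ",")),
                          lapply(seq_len(ncol(h)), function(k) h[, k]),
                          sep = "|"))
  cp <- collapse_patterns(key)
  nll <- negloglik_single_factory(des$X[cp$idx, , drop = FALSE],
                                  lapply(des$W, function(w) w[cp$idx, , drop = FALSE]),
                                  h[cp$idx, , drop = FALSE], cp$weight)
  kpsi <- ncol(des$X); kp <- ncol(des$W[[1]])
  res <- mle_optim(nll, kpsi + kp, n_starts, seed)

  beta <- res$par
  names(beta) <- c(paste0("psi_", colnames(des$X)),
                   paste0("p_", colnames(des$W[[1]])))
  psi_hat <- plogis(drop(des$X %*% beta[seq_len(kpsi)]))
  p_hat <- vapply(des$W, function(w) plogis(drop(w %*% beta[kpsi + seq_len(kp)])),
                  numeric(n_sites(data)))
  if (n_sites(data) == 1) p_hat <- matrix(p_hat, nrow = 1)
  boundary <- is.finite(beta[1]) && boundary_flag(beta, c(psi_hat, p_hat))
  if (!is.null(res$vcov)) dimnames(res$vcov) <- list(names(beta), names(beta))
  structure(list(beta_psi = beta[seq_len(kpsi)], beta_p = beta[kpsi + seq_len(kp)],
                 coefficients = beta, vcov = res$vcov,
                 neg2loglik = 2 * res$value, K = kpsi + kp,
                 converged = res$ok && !boundary && !no_detections,
                 boundary = isTRUE(boundary), no_detections = no_detections,
                 psi_hat = psi_hat, p_hat = p_hat,
                 psi_formula = psi_formula, p_formula = p_formula,
                 species = if (is.character(species)) species
                           else names(data$histories)[species],
                 data = data, n_sites = n_sites(data)),
            class = "occu_single")
}

#' @export
print.occu_single <- function(x, digits = 4, ...) {
  cat("Single-species occupancy model:", x$species, "\n")
  cat("psi ~", deparse(x$psi_formula[[2]]), "  p ~", deparse(x$p_formula[[2]]), "\n")
  if (!x$converged)
    cat("** did not converge",
        if (x$no_detections) "(no detections)" else if (x$boundary) "(boundary estimate)",
        "**\n")
  cat("Coefficients:\n")
  print(round(x$coefficients, digits))
  cat(sprintf("-2l = %.*f, K = %d, AIC = %.*f\n", 2, x$neg2loglik, x$K,
              2, x$neg2loglik + 2 * x$K))
  cat(sprintf("mean psi-hat = %.3f (range %.3f-%.3f)\n",
              mean(x$psi_hat), min(x$psi_hat), max(x$psi_hat)))
  invisible(x)
}

#' @export
coef.occu_single <- function(object, ...) object$coefficients

#' @export
vcov.occu_single <- function(object, ...) object$vcov

#' @export
logLik.occu_single <- function(object, ...)
  structure(-object$neg2loglik / 2, df = object$K, nobs = object$n_sites,
            class = "logLik")

#' Per-site occupancy and detection predictions
#'
#' `type = "psi"` returns the model's unconditional per-site occupancy
#' with delta-method standard errors, plus the across-site mean and range
#' as attributes (the reporting format "mean (range min-max)").
#' `type = "p"` returns the site x occasion detection probabilities.
#' `type = "conditional"` returns the probability each site is occupied
#' given its observed history: 1 for any site with a detection (no false
#' positives), and `psi q / (psi q + 1 - psi)` with
#' `q = prod_k (1 - p_k)` for all-zero sites.
#'
#' @param object a fitted `occu_single` model.
#' @param type one of "psi", "p", "conditional".
#' @param ... unused.
#' @return A vector (psi, conditional) or matrix (p); for "psi" the
#'   attributes `mean` and `range` summarize the sites.
#' @export
predict.occu_single <- function(object, type = c("psi", "p", "conditional"), ...) {
  type <- match.arg(type)
  if (!object$converged && type != "p")
    warning("model did not converge; predictions are unreliable")
  if (type == "p") return(object$p_hat)
  if (type == "psi") {
    psi <- object$psi_hat
    se <- rep(NA_real_, length(psi))
    if (!is.null(object$vcov)) {
      des <- build_designs(object$data, object$psi_formula, object$p_formula)
      kpsi <- length(object$beta_psi)
      Vp <- object$vcov[seq_len(kpsi), seq_len(kpsi), drop = FALSE]
      # delta method on logit scale: se(psi) = psi(1-psi) * se(eta)
      se_eta <- sqrt(pmax(0, rowSums((des$X %*% Vp) * des$X)))
      se <- psi * (1 - psi) * se_eta
    }
    return(structure(psi, se = se, mean = mean(psi), range = range(psi)))
  }
  conditional_occupancy(object)
}

#' Occupancy probability conditional on the detection history
#'
#' Empirical-Bayes per-site occupancy: sites with at least one detection
#' get probability 1 (species are assumed never falsely identified);
#' all-zero sites get the posterior
#' `psi prod(1-p) / (psi prod(1-p) + 1 - psi)`.
#'
#' @param fit a fitted `occu_single` model.
#' @return A numeric vector, one probability per site.
#' @export
conditional_occupancy <- function(fit) {
  stopifnot(inherits(fit, "occu_single"))
  h <- fit$data$histories[[fit$species]]
  detected <- rowSums(h == 1, na.rm = TRUE) > 0
  q <- exp(bern_logsum(0 * h, fit$p_hat))    # prod over non-missing (1-p)
  post <- fit$psi_hat * q / (fit$psi_hat * q + 1 - fit$psi_hat)
  ifelse(detected, 1, post)
}

#' @export
summary.occu_single <- function(object, ...) {
  se <- if (!is.null(object$vcov)) sqrt(pmax(0, diag(object$vcov)))
        else rep(NA_real_, object$K)
  tab <- data.frame(estimate = object$coefficients, se = se,
                    z = object$coefficients / se,
                    row.names = names(object$coefficients))
  out <- list(call_species = object$species, coefficients = tab,
              neg2loglik = object$neg2loglik, K = object$K,
              aic = object$neg2loglik + 2 * object$K,
              converged = object$converged,
              psi_mean = mean(object$psi_hat), psi_range = range(object$psi_hat))
  class(out) <- "summary.occu_single"
  out
}

#' @export
print.summary.occu_single <- function(x, digits = 4, ...) {
  cat("Single-species occupancy fit:", x$call_species,
      if (!x$converged) "(NOT CONVERGED)", "\n")
  print(round(x$coefficients, digits))
  cat(sprintf("-2l = %.2f, K = %d, AIC = %.2f\n", x$neg2loglik, x$K, x$aic))
  cat(sprintf("mean psi-hat = %.3f (range %.3f-%.3f)\n",
              x$psi_mean, x$psi_range[1], x$psi_range[2]))
  invisible(x)
}

#' Simulate detection histories from a fitted single-species model
#'
#' @param object a fitted `occu_single` model.
#' @param nsim number of replicate datasets.
#' @param seed optional seed.
#' @param ... unused.
#' @return A list of detection matrices.
#' @export
simulate.occu_single <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$n_sites; K <- ncol(object$p_hat)
  lapply(seq_len(nsim), function(i) {
    z <- stats::rbinom(n, 1, object$psi_hat)
    matrix(stats::rbinom(n * K, 1, rep(z, K) * as.vector(object$p_hat)),
           n, K)
  })
}
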