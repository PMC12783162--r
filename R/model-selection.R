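#' Akaike information criterion from -2 log likelihood
#'
#' @param neg2loglik twice the negative maximized log-likelihood.
#' @param K number of estimated parameters (>= 1).
#' @return `neg2loglik + 2 * K`.
#' @examples
#' aic(863.85, 9)   # 881.85
#' @export
aic <- function(neg2loglik, K) {
  stopifnot(all(K >= 1))
  neg2loglik + 2 * K
}

#' Rank models by AIC
#'
#' Builds the standard model-selection table: AIC, delta-AIC relative to
#' the best model, Akaike weights `w_i = exp(-delta_i/2) / sum_j
#' exp(-delta_j/2)`, and model likelihoods `exp(-delta_i/2)`.  Weights are
#' relative to the supplied set of models only.
#'
#' @param models either a list of fitted `occu_single`/`occu_pair` objects
#'   (optionally named), or a data frame with columns `name`,
#'   `neg2loglik`, `K`.
#' @return A data frame of class `model_ranking`, sorted by AIC, with
#'   columns `name`, `aic`, `delta_aic`, `weight`, `model_likelihood`,
#'   `K`, `neg2loglik`, and `converged` when fits are supplied.
#' @export
rank_models <- function(models) {
  if (is.data.frame(models)) {
    stopifnot(all(c("name", "neg2loglik", "K") %in% names(models)))
    tab <- data.frame(name = as.character(models$name),
                      neg2loglik = models$neg2loglik, K = models$K,
                      converged = models$converged %||% TRUE,
                      stringsAsFactors = FALSE)
  } else {
    stopifnot(is.list(models), length(models) >= 1)
    nm <- names(models) %||% paste0("model", seq_along(models))
    tab <- data.frame(name = nm,
                      neg2loglik = vapply(models, `[[`, 0, "neg2loglik"),
                      K = vapply(models, `[[`, 0L, "K"),
                      converged = vapply(models, `[[`, TRUE, "converged"),
                      stringsAsFactors = FALSE)
  }
  tab$aic <- aic(tab$neg2loglik, tab$K)
  tab <- tab[order(tab$aic), ]
  tab$delta_aic <- tab$aic - tab$aic[1]
  tab$model_likelihood <- exp(-tab$delta_aic / 2)
  tab$weight <- tab$model_likelihood / sum(tab$model_likelihood)
  rownames(tab) <- NULL
  out <- tab[c("name", "aic", "delta_aic", "weight", "model_likelihood",
               "K", "neg2loglik", "converged")]
  class(out) <- c("model_ranking", "data.frame")
  out
}

#' @export
print.model_ranking <- function(x, digits = 2, ...) {
  y <- as.data.frame(x)
  for (cl in c("aic", "delta_aic", "neg2loglik")) y[[cl]] <- round(y[[cl]], digits)
  for (cl in c("weight", "model_likelihood")) y[[cl]] <- round(y[[cl]], 2)
  print(y)
  invisible(x)
}

#' Candidate set of competitive models
#'
#' Subsets a ranked table to the models with `delta_aic` strictly below
#' the cutoff, preserving rank order.
#'
#' @param table a `model_ranking` table from [rank_models()].
#' @param cutoff delta-AIC cutoff; default 2 (strict inequality).
#' @return The competitive subset, same class as the input.
#' @export
candidate_set <- function(table, cutoff = 2) {
  stopifnot(inherits(table, "model_ranking"))
  out <- table[table$delta_aic < cutoff, , drop = FALSE]
  rownames(out) <- NULL
  out
}
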