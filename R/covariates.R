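#' Z-standardize site covariates
#'
#' Replaces each named continuous site covariate by `(x - mean(x)) / sd(x)`
#' (sample standard deviation, n - 1 denominator), so standardized columns
#' have mean 0 and standard deviation 1.  The (mean, sd) pairs are retained
#' on the dataset so prediction grids can be expressed on the original
#' scale (see [sif_profile()]).
#'
#' @param data a [detection_data] object.
#' @param names covariates to standardize; default all site covariates
#'   with at least two distinct values.
#' @return The dataset with standardized covariates and a `scaling`
#'   attribute recording the centers and scales.
#' @export
standardize_covariates <- function(data, names = NULL) {
  stopifnot(inherits(data, "detection_data"))
  names <- names %||% base::names(data$site_covariates)
  missing <- setdiff(names, base::names(data$site_covariates))
  if (length(missing))
    stop("unknown site covariates: ", paste(missing, collapse = ", "))
  for (nm in names) {
    x <- data$site_covariates[[nm]]
    if (!is.numeric(x)) stop("covariate '", nm, "' is not numeric")
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0)
      stop("covariate '", nm, "' has zero variance; cannot z-scale")
    m <- mean(x)
    data$site_covariates[[nm]] <- (x - m) / s
    data$scaling[[nm]] <- c(center = m, scale = s)
  }
  data
}

#' Screen covariates for collinearity
#'
#' Computes all pairwise Pearson correlations among the named site
#' covariates and flags, for every pair with `|r|` above the threshold,
#' the member appearing later in `names` for exclusion.  The absolute
#' value is used, and the drop order follows the user-supplied list, so
#' runs are deterministic.
#'
#' @param data a [detection_data] object.
#' @param names covariates to screen (>= 2); default all site covariates.
#' @param threshold exclusion criterion on `|r|`, in (0, 1); default 0.6.
#' @return A list of class `collinearity_screen` with elements `retained`,
#'   `dropped`, and the full `correlations` matrix.
#' @export
collinearity_screen <- function(data, names = NULL, threshold = 0.6) {
  stopifnot(inherits(data, "detection_data"),
            threshold > 0, threshold < 1)
  names <- names %||% base::names(data$site_covariates)
  if (length(names) < 2) stop("need at least two covariates to screen")
  missing <- setdiff(names, base::names(data$site_covariates))
  if (length(missing))
    stop("unknown site covariates: ", paste(missing, collapse = ", "))
  if (n_sites(data) < 3)
    stop("fewer than 3 sites: pairwise correlation is degenerate")
  X <- as.matrix(data$site_covariates[names])
  r <- stats::cor(X)
  dropped <- character()
  for (j in seq_along(names)) {
    nm <- names[j]
    earlier <- setdiff(names[seq_len(j - 1)], dropped)
    if (length(earlier) && any(abs(r[nm, earlier]) > threshold))
      dropped <- c(dropped, nm)
  }
  structure(list(retained = setdiff(names, dropped), dropped = dropped,
                 correlations = r, threshold = threshold),
            class = "collinearity_screen")
}

#' @export
print.collinearity_screen <- function(x, digits = 3, ...) {
  cat("Collinearity screen (|r| >", x$threshold, "excluded)\n")
  print(round(x$correlations, digits))
  cat("Retained:", paste(x$retained, collapse = ", "), "\n")
  if (length(x$dropped))
    cat("Dropped: ", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Build the detection-recapture covariate
#'
#' Occasion-level 0/1 covariate absorbing serial dependence between
#' consecutive occasions: occasion 1 is always 0, and occasion k > 1
#' equals the detection at occasion k - 1 (missing previous occasions
#' count as 0).  For a two-occasion design this is exactly the rule
#' "0 if the animal was not seen in occasion 1, 1 if it was".
#'
#' @param history a sites x occasions detection matrix (0/1/NA).
#' @return A matrix of the same dimensions with values in \{0, 1\}.
#' @export
make_recapture_covariate <- function(history) {
  history <- as.matrix(history)
  if (ncol(history) < 2)
    stop("recapture covariate undefined for a single-occasion history")
  prev <- cbind(0, history[, -ncol(history), drop = FALSE])
  prev[is.na(prev)] <- 0
  storage.mode(prev) <- "double"
  dimnames(prev) <- dimnames(history)
  prev
}
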