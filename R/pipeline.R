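pipeline_defaults <- function() {
  list(dominant = "lion",
       subordinates = c("cheetah", "leopard", "spotted_hyena", "wild_dog"),
       prey = c("buffalo", "impala", "kudu", "cattle", "poaching"),
       landscape = c("water", "bushlands", "grasslands", "thicket",
                     "settlement"),
       collinearity_threshold = 0.6,
       delta_aic_cutoff = 2,
       n_starts = 5,
       seed = 1,
       conditional_prey = FALSE,
       profile_points = 11,
       out_dir = NULL,
       simulate_seed = NULL,
       data_path = NULL)
}

read_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- pipeline_defaults()
  for (nm in names(config)) cfg[[nm]] <- config[[nm]]
  cfg
}

#' Run the hierarchical co-occurrence analysis pipeline
#'
#' End-to-end orchestration of the multi-stage procedure, separately per
#' survey area: (1) z-standardize landscape covariates and screen them for
#' collinearity (|r| > threshold); (2) fit single-species occupancy models
#' for prey and threat species and attach their per-site occupancy
#' estimates as carnivore covariates; (3) fit univariate single-species
#' carnivore models over every candidate covariate, rank them by AIC, and
#' carry the top-ranking covariate forward (falling back to the null model
#' when nothing converges); (4) fit the two-species SP and SP+INT models
#' for each dominant-subordinate pair with those covariates and substrate
#' on detection; (5) rank the pair models and form the delta-AIC < cutoff
#' candidate set; (6) compute the averaged species interaction factor with
#' delta-method SE and an SIF profile over the dominant's top covariate.
#' Non-convergence at any stage is logged and flagged, never dropped.
#'
#' @param config a named list or path to a YAML file.  Recognized fields:
#'   `data` (a [detection_data] object), `data_path` + `species` (CSV
#'   input), `simulate_seed` (generate the built-in study emulation),
#'   `dominant`, `subordinates`, `prey`, `landscape` (species/covariate
#'   names), `collinearity_threshold` (default 0.6), `delta_aic_cutoff`
#'   (default 2), `n_starts`, `seed`, `conditional_prey` (use
#'   history-conditioned instead of unconditional prey occupancy as
#'   covariates), `profile_points`, `out_dir` (write CSV/JSON outputs).
#' @return An object of class `occu_pipeline`: per-area stage results,
#'   a pair-level summary table (one row per dominant-subordinate pair
#'   and area, with averaged parameters and SIF), model rankings,
#'   SIF profiles and a run log.
#' @export
run_pipeline <- function(config = list()) {
  data_obj <- if (is.list(config) && !is.null(config$data)) config$data
  cfg <- read_pipeline_config(if (is.list(config))
    config[setdiff(names(config), "data")] else config)
  log <- character()
  note <- function(...) {
    msg <- paste0(...)
    log <<- c(log, msg)
    message(msg)
  }
  if (is.null(data_obj)) {
    if (!is.null(cfg$data_path)) {
      data_obj <- read_detection_data(cfg$data_path,
                                      species = c(cfg$prey, cfg$dominant,
                                                  cfg$subordinates))
      note("loaded data from ", cfg$data_path)
    } else {
      data_obj <- sim_study(seed = cfg$simulate_seed %||% cfg$seed)
      note("simulated study-design emulation, seed ",
           cfg$simulate_seed %||% cfg$seed)
    }
  }
  stopifnot(inherits(data_obj, "detection_data"))
  areas <- unique(data_obj$area %||% "all")

  area_results <- list()
  pair_rows <- list()
  rankings <- list()
  profiles <- list()
  for (ar in areas) {
    d <- if (is.null(data_obj$area)) data_obj else data_obj[data_obj$area == ar]
    d$area <- NULL   # single-area analysis; no stratum term
    note("=== area ", ar, ": ", n_sites(d), " sites ===")

    ## stage 1: standardize + collinearity screen
    d <- standardize_covariates(d, intersect(cfg$landscape,
                                             names(d$site_covariates)))
    scr <- collinearity_screen(d, intersect(cfg$landscape,
                                            names(d$site_covariates)),
                               threshold = cfg$collinearity_threshold)
    note("collinearity screen retained: ",
         paste(scr$retained, collapse = ", "),
         if (length(scr$dropped)) paste0(" (dropped ",
                                         paste(scr$dropped, collapse = ", "), ")"))

    ## stage 2: prey/threat occupancy as covariates
    prey_fits <- list()
    for (sp in intersect(cfg$prey, names(d$histories))) {
      f <- occu_single(d, species = sp,
                       psi_formula = stats::reformulate(scr$retained),
                       p_formula = ~substrate,
                       n_starts = cfg$n_starts, seed = cfg$seed)
      prey_fits[[sp]] <- f
      note("prey fit ", sp, ": ",
           if (f$converged) sprintf("converged, mean psi %.3f", mean(f$psi_hat))
           else "NOT CONVERGED (intercept-only fallback)")
      if (!f$converged)
        f <- occu_single(d, species = sp, psi_formula = ~1,
                         p_formula = ~substrate,
                         n_starts = cfg$n_starts, seed = cfg$seed)
      d$site_covariates[[paste0(sp, "_psi")]] <-
        if (cfg$conditional_prey) conditional_occupancy(f)
        else as.numeric(f$psi_hat)
    }

    ## stage 3: univariate carnivore models, top covariate per species
    candidates <- c(scr$retained,
                    paste0(intersect(cfg$prey, names(d$histories)), "_psi"))
    top_cov <- list()
    carn_tables <- list()
    for (sp in intersect(c(cfg$dominant, cfg$subordinates),
                         names(d$histories))) {
      recap_nm <- paste0("recap_", sp)
      p_form <- if (recap_nm %in% names(d$occasion_covariates))
        stats::reformulate(c("substrate", recap_nm)) else ~substrate
      fits <- list()
      fits[["null"]] <- occu_single(d, species = sp, psi_formula = ~1,
                                    p_formula = ~1,
                                    n_starts = cfg$n_starts, seed = cfg$seed)
      for (cv in candidates) {
        nmv <- paste0("psi(", cv, ")p(det)")
        fits[[nmv]] <- occu_single(d, species = sp,
                                   psi_formula = stats::reformulate(cv),
                                   p_formula = p_form,
                                   n_starts = cfg$n_starts, seed = cfg$seed)
      }
      conv <- vapply(fits, `[[`, TRUE, "converged")
      tab <- rank_models(fits)
      carn_tables[[sp]] <- tab
      usable <- tab[tab$converged, , drop = FALSE]
      best <- if (nrow(usable)) usable$name[1] else "null"
      top_cov[[sp]] <- if (best == "null") NULL
                       else sub("^psi\\(([^)]*)\\).*$", "\\1", best)
      note("carnivore ", sp, ": top model ", best,
           if (!all(conv)) paste0(" (", sum(!conv), " fits unconverged)"))
    }

    ## stages 4-6: two-species models, ranking, SIF
    for (sub_sp in intersect(cfg$subordinates, names(d$histories))) {
      covA <- top_cov[[cfg$dominant]]
      covB <- top_cov[[sub_sp]]
      fA <- if (is.null(covA)) ~1 else stats::reformulate(covA)
      fB <- if (is.null(covB)) ~1 else stats::reformulate(covB)
      nmSP <- model_name(covA, covB, FALSE)
      nmINT <- model_name(covA, covB, TRUE)
      fitSP <- occu_pair(d, speciesA = cfg$dominant, speciesB = sub_sp,
                         psiA_formula = fA, psiBA_formula = fB,
                         p_formula = ~substrate, interaction = FALSE,
                         n_starts = cfg$n_starts, seed = cfg$seed)
      fitINT <- occu_pair(d, speciesA = cfg$dominant, speciesB = sub_sp,
                          psiA_formula = fA, psiBA_formula = fB,
                          p_formula = ~substrate, interaction = TRUE,
                          n_starts = cfg$n_starts, seed = cfg$seed)
      note("pair ", cfg$dominant, "-", sub_sp, ": SP ",
           if (fitSP$converged) "ok" else "UNCONVERGED", ", SP+INT ",
           if (fitINT$converged) "ok" else "UNCONVERGED")
      pm <- list(fitSP, fitINT)
      names(pm) <- c(nmSP, nmINT)
      rk <- rank_models(pm)
      cs <- candidate_set(rk, cfg$delta_aic_cutoff)
      key <- paste(ar, sub_sp, sep = ":")
      rankings[[key]] <- cbind(area = ar,
                               pair = paste(cfg$dominant, sub_sp, sep = "-"),
                               as.data.frame(rk))
      row <- summarize_pair(fitSP, fitINT,
                            model_names = c(nmSP, nmINT))
      pair_rows[[key]] <- cbind(area = ar, row)
      conv_names <- rk$name[rk$converged]
      top_fit <- if (length(conv_names))
        list(fitSP, fitINT)[[match(conv_names[1], c(nmSP, nmINT))]]
      if (!is.null(covA) && !is.null(top_fit) && isTRUE(top_fit$converged) &&
          covA %in% unlist(lapply(top_fit$formulas[1:3], all.vars))) {
        prof <- sif_profile(top_fit, covA,
                            length.out = cfg$profile_points)
        profiles[[key]] <- cbind(area = ar,
                                 pair = paste(cfg$dominant, sub_sp, sep = "-"),
                                 variable = covA, prof)
      }
    }
    area_results[[ar]] <- list(screen = scr, prey_fits = prey_fits,
                               carnivore_tables = carn_tables,
                               top_covariates = top_cov)
  }
  out <- structure(list(
    pair_summary = do.call(rbind, c(pair_rows, list(make.row.names = FALSE))),
    rankings = do.call(rbind, c(rankings, list(make.row.names = FALSE))),
    profiles = if (length(profiles))
      do.call(rbind, c(profiles, list(make.row.names = FALSE))),
    areas = area_results, log = log, config = cfg),
    class = "occu_pipeline")
  if (!is.null(cfg$out_dir)) write_pipeline(out, cfg$out_dir)
  out
}

model_name <- function(covA, covB, interaction) {
  sprintf("psi(%s,%s,SP%s)p(substrate)", covA %||% ".", covB %||% ".",
          if (interaction) "+INT" else "")
}

#' Pair-level summary row from SP and SP+INT fits
#'
#' Picks the lower-AIC converged model of the two parameterizations and
#' reports the site-averaged occupancy and detection parameters, the
#' averaged species interaction factor with delta-method SE, and the
#' significance flag (95% CI excluding 1).  When both fits failed, an
#' all-NA flagged row is returned.
#'
#' @param fitSP,fitINT [occu_pair] fits with `interaction = FALSE` / `TRUE`.
#' @param model_names optional display names for the two models.
#' @return A one-row data frame.
#' @export
summarize_pair <- function(fitSP, fitINT, model_names = c("SP", "SP+INT")) {
  fits <- list(fitSP, fitINT)
  conv <- vapply(fits, `[[`, TRUE, "converged")
  if (!any(conv)) {
    return(data.frame(pair = paste(fitSP$speciesA, fitSP$speciesB, sep = "-"),
                      top_model = NA, converged = FALSE, psiA = NA, psiBA = NA,
                      psiBa = NA, rA = NA, pA = NA, pB = NA, rBA = NA,
                      rBa = NA, phi = NA, phi_se = NA, significant = NA,
                      aic = NA, K = NA, neg2loglik = NA))
  }
  aics <- vapply(fits, function(f) f$neg2loglik + 2 * f$K, 0)
  aics[!conv] <- Inf
  top <- fits[[which.min(aics)]]
  s <- sif_estimate(top)
  data.frame(pair = paste(top$speciesA, top$speciesB, sep = "-"),
             top_model = model_names[which.min(aics)],
             converged = TRUE,
             psiA = mean(top$psiA_hat), psiBA = mean(top$psiBA_hat),
             psiBa = mean(top$psiBa_hat), rA = mean(top$rA_hat),
             pA = mean(top$pA_hat), pB = mean(top$pB_hat),
             rBA = mean(top$rBA_hat), rBa = mean(top$rBa_hat),
             phi = s$phi_mean, phi_se = s$se, significant = s$significant,
             aic = min(aics), K = top$K, neg2loglik = top$neg2loglik)
}

write_pipeline <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(x$pair_summary, file.path(out_dir, "pair_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(x$rankings, file.path(out_dir, "model_ranking.csv"),
                   row.names = FALSE)
  if (!is.null(x$profiles))
    utils::write.csv(x$profiles, file.path(out_dir, "sif_profiles.csv"),
                     row.names = FALSE)
  writeLines(x$log, file.path(out_dir, "run_log.txt"))
  jsonlite::write_json(list(pair_summary = x$pair_summary),
                       file.path(out_dir, "summary.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.occu_pipeline <- function(x, ...) {
  cat("Co-occurrence pipeline:", nrow(x$pair_summary), "pair analyses\n\n")
  y <- x$pair_summary
  for (cl in c("psiA", "psiBA", "psiBa", "phi", "phi_se"))
    y[[cl]] <- round(y[[cl]], 3)
  print(y[c("area", "pair", "top_model", "converged", "psiA", "psiBA",
            "psiBa", "phi", "phi_se", "significant")])
  invisible(x)
}
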