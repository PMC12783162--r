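#' Detection/non-detection survey data
#'
#' Container for single- or two-species detection histories together with
#' site-level and occasion-level covariates.  A history is a sites x
#' occasions matrix with entries 0 (not detected), 1 (detected) or `NA`
#' (occasion not surveyed); a site enters the likelihood only through its
#' non-missing occasions.
#'
#' @param histories a sites x occasions 0/1/NA matrix, or a named list of
#'   such matrices (one per species).
#' @param site_covariates optional data frame of per-site covariates
#'   (one row per site).
#' @param occasion_covariates optional named list of sites x occasions
#'   numeric matrices (e.g. substrate class, recapture indicator).
#' @param site_id optional character vector of site labels.
#' @param area optional per-site area/stratum labels (e.g. survey region).
#' @return An object of class `detection_data`.
#' @examples
#' h <- rbind(c(1, 0), c(0, 0), c(0, 1))
#' d <- detection_data(h, site_covariates = data.frame(water = c(0.1, 0.5, 0.9)))
#' d
#' @export
detection_data <- function(histories, site_covariates = NULL,
                           occasion_covariates = NULL,
                           site_id = NULL, area = NULL) {
  if (is.matrix(histories)) histories <- list(species = histories)
  if (!is.list(histories) || !length(histories))
    stop("'histories' must be a matrix or a non-empty named list of matrices")
  if (is.null(names(histories)) || any(!nzchar(names(histories))))
    names(histories) <- paste0("species", seq_along(histories))
  histories <- lapply(histories, function(h) {
    h <- as.matrix(h)
    storage.mode(h) <- "double"
    h
  })
  n <- nrow(histories[[1]])
  K <- ncol(histories[[1]])
  if (K < 1) stop("histories need at least one occasion")
  for (sp in names(histories)) {
    h <- histories[[sp]]
    if (nrow(h) != n || ncol(h) != K)
      stop("history dimensions differ between species")
    bad <- which(!(is.na(h) | h == 0 | h == 1), arr.ind = TRUE)
    if (nrow(bad)) {
      cells <- paste0(sp, "[", bad[, 1], ",", bad[, 2], "]=",
                      h[bad], collapse = ", ")
      stop("detection values must be 0, 1 or NA; offending cells: ", cells)
    }
    all_missing <- rowSums(!is.na(h)) == 0
    if (any(all_missing))
      stop("sites with all-missing history for '", sp, "': rows ",
           paste(which(all_missing), collapse = ", "))
  }
  if (!is.null(site_covariates)) {
    site_covariates <- as.data.frame(site_covariates)
    if (nrow(site_covariates) != n)
      stop("site_covariates must have one row per site")
    if (anyNA(site_covariates))
      stop("site_covariates contain NA after validation")
  } else site_covariates <- data.frame(row.names = seq_len(n))
  if (!is.null(occasion_covariates)) {
    if (!is.list(occasion_covariates) || is.null(names(occasion_covariates)))
      stop("occasion_covariates must be a named list of matrices")
    occasion_covariates <- lapply(occasion_covariates, function(m) {
      m <- as.matrix(m)
      if (nrow(m) != n || ncol(m) != K)
        stop("occasion covariate dimensions must match the histories")
      if (anyNA(m)) stop("occasion covariates contain NA after validation")
      storage.mode(m) <- "double"
      m
    })
  } else occasion_covariates <- list()
  site_id <- as.character(site_id %||% seq_len(n))
  if (length(site_id) != n) stop("site_id must have one entry per site")
  if (!is.null(area)) {
    area <- as.character(area)
    if (length(area) != n) stop("area must have one entry per site")
  }
  structure(list(histories = histories,
                 site_covariates = site_covariates,
                 occasion_covariates = occasion_covariates,
                 site_id = site_id, area = area,
                 scaling = list()),
            class = "detection_data")
}

#' @export
print.detection_data <- function(x, ...) {
  n <- nrow(x$histories[[1]]); K <- ncol(x$histories[[1]])
  cat("Detection/non-detection data:", n, "sites x", K, "occasions\n")
  cat("Species:", paste(names(x$histories), collapse = ", "), "\n")
  for (sp in names(x$histories)) {
    h <- x$histories[[sp]]
    cat(sprintf("  %-14s naive occupancy %.3f (%d sites with >=1 detection)\n",
                sp, mean(rowSums(h == 1, na.rm = TRUE) > 0),
                sum(rowSums(h == 1, na.rm = TRUE) > 0)))
  }
  if (ncol(x$site_covariates))
    cat("Site covariates:", paste(names(x$site_covariates), collapse = ", "), "\n")
  if (length(x$occasion_covariates))
    cat("Occasion covariates:", paste(names(x$occasion_covariates), collapse = ", "), "\n")
  if (!is.null(x$area)) {
    tab <- table(x$area)
    cat("Areas:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

n_sites <- function(x) nrow(x$histories[[1]])
n_occasions <- function(x) ncol(x$histories[[1]])

#' Subset a detection dataset by site
#'
#' @param x a `detection_data` object.
#' @param i integer or logical site index.
#' @param ... unused.
#' @export
`[.detection_data` <- function(x, i, ...) {
  out <- x
  out$histories <- lapply(x$histories, function(h) h[i, , drop = FALSE])
  out$site_covariates <- x$site_covariates[i, , drop = FALSE]
  rownames(out$site_covariates) <- NULL
  out$occasion_covariates <- lapply(x$occasion_covariates,
                                    function(m) m[i, , drop = FALSE])
  out$site_id <- x$site_id[i]
  if (!is.null(x$area)) out$area <- x$area[i]
  out
}

#' Read a detection table from CSV
#'
#' Expects one row per site.  Detection columns are named
#' `<species>_o<k>` (e.g. `lion_o1`, `lion_o2`); occasion-level covariate
#' columns use the same suffix convention (e.g. `substrate_o1`).  A `site`
#' column provides site labels and an optional `area` column provides
#' stratum labels; every remaining column is taken as a site covariate.
#' Missing detections are encoded as empty cells or `NA`.
#'
#' @param path path to a CSV file.
#' @param species character vector of species column prefixes to read.
#' @return A [detection_data] object.
#' @seealso [write_detection_data()]
#' @export
read_detection_data <- function(path, species) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- names(df)
  occ_rx <- "_o([0-9]+)$"
  histories <- list()
  used <- character()
  for (sp in species) {
    det_cols <- grep(paste0("^", sp, occ_rx), cols, value = TRUE)
    if (!length(det_cols))
      stop("no detection columns found for species '", sp,
           "' (expected e.g. ", sp, "_o1)")
    k <- as.integer(sub(paste0("^", sp, "_o"), "", det_cols))
    det_cols <- det_cols[order(k)]
    h <- as.matrix(df[det_cols])
    bad <- which(!(is.na(h) | h %in% c(0, 1)), arr.ind = TRUE)
    if (nrow(bad)) {
      cells <- paste0("row ", bad[, 1], " column ", det_cols[bad[, 2]],
                      " value ", h[bad], collapse = "; ")
      stop("invalid detection codes in '", path, "': ", cells)
    }
    histories[[sp]] <- h
    used <- c(used, det_cols)
  }
  other_occ <- setdiff(grep(occ_rx, cols, value = TRUE), used)
  occ_names <- unique(sub(occ_rx, "", other_occ))
  occasion_covariates <- list()
  for (nm in occ_names) {
    oc <- grep(paste0("^", nm, occ_rx), cols, value = TRUE)
    k <- as.integer(sub(paste0("^", nm, "_o"), "", oc))
    occasion_covariates[[nm]] <- as.matrix(df[oc[order(k)]])
    used <- c(used, oc)
  }
  site_id <- if ("site" %in% cols) as.character(df$site) else NULL
  area <- if ("area" %in% cols) df$area else NULL
  cov_cols <- setdiff(cols, c(used, "site", "area"))
  detection_data(histories,
                 site_covariates = if (length(cov_cols)) df[cov_cols],
                 occasion_covariates = if (length(occasion_covariates)) occasion_covariates,
                 site_id = site_id, area = area)
}

#' Write a detection dataset to CSV
#'
#' Inverse of [read_detection_data()]: detections as `<species>_o<k>`,
#' occasion covariates as `<name>_o<k>`, site covariates as plain columns.
#'
#' @param x a `detection_data` object.
#' @param path output CSV path.
#' @export
write_detection_data <- function(x, path) {
  K <- n_occasions(x)
  out <- data.frame(site = x$site_id, stringsAsFactors = FALSE)
  if (!is.null(x$area)) out$area <- x$area
  for (sp in names(x$histories))
    for (k in seq_len(K)) out[[paste0(sp, "_o", k)]] <- x$histories[[sp]][, k]
  for (nm in names(x$occasion_covariates))
    for (k in seq_len(K))
      out[[paste0(nm, "_o", k)]] <- x$occasion_covariates[[nm]][, k]
  out <- cbind(out, x$site_covariates)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
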