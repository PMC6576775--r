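#' Covariate table for occupancy and detection modelling
#'
#' Holds a site-level block (one row per site: study area, access type,
#' tree-loss proportions at several buffer scales, ...) and an optional
#' (site, method)-level block (one row per site x pooling method: distance
#' summaries of the member cameras, ...). Occupancy and availability
#' predictors come from the site block; detection predictors may come from
#' either.
#'
#' Categorical columns `Area` and `Access` are coerced to factors with fixed
#' baselines (`SL` and `RD` respectively) when present.
#'
#' @param site data frame with a `site` column plus site-level covariates.
#' @param site_method optional data frame with `site` and `method` columns
#'   plus (site, method)-level covariates.
#' @return an object of class `covariate_table`.
#' @export
covariate_table <- function(site, site_method = NULL) {
  stopifnot(is.data.frame(site), "site" %in% names(site))
  site$site <- as.character(site$site)
  if (anyDuplicated(site$site)) stop("one row per site required")
  if ("Area" %in% names(site))
    site$Area <- factor(site$Area, levels = intersect(
      c("SL", "TN", "ML"), unique(as.character(site$Area))))
  if ("Access" %in% names(site))
    site$Access <- factor(site$Access, levels = intersect(
      c("RD", "SM"), unique(as.character(site$Access))))
  loss <- grep("^Loss", names(site), value = TRUE)
  for (col in loss) {
    v <- site[[col]]
    if (any(!is.na(v) & (v < 0 | v > 1)))
      stop("column '", col, "' must hold proportions in [0, 1]")
  }
  if (!is.null(site_method)) {
    stopifnot(is.data.frame(site_method),
              all(c("site", "method") %in% names(site_method)))
    site_method$site <- as.character(site_method$site)
    site_method$method <- as.character(site_method$method)
    if (anyDuplicated(paste(site_method$site, site_method$method, sep = "\r")))
      stop("one row per (site, method) required")
    if (!all(site_method$site %in% site$site))
      stop("site_method block references unknown site(s)")
  }
  structure(list(site = site, site_method = site_method),
            class = "covariate_table")
}

#' @export
print.covariate_table <- function(x, ...) {
  cat("Covariate table:", nrow(x$site), "sites; site-level columns:",
      paste(setdiff(names(x$site), "site"), collapse = ", "), "\n")
  if (!is.null(x$site_method))
    cat("  (site, method)-level columns:",
        paste(setdiff(names(x$site_method), c("site", "method")),
              collapse = ", "), "\n")
  invisible(x)
}

#' Read a covariate table from CSV
#'
#' A single file may carry both blocks: rows with a blank/`NA` `method`
#' column are site-level, the rest (site, method)-level. Alternatively pass
#' two files.
#'
#' @param site_path CSV with the site-level block (and optionally a `method`
#'   column mixing in the method-level block).
#' @param method_path optional CSV with the (site, method)-level block.
#' @return a [covariate_table()].
#' @export
read_covariates <- function(site_path, method_path = NULL) {
  df <- utils::read.csv(site_path, stringsAsFactors = FALSE)
  sm <- NULL
  if ("method" %in% names(df) && is.null(method_path)) {
    is_site <- is.na(df$method) | df$method == ""
    sm <- df[!is_site, , drop = FALSE]
    df <- df[is_site, setdiff(names(df), "method"), drop = FALSE]
    sm <- sm[, colSums(!is.na(sm)) > 0, drop = FALSE]
    df <- df[, colSums(!is.na(df)) > 0, drop = FALSE]
  } else if (!is.null(method_path)) {
    sm <- utils::read.csv(method_path, stringsAsFactors = FALSE)
  }
  covariate_table(df, sm)
}

#' Standardize continuous covariates by z-scoring
#'
#' Each named column is centred and scaled to sample mean 0 and sample
#' standard deviation 1 (n - 1 denominator) over the rows of its block. The
#' scaler (per-column mean and sd) is attached as attribute `"scaler"` so
#' the same transform can be reapplied to new (e.g. simulated) data.
#'
#' @param cov a [covariate_table()].
#' @param columns character vector of continuous column names (in either
#'   block).
#' @param scaler optional scaler data frame from a previous call (columns
#'   `column`, `mean`, `sd`); when supplied, those constants are reused
#'   instead of re-estimated.
#' @return the transformed `covariate_table`, with attribute `"scaler"`.
#' @examples
#' ct <- covariate_table(data.frame(site = 1:3, DistAve = c(100, 200, 300)))
#' zscore_covariates(ct, "DistAve")$site$DistAve
#' @export
zscore_covariates <- function(cov, columns, scaler = NULL) {
  stopifnot(inherits(cov, "covariate_table"))
  recs <- list()
  for (col in columns) {
    in_site <- col %in% names(cov$site)
    in_sm <- !is.null(cov$site_method) && col %in% names(cov$site_method)
    if (!in_site && !in_sm) stop("unknown covariate column: ", col)
    v <- if (in_site) cov$site[[col]] else cov$site_method[[col]]
    if (!is.numeric(v)) stop("column '", col, "' is not continuous")
    if (!is.null(scaler) && col %in% scaler$column) {
      mu <- scaler$mean[scaler$column == col]
      sd <- scaler$sd[scaler$column == col]
    } else {
      if (length(unique(v[!is.na(v)])) < 2L)
        stop("column '", col, "' is constant (sd = 0); cannot z-score")
      mu <- mean(v, na.rm = TRUE)
      sd <- stats::sd(v, na.rm = TRUE)
    }
    if (in_site) cov$site[[col]] <- (cov$site[[col]] - mu) / sd
    if (in_sm) cov$site_method[[col]] <- (cov$site_method[[col]] - mu) / sd
    recs[[col]] <- data.frame(column = col, mean = mu, sd = sd)
  }
  attr(cov, "scaler") <- do.call(rbind, c(recs, list(make.row.names = FALSE)))
  cov
}
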