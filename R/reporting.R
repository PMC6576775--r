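#' Parse a model string into formulas
#'
#' Accepts the compact field notation, e.g.
#' `"psi(Loss1k) theta(.) p(Method+Access)"` or, for a shared
#' occupancy/availability effect, `"psi=theta(Area) p(Method)"`.
#' `Method`/`method` refers to the pooling-method factor; `.` is the
#' intercept-only predictor.
#'
#' @param s the model string.
#' @return a list with formulas `psi`, `theta`, `p` and the `sharing` flag,
#'   directly usable as [occu_ms()] arguments.
#' @export
parse_model_string <- function(s) {
  grab <- function(tag) {
    m <- regmatches(s, regexec(paste0(tag, "\\(([^)]*)\\)"), s))[[1]]
    if (length(m) < 2) NULL else m[2]
  }
  to_formula <- function(txt) {
    if (is.null(txt) || txt == "." || txt == "") return(~1)
    terms <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
    terms[tolower(terms) == "method"] <- "method"
    terms_to_formula(terms)
  }
  shared <- grab("psi\\s*=\\s*theta")
  if (!is.null(shared)) {
    f <- to_formula(shared)
    return(list(psi = f, theta = f, p = to_formula(grab("p")),
                sharing = "psi_theta"))
  }
  list(psi = to_formula(grab("psi")), theta = to_formula(grab("theta")),
       p = to_formula(grab("p")), sharing = "none")
}

run_config_keys <- c("detections", "covariates", "method_covariates",
                     "method_map", "model", "selection", "simulation",
                     "out_dir", "seed", "verbose")

#' Read and validate a run configuration
#'
#' A YAML file describing a full analysis run: input paths (`detections`,
#' `covariates`, `method_covariates`, `method_map`), a `model` string or a
#' `selection` block (fields `detection_covariates`,
#' `occupancy_covariates`, `buffer_covariates`, `profile`, `n_starts`), a
#' `simulation` block (fields of [simulate_method_level()] /
#' [simulate_camera_level()] plus `level` and `missing_rate`), `out_dir`,
#' and `seed`. Unknown keys are rejected as typo guards. A run is
#' reproducible from its persisted config and seed.
#'
#' @param path path to the YAML config.
#' @return the validated config list, class `camoccu_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), run_config_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$out_dir)) cfg$out_dir <- "."
  structure(cfg, class = "camoccu_config")
}

run_log <- function(cfg, ...) {
  if (isFALSE(cfg$verbose)) return(invisible())
  msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
  message(msg)
  logfile <- file.path(cfg$out_dir, "run.log")
  if (dir.exists(cfg$out_dir)) cat(msg, "\n", file = logfile, append = TRUE)
  invisible()
}

config_method_map <- function(cfg) {
  if (is.null(cfg$method_map)) default_method_map()
  else read_method_map(cfg$method_map)
}

#' Simulate survey data from a run config
#'
#' Writes detection and covariate CSVs plus the latent truth record (YAML)
#' into the config's output directory; the seed is logged.
#'
#' @param cfg a config from [read_run_config()] (or an equivalent list).
#' @return named vector of output paths, invisibly.
#' @export
run_simulate <- function(cfg) {
  sim <- cfg$simulation
  if (is.null(sim)) stop("config has no 'simulation' block")
  if (is.null(sim$n_sites) || sim$n_sites < 1)
    stop("simulation block needs n_sites >= 1")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  run_log(cfg, "simulate: seed = ", cfg$seed,
          ", version = ", as.character(utils::packageVersion("camoccu")))
  map <- config_method_map(cfg)
  occasions <- if (is.null(sim$occasions)) 16:23 else
    unlist(sim$occasions)
  level <- if (is.null(sim$level)) "camera" else sim$level
  paths <- c()
  if (level == "camera") {
    res <- simulate_camera_level(sim$n_sites, occasions, psi = sim$psi,
                                 theta = sim$theta, q = unlist(sim$q),
                                 seed = cfg$seed)
    arr <- res$array
    if (!is.null(sim$missing_rate) && sim$missing_rate > 0)
      arr <- inject_missing(arr, sim$missing_rate,
                            mode = if (is.null(sim$missing_mode))
                              "camera-day" else sim$missing_mode,
                            seed = cfg$seed + 1L)
    f <- file.path(cfg$out_dir, "detections.csv")
    write_detections(arr, f)
    paths["detections"] <- f
  } else {
    res <- simulate_method_level(sim$n_sites, occasions, psi = sim$psi,
                                 theta = sim$theta, p = unlist(sim$p),
                                 map = map, seed = cfg$seed)
    f <- file.path(cfg$out_dir, "pooled.csv")
    write_pooled(res$history, f)
    paths["pooled"] <- f
  }
  cov <- simulate_covariates(sim$n_sites, map, seed = cfg$seed + 2L)
  fcov <- file.path(cfg$out_dir, "covariates_site.csv")
  fm <- file.path(cfg$out_dir, "covariates_method.csv")
  utils::write.csv(cov$site, fcov, row.names = FALSE, na = "NA")
  utils::write.csv(cov$site_method, fm, row.names = FALSE, na = "NA")
  truth <- res$truth
  ftr <- file.path(cfg$out_dir, "truth.yaml")
  yaml::write_yaml(lapply(truth, function(x)
    if (is.matrix(x)) apply(x, 1, paste, collapse = ",") else x), ftr)
  paths <- c(paths, covariates = fcov, method_covariates = fm,
             truth = ftr)
  run_log(cfg, "simulate: wrote ", paste(basename(paths), collapse = ", "))
  invisible(paths)
}

#' Pool per-camera detections from a run config
#'
#' Reads the configured detection file and method map, pools, writes the
#' pooled long-format CSV, and logs detections per method.
#'
#' @param cfg a config from [read_run_config()].
#' @return the `pooled_history`, invisibly; the CSV lands in `out_dir`.
#' @export
run_pool <- function(cfg) {
  if (is.null(cfg$detections)) stop("config has no 'detections' path")
  d <- read_detections(cfg$detections)
  map <- config_method_map(cfg)
  pooled <- pool_histories(d, map)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  f <- file.path(cfg$out_dir, "pooled.csv")
  write_pooled(pooled, f)
  det <- apply(pooled$obs == 1, 2, sum, na.rm = TRUE)
  if (sum(det) == 0) warning("no detections in any pooled method")
  run_log(cfg, "pool: detection-days per method: ",
          paste(sprintf("%s=%d", pooled$method_ids, det), collapse = ", "))
  invisible(pooled)
}

read_pooled_csv <- function(path, map) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  sites <- unique(df$site)
  methods <- map$method_id
  occ <- vapply(sites, function(s) max(df$occasion[df$site == s]),
                integer(1))
  obs <- array(NA_real_, c(length(sites), length(methods), max(occ)),
               dimnames = list(sites, methods, NULL))
  obs[cbind(match(df$site, sites), match(df$method, methods),
            df$occasion)] <- df$value
  structure(list(obs = obs, site_ids = sites, method_ids = methods,
                 occasions = occ, map = map), class = "pooled_history")
}

#' Fit or select models from a run config
#'
#' With a `model` string, fits that single model; with a `selection` block,
#' runs [run_three_stage()]. Writes a ranking CSV (`model, K, logLik, AICc,
#' dAICc, weight`), a per-method estimate table (probabilities to 2
#' decimals, daily detection to 3), and the model-averaged detection table.
#'
#' @param cfg a config from [read_run_config()].
#' @return the fit or staged-selection result, invisibly.
#' @export
run_select <- function(cfg) {
  map <- config_method_map(cfg)
  pooled <- if (!is.null(cfg$detections)) {
    pool_histories(read_detections(cfg$detections), map)
  } else stop("config has no 'detections' path")
  cov <- NULL
  if (!is.null(cfg$covariates))
    cov <- read_covariates(cfg$covariates, cfg$method_covariates)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  sel <- cfg$selection
  if (!is.null(cfg$model)) {
    ms <- parse_model_string(cfg$model)
    fit <- occu_ms(pooled, cov, psi = ms$psi, theta = ms$theta, p = ms$p,
                   sharing = ms$sharing, seed = cfg$seed)
    run_log(cfg, "fit: ", model_label(fit), " converged = ",
            fit$converged)
    r <- rank_models(list(fit))
    utils::write.csv(as.data.frame(r),
                     file.path(cfg$out_dir, "ranking.csv"),
                     row.names = FALSE)
    utils::write.csv(estimate_table(fit),
                     file.path(cfg$out_dir, "estimates.csv"),
                     row.names = FALSE)
    return(invisible(fit))
  }
  if (is.null(sel)) stop("config needs a 'model' string or 'selection' block")
  res <- run_three_stage(
    pooled, cov,
    detection_covariates = unlist(sel$detection_covariates),
    occupancy_covariates = unlist(sel$occupancy_covariates),
    buffer_covariates = unlist(sel$buffer_covariates),
    profile = sel$profile,
    n_starts = if (is.null(sel$n_starts)) 5 else sel$n_starts,
    seed = cfg$seed)
  for (s in 1:3) {
    r <- res[[paste0("stage", s)]]
    if (!is.null(r))
      utils::write.csv(as.data.frame(r),
                       file.path(cfg$out_dir,
                                 sprintf("ranking_stage%d.csv", s)),
                       row.names = FALSE)
  }
  if (!is.null(res$estimate_table))
    utils::write.csv(res$estimate_table,
                     file.path(cfg$out_dir, "estimates.csv"),
                     row.names = FALSE)
  if (!is.null(res$averaged_detection))
    utils::write.csv(transform(res$averaged_detection,
                               estimate = round(estimate, 2),
                               se = round(se, 2)),
                     file.path(cfg$out_dir, "averaged_detection.csv"),
                     row.names = FALSE)
  run_log(cfg, "select: done",
          if (!is.na(res$aborted_at))
            paste0(" (aborted at stage ", res$aborted_at, ")") else "")
  invisible(res)
}

#' Published multi-scale occupancy estimates for six Maine mammals
#'
#' Parameter estimates (occupancy, daily availability, and per-method
#' conditional detection, with standard errors) from a published winter
#' camera-trap survey of six North American mammal species at 32
#' five-camera T-arrays in Maine. Useful as realistic generating values for
#' simulation studies and as worked examples for the combined daily
#' detection probability.
#'
#' @return a data frame with one row per species: `species`, `psi`,
#'   `psi_se`, `theta`, `theta_se`, `p1`..`p5`, `p1_se`..`p5_se`.
#' @examples
#' est <- species_estimates()
#' combined_daily_detection(est$theta[1], est$p1[1])
#' @export
species_estimates <- function() {
  utils::read.csv(system.file("extdata", "species_estimates.csv",
                              package = "camoccu"),
                  stringsAsFactors = FALSE)
}
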