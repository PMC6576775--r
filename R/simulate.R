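# Expand a probability argument to per-site (vector) or per-(site, method)
# (matrix) form and range-check it.
expand_prob <- function(x, n, S = NULL, what = "probability") {
  if (is.null(S)) {
    if (length(x) == 1L) x <- rep(x, n)
    if (length(x) != n) stop(what, " must be scalar or length n_sites")
  } else {
    if (is.null(dim(x))) {
      if (length(x) == 1L) x <- matrix(x, n, S)
      else if (length(x) == S) x <- matrix(x, n, S, byrow = TRUE)
      else stop(what, " must be scalar, length-S, or an n x S matrix")
    }
    if (!all(dim(x) == c(n, S))) stop(what, " matrix must be n_sites x S")
  }
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(what, " values must lie in [0, 1]")
  x
}

draw_occasions <- function(n_sites, occasions) {
  if (length(occasions) == 1L) rep(as.integer(occasions), n_sites)
  else sample(as.integer(occasions), n_sites, replace = TRUE)
}

#' Simulate method-level pooled detection histories
#'
#' Hierarchical Bernoulli generator matching the fitted model exactly: per
#' site an occupancy state `z ~ Bern(psi)`; per occasion of an occupied site
#' an availability state `a_t ~ Bern(theta)`; per method a detection
#' `y ~ Bern(p_s)` when `z * a_t = 1`, else 0 — conditionally independent
#' across methods. Detections at unoccupied or unavailable site-occasions
#' never occur (no false positives).
#'
#' Probabilities may be scalars, per-site vectors (`psi`, `theta`), or a
#' per-site-by-method matrix (`p`), so covariate-driven designs can be
#' simulated by passing inverse-logit linear predictors.
#'
#' @param n_sites number of survey sites.
#' @param occasions integer: a single occasion count, or a vector of
#'   candidate counts sampled uniformly per site (default `16:23`, a two- to
#'   three-week winter deployment).
#' @param psi occupancy probability (scalar or length `n_sites`).
#' @param theta availability probability (scalar or length `n_sites`).
#' @param p detection probabilities: scalar, one per method, or an
#'   `n_sites x n_methods` matrix.
#' @param map a [method_map()] supplying method ids (default
#'   [default_method_map()]).
#' @param seed optional integer seed; the seed fully determines the output.
#' @return a list with `history` (a `pooled_history`) and `truth` (the
#'   latent draws: `z`, availability matrix `a`, and the generating
#'   parameters).
#' @examples
#' sim <- simulate_method_level(50, 16:23, psi = 0.7, theta = 0.2,
#'                              p = c(0.1, 0.3, 0.4, 0.3, 0.4), seed = 1)
#' sim$history
#' @export
simulate_method_level <- function(n_sites, occasions = 16:23, psi, theta, p,
                                  map = default_method_map(), seed = NULL) {
  stopifnot(inherits(map, "method_map"), n_sites >= 1)
  if (!is.null(seed)) set.seed(seed)
  S <- nrow(map)
  psi <- expand_prob(psi, n_sites, what = "psi")
  theta <- expand_prob(theta, n_sites, what = "theta")
  p <- expand_prob(p, n_sites, S, what = "p")
  Tocc <- draw_occasions(n_sites, occasions)
  Tmax <- max(Tocc)
  z <- stats::rbinom(n_sites, 1, psi)
  a <- matrix(stats::rbinom(n_sites * Tmax, 1, rep(theta, Tmax)),
              n_sites, Tmax) * z
  obs <- array(0, dim = c(n_sites, S, Tmax))
  for (s in seq_len(S)) {
    y <- matrix(stats::rbinom(n_sites * Tmax, 1, rep(p[, s], Tmax)),
                n_sites, Tmax) * a
    obs[, s, ] <- y
  }
  for (i in seq_len(n_sites))
    if (Tocc[i] < Tmax) {
      obs[i, , (Tocc[i] + 1L):Tmax] <- NA
      a[i, (Tocc[i] + 1L):Tmax] <- NA
    }
  dimnames(obs) <- list(paste0("site", seq_len(n_sites)), map$method_id,
                        NULL)
  hist <- structure(list(obs = obs,
                         site_ids = paste0("site", seq_len(n_sites)),
                         method_ids = map$method_id, occasions = Tocc,
                         map = map),
                    class = "pooled_history")
  list(history = hist,
       truth = list(z = z, a = a, psi = psi, theta = theta, p = p,
                    occasions = Tocc))
}

#' Simulate camera-level detection arrays
#'
#' Physically realistic generator: detections are drawn per camera
#' (`y_c ~ Bern(q_c)` given occupancy and availability), so pooled methods
#' that share cameras are positively dependent — the dependence a real
#' T-array induces and the method-level generator deliberately omits. The
#' pooled detection probability implied for a method with member cameras `C`
#' is `1 - prod_{c in C}(1 - q_c)`.
#'
#' @inheritParams simulate_method_level
#' @param q per-camera detection probabilities: scalar, one per camera
#'   label, or an `n_sites x n_cameras` matrix.
#' @param camera_labels camera labels (default `A`-`E`).
#' @return a list with `array` (a [detection_array()]) and `truth`.
#' @export
simulate_camera_level <- function(n_sites, occasions = 16:23, psi, theta, q,
                                  camera_labels = LETTERS[1:5],
                                  seed = NULL) {
  stopifnot(n_sites >= 1)
  if (!is.null(seed)) set.seed(seed)
  C <- length(camera_labels)
  psi <- expand_prob(psi, n_sites, what = "psi")
  theta <- expand_prob(theta, n_sites, what = "theta")
  q <- expand_prob(q, n_sites, C, what = "q")
  Tocc <- draw_occasions(n_sites, occasions)
  Tmax <- max(Tocc)
  z <- stats::rbinom(n_sites, 1, psi)
  a <- matrix(stats::rbinom(n_sites * Tmax, 1, rep(theta, Tmax)),
              n_sites, Tmax) * z
  obs <- array(0, dim = c(n_sites, C, Tmax))
  for (cc in seq_len(C))
    obs[, cc, ] <- matrix(stats::rbinom(n_sites * Tmax, 1,
                                        rep(q[, cc], Tmax)),
                          n_sites, Tmax) * a
  for (i in seq_len(n_sites))
    if (Tocc[i] < Tmax) obs[i, , (Tocc[i] + 1L):Tmax] <- NA
  arr <- detection_array(obs, paste0("site", seq_len(n_sites)),
                         camera_labels, Tocc)
  list(array = arr,
       truth = list(z = z, a = a, psi = psi, theta = theta, q = q,
                    occasions = Tocc))
}

#' Inject missing visits into a detection array
#'
#' Emulates camera failures: either independent camera-days become missing
#' (`"camera-day"`: snow burial, intermittent battery), or whole cameras
#' fail for their entire deployment (`"whole-camera"`). Original values are
#' unrecoverable by design.
#'
#' @param d a [detection_array()].
#' @param rate probability in `[0, 1]` that a camera-day (or camera) is
#'   affected.
#' @param mode `"camera-day"` (default) or `"whole-camera"`.
#' @param seed optional integer seed.
#' @return the modified [detection_array()].
#' @export
inject_missing <- function(d, rate, mode = c("camera-day", "whole-camera"),
                           seed = NULL) {
  stopifnot(inherits(d, "detection_array"), rate >= 0, rate <= 1)
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  obs <- d$obs
  if (mode == "camera-day") {
    hit <- array(stats::runif(length(obs)) < rate, dim = dim(obs))
    obs[hit] <- NA
  } else {
    n <- dim(obs)[1]; C <- dim(obs)[2]
    hit <- matrix(stats::runif(n * C) < rate, n, C)
    for (i in seq_len(n)) for (cc in seq_len(C))
      if (hit[i, cc]) obs[i, cc, ] <- NA
  }
  detection_array(obs, d$site_ids, d$camera_labels, d$occasions)
}

#' Simulate a site and method covariate table
#'
#' Generates an internally consistent covariate table of the kind a
#' camera-array study records: a study-area factor with fixed site counts
#' (deterministic largest-remainder allocation), an access-type factor,
#' tree-loss proportions in `[0, 1]` at four buffer scales, and per-camera
#' distances to the access feature from which per-(site, method) `DistAve`,
#' `DistMax`, `DistMin` are derived (so the ordering
#' `DistMin <= DistAve <= DistMax` holds by construction).
#'
#' @param n_sites number of sites.
#' @param map a [method_map()] for the distance summaries.
#' @param area_freq named proportions for the `Area` levels (default the
#'   12/12/8-of-32 split across SL, TN, ML).
#' @param access_freq named proportions for `Access` (default 50/50 RD/SM).
#' @param loss_shape `c(shape1, shape2)` of the Beta distribution for the
#'   loss proportions (default `c(2, 10)`).
#' @param dist_meanlog,dist_sdlog log-normal parameters for per-camera
#'   distances in meters, truncated to `[10, 320]` (default mean about
#'   130 m).
#' @param seed optional integer seed.
#' @return a [covariate_table()] with site columns `Area`, `Access`,
#'   `Loss100m`, `Loss500m`, `Loss1k`, `Loss5k` and method-level columns
#'   `DistAve`, `DistMax`, `DistMin`.
#' @export
simulate_covariates <- function(n_sites, map = default_method_map(),
                                area_freq = c(SL = 12 / 32, TN = 12 / 32,
                                              ML = 8 / 32),
                                access_freq = c(RD = 0.5, SM = 0.5),
                                loss_shape = c(2, 10),
                                dist_meanlog = log(120), dist_sdlog = 0.55,
                                seed = NULL) {
  stopifnot(n_sites >= 1, inherits(map, "method_map"))
  if (abs(sum(area_freq) - 1) > 1e-8 || abs(sum(access_freq) - 1) > 1e-8)
    stop("level frequencies must sum to 1")
  if (!is.null(seed)) set.seed(seed)
  alloc <- function(freq, n) {
    cnt <- floor(freq * n)
    rem <- n - sum(cnt)
    if (rem > 0) {
      frac <- freq * n - cnt
      extra <- order(frac, decreasing = TRUE)[seq_len(rem)]
      cnt[extra] <- cnt[extra] + 1
    }
    rep(names(freq), times = cnt)
  }
  site <- data.frame(site = paste0("site", seq_len(n_sites)),
                     Area = alloc(area_freq, n_sites),
                     Access = alloc(access_freq, n_sites),
                     stringsAsFactors = FALSE)
  for (col in c("Loss100m", "Loss500m", "Loss1k", "Loss5k"))
    site[[col]] <- stats::rbeta(n_sites, loss_shape[1], loss_shape[2])
  cams <- sort(unique(unlist(map$cameras)))
  cd <- matrix(pmin(pmax(stats::rlnorm(n_sites * length(cams),
                                       dist_meanlog, dist_sdlog), 10), 320),
               n_sites, length(cams), dimnames = list(NULL, cams))
  sm <- do.call(rbind, lapply(seq_len(nrow(map)), function(s) {
    dd <- cd[, map$cameras[[s]], drop = FALSE]
    data.frame(site = site$site, method = map$method_id[s],
               DistAve = rowMeans(dd), DistMax = apply(dd, 1, max),
               DistMin = apply(dd, 1, min), stringsAsFactors = FALSE)
  }))
  covariate_table(site, sm)
}
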