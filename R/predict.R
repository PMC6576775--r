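# Build a one-site covariate table from a named profile list, filling
# unspecified terms with their baseline (first factor level / 0 after
# z-scoring).
profile_covariates <- function(object, profile = NULL) {
  vars <- unique(c(all.vars(object$formulas$psi),
                   all.vars(object$formulas$theta),
                   all.vars(object$formulas$p)))
  vars <- setdiff(vars, "method")
  xlev <- c(object$xlev$psi, object$xlev$theta, object$xlev$p)
  site <- data.frame(site = "profile", stringsAsFactors = FALSE)
  for (v in vars) {
    val <- if (!is.null(profile) && v %in% names(profile)) profile[[v]]
    else if (v %in% names(xlev)) xlev[[v]][1] else 0
    if (v %in% names(xlev) && !val %in% xlev[[v]])
      stop("covariate profile outside training categories: ", v, " = ", val)
    site[[v]] <- val
  }
  extra <- setdiff(names(profile), vars)
  if (length(extra))
    warning("profile entries not used by the model: ",
            paste(extra, collapse = ", "))
  site
}

# Linear predictors with delta-method SEs for one covariate block.
block_estimates <- function(object, X, map) {
  G <- X %*% map
  eta <- drop(G %*% object$coef)
  se_eta <- if (is.null(object$vcov)) rep(NA_real_, length(eta)) else
    sqrt(pmax(rowSums((G %*% object$vcov) * G), 0))
  data.frame(estimate = stats::plogis(eta),
             se = stats::dlogis(eta) * se_eta)
}

#' Predicted occupancy, availability and detection probabilities
#'
#' Probability-scale estimates with delta-method standard errors, either for
#' every training site (`profile = NULL, newdata = NULL`), for new sites in
#' a covariate table, or for a single reference covariate profile (e.g. one
#' study area and access type), which is how per-method detection tables are
#' usually reported.
#'
#' @param object a fitted [occu_ms()] model.
#' @param newdata optional [covariate_table()] for new sites.
#' @param profile optional named list of covariate values defining one
#'   reference profile; unnamed covariates default to their baseline level
#'   (categorical) or 0 (continuous, i.e. the mean after z-scoring).
#' @param ... unused.
#' @return a list with data frames `psi`, `theta` (per site) and `p` (per
#'   site x method), each with columns `estimate` and `se`.
#' @export
predict.occu_ms <- function(object, newdata = NULL, profile = NULL, ...) {
  if (!object$converged) stop("cannot predict from a non-converged fit")
  if (!is.null(profile) || (is.null(newdata) && is.null(object$covariates))) {
    site <- profile_covariates(object, profile)
    newdata <- covariate_table(site)
    pooled <- list(site_ids = site$site, method_ids = object$method_ids,
                   occasions = 1L,
                   obs = array(0, c(1, length(object$method_ids), 1)))
    class(pooled) <- "pooled_history"
  } else if (is.null(newdata)) {
    newdata <- object$covariates
    pooled <- object$pooled
  } else {
    stopifnot(inherits(newdata, "covariate_table"))
    pooled <- list(site_ids = newdata$site$site,
                   method_ids = object$method_ids,
                   occasions = rep(1L, nrow(newdata$site)),
                   obs = array(0, c(nrow(newdata$site),
                                    length(object$method_ids), 1)))
    class(pooled) <- "pooled_history"
  }
  dm <- tryCatch(
    build_design_matrices(object$formulas$psi, object$formulas$theta,
                          object$formulas$p, pooled, newdata,
                          xlev = object$xlev),
    error = function(e)
      stop("covariate profile/newdata incompatible with the fit: ",
           conditionMessage(e)))
  psi <- cbind(site = pooled$site_ids,
               block_estimates(object, dm$X_psi, object$maps$psi))
  theta <- if (is.null(object$fix_theta))
    cbind(site = pooled$site_ids,
          block_estimates(object, dm$X_theta, object$maps$theta))
  else data.frame(site = pooled$site_ids, estimate = object$fix_theta,
                  se = 0)
  p <- cbind(site = rep(pooled$site_ids, times = dm$S),
             method = rep(object$method_ids, each = dm$n),
             block_estimates(object, dm$X_p, object$maps$p))
  list(psi = psi, theta = theta, p = p)
}

#' Per-method estimate table for a reference profile
#'
#' A reporting table in the conventional shape: occupancy and availability
#' estimates with SEs, the method-conditional detection estimate per pooling
#' method, and the combined daily detection probability `theta * p_s` (the
#' daily detection rate a single-scale model using only that method's data
#' would see).
#'
#' @param fit a fitted [occu_ms()] model.
#' @param profile reference covariate profile as in [predict.occu_ms()].
#' @param digits rounding for the probabilities (default 2) — the product
#'   column uses `digits + 1`.
#' @return a data frame with one row per method.
#' @export
estimate_table <- function(fit, profile = NULL, digits = 2) {
  pr <- predict(fit, profile = if (is.null(profile)) list() else profile)
  data.frame(
    method = pr$p$method,
    psi = round(pr$psi$estimate[1], digits),
    psi_se = round(pr$psi$se[1], digits),
    theta = round(pr$theta$estimate[1], digits),
    theta_se = round(pr$theta$se[1], digits),
    p = round(pr$p$estimate, digits),
    p_se = round(pr$p$se, digits),
    daily_detection = combined_daily_detection(
      round(pr$theta$estimate[1], digits), round(pr$p$estimate, digits),
      digits = digits + 1))
}

#' Simulate pooled histories from a fitted model
#'
#' Parametric-bootstrap style draws: per-site probabilities are taken from
#' the fit at the training covariates, then occupancy, daily availability
#' and method detections are drawn hierarchically over the training survey
#' windows. Missing cells of the training data stay missing.
#'
#' @param object a fitted [occu_ms()] model.
#' @param nsim number of replicate datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return a list of `pooled_history` objects of length `nsim`.
#' @export
simulate.occu_ms <- function(object, nsim = 1, seed = NULL, ...) {
  if (!object$converged) stop("cannot simulate from a non-converged fit")
  pr <- predict(object)
  n <- object$n_sites
  S <- length(object$method_ids)
  P <- matrix(NA_real_, n, S)
  for (s in seq_len(S)) {
    v <- pr$p$estimate[pr$p$method == object$method_ids[s]]
    P[, s] <- if (length(v) == n) v else v[1]
  }
  psi_hat <- pr$psi$estimate
  theta_hat <- pr$theta$estimate
  if (length(psi_hat) != n) psi_hat <- rep(psi_hat[1], n)
  if (length(theta_hat) != n) theta_hat <- rep(theta_hat[1], n)
  if (!is.null(seed)) set.seed(seed)
  tmpl <- object$pooled
  lapply(seq_len(nsim), function(r) {
    sim <- simulate_method_level(
      n_sites = n, occasions = max(tmpl$occasions), psi = psi_hat,
      theta = theta_hat, p = P, map = tmpl$map)
    h <- sim$history
    # training survey windows and missing-visit pattern carry over
    h$obs[is.na(tmpl$obs)] <- NA
    h$occasions <- tmpl$occasions
    h$site_ids <- tmpl$site_ids
    dimnames(h$obs)[[1]] <- tmpl$site_ids
    h
  })
}

#' Plot method-conditional detection estimates
#'
#' Barplot of the detection probability per pooling method with +/- 1 SE
#' error bars, at a reference covariate profile.
#'
#' @param x a fitted [occu_ms()] model.
#' @param profile reference profile as in [predict.occu_ms()].
#' @param ... passed to [graphics::barplot()].
#' @return the bar midpoints, invisibly.
#' @export
plot.occu_ms <- function(x, profile = NULL, ...) {
  pr <- predict(x, profile = profile)
  est <- pr$p$estimate
  se <- pr$p$se
  mid <- graphics::barplot(est, names.arg = pr$p$method, ylim = c(0, 1),
                           ylab = "detection probability (given availability)",
                           xlab = "pooling method", ...)
  ok <- !is.na(se)
  graphics::arrows(mid[ok], pmax(est[ok] - se[ok], 0), mid[ok],
                   pmin(est[ok] + se[ok], 1),
                   angle = 90, code = 3, length = 0.05)
  invisible(mid)
}
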