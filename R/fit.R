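# Design-matrix construction for the three linear predictors.
# psi and theta use site-level covariates only; p may additionally use the
# method factor and (site, method)-level covariates. Rows of the p design are
# ordered column-major in (site, method): matrix(eta_p, n, S) restores P.
build_design_matrices <- function(psi, theta, p, pooled, covariates = NULL,
                                  xlev = NULL) {
  n <- length(pooled$site_ids)
  S <- length(pooled$method_ids)
  site_df <- data.frame(site = pooled$site_ids, stringsAsFactors = FALSE)
  sm_df <- NULL
  if (!is.null(covariates)) {
    stopifnot(inherits(covariates, "covariate_table"))
    idx <- match(pooled$site_ids, covariates$site$site)
    if (anyNA(idx)) stop("covariate table lacks rows for some sites")
    site_df <- covariates$site[idx, , drop = FALSE]
    sm_df <- covariates$site_method
  }
  p_df <- data.frame(site = rep(pooled$site_ids, times = S),
                     method = factor(rep(pooled$method_ids, each = n),
                                     levels = pooled$method_ids),
                     stringsAsFactors = FALSE)
  p_df <- cbind(p_df, site_df[match(p_df$site, site_df$site),
                              setdiff(names(site_df), "site"), drop = FALSE])
  if (!is.null(sm_df)) {
    j <- match(paste(p_df$site, p_df$method, sep = "\r"),
               paste(sm_df$site, sm_df$method, sep = "\r"))
    extra <- sm_df[j, setdiff(names(sm_df), c("site", "method")),
                   drop = FALSE]
    p_df <- cbind(p_df, extra)
  }
  site_only <- setdiff(names(site_df), "site")
  for (f in list(psi = psi, theta = theta)) {
    vars <- all.vars(f)
    bad <- setdiff(vars, site_only)
    if (length(bad))
      stop("psi/theta formulas may use site-level covariates only; ",
           "offending term(s): ", paste(bad, collapse = ", "))
  }
  bad <- setdiff(all.vars(p), names(p_df))
  if (length(bad))
    stop("unresolvable term(s) in p formula: ", paste(bad, collapse = ", "))
  mm <- function(f, df, which) {
    mf <- stats::model.frame(f, df, na.action = stats::na.fail,
                             xlev = xlev[[which]])
    list(X = stats::model.matrix(f, mf, xlev = xlev[[which]]),
         xlev = stats::.getXlevels(stats::terms(f), mf))
  }
  r_psi <- mm(psi, site_df, "psi")
  r_theta <- mm(theta, site_df, "theta")
  r_p <- mm(p, p_df, "p")
  list(X_psi = r_psi$X, X_theta = r_theta$X, X_p = r_p$X,
       xlev = list(psi = r_psi$xlev, theta = r_theta$xlev, p = r_p$xlev),
       n = n, S = S)
}

# Parameter packing: selection matrices map the full parameter vector onto
# each block's coefficients so that beta_block = map %*% par.
make_par_maps <- function(dm, sharing, fix_theta) {
  k1 <- ncol(dm$X_psi); k2 <- ncol(dm$X_theta); k3 <- ncol(dm$X_p)
  if (sharing == "psi_theta") {
    if (!identical(colnames(dm$X_psi), colnames(dm$X_theta)))
      stop("sharing = 'psi_theta' requires identical psi and theta terms")
    if (k1 < 2L)
      stop("sharing = 'psi_theta' needs at least one covariate term")
    ns <- k1 - 1L
    K <- 2L + ns + k3
    map_psi <- matrix(0, k1, K); map_theta <- matrix(0, k2, K)
    map_psi[1, 1] <- 1; map_theta[1, 2] <- 1
    for (j in seq_len(ns)) {
      map_psi[1 + j, 2 + j] <- 1
      map_theta[1 + j, 2 + j] <- 1
    }
    map_p <- cbind(matrix(0, k3, 2 + ns), diag(k3))
    names_full <- c("psi_(Intercept)", "theta_(Intercept)",
                    paste0("psitheta_", colnames(dm$X_psi)[-1]),
                    paste0("p_", colnames(dm$X_p)))
  } else {
    if (!is.null(fix_theta)) k2 <- 0L
    K <- k1 + k2 + k3
    map_psi <- cbind(diag(k1), matrix(0, k1, k2 + k3))
    map_theta <- if (k2) cbind(matrix(0, k2, k1), diag(k2),
                               matrix(0, k2, k3)) else
      matrix(0, 0, K)
    map_p <- cbind(matrix(0, k3, k1 + k2), diag(k3))
    names_full <- c(paste0("psi_", colnames(dm$X_psi)),
                    if (k2) paste0("theta_", colnames(dm$X_theta)),
                    paste0("p_", colnames(dm$X_p)))
  }
  list(psi = map_psi, theta = map_theta, p = map_p, K = K,
       names = names_full)
}

#' Fit a multi-scale occupancy model to pooled camera-trap histories
#'
#' Maximum-likelihood fit of the three-level hierarchy: large-scale
#' occupancy `psi`, daily availability `theta` (occasion-constant within a
#' site), and method-conditional detection `p`, each on the logit scale with
#' covariates given as one-sided formulas. The `psi` and `theta` predictors
#' draw on site-level covariates; the `p` predictor may additionally use the
#' pooling-method factor (`method`) and (site, method)-level covariates such
#' as distance summaries.
#'
#' The negative log-likelihood is minimized by quasi-Newton (BFGS) search
#' from `n_starts` dispersed starting points drawn uniformly in [-2, 2] on
#' the link scale; the best converged optimum is kept. Standard errors come
#' from the inverse of a central-finite-difference Hessian; if that matrix
#' is not positive definite the variance matrix is reported as unavailable
#' with a warning rather than fabricated. Linear predictors beyond 10 in
#' absolute value at the optimum are flagged as boundary estimates.
#'
#' @param pooled a `pooled_history` from [pool_histories()] or
#'   [simulate_method_level()].
#' @param covariates optional [covariate_table()].
#' @param psi,theta one-sided formulas over site-level covariates
#'   (default `~1`).
#' @param p one-sided formula for detection; `method` refers to the pooling
#'   method factor (default `~method`).
#' @param sharing `"none"` (default) or `"psi_theta"`: the latter constrains
#'   psi and theta to one common covariate-slope vector (their formulas must
#'   then be identical) while keeping two free intercepts, the usual
#'   "single effect on occupancy and availability" constraint.
#' @param fix_theta optional probability: hold availability fixed at this
#'   value instead of estimating it (then `theta` must be `~1`). With one
#'   method and `fix_theta = 1` the model collapses to the standard
#'   single-season occupancy model.
#' @param n_starts number of random multi-starts (default 10).
#' @param seed integer seed for the start draws.
#' @param control passed to [stats::optim()]; defaults to
#'   `list(maxit = 1000, reltol = 1e-10)`.
#' @param hessian compute the finite-difference Hessian (default TRUE).
#' @return an object of class `occu_ms` with components `coef`, `vcov`,
#'   `loglik`, `K`, `n_sites`, `converged`, `warnings`, plus the design
#'   information needed by [predict.occu_ms()] and [simulate.occu_ms()].
#' @seealso [predict.occu_ms()], [rank_models()], [run_three_stage()]
#' @export
occu_ms <- function(pooled, covariates = NULL, psi = ~1, theta = ~1,
                    p = ~method, sharing = c("none", "psi_theta"),
                    fix_theta = NULL, n_starts = 10, seed = NULL,
                    control = list(maxit = 1000, reltol = 1e-10),
                    hessian = TRUE) {
  stopifnot(inherits(pooled, "pooled_history"))
  sharing <- match.arg(sharing)
  if (length(pooled$site_ids) == 0L) stop("no sites in pooled history")
  if (!any(!is.na(pooled$obs)))
    stop("pooled history holds no informative occasions")
  if (!is.null(fix_theta)) {
    stopifnot(fix_theta >= 0, fix_theta <= 1)
    if (sharing != "none" || !identical(theta, ~1))
      stop("fix_theta requires sharing = 'none' and theta = ~1")
  }
  dm <- build_design_matrices(psi, theta, p, pooled, covariates)
  maps <- make_par_maps(dm, sharing, fix_theta)
  n <- dm$n; S <- dm$S
  Y <- pooled$obs
  nll <- function(par) {
    if (any(!is.finite(par))) return(1e10)
    eta_psi <- drop(dm$X_psi %*% (maps$psi %*% par))
    th <- if (is.null(fix_theta))
      stats::plogis(drop(dm$X_theta %*% (maps$theta %*% par)))
    else rep(fix_theta, n)
    eta_p <- drop(dm$X_p %*% (maps$p %*% par))
    multiscale_negloglik(stats::plogis(eta_psi), th,
                         matrix(stats::plogis(eta_p), n, S), Y)
  }
  if (!is.null(seed)) set.seed(seed)
  starts <- lapply(seq_len(n_starts), function(i)
    if (i == 1L) rep(0, maps$K) else stats::runif(maps$K, -2, 2))
  best <- NULL
  n_conv <- 0L
  for (st in starts) {
    opt <- tryCatch(stats::optim(st, nll, method = "BFGS", control = control),
                    error = function(e) NULL)
    if (is.null(opt)) next
    if (opt$convergence == 0L) n_conv <- n_conv + 1L
    if (opt$convergence == 0L &&
        (is.null(best) || opt$value < best$value)) best <- opt
  }
  warns <- character(0)
  if (is.null(best)) {
    out <- structure(list(
      call = match.call(), formulas = list(psi = psi, theta = theta, p = p),
      sharing = sharing, fix_theta = fix_theta, converged = FALSE,
      coef = stats::setNames(rep(NA_real_, maps$K), maps$names),
      vcov = NULL, loglik = NA_real_, K = maps$K, n_sites = n,
      warnings = "no start converged", pooled = pooled,
      covariates = covariates, xlev = dm$xlev, maps = maps,
      method_ids = pooled$method_ids), class = "occu_ms")
    warning("occu_ms: no optimization start converged")
    return(out)
  }
  par <- stats::setNames(best$par, maps$names)
  eta_all <- c(drop(dm$X_psi %*% (maps$psi %*% par)),
               if (is.null(fix_theta))
                 drop(dm$X_theta %*% (maps$theta %*% par)),
               drop(dm$X_p %*% (maps$p %*% par)))
  if (any(abs(eta_all) > 10))
    warns <- c(warns,
               "boundary estimate: |linear predictor| > 10 at the optimum")
  V <- NULL
  if (hessian) {
    H <- tryCatch(pracma::hessian(nll, best$par), error = function(e) NULL)
    ev <- if (!is.null(H)) tryCatch(eigen((H + t(H)) / 2,
                                          symmetric = TRUE,
                                          only.values = TRUE)$values,
                                    error = function(e) NULL)
    if (!is.null(ev) && all(ev > 1e-10 * max(abs(ev)))) {
      V <- solve((H + t(H)) / 2)
      dimnames(V) <- list(maps$names, maps$names)
    } else {
      warns <- c(warns,
                 "Hessian not positive definite; standard errors unavailable")
    }
  }
  for (w in warns) warning("occu_ms: ", w)
  structure(list(
    call = match.call(), formulas = list(psi = psi, theta = theta, p = p),
    sharing = sharing, fix_theta = fix_theta, converged = TRUE,
    coef = par, vcov = V, loglik = -best$value, K = maps$K, n_sites = n,
    n_converged_starts = n_conv,
    warnings = warns, pooled = pooled, covariates = covariates,
    xlev = dm$xlev, maps = maps, method_ids = pooled$method_ids),
    class = "occu_ms")
}

# Compact model label, e.g. "psi(Loss1k) theta(.) p(method+Access)"
model_label <- function(fit) {
  lab <- function(f) {
    t <- attr(stats::terms(f), "term.labels")
    if (!length(t)) "." else paste(t, collapse = "+")
  }
  if (fit$sharing == "psi_theta")
    sprintf("psi=theta(%s) p(%s)", lab(fit$formulas$psi),
            lab(fit$formulas$p))
  else
    sprintf("psi(%s) theta(%s) p(%s)", lab(fit$formulas$psi),
            lab(fit$formulas$theta), lab(fit$formulas$p))
}

#' @export
print.occu_ms <- function(x, ...) {
  cat("Multi-scale occupancy model:", model_label(x), "\n")
  if (!x$converged) {
    cat("  FIT FAILED:", x$warnings, "\n")
    return(invisible(x))
  }
  cat(sprintf("  n_sites = %d, K = %d, logLik = %.3f, AICc = %.3f\n",
              x$n_sites, x$K, x$loglik,
              tryCatch(aicc(x$loglik, x$K, x$n_sites),
                       error = function(e) NA_real_)))
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' @export
coef.occu_ms <- function(object, ...) object$coef

#' @export
vcov.occu_ms <- function(object, ...) object$vcov

#' @export
logLik.occu_ms <- function(object, ...) {
  structure(object$loglik, df = object$K, nobs = object$n_sites,
            class = "logLik")
}

#' @export
summary.occu_ms <- function(object, ...) {
  se <- if (is.null(object$vcov)) rep(NA_real_, object$K) else
    sqrt(pmax(diag(object$vcov), 0))
  tab <- data.frame(Estimate = unname(object$coef), SE = se,
                    z = unname(object$coef) / se,
                    row.names = names(object$coef))
  out <- list(model = model_label(object), coefficients = tab,
              loglik = object$loglik, K = object$K,
              n_sites = object$n_sites, converged = object$converged,
              warnings = object$warnings)
  class(out) <- "summary.occu_ms"
  out
}

#' @export
print.summary.occu_ms <- function(x, ...) {
  cat("Multi-scale occupancy model:", x$model, "\n")
  cat(sprintf("n_sites = %d, K = %d, logLik = %.3f\n\n",
              x$n_sites, x$K, x$loglik))
  print(round(x$coefficients, 4))
  if (length(x$warnings)) cat("\nWarnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}
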