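#' Akaike information criterion corrected for small samples
#'
#' `AICc = -2 logLik + 2K + 2K(K + 1) / (n - K - 1)`, where `n` is the
#' number of independent sites. The correction is undefined when
#' `n <= K + 1`.
#'
#' @param loglik maximized log-likelihood.
#' @param K number of free parameters.
#' @param n effective sample size (number of sites).
#' @return the AICc value.
#' @examples
#' aicc(-100, 3, 32)
#' @export
aicc <- function(loglik, K, n) {
  stopifnot(is.finite(loglik), K >= 0, n >= 1)
  if (n <= K + 1)
    stop("AICc undefined: need n > K + 1 (n = ", n, ", K = ", K, ")")
  -2 * loglik + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Rank models by AICc with Akaike weights
#'
#' Non-converged fits are dropped with a message. Exact AICc ties are broken
#' by fewer parameters, then lexical model id (and logged).
#'
#' @param fits a named list of [occu_ms()] fits (names become model ids;
#'   unnamed fits are labelled from their formulas).
#' @param n effective sample size for AICc; defaults to the fits' site
#'   count.
#' @return an object of class `occu_ms_ranking`: a data frame with columns
#'   `model`, `K`, `logLik`, `AICc`, `dAICc`, `weight`, sorted ascending by
#'   AICc, carrying the converged fits as attribute `"fits"`.
#' @export
rank_models <- function(fits, n = NULL) {
  if (inherits(fits, "occu_ms")) fits <- list(fits)
  ids <- names(fits)
  if (is.null(ids)) ids <- rep("", length(fits))
  blank <- !nzchar(ids)
  ids[blank] <- vapply(fits[blank], model_label, character(1))
  names(fits) <- ids
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (any(!conv))
    message("rank_models: dropping non-converged fit(s): ",
            paste(ids[!conv], collapse = ", "))
  fits <- fits[conv]
  if (!length(fits)) stop("no converged fits to rank")
  if (is.null(n)) n <- fits[[1]]$n_sites
  tab <- data.frame(
    model = names(fits),
    K = vapply(fits, function(f) f$K, numeric(1)),
    logLik = vapply(fits, function(f) f$loglik, numeric(1)),
    stringsAsFactors = FALSE)
  tab$AICc <- mapply(aicc, tab$logLik, tab$K, MoreArgs = list(n = n))
  ord <- order(tab$AICc, tab$K, tab$model)
  tab <- tab[ord, , drop = FALSE]
  if (nrow(tab) > 1 && any(diff(tab$AICc) == 0))
    message("rank_models: exact AICc tie broken by K, then model id")
  tab$dAICc <- tab$AICc - tab$AICc[1]
  w <- exp(-tab$dAICc / 2)
  tab$weight <- w / sum(w)
  rownames(tab) <- NULL
  structure(tab, fits = fits[tab$model], n = n,
            class = c("occu_ms_ranking", "data.frame"))
}

#' @export
print.occu_ms_ranking <- function(x, digits = 3, ...) {
  cat("Model ranking (AICc, n =", attr(x, "n"), "sites):\n")
  y <- as.data.frame(x)
  y$logLik <- round(y$logLik, digits)
  y$AICc <- round(y$AICc, digits)
  y$dAICc <- round(y$dAICc, digits)
  y$weight <- round(y$weight, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Akaike-weight average of estimates across models
#'
#' Weighted mean on the probability scale, with the unconditional standard
#' error `sum_i w_i * sqrt(se_i^2 + (est_i - mean)^2)` that absorbs
#' between-model spread.
#'
#' @param est per-model estimates.
#' @param se per-model standard errors.
#' @param w Akaike weights (must sum to 1).
#' @return `c(estimate, se)`.
#' @export
average_estimates <- function(est, se, w) {
  stopifnot(length(est) == length(se), length(est) == length(w),
            abs(sum(w) - 1) < 1e-6)
  m <- sum(w * est)
  c(estimate = m, se = sum(w * sqrt(se^2 + (est - m)^2)))
}

#' Model-averaged probability estimates at a reference profile
#'
#' Averages the predicted occupancy, availability and per-method detection
#' probabilities over a ranked model set using Akaike weights, on the
#' probability scale, with unconditional SEs.
#'
#' @param ranking an `occu_ms_ranking` from [rank_models()].
#' @param profile reference covariate profile as in [predict.occu_ms()].
#' @return a list of data frames `psi`, `theta` (one row) and `p` (one row
#'   per method), columns `estimate`, `se`.
#' @export
model_average <- function(ranking, profile = NULL) {
  stopifnot(inherits(ranking, "occu_ms_ranking"))
  fits <- attr(ranking, "fits")
  w <- ranking$weight
  # NULL means the baseline profile, not per-site predictions
  if (is.null(profile)) profile <- list()
  preds <- lapply(fits, predict, profile = profile)
  avg1 <- function(get_est, get_se) {
    e <- vapply(preds, get_est, numeric(1))
    s <- vapply(preds, get_se, numeric(1))
    average_estimates(e, s, w)
  }
  psi <- avg1(function(pr) pr$psi$estimate[1], function(pr) pr$psi$se[1])
  theta <- avg1(function(pr) pr$theta$estimate[1],
                function(pr) pr$theta$se[1])
  methods <- preds[[1]]$p$method
  p <- t(vapply(seq_along(methods), function(s)
    avg1(function(pr) pr$p$estimate[s], function(pr) pr$p$se[s]),
    numeric(2)))
  list(psi = data.frame(estimate = psi[1], se = psi[2]),
       theta = data.frame(estimate = theta[1], se = theta[2]),
       p = data.frame(method = methods, estimate = p[, 1], se = p[, 2]))
}

#' Choose the best-supported buffer scale
#'
#' Given one fit per tree-loss buffer scale (models otherwise identical),
#' returns the buffer whose model minimizes AICc. Exact ties go to the
#' smaller buffer and are logged.
#'
#' @param fits a list of converged [occu_ms()] fits named by their Loss
#'   column (e.g. `Loss100m`, `Loss500m`, `Loss1k`, `Loss5k`).
#' @param n effective sample size for AICc.
#' @return the winning buffer column name, with the AICc table as attribute
#'   `"aicc"`.
#' @export
select_buffer_scale <- function(fits, n = NULL) {
  stopifnot(length(fits) >= 1, !is.null(names(fits)))
  if (is.null(n)) n <- fits[[1]]$n_sites
  a <- vapply(fits, function(f) aicc(f$loglik, f$K, n), numeric(1))
  canonical <- c("Loss100m", "Loss500m", "Loss1k", "Loss5k")
  size_rank <- match(names(fits), canonical)
  size_rank[is.na(size_rank)] <- seq_along(fits)[is.na(size_rank)] +
    length(canonical)
  ord <- order(a, size_rank)
  if (length(a) > 1 && sum(a == min(a)) > 1)
    message("select_buffer_scale: exact AICc tie; smaller buffer retained")
  structure(names(fits)[ord[1]], aicc = a)
}

all_additive_combos <- function(vars, max_size) {
  out <- list()
  for (k in seq_len(min(max_size, length(vars))))
    out <- c(out, utils::combn(vars, k, simplify = FALSE))
  out
}

terms_to_formula <- function(terms) {
  if (!length(terms)) ~1
  else stats::as.formula(paste("~", paste(terms, collapse = "+")))
}

#' Three-stage model selection for camera-array survey designs
#'
#' The staged workflow for comparing pooling methods while screening
#' covariates: stage 1 asks whether detection varies by pooling method
#' (`p(method)` vs `p(.)`); stage 2 screens additional detection covariates
#' on top of the stage-1 winner, builds additive combinations of every
#' covariate appearing within 2 dAICc of the top model (capped at
#' `max_additive` covariates beyond the method factor), and retains the
#' single top detection structure; stage 3 compares the best-supported
#' tree-loss buffer scale, then places each occupancy covariate on `psi`
#' only, on `psi` and `theta` as a single shared effect, and on `psi` and
#' `theta` as separate effects. The final candidate set is ranked and
#' model-averaged detection estimates are reported at a reference profile.
#'
#' If every candidate of a stage fails to converge the workflow aborts,
#' returning the rankings completed so far.
#'
#' @param pooled a `pooled_history`.
#' @param covariates a [covariate_table()].
#' @param detection_covariates covariate columns screened on `p` in stage 2
#'   (default none).
#' @param occupancy_covariates site-level columns placed on `psi`/`theta`
#'   in stage 3 (default none).
#' @param buffer_covariates tree-loss columns compared as alternative buffer
#'   scales; the best-supported one joins `occupancy_covariates` (default
#'   none).
#' @param max_additive cap on the number of detection covariates combined
#'   additively in stage 2 (default 3).
#' @param profile reference covariate profile for the reported estimates.
#' @param n_starts,seed,control passed to [occu_ms()].
#' @return an object of class `occu_ms_stages`: a list with per-stage
#'   rankings, `best_buffer`, `final_fit`, `averaged_detection`,
#'   `estimate_table`, and `aborted_at` (`NA` on success).
#' @export
run_three_stage <- function(pooled, covariates = NULL,
                            detection_covariates = character(0),
                            occupancy_covariates = character(0),
                            buffer_covariates = character(0),
                            max_additive = 3, profile = NULL,
                            n_starts = 5, seed = 1,
                            control = list(maxit = 1000, reltol = 1e-10)) {
  known <- c(if (!is.null(covariates))
    c(setdiff(names(covariates$site), "site"),
      setdiff(names(covariates$site_method), c("site", "method"))),
    "method")
  wanted <- c(detection_covariates, occupancy_covariates, buffer_covariates)
  bad <- setdiff(wanted, known)
  if (length(bad))
    stop("unknown covariate(s): ", paste(bad, collapse = ", "))
  fit1 <- function(psi, theta, p, sharing = "none")
    occu_ms(pooled, covariates, psi = psi, theta = theta, p = p,
            sharing = sharing, n_starts = n_starts, seed = seed,
            control = control, hessian = FALSE)
  out <- list(stage1 = NULL, stage2 = NULL, stage3 = NULL,
              best_buffer = NULL, final_fit = NULL,
              averaged_detection = NULL, estimate_table = NULL,
              aborted_at = NA_integer_)
  class(out) <- "occu_ms_stages"
  abort <- function(stage, e) {
    warning("stage ", stage, " aborted: ", conditionMessage(e))
    out$aborted_at <- stage
    out
  }

  ## stage 1: method factor on detection, or not
  s1 <- list("psi(.) theta(.) p(.)" = fit1(~1, ~1, ~1),
             "psi(.) theta(.) p(method)" = fit1(~1, ~1, ~method))
  r1 <- tryCatch(rank_models(s1), error = function(e) e)
  if (inherits(r1, "error")) return(abort(1L, r1))
  out$stage1 <- r1
  base_p <- if (grepl("p\\(method\\)", r1$model[1])) "method" else character(0)

  ## stage 2: additional detection covariates
  p_terms <- base_p
  if (length(detection_covariates)) {
    cand <- list(terms_to_formula(base_p))
    names(cand) <- paste0("p(", if (length(base_p)) base_p else ".", ")")
    for (v in detection_covariates) {
      f <- terms_to_formula(c(base_p, v))
      cand[[paste0("p(", paste(c(base_p, v), collapse = "+"), ")")]] <- f
    }
    s2 <- lapply(cand, function(f) fit1(~1, ~1, f))
    r2a <- tryCatch(rank_models(s2), error = function(e) e)
    if (inherits(r2a, "error")) return(abort(2L, r2a))
    keep <- r2a$model[r2a$dAICc <= 2]
    retained <- intersect(detection_covariates,
                          unique(unlist(lapply(keep, function(m)
                            all.vars(stats::as.formula(
                              paste("~", gsub("^p\\(|\\)$", "", m))))))))
    if (length(retained) > 1) {
      for (combo in all_additive_combos(retained, max_additive)) {
        if (length(combo) < 2) next
        nm <- paste0("p(", paste(c(base_p, combo), collapse = "+"), ")")
        if (!nm %in% names(s2))
          s2[[nm]] <- fit1(~1, ~1, terms_to_formula(c(base_p, combo)))
      }
    }
    r2 <- tryCatch(rank_models(s2), error = function(e) e)
    if (inherits(r2, "error")) return(abort(2L, r2))
    out$stage2 <- r2
    top <- gsub("^p\\(|\\)$", "", r2$model[1])
    p_terms <- if (top == ".") character(0) else
      strsplit(top, "+", fixed = TRUE)[[1]]
  } else {
    out$stage2 <- r1
  }
  p_formula <- terms_to_formula(p_terms)

  ## stage 3: occupancy/availability covariates and buffer scale
  occ_vars <- occupancy_covariates
  if (length(buffer_covariates)) {
    bfits <- lapply(stats::setNames(buffer_covariates, buffer_covariates),
                    function(v) fit1(terms_to_formula(v), ~1, p_formula))
    bfits <- bfits[vapply(bfits, function(f) isTRUE(f$converged),
                          logical(1))]
    if (!length(bfits))
      return(abort(3L, simpleError("no converged buffer-scale candidate")))
    out$best_buffer <- select_buffer_scale(bfits)
    occ_vars <- c(occ_vars, as.character(out$best_buffer))
  }
  s3 <- list()
  s3[[sprintf("psi(.) theta(.) p(%s)",
              if (length(p_terms)) paste(p_terms, collapse = "+") else ".")]] <-
    fit1(~1, ~1, p_formula)
  for (v in occ_vars) {
    f <- terms_to_formula(v)
    s3[[sprintf("psi(%s) theta(.)", v)]] <- fit1(f, ~1, p_formula)
    s3[[sprintf("psi=theta(%s)", v)]] <- fit1(f, f, p_formula,
                                              sharing = "psi_theta")
    s3[[sprintf("psi(%s) theta(%s)", v, v)]] <- fit1(f, f, p_formula)
  }
  r3 <- tryCatch(rank_models(s3), error = function(e) e)
  if (inherits(r3, "error")) return(abort(3L, r3))
  out$stage3 <- r3
  final_id <- r3$model[1]
  ## refit the winner with a Hessian for reporting
  ffit <- attr(r3, "fits")[[final_id]]
  out$final_fit <- occu_ms(pooled, covariates, psi = ffit$formulas$psi,
                           theta = ffit$formulas$theta,
                           p = ffit$formulas$p, sharing = ffit$sharing,
                           n_starts = n_starts, seed = seed,
                           control = control)
  r3h <- rank_models(lapply(attr(r3, "fits"), function(f)
    occu_ms(pooled, covariates, psi = f$formulas$psi,
            theta = f$formulas$theta, p = f$formulas$p,
            sharing = f$sharing, n_starts = n_starts, seed = seed,
            control = control)))
  out$averaged_detection <- model_average(r3h, profile = profile)$p
  out$estimate_table <- estimate_table(out$final_fit, profile = profile)
  out
}

#' @export
print.occu_ms_stages <- function(x, ...) {
  for (s in 1:3) {
    r <- x[[paste0("stage", s)]]
    if (is.null(r)) next
    cat("== Stage", s, "==\n")
    print(r)
  }
  if (!is.null(x$best_buffer))
    cat("Best-supported buffer scale:", x$best_buffer, "\n")
  if (!is.na(x$aborted_at))
    cat("WORKFLOW ABORTED at stage", x$aborted_at, "\n")
  else if (!is.null(x$final_fit))
    cat("Final model:", model_label(x$final_fit), "\n")
  invisible(x)
}
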