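#' Multi-scale occupancy likelihood for one site
#'
#' Probability of one site's pooled detection history under the three-level
#' hierarchy: the site is occupied at the large scale with probability `psi`;
#' given occupancy, the species is available near the array on occasion `t`
#' with probability `theta[t]`; given availability, method `s` detects it
#' with probability `p[t, s]`, conditionally independently across methods.
#'
#' An occasion with at least one detection pins availability down, so it
#' contributes `theta_t * prod_s p^y (1-p)^(1-y)`. An occasion with only
#' non-detections is a mixture of "not available" and "available but every
#' method missed". Missing entries contribute no factor. A history with no
#' detections at all additionally admits the unoccupied explanation `1 - psi`.
#'
#' @param psi occupancy probability (scalar in `[0, 1]`).
#' @param theta availability probability: scalar or length-`T` vector.
#' @param p detection probabilities: length-`S` vector (occasion-constant)
#'   or `T x S` matrix.
#' @param y the site's history: `T x S` matrix (occasions x methods) with
#'   values in `{0, 1, NA}`.
#' @return the likelihood, a probability.
#' @examples
#' y <- rbind(c(0, 1, 1, 0, 0), c(0, 0, 0, 0, 0))
#' site_likelihood(0.5, 0.5, rep(0.5, 5), y)  # 0.0040283203125
#' @export
site_likelihood <- function(psi, theta, p, y) {
  y <- as.matrix(y)
  Tn <- nrow(y); S <- ncol(y)
  if (length(theta) == 1L) theta <- rep(theta, Tn)
  if (is.null(dim(p))) p <- matrix(p, Tn, S, byrow = TRUE)
  if (length(theta) != Tn || nrow(p) != Tn || ncol(p) != S)
    stop("dimension mismatch between y, theta and p")
  probs <- c(psi, theta, p)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("all of psi, theta, p must be probabilities in [0, 1]")
  if (!all(y %in% c(0, 1) | is.na(y)))
    stop("history values must be 0, 1 or NA")
  occ <- 1
  for (t in seq_len(Tn)) {
    obs <- which(!is.na(y[t, ]))
    if (!length(obs)) next
    A <- prod(ifelse(y[t, obs] == 1, p[t, obs], 1 - p[t, obs]))
    occ <- occ * if (any(y[t, obs] == 1)) theta[t] * A
                 else theta[t] * A + (1 - theta[t])
  }
  if (any(y == 1, na.rm = TRUE)) psi * occ else psi * occ + (1 - psi)
}

#' Brute-force site likelihood by latent-state enumeration
#'
#' Independent oracle for [site_likelihood()]: sums
#' `Pr(z) Pr(a | z) Pr(y | z, a)` over every latent occupancy state
#' `z in {0, 1}` and availability vector `a in {0, 1}^T`. Exponential in
#' the number of occasions, so refuses `T > 12`.
#'
#' @inheritParams site_likelihood
#' @return the likelihood, a probability.
#' @export
brute_force_site_likelihood <- function(psi, theta, p, y) {
  y <- as.matrix(y)
  Tn <- nrow(y); S <- ncol(y)
  if (Tn > 12L) stop("T too large for exhaustive enumeration (max 12)")
  if (length(theta) == 1L) theta <- rep(theta, Tn)
  if (is.null(dim(p))) p <- matrix(p, Tn, S, byrow = TRUE)
  # z = 0: detections are impossible, non-detections and missing certain
  total <- (1 - psi) * as.numeric(!any(y == 1, na.rm = TRUE))
  for (code in 0:(2^Tn - 1)) {
    a <- as.integer(intToBits(code))[seq_len(Tn)]
    pr <- psi
    for (t in seq_len(Tn)) {
      pr <- pr * if (a[t] == 1) theta[t] else 1 - theta[t]
      for (s in seq_len(S)) {
        if (is.na(y[t, s])) next
        pys <- if (a[t] == 1) {
          if (y[t, s] == 1) p[t, s] else 1 - p[t, s]
        } else {
          if (y[t, s] == 1) 0 else 1
        }
        pr <- pr * pys
      }
    }
    total <- total + pr
  }
  total
}

# Vectorized negative log-likelihood over all sites.
# Y: n x S x Tmax array in {0,1,NA}; psi, theta: length-n; P: n x S.
# Occasions beyond a site's window are NA throughout and drop out.
multiscale_negloglik <- function(psi, theta, P, Y) {
  n <- dim(Y)[1]; S <- dim(Y)[2]; Tmax <- dim(Y)[3]
  logP <- log(P); log1mP <- log1p(-P)
  occ_sum <- numeric(n)
  anydet <- logical(n)
  log_theta <- log(theta); log_1mtheta <- log1p(-theta)
  for (t in seq_len(Tmax)) {
    Yt <- matrix(Y[, , t], n, S)
    miss <- is.na(Yt)
    term <- Yt * logP + (1 - Yt) * log1mP
    term[miss] <- 0
    la <- rowSums(term)                       # log Pr(y_t | available)
    det_t <- rowSums(Yt == 1, na.rm = TRUE) > 0
    obs_t <- rowSums(!miss) > 0
    contrib <- numeric(n)
    contrib[det_t] <- log_theta[det_t] + la[det_t]
    nd <- obs_t & !det_t
    # mixture: available-but-missed + not-available
    contrib[nd] <- log(theta[nd] * exp(la[nd]) + (1 - theta[nd]))
    occ_sum <- occ_sum + contrib
    anydet <- anydet | det_t
  }
  ll <- numeric(n)
  ll[anydet] <- log(psi[anydet]) + occ_sum[anydet]
  z <- !anydet
  if (any(z)) {
    a <- log(psi[z]) + occ_sum[z]
    b <- log1p(-psi[z])
    m <- pmax(a, b)
    ll[z] <- ifelse(is.infinite(m) & m < 0, -Inf,
                    m + log(exp(a - m) + exp(b - m)))
  }
  v <- -sum(ll)
  if (!is.finite(v)) return(1e10)
  v
}

#' Combined daily detection probability
#'
#' Product of the daily availability estimate and a method-conditional
#' detection estimate: the single-scale daily detection probability implied
#' for a survey that used only that pooling method, rounded to reporting
#' precision.
#'
#' @param theta_hat availability estimate in `[0, 1]`.
#' @param p_hat method-conditional detection estimate in `[0, 1]`.
#' @param digits decimal places for the reported value (default 3, the
#'   usual table precision).
#' @return `round(theta_hat * p_hat, digits)`.
#' @examples
#' combined_daily_detection(0.07, 0.13)  # 0.009
#' @export
combined_daily_detection <- function(theta_hat, p_hat, digits = 3) {
  stopifnot(all(theta_hat >= 0 & theta_hat <= 1),
            all(p_hat >= 0 & p_hat <= 1))
  round(theta_hat * p_hat, digits)
}
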