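# Small in-code fixtures shared across test files.

# A 2-site, 5-camera, 4-day array with one detection, one missing visit,
# and unequal survey windows (site s2 surveyed 3 days).
tiny_array <- function() {
  obs <- array(0, dim = c(2, 5, 4))
  obs[1, 1, 2] <- 1   # camera A detects at s1, day 2
  obs[1, 3, 1] <- NA  # camera C missing at s1, day 1
  obs[2, , 4] <- NA
  detection_array(obs, site_ids = c("s1", "s2"),
                  occasions = c(4L, 3L))
}

# Random ternary detection array for property tests.
random_array <- function(n_sites, n_cams = 5, Tmax = 6,
                         probs = c(0.5, 0.3, 0.2)) {
  obs <- array(sample(c(0, 1, NA), n_sites * n_cams * Tmax, TRUE, probs),
               dim = c(n_sites, n_cams, Tmax))
  detection_array(obs)
}

# Fits kept cheap for workflows exercised many times.
fit_quick <- function(...) {
  occu_ms(..., n_starts = 2, seed = 1, hessian = FALSE)
}
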