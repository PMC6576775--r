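# Minimal stand-in fit objects for ranking arithmetic tests.
fake_fit <- function(loglik, K, n_sites = 32, converged = TRUE) {
  structure(list(converged = converged, loglik = loglik, K = K,
                 n_sites = n_sites), class = "occu_ms")
}

test_that("AICc arithmetic and guards", {
  expect_equal(aicc(-100, 3, 32), 206 + 6 / 7, tolerance = 1e-12)
  expect_error(aicc(-100, 3, 4), "n > K \\+ 1")
  # n -> infinity limit is plain AIC
  expect_equal(aicc(-100, 3, 1e9), -2 * -100 + 2 * 3, tolerance = 1e-6)
})

test_that("rankings normalize weights and honor the weight-ratio identity", {
  r1 <- rank_models(list(only = fake_fit(-100, 3)))
  expect_equal(r1$dAICc, 0)
  expect_equal(r1$weight, 1)

  r2 <- rank_models(list(a = fake_fit(-100, 3), b = fake_fit(-100, 3)))
  expect_equal(r2$weight, c(0.5, 0.5))

  # deltas (0, 2, 4) -> weights proportional to (1, 1/e, 1/e^2)
  f <- list(m0 = fake_fit(-100, 3), m1 = fake_fit(-101, 3),
            m2 = fake_fit(-102, 3))
  r3 <- rank_models(f)
  expect_equal(r3$dAICc, c(0, 2, 4))
  # weights 1 : 1/e : 1/e^2, normalized
  expect_equal(r3$weight, c(1, exp(-1), exp(-2)) / sum(c(1, exp(-1), exp(-2))),
               tolerance = 1e-12)
  expect_equal(round(r3$weight, 2), c(0.67, 0.24, 0.09))
  expect_equal(r3$weight[1] / r3$weight[2], exp(1), tolerance = 1e-12)
  expect_equal(sum(r3$weight), 1, tolerance = 1e-12)
})

test_that("ranking is stable under likelihood shifts and hopeless models", {
  f <- list(a = fake_fit(-100, 3), b = fake_fit(-103, 4))
  r <- rank_models(f)
  shifted <- rank_models(list(a = fake_fit(-50, 3), b = fake_fit(-53, 4)))
  expect_equal(shifted$model, r$model)
  expect_equal(shifted$dAICc, r$dAICc, tolerance = 1e-12)
  # adding an enormous-AICc model leaves the others unchanged
  r2 <- rank_models(c(f, list(z = fake_fit(-500, 3))))
  expect_equal(r2$weight[1:2], r$weight, tolerance = 1e-9)
})

test_that("exact ties break by fewer parameters then model id", {
  # equal AICc engineered: K=2 vs K=3 with compensating logLik
  ll3 <- -100
  a3 <- aicc(ll3, 3, 32)
  ll2 <- -(a3 - 2 * 2 - 2 * 2 * 3 / (32 - 3)) / 2
  f <- list(bigger = fake_fit(ll3, 3), smaller = fake_fit(ll2, 2))
  suppressMessages(r <- rank_models(f))
  expect_equal(r$model[1], "smaller")
  suppressMessages(r2 <- rank_models(list(b = fake_fit(-100, 3),
                                          a = fake_fit(-100, 3))))
  expect_equal(r2$model, c("a", "b"))
})

test_that("non-converged fits are excluded; an empty set errors", {
  f <- list(ok = fake_fit(-100, 3), bad = fake_fit(NA, 3, converged = FALSE))
  expect_message(r <- rank_models(f), "non-converged")
  expect_equal(nrow(r), 1)
  expect_error(suppressMessages(
    rank_models(list(bad = fake_fit(NA, 3, converged = FALSE)))),
    "no converged")
})

test_that("averaging follows the unconditional-SE formula and its bounds", {
  expect_equal(average_estimates(c(0.2, 0.4), c(0, 0), c(0.5, 0.5)),
               c(estimate = 0.3, se = 0.1))
  expect_equal(average_estimates(0.37, 0.05, 1),
               c(estimate = 0.37, se = 0.05))
  expect_equal(average_estimates(c(0.2, 0.9), c(0.01, 0.5), c(1, 0)),
               c(estimate = 0.2, se = 0.01))
  set.seed(41)
  for (i in 1:25) {
    k <- sample(2:5, 1)
    est <- runif(k); se <- runif(k, 0, 0.2)
    w <- runif(k); w <- w / sum(w)
    out <- average_estimates(est, se, w)
    expect_gte(out["estimate"], min(est))
    expect_lte(out["estimate"], max(est))
  }
})

test_that("buffer-scale selection is argmin with a smaller-buffer tie-break", {
  mk <- function(ll) fake_fit(ll, 4)
  fits <- list(Loss100m = mk(-101), Loss500m = mk(-100), Loss1k = mk(-98.5),
               Loss5k = mk(-99.5))
  expect_equal(as.character(select_buffer_scale(fits, 32)), "Loss1k")
  tie <- list(Loss500m = mk(-100), Loss100m = mk(-100))
  expect_message(b <- select_buffer_scale(tie, 32), "tie")
  expect_equal(as.character(b), "Loss100m")
  expect_equal(as.character(select_buffer_scale(list(Loss5k = mk(-1)), 32)),
               "Loss5k")
})

test_that("a strong method effect is retained in stage 1 with clear support", {
  sim <- simulate_method_level(200, 16:23, psi = 0.7, theta = 0.35,
                               p = c(0.1, 0.45, 0.65, 0.4, 0.6), seed = 61)
  res <- run_three_stage(sim$history, n_starts = 2, seed = 1)
  expect_true(grepl("p\\(method\\)", res$stage1$model[1]))
  expect_gt(res$stage1$dAICc[2], 2)
  expect_true(is.na(res$aborted_at))
})

test_that("null data keep null covariate forms in the short-list and the workflow completes", {
  # no covariate effects anywhere: generated independently of Area/Access/Loss
  sim <- simulate_method_level(150, 12, psi = 0.7, theta = 0.4,
                               p = c(0.15, 0.4, 0.55, 0.35, 0.5), seed = 62)
  cov <- simulate_covariates(150, seed = 62)
  cov <- zscore_covariates(cov, c("DistAve", "Loss100m", "Loss1k"))
  res <- run_three_stage(sim$history, cov,
                         detection_covariates = "Access",
                         occupancy_covariates = "Area",
                         buffer_covariates = c("Loss100m", "Loss1k"),
                         n_starts = 2, seed = 1)
  expect_true(is.na(res$aborted_at))
  # the no-covariate detection structure sits within 2 dAICc of the top
  s2 <- res$stage2
  null_rows <- grepl("p\\(method\\)$|p\\(\\.\\)$", s2$model)
  expect_true(any(s2$dAICc[null_rows] <= 2))
  # stage 3 ranks the psi/theta placements and reports averaged detection
  expect_true(grepl("psi\\(\\.\\)", res$stage3$model[1]) ||
                res$stage3$dAICc[grepl("psi\\(\\.\\)", res$stage3$model)] <= 2)
  expect_equal(nrow(res$averaged_detection), 5)
  expect_true(all(res$averaged_detection$estimate >= 0 &
                    res$averaged_detection$estimate <= 1))
  # averaged estimates lie inside the per-model envelope
  expect_equal(nrow(res$estimate_table), 5)
  expect_true(res$best_buffer %in% c("Loss100m", "Loss1k"))
})

test_that("unknown covariates abort before any fitting", {
  sim <- simulate_method_level(20, 6, psi = 0.7, theta = 0.4,
                               p = rep(0.4, 5), seed = 63)
  expect_error(run_three_stage(sim$history,
                               detection_covariates = "NotThere"),
               "unknown covariate")
})
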