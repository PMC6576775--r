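test_that("design matrices expand factors with fixed baselines", {
  sim <- simulate_method_level(8, 5, psi = 0.7, theta = 0.4,
                               p = rep(0.4, 5), seed = 5)
  cov <- simulate_covariates(8, seed = 5)
  cov <- zscore_covariates(cov, c("DistAve", "Loss1k"))
  dm <- camoccu:::build_design_matrices(~1, ~1, ~method, sim$history, cov)
  expect_equal(ncol(dm$X_psi), 1)          # null model: intercept only
  expect_equal(ncol(dm$X_p), 5)            # intercept + 4 method indicators
  expect_equal(colnames(dm$X_p)[1:2], c("(Intercept)", "methodm2"))
  dm2 <- camoccu:::build_design_matrices(~1, ~1, ~method + Access + DistAve,
                                         sim$history, cov)
  expect_equal(ncol(dm2$X_p), 7)           # 5 + 1 + 1
  # (site, method)-level terms are rejected for psi/theta
  expect_error(
    camoccu:::build_design_matrices(~DistAve, ~1, ~method, sim$history, cov),
    "site-level")
  expect_error(
    camoccu:::build_design_matrices(~1, ~1, ~NotACovariate, sim$history, cov),
    "unresolvable")
})

test_that("intercept-only predictions are inverse-logit of coefficients", {
  sim <- simulate_method_level(300, 10, psi = 0.6, theta = 0.5,
                               p = rep(0.45, 5), seed = 8)
  fit <- occu_ms(sim$history, p = ~1, n_starts = 3, seed = 1)
  expect_true(fit$converged)
  pr <- predict(fit)
  expect_equal(pr$psi$estimate[1], plogis(fit$coef[["psi_(Intercept)"]]),
               tolerance = 1e-12)
  # delta-method identity for the intercept-only block
  eta <- fit$coef[["psi_(Intercept)"]]
  expect_equal(pr$psi$se[1],
               dlogis(eta) * sqrt(fit$vcov["psi_(Intercept)",
                                           "psi_(Intercept)"]),
               tolerance = 1e-12)
  # refitting from the returned coefficients does not improve the optimum
  f2 <- occu_ms(sim$history, p = ~1, n_starts = 1, seed = 1)
  expect_lte(abs(f2$loglik - fit$loglik), 1e-4)
})

test_that("method-factor fits recover distinct per-method detection rates", {
  p_true <- c(0.15, 0.45, 0.65, 0.4, 0.6)
  sim <- simulate_method_level(800, 15, psi = 0.7, theta = 0.35,
                               p = p_true, seed = 21)
  fit <- fit_quick(sim$history, p = ~method)
  pr <- predict(fit)
  p_hat <- pr$p$estimate
  expect_length(unique(round(p_hat, 6)), 5)
  expect_lt(max(abs(p_hat - p_true)), 0.06)
  expect_lt(abs(pr$psi$estimate[1] - 0.7), 0.06)
  expect_lt(abs(pr$theta$estimate[1] - 0.35), 0.05)
})

test_that("estimator bias shrinks as the number of sites grows", {
  truth <- c(psi = 0.73, theta = 0.3)
  err <- sapply(c(100, 1000), function(n) {
    sim <- simulate_method_level(n, 15, psi = truth["psi"],
                                 theta = truth["theta"],
                                 p = c(0.2, 0.45, 0.6, 0.4, 0.55),
                                 seed = 1000 + n)
    pr <- predict(fit_quick(sim$history))
    sqrt(mean((c(pr$psi$estimate[1], pr$theta$estimate[1]) - truth)^2))
  })
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.05)
  expect_lt(err[1], 0.2)
})

test_that("degenerate data hit the boundary with explicit warnings", {
  # no detections at all
  sim0 <- simulate_method_level(40, 8, psi = 0, theta = 0.5,
                                p = rep(0.5, 5), seed = 2)
  expect_warning(fit0 <- occu_ms(sim0$history, p = ~1, n_starts = 2,
                                 seed = 1, hessian = FALSE),
                 "boundary|Hessian")
  expect_true(any(grepl("boundary", fit0$warnings)))
  expect_lt(plogis(fit0$coef[["psi_(Intercept)"]]), 0.01)

  # saturated detections
  sim1 <- simulate_method_level(40, 8, psi = 1, theta = 1, p = rep(1, 5),
                                seed = 3)
  fit1 <- suppressWarnings(occu_ms(sim1$history, p = ~1, n_starts = 2,
                                   seed = 1, hessian = FALSE))
  expect_true(any(grepl("boundary", fit1$warnings)))
  expect_gt(plogis(fit1$coef[["p_(Intercept)"]]), 0.99)
})

test_that("shared psi/theta effects cost fewer parameters than separate ones", {
  sim <- simulate_method_level(60, 8, psi = 0.7, theta = 0.4,
                               p = rep(0.4, 5), seed = 9)
  cov <- simulate_covariates(60, seed = 9)
  sep <- fit_quick(sim$history, cov, psi = ~Area, theta = ~Area)
  sha <- fit_quick(sim$history, cov, psi = ~Area, theta = ~Area,
                   sharing = "psi_theta")
  expect_lt(sha$K, sep$K)
  expect_equal(sep$K - sha$K, 2)  # two Area slopes collapse onto one pair
  expect_error(occu_ms(sim$history, cov, psi = ~Area, theta = ~1,
                       sharing = "psi_theta"),
               "identical")
})

test_that("covariate effects on detection are recovered on the link scale", {
  set.seed(31)
  n <- 600
  cov <- simulate_covariates(n, seed = 31)
  cov <- zscore_covariates(cov, "DistAve")
  # build p varying by method and by the z-scored distance (slope 0.8)
  map <- default_method_map()
  base <- qlogis(c(0.2, 0.4, 0.55, 0.35, 0.5))
  sm <- cov$site_method
  eta <- base[match(sm$method, map$method_id)] + 0.8 * sm$DistAve
  P <- matrix(NA_real_, n, 5)
  P[cbind(match(sm$site, cov$site$site),
          match(sm$method, map$method_id))] <- plogis(eta)
  sim <- simulate_method_level(n, 12, psi = 0.75, theta = 0.5, p = P,
                               seed = 31)
  fit <- fit_quick(sim$history, cov, p = ~method + DistAve)
  expect_true(fit$converged)
  expect_lt(abs(fit$coef[["p_DistAve"]] - 0.8), 0.15)
})

test_that("empty or uninformative pooled data are hard errors", {
  sim <- simulate_method_level(5, 4, psi = 0.5, theta = 0.5,
                               p = rep(0.5, 5), seed = 4)
  h <- sim$history
  h$obs[] <- NA
  expect_error(occu_ms(h), "no informative")
})

test_that("profile prediction honors baselines and rejects unseen categories", {
  sim <- simulate_method_level(60, 8, psi = 0.7, theta = 0.4,
                               p = rep(0.4, 5), seed = 12)
  cov <- simulate_covariates(60, seed = 12)
  fit <- occu_ms(sim$history, cov, psi = ~Area, p = ~method + Access,
                 n_starts = 2, seed = 1)
  pr_base <- predict(fit, profile = list(Area = "SL", Access = "RD"))
  pr_default <- predict(fit, profile = list())  # defaults are the baselines
  expect_equal(pr_base$psi$estimate, pr_default$psi$estimate,
               tolerance = 1e-12)
  expect_equal(nrow(pr_base$p), 5)
  expect_error(predict(fit, profile = list(Area = "XX")),
               "outside training categories")
})

test_that("simulate() from a fit reproduces the training survey windows", {
  sim <- simulate_method_level(50, 16:23, psi = 0.7, theta = 0.4,
                               p = rep(0.4, 5), seed = 14)
  fit <- fit_quick(sim$history)
  reps <- simulate(fit, nsim = 2, seed = 99)
  expect_length(reps, 2)
  expect_equal(reps[[1]]$occasions, sim$history$occasions)
  expect_identical(is.na(reps[[1]]$obs), is.na(sim$history$obs))
})
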