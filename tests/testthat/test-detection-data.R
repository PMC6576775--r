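test_that("long-format reader transcribes records and rejects bad cells", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site,camera,occasion,value",
               "s1,A,1,1",
               "s1,A,2,0"), f)
  d <- read_detections(f)
  expect_equal(as.numeric(d$obs[1, 1, ]), c(1, 0))
  expect_equal(d$occasions, 2L)

  # out-of-alphabet value names the offending cell
  writeLines(c("site,camera,occasion,value",
               "s1,A,1,1",
               "s1,A,2,2"), f)
  expect_error(read_detections(f), "s1.*A.*2")

  # duplicate (site, camera, occasion)
  writeLines(c("site,camera,occasion,value",
               "s1,A,1,1",
               "s1,A,1,0"), f)
  expect_error(read_detections(f), "duplicate")
})

test_that("reading is invariant to row order", {
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  rows <- c("s1,A,1,1", "s1,A,2,0", "s1,B,1,NA", "s1,B,2,1",
            "s2,A,1,0", "s2,A,2,0", "s2,B,1,0", "s2,B,2,NA")
  writeLines(c("site,camera,occasion,value", rows), f1)
  writeLines(c("site,camera,occasion,value", rev(rows)), f2)
  expect_equal(read_detections(f1), read_detections(f2))
})

test_that("write/read round-trip preserves the array exactly, both layouts", {
  set.seed(11)
  d <- random_array(4)
  for (layout in c("long", "wide")) {
    f <- withr::local_tempfile(fileext = ".csv")
    write_detections(d, f, layout = layout)
    d2 <- read_detections(f, layout = layout)
    expect_equal(d2$obs, d$obs, info = layout)
    expect_equal(d2$occasions, d$occasions, info = layout)
  }
})

test_that("constructor validates the observation alphabet and shapes", {
  expect_error(detection_array(array(c(0, 1, 2), c(1, 3, 1))),
               "invalid observation value")
  expect_error(detection_array(array(0, c(2, 2, 3)), occasions = c(3, 0)),
               ">= 1 occasion")
  # a failed camera is representable as all-missing
  obs <- array(0, c(1, 2, 3)); obs[1, 2, ] <- NA
  d <- detection_array(obs)
  expect_true(all(is.na(d$obs[1, 2, ])))
})

test_that("pooling follows OR-with-missing semantics on the default map", {
  # day 1: only camera A detects -> m1, m3 detect; m2, m4, m5 do not
  obs <- array(0, c(1, 5, 2))
  obs[1, 1, 1] <- 1
  # day 2: B missing, C detects, D = E = 0
  obs[1, 2, 2] <- NA; obs[1, 3, 2] <- 1
  p <- pool_histories(detection_array(obs))
  expect_equal(as.numeric(p$obs[1, , 1]), c(1, 0, 1, 0, 0))
  expect_equal(as.numeric(p$obs[1, , 2]), c(0, 1, 1, 0, 0))

  # all five cameras missing -> all methods missing
  obs2 <- array(NA_real_, c(1, 5, 1))
  p2 <- pool_histories(detection_array(obs2))
  expect_true(all(is.na(p2$obs)))
})

test_that("pooled value matches the OR-with-missing truth table exactly", {
  # enumerate every two-camera observation pair for method m2 = {B, C}
  vals <- c(0, 1, NA)
  for (b in vals) for (cc in vals) {
    obs <- array(0, c(1, 5, 1))
    obs[1, 2, 1] <- b; obs[1, 3, 1] <- cc
    got <- pool_histories(detection_array(obs))$obs[1, 2, 1]
    expected <- if (all(is.na(c(b, cc)))) NA_real_
                else as.numeric(any(c(b, cc) == 1, na.rm = TRUE))
    expect_equal(got, expected,
                 info = sprintf("B=%s C=%s", format(b), format(cc)))
  }
})

test_that("pooling is monotone over nested methods and idempotent", {
  set.seed(22)
  for (r in 1:20) {
    d <- random_array(3)
    p <- pool_histories(d)
    p2 <- pool_histories(d)
    expect_identical(p$obs, p2$obs)
    for (pair in list(c(1, 3), c(2, 3), c(4, 5))) {
      sub <- p$obs[, pair[1], ]; sup <- p$obs[, pair[2], ]
      hit <- which(sub == 1)
      expect_true(all(sup[hit] == 1))
    }
  }
})

test_that("a single-camera method returns that camera's history verbatim", {
  set.seed(33)
  d <- random_array(3)
  p <- pool_histories(d, method_map(list(onlyB = "B")))
  expect_equal(p$obs[, 1, ], d$obs[, 2, ])
})

test_that("method map validation catches unknown cameras before pooling", {
  d <- tiny_array()
  bad <- method_map(list(mx = c("A", "Z")))
  expect_error(pool_histories(d, bad), "unknown camera")
  expect_error(method_map(list(m = character(0))), "distinct camera")
  expect_error(method_map(list(a = "A", a = "B")), "duplicate")
})

test_that("z-scoring standardizes with the n-1 denominator and keeps a scaler", {
  ct <- covariate_table(data.frame(site = 1:3, DistAve = c(100, 200, 300)))
  z <- zscore_covariates(ct, "DistAve")
  expect_equal(z$site$DistAve, c(-1, 0, 1))  # sample sd = 100
  expect_equal(mean(z$site$DistAve), 0)
  expect_equal(sd(z$site$DistAve), 1)
  sc <- attr(z, "scaler")
  expect_equal(sc$mean, 200)
  expect_equal(sc$sd, 100)

  # scaler reuse applies the training transform to new data
  ct2 <- covariate_table(data.frame(site = 1:2, DistAve = c(200, 400)))
  z2 <- zscore_covariates(ct2, "DistAve", scaler = sc)
  expect_equal(z2$site$DistAve, c(0, 2))

  # idempotence on already-standardized input
  z3 <- zscore_covariates(z, "DistAve")
  expect_equal(z3$site$DistAve, z$site$DistAve, tolerance = 1e-12)

  # constant column is rejected
  ct4 <- covariate_table(data.frame(site = 1:3, DistAve = c(5, 5, 5)))
  expect_error(zscore_covariates(ct4, "DistAve"), "constant")
})

test_that("naive summaries count cameras, nights and trap-nights", {
  d0 <- detection_array(array(0, c(2, 5, 10)))
  expect_equal(unlist(naive_summaries(d0)),
               c(cameras_with_detection = 0, nights_with_detection = 0,
                 active_trap_nights = 100))
  obs <- array(0, c(2, 5, 10))
  obs[1, 2, c(1, 4, 7)] <- 1
  expect_equal(naive_summaries(detection_array(obs))$cameras_with_detection, 1)
  expect_equal(naive_summaries(detection_array(obs))$nights_with_detection, 3)
  obs[2, 3, 1:4] <- NA
  expect_equal(naive_summaries(detection_array(obs))$active_trap_nights, 96)
})

test_that("covariate CSV reading splits site and method blocks", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site,method,Area,Access,DistAve",
               "s1,,SL,RD,NA",
               "s2,,TN,SM,NA",
               "s1,m1,NA,NA,50",
               "s2,m1,NA,NA,150"), f)
  ct <- read_covariates(f)
  expect_equal(nrow(ct$site), 2)
  expect_equal(levels(ct$site$Area), c("SL", "TN"))
  expect_equal(ct$site_method$DistAve, c(50, 150))
})
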