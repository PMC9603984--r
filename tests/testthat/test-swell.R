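test_that("an exact line is fitted exactly", {
  tr <- make_track(0:2, c(100, 112, 124))
  fit <- fit_swell(tr, n_frames_total = 3)
  f <- fit$fits
  expect_equal(f$slope, 12)
  expect_equal(f$intercept, 100)
  expect_equal(f$slope_se, 0)
  expect_equal(coef(fit), c("1" = 12))
  expect_equal(unname(predict(fit, data.frame(track_id = 1, frame = 5))), 160)
  expect_equal(residuals(fit), rep(0, 3))
})

test_that("slope and SE agree with lm on noisy tracks", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(c(5, 8, 13), 1)
    f <- sort(sample(0:12, n))
    a <- 200 + 3.5 * f + rnorm(n, 0, 5)
    got <- ols_slope(f, a)
    m <- summary(lm(a ~ f))$coefficients
    expect_equal(unname(got["slope"]), m["f", "Estimate"], tolerance = 1e-10)
    expect_equal(unname(got["slope_se"]), m["f", "Std. Error"], tolerance = 1e-10)
    expect_equal(unname(got["intercept"]), m["(Intercept)", "Estimate"], tolerance = 1e-10)
  }
})

test_that("degenerate tracks are handled: one point errors, two points have no SE", {
  expect_error(ols_slope(0, 100), "at least 2")
  expect_error(ols_slope(c(2, 2), c(5, 9)), "at least 2")
  two <- ols_slope(c(0, 1), c(10, 14))
  expect_equal(unname(two["slope"]), 4)
  expect_equal(unname(two["slope_se"]), Inf)
  # in a 3-frame acquisition a 2-point fit passes the frame rule (ceil(8*3/13)=2)
  # but its undefined SE excludes it
  fit <- fit_swell(make_track(c(0, 1), c(10, 14)), n_frames_total = 3)
  expect_equal(fit$fits$qc_status, "excluded_se")
})

test_that("slope is invariant to a uniform area offset", {
  set.seed(5)
  f <- 0:12
  a <- 150 + 2 * f + rnorm(13, 0, 4)
  s1 <- ols_slope(f, a)
  s2 <- ols_slope(f, a + 1234.5)
  expect_equal(s1["slope"], s2["slope"], tolerance = 1e-10)
  expect_equal(s1["slope_se"], s2["slope_se"], tolerance = 1e-10)
})

test_that("QC boundaries follow the 8-of-13 and SE > 2.5 rules exactly", {
  fits <- data.frame(n_frames_observed = c(7, 8, 13, 8, 13, 2),
                     slope_se = c(0.1, 2.5, 2.6, 2.5 + 1e-9, 0, Inf))
  expect_equal(apply_qc(fits, n_frames_total = 13),
               c("excluded_frames",  # 7 of 13
                 "included",         # SE exactly 2.5 is kept (strict >)
                 "excluded_se",      # 2.6
                 "excluded_se",      # epsilon above the cutoff
                 "included",
                 "excluded_frames")) # frame rule checked before the SE rule
  # frame rule scales with acquisition length: ceil(8*26/13) = 16
  fits2 <- data.frame(n_frames_observed = c(15, 16), slope_se = c(0, 0))
  expect_equal(apply_qc(fits2, n_frames_total = 26), c("excluded_frames", "included"))
  # frame rule takes precedence even when the SE also fails
  expect_equal(apply_qc(data.frame(n_frames_observed = 3, slope_se = 99)),
               "excluded_frames")
})

test_that("well aggregation averages included organoids only", {
  fits <- data.frame(
    track_id = 1:5,
    plate_id = "P1",
    well = c("A01", "A01", "A01", "A02", "A02"),
    slope = c(10, 14, 50, 7, 9),
    qc_status = c("included", "included", "excluded_se", "excluded_frames", "excluded_se"))
  w <- aggregate_wells(fits)
  expect_equal(w$mean_swell_rate[w$well == "A01"], 12)
  expect_equal(w$n_included[w$well == "A01"], 2)
  expect_true(is.na(w$mean_swell_rate[w$well == "A02"]))
  expect_true(w$missing[w$well == "A02"])
  expect_equal(w$n_total, w$n_included + w$n_excluded_frames + w$n_excluded_se)
})

test_that("fitted slopes recover truth with SE-consistent spread", {
  # parameter recovery at moderate replication; the large-n version lives in
  # the acceptance suite
  set.seed(41)
  beta <- 3; sigma <- 5; nrep <- 2000
  f <- 0:12
  sxx <- sum((f - mean(f))^2)
  slopes <- replicate(nrep, ols_slope(f, 100 + beta * f + rnorm(13, 0, sigma))["slope"])
  expect_lt(abs(mean(slopes) - beta), 4 * sigma / sqrt(sxx) / sqrt(nrep))
  expect_lt(abs(sd(slopes) / (sigma / sqrt(sxx)) - 1), 0.06)
})

test_that("swell_fit summary and plot run", {
  lay <- tiny_layout(n_compounds = 4, n_dmso = 1, n_eact = 1)
  sim <- simulate_screen(lay, sim_config(seed = 2))
  fit <- fit_swell(link_tracks(boxes_to_areas(sim$detections)))
  s <- summary(fit)
  expect_s3_class(s, "summary.swell_fit")
  expect_output(print(fit), "QC")
  expect_output(print(s), "Swell-rate")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})
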