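test_that("identical seed and config give byte-identical outputs", {
  lay <- tiny_layout(n_compounds = 8)
  a <- simulate_screen(lay, sim_config(seed = 42))
  b <- simulate_screen(lay, sim_config(seed = 42))
  expect_identical(a, b)
  c <- simulate_screen(lay, sim_config(seed = 43))
  expect_false(identical(a$detections, c$detections))
})

test_that("noise-free simulation yields complete, exactly linear tracks", {
  lay <- tiny_layout(n_compounds = 6, n_dmso = 1, n_eact = 1)
  cfg <- sim_config(seed = 3, detection_dropout_p = 0, bbox_jitter_sd = 0,
                    area_obs_noise_sd = 0)
  sim <- simulate_screen(lay, cfg)
  # every organoid detected in all 13 frames
  expect_true(all(sim$truth$organoids$n_frames_detected == 13))
  ar <- boxes_to_areas(sim$detections)
  # per (well, center) the areas lie exactly on a line in frame
  key <- paste(ar$well, round(ar$x, 6), round(ar$y, 6))
  for (ix in split(seq_len(nrow(ar)), key)) {
    expect_length(ix, 13)
    f <- ar$frame[ix]; a <- ar$area[ix]
    fit <- ols_slope(f, a)
    expect_lt(max(abs(a - fit["intercept"] - fit["slope"] * f)), 1e-8)
  }
})

test_that("noise-free pipeline recovers every true slope to float tolerance", {
  lay <- tiny_layout(n_compounds = 8, n_dmso = 2, n_eact = 2)
  cfg <- sim_config(seed = 5, detection_dropout_p = 0, bbox_jitter_sd = 0,
                    area_obs_noise_sd = 0)
  sim <- simulate_screen(lay, cfg)
  fit <- fit_swell(link_tracks(boxes_to_areas(sim$detections)))
  for (w in unique(fit$fits$well)) {
    got <- sort(fit$fits$slope[fit$fits$well == w])
    want <- sort(sim$truth$organoids$true_slope[sim$truth$organoids$well == w])
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("dropout fraction matches its binomial distribution", {
  lay <- screen_layout("P1", sprintf("C%03d", 1:80), n_dmso = 0, n_eact = 0)
  cfg <- sim_config(seed = 11, detection_dropout_p = 0.3, organoids_per_well = 20)
  sim <- simulate_screen(lay, cfg)
  n_of <- nrow(sim$truth$frames)              # organoid-frames simulated
  expect_gt(n_of, 1e4)
  dropped <- mean(!sim$truth$frames$detected)
  se <- sqrt(0.3 * 0.7 / n_of)
  expect_lt(abs(dropped - 0.3), 3 * se)
  # detections table agrees with the truth flags
  expect_equal(nrow(sim$detections), sum(sim$truth$frames$detected))
})

test_that("per-well random streams are independent of other wells", {
  # the larger layout extends the smaller one without touching its wells'
  # conditions, so the shared wells' draws must be bit-identical
  lay_small <- tiny_layout(n_compounds = 4, n_dmso = 1, n_eact = 1)
  extra <- validate_layout(data.frame(
    plate_id = "P1", well = c("B01", "B02", "B03"),
    role = c("compound", "dmso", "eact"),
    compound_1 = c("X1", NA, NA), compound_2 = c("X2", NA, NA)))
  lay_big <- validate_layout(rbind(as.data.frame(lay_small), as.data.frame(extra)))
  a <- simulate_screen(lay_small, sim_config(seed = 9))
  b <- simulate_screen(lay_big, sim_config(seed = 9))
  shared <- unique(a$detections$well)
  expect_identical(a$detections,
                   b$detections[b$detections$well %in% shared, ])
})

test_that("invalid configuration errors name the offending field", {
  expect_error(sim_config(detection_dropout_p = 1.5), "detection_dropout_p")
  expect_error(sim_config(n_frames = 1), "n_frames")
  expect_error(sim_config(plate_scale = -2), "plate_scale")
  expect_error(sim_config(area_obs_noise_sd = -1), "area_obs_noise_sd")
})

test_that("simulated traces honour their construction", {
  # clean isc step of +5 uA
  tr <- simulate_trace("isc", duration = 600, interval = 10, event_time = 300,
                       amplitude = 5, baseline = 10, noise_sd = 0)
  expect_equal(unique(tr$value[tr$time_s <= 300]), 10)
  expect_equal(unique(tr$value[tr$time_s > 300]), 15)
  # yfp with no decay is constant
  flat <- simulate_trace("yfp", duration = 12, interval = 0.5, event_time = 2,
                         segments = data.frame(duration = Inf, slope = 0), noise_sd = 0)
  expect_equal(unique(flat$value), 1)
  # two linear segments: steepest is the second
  seg <- simulate_trace("yfp", duration = 60, interval = 1, event_time = 10,
                        segments = data.frame(duration = c(20, Inf), slope = c(-0.01, -0.08)),
                        noise_sd = 0)
  qr <- quench_rate(seg, injection_time = 10, window = 5)
  expect_equal(as.numeric(qr), 0.08, tolerance = 1e-10)
  # event outside the trace
  expect_error(simulate_trace("isc", duration = 100, event_time = 200), "outside")
})
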