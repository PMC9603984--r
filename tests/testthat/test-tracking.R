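test_that("well-separated stationary organoids are tracked unambiguously", {
  obs <- data.frame(plate_id = "P1", well = "A01",
                    frame = rep(0:2, each = 2),
                    x = rep(c(100, 300), 3), y = rep(c(100, 100), 3),
                    area = 50 + rep(0:2, each = 2))
  tr <- link_tracks(obs, max_displacement = 50, memory = 0)
  expect_equal(length(unique(tr$track_id)), 2)
  expect_true(all(table(tr$track_id) == 3))
  # every observation lands in exactly one track
  expect_equal(nrow(tr), nrow(obs))
})

test_that("a gap within memory keeps the track; beyond memory it splits", {
  obs <- data.frame(plate_id = "P1", well = "A01", frame = setdiff(0:12, 5),
                    x = 100, y = 100, area = 100 + setdiff(0:12, 5))
  tr <- link_tracks(obs, max_displacement = 30, memory = 1)
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(sort(tr$frame), setdiff(0:12, 5))

  obs2 <- data.frame(plate_id = "P1", well = "A01", frame = c(0:2, 8:10),
                     x = 100, y = 100, area = 100)
  # duplicate centers across frames are fine; gap of 5 > memory 2 splits
  tr2 <- link_tracks(obs2, max_displacement = 30, memory = 2)
  expect_equal(length(unique(tr2$track_id)), 2)
  tr3 <- link_tracks(obs2, max_displacement = 30, memory = 5)
  expect_equal(length(unique(tr3$track_id)), 1)
})

test_that("track partition is invariant to input row order with canonical ids", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(3:6, 1)
    base <- data.frame(x = runif(n, 0, 400), y = runif(n, 0, 400))
    obs <- do.call(rbind, lapply(0:5, function(f)
      data.frame(plate_id = "P1", well = "A01", frame = f,
                 x = base$x + rnorm(n, 0, 3), y = base$y + rnorm(n, 0, 3),
                 area = 100 + f * 5 + seq_len(n))))
    tr1 <- link_tracks(obs, max_displacement = 20, memory = 2)
    shuffled <- obs[sample(nrow(obs)), ]
    tr2 <- link_tracks(shuffled, max_displacement = 20, memory = 2)
    expect_identical(partition_signature(tr1), partition_signature(tr2))
    expect_equal(as.data.frame(tr1)[order(tr1$track_id, tr1$frame), ],
                 as.data.frame(tr2)[order(tr2$track_id, tr2$frame), ],
                 ignore_attr = TRUE)
  }
})

test_that("frame-pair assignment equals the brute-force minimum-cost matching", {
  set.seed(11)
  for (rep in 1:60) {
    n <- sample(2:6, 1)
    p0 <- cbind(runif(n, 0, 300), runif(n, 0, 300))
    p1 <- p0[sample(n), ] + matrix(rnorm(2 * n, 0, 8), n)
    d <- sqrt(outer(p0[, 1], p1[, 1], "-")^2 + outer(p0[, 2], p1[, 2], "-")^2)
    ok <- matrix(TRUE, n, n)
    got <- orgaswell:::.assign(d, ok, nomatch_cost = 1e6)
    want <- bf_perm_match(d)
    expect_equal(got, as.integer(want))
  }
})

test_that("gated assignment matches brute-force partial matching", {
  set.seed(13)
  for (rep in 1:40) {
    nt <- sample(2:4, 1); no <- sample(2:4, 1)
    d <- matrix(runif(nt * no, 0, 100), nt)
    gate <- 40
    ok <- d <= gate
    got <- orgaswell:::.assign(d, ok, nomatch_cost = gate)
    want <- bf_partial_match(d, ok, nomatch = gate)
    # matchings may differ only if costs tie (prob. 0 here): compare pairings
    expect_equal(got, want)
  }
})

test_that("duplicate (frame, center) observations raise a data error", {
  obs <- data.frame(plate_id = "P1", well = "A01", frame = c(0, 0),
                    x = c(10, 10), y = c(20, 20), area = c(5, 6))
  expect_error(link_tracks(obs), "duplicate")
})

test_that("noise-free synthetic wells are tracked to ground-truth identities", {
  lay <- tiny_layout(n_compounds = 6, n_dmso = 1, n_eact = 1)
  cfg <- sim_config(seed = 17, detection_dropout_p = 0, bbox_jitter_sd = 0,
                    area_obs_noise_sd = 0)
  sim <- simulate_screen(lay, cfg)
  tr <- link_tracks(boxes_to_areas(sim$detections))
  org <- sim$truth$organoids
  expect_equal(length(unique(tr$track_id)), nrow(org))
  for (id in unique(tr$track_id)) {
    tk <- tr[tr$track_id == id, ]
    expect_equal(nrow(tk), 13)                        # complete
    expect_lt(max(abs(tk$x - mean(tk$x))), 1e-9)      # one center (to rounding)
    i <- which(org$well == tk$well[1] & abs(org$x - tk$x[1]) < 1e-6 &
               abs(org$y - tk$y[1]) < 1e-6)
    expect_length(i, 1)                    # exactly one true organoid
  }
})
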