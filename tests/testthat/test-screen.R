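# a layout with n compound wells (single compounds for simplicity) + controls
flat_layout <- function(n, plate_id = "P1", n_dmso = 2, n_eact = 2) {
  screen_layout(plate_id, sprintf("C%03d", seq_len(n)), pooled = FALSE,
                n_dmso = n_dmso, n_eact = n_eact)
}

wells_of <- function(layout, rates) {
  data.frame(plate_id = layout$plate_id, well = layout$well,
             mean_swell_rate = rates, stringsAsFactors = FALSE)
}

test_that("plate normalization centres the median at 0 and median+IQR at 1", {
  lay <- flat_layout(9)
  w <- wells_of(lay, c(1:9, 0, 0, 20, 20))  # compounds 1..9; dmso 0,0; eact 20,20
  nm <- normalize_plate(w, lay)
  # reference set: the 9 compound wells; median 5, IQR 4 (type-7 quantiles)
  expect_equal(nm$norm_rate[nm$raw_rate == 5 & nm$role == "compound"], 0)
  expect_equal(nm$norm_rate[nm$raw_rate == 9], 1.0)
  # controls are normalized against the compound reference
  expect_equal(nm$norm_rate[nm$role == "eact"], c(3.75, 3.75))
  # control policy "all" changes the reference set
  nm2 <- normalize_plate(w, lay, control_policy = "all")
  expect_false(isTRUE(all.equal(nm$norm_rate[1], nm2$norm_rate[1])))
})

test_that("degenerate and undersized plates are rejected by name", {
  lay <- flat_layout(6)
  expect_error(normalize_plate(wells_of(lay, rep(2, 10)), lay), "degenerate plate P1")
  lay3 <- flat_layout(3)
  expect_error(normalize_plate(wells_of(lay3, c(1, 2, 3, 0, 0, 9, 9)), lay3),
               "at least 4")
})

test_that("normalization is location and scale equivariant", {
  set.seed(19)
  lay <- flat_layout(24)
  for (rep in 1:30) {
    rates <- rnorm(nrow(lay), 5, 2)
    w <- wells_of(lay, rates)
    base <- normalize_plate(w, lay)$norm_rate
    shift <- runif(1, -50, 50); scale <- runif(1, 0.1, 10)
    w2 <- wells_of(lay, rates * scale + shift)
    expect_equal(normalize_plate(w2, lay)$norm_rate, base, tolerance = 1e-9)
  }
})

test_that("compound averaging pools wells across plates and is order-invariant", {
  lay <- validate_layout(rbind(flat_layout(4, "P1"), flat_layout(4, "P2")))
  nm <- data.frame(plate_id = rep(c("P1", "P2"), each = 4),
                   well = rep(c("A01", "A02", "A03", "A04"), 2),
                   role = "compound",
                   raw_rate = 0,
                   norm_rate = c(0.5, 0, 1, 2, 1.5, 0.2, -1, 2.2))
  tab <- average_conditions(nm, lay)
  expect_equal(tab$mean_norm_rate[tab$compound == "C001"], 1.0)  # (0.5 + 1.5)/2
  expect_equal(tab$n_measurements[tab$compound == "C001"], 2)
  tab2 <- average_conditions(nm[sample(nrow(nm)), ], lay)
  expect_equal(tab, tab2, ignore_attr = TRUE)
  # pooled wells attribute their rate to both compounds
  layp <- tiny_layout(n_compounds = 8)  # 4 pooled wells
  nmp <- data.frame(plate_id = "P1", well = layp$well[layp$role == "compound"],
                    role = "compound", raw_rate = 0, norm_rate = c(2, 0, 0, 0))
  tabp <- average_conditions(nmp, layp)
  expect_equal(tabp$mean_norm_rate[tabp$compound %in% c("C001", "C002")], c(2, 2))
})

test_that("hit calling is strictly greater-than the threshold", {
  tab <- data.frame(compound = c("a", "b", "c"),
                    mean_norm_rate = c(1.01, 1.00, 0.2))
  h <- call_hits(tab)
  expect_equal(h$hit, c(TRUE, FALSE, FALSE))
  same <- call_hits(data.frame(compound = letters[1:5], mean_norm_rate = rep(0.7, 5)))
  expect_equal(sum(same$hit), 0)
})

test_that("pooled hit wells deconvolve with set semantics", {
  # 45 distinct-compound hit wells yield 90 compounds
  lay <- screen_layout("P1", sprintf("C%03d", 1:90), n_dmso = 8, n_eact = 8)
  hw <- data.frame(plate_id = "P1", well = lay$well[lay$role == "compound"])
  expect_equal(nrow(hw), 45)
  expect_length(deconvolve_pairs(hw, lay), 90)
  # one hit well gives its two compounds
  expect_equal(deconvolve_pairs(hw[1, ], lay), c("C001", "C002"))
  # a compound shared by two hit wells appears once
  lay2 <- validate_layout(data.frame(
    plate_id = "P1", well = c("A01", "A02"), role = "compound",
    compound_1 = c("X", "X"), compound_2 = c("Y", "Z")))
  expect_equal(deconvolve_pairs(data.frame(plate_id = "P1", well = c("A01", "A02")), lay2),
               c("X", "Y", "Z"))
  # hit well missing from the layout
  expect_error(deconvolve_pairs(data.frame(plate_id = "P1", well = "Z99"), lay),
               "missing from layout")
})

test_that("screen_organoids drops degenerate plates and reports lost compounds", {
  lay <- validate_layout(rbind(flat_layout(8, "P1"), flat_layout(8, "P2")))
  # P2 is degenerate (all wells identical); its compounds survive on P1 except
  # C008, which we remove from P1 scoring by making its well NA
  set.seed(3)
  w1 <- wells_of(lay[lay$plate_id == "P1", ], c(rnorm(8, 5), 5, 5, 9, 9))
  w1$mean_swell_rate[8] <- NA
  w2 <- wells_of(lay[lay$plate_id == "P2", ], rep(4, 12))
  scr <- screen_organoids(rbind(w1, w2), lay)
  expect_s3_class(scr, "organoid_screen")
  expect_equal(scr$dropped_plates, "P2")
  expect_equal(scr$dropped_compounds, "C008")
  expect_output(print(scr), "dropped plates: P2")
})

test_that("plate normalization removes simulated plate shift/scale artifacts", {
  lay1 <- tiny_layout(n_compounds = 40, plate_id = "P1", n_dmso = 3, n_eact = 3)
  lay2 <- tiny_layout(n_compounds = 40, plate_id = "P2", n_dmso = 3, n_eact = 3)
  cfg <- sim_config(seed = 23, plate_shift = c(P1 = 0, P2 = 6),
                    plate_scale = c(P1 = 1, P2 = 2.5))
  sim <- simulate_screen(validate_layout(rbind(lay1, lay2)), cfg)
  fit <- fit_swell(link_tracks(boxes_to_areas(sim$detections)))
  lay <- validate_layout(rbind(lay1, lay2))
  nm <- do.call(rbind, lapply(c("P1", "P2"), function(p)
    normalize_plate(fit$wells[fit$wells$plate_id == p, ], lay)))
  # identical true conditions on both plates: normalized compound-well
  # distributions agree despite the gross raw-scale difference
  x1 <- nm$norm_rate[nm$plate_id == "P1" & nm$role == "compound"]
  x2 <- nm$norm_rate[nm$plate_id == "P2" & nm$role == "compound"]
  r1 <- fit$wells$mean_swell_rate[fit$wells$plate_id == "P1"]
  r2 <- fit$wells$mean_swell_rate[fit$wells$plate_id == "P2"]
  expect_gt(abs(median(r2, na.rm = TRUE) - median(r1, na.rm = TRUE)), 3)  # raw rates differ
  ks <- suppressWarnings(ks.test(x1, x2))
  expect_gt(ks$p.value, 0.001)  # normalized rates agree in distribution
})
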