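test_that("default phantom contains the expected tissues and plaque size", {
  cfg <- phantom_config()
  ph <- build_phantom(cfg)
  labs <- sort(unique(as.vector(ph$labels)))
  expect_setequal(labs, unname(tissue_labels[c("air", "lung", "soft", "fat",
                                               "myocardium", "blood", "plaque")]))
  npl <- sum(ph$labels == tissue_labels[["plaque"]])
  expect_gte(npl, 1); expect_lte(npl, 4)  # 3 mm plaque on a 2 mm grid

  ph2 <- build_phantom(phantom_config(stent_enabled = TRUE))
  expect_gt(sum(ph2$labels == tissue_labels[["stent_void"]]), 0)
  expect_true(all(ph2$water[ph2$labels == tissue_labels[["stent_void"]]] == 0))
  expect_true(all(ph2$activity[ph2$labels == tissue_labels[["stent_void"]]] > 0))
})

test_that("phantom construction is deterministic and validates its config", {
  expect_identical(build_phantom(phantom_config(seed = 5L)),
                   build_phantom(phantom_config(seed = 5L)))
  expect_error(phantom_config(resp_amplitude = 200), "resp_amplitude")
  expect_error(phantom_config(plaque_to_blood_activity_ratio = 0.5),
               "plaque_to_blood_activity_ratio")
  expect_error(phantom_config(pixel_size = -1), "pixel_size")
})

test_that("deform is exact at identity and moves the diaphragm correctly", {
  cfg <- phantom_config()
  ph <- build_phantom(cfg)
  d0 <- deform(ph, 0, 0)
  expect_identical(d0$labels, ph$labels)
  expect_equal(d0$activity, ph$activity, tolerance = 1e-12)
  expect_true(is_zero_field(d0$gt))

  diaph_row <- function(lab) {
    cols <- round(0.60 * ncol(lab)):round(0.76 * ncol(lab))
    max(which(apply(lab[, cols] == tissue_labels[["lung"]], 1, any)))
  }
  d1 <- deform(ph, cfg$resp_amplitude, 0)
  shift_px <- diaph_row(d1$labels) - diaph_row(ph$labels)
  expect_equal(shift_px, cfg$resp_amplitude / cfg$pixel_size, tolerance = 1)
  expect_error(deform(ph, cfg$resp_amplitude + 5, 0), "outside")
})

test_that("deformation conserves activity and composes like the ground truth", {
  ph <- build_phantom(phantom_config())
  for (st in list(c(15, 0), c(0, 0.35), c(15, 0.35), c(7, 0.6))) {
    d <- deform(ph, st[1], st[2])
    expect_true(all(d$activity >= 0))
    expect_lt(abs(sum(d$activity) / sum(ph$activity) - 1), 0.02)
  }
  gt_r <- deform(ph, 10, 0)$gt
  gt_c <- deform(ph, 0, 0.35)$gt
  gt_rc <- deform(ph, 10, 0.35)$gt
  comp <- compose_fields(gt_r, gt_c)
  rms_px <- sqrt(mean((comp$ux - gt_rc$ux)^2 + (comp$uy - gt_rc$uy)^2)) / 2
  expect_lt(rms_px, 0.25)
})

test_that("surrogate signals have the configured physiology", {
  cfg <- phantom_config(duration = 600, mr_window = c(0, 300), seed = 21L)
  s <- generate_surrogates(cfg)
  expect_identical(s, generate_surrogates(cfg))
  n_rp <- length(s$rpeaks)
  expect_lt(abs(n_rp - 600), 3 * 0.05 * sqrt(600) + 2)
  expect_true(all(diff(s$rpeaks) > 0))
  # end-exhale (low amplitude) is the prevalent state
  expect_gt(mean(s$belt < 0.5 * cfg$resp_amplitude), 0.5)
  # belt is a lagged copy of the true displacement
  lagged <- resp_waveform(s$time - cfg$belt_lag, cfg)
  expect_gt(cor(s$belt, lagged), 0.99)
})

test_that("cardiac phase is the elapsed RR fraction with wrap-around", {
  rp <- c(1, 2, 3.2)
  expect_equal(cardiac_phase_at(1.5, rp), 0.5)
  expect_equal(cardiac_phase_at(2.3, rp), 0.25)
  expect_equal(cardiac_phase_at(0.5, rp), 0.5)   # wrapped via first RR
  expect_true(all(cardiac_phase_at(seq(0, 4, 0.1), rp) >= 0))
  expect_true(all(cardiac_phase_at(seq(0, 4, 0.1), rp) < 1))
})
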