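local_phantom_pair <- function() {
  cfg <- phantom_config()
  ph <- build_phantom(cfg)
  fixed <- waterfat_image(ph$water + 0i, ph$fat + 0i, 1, cfg$pixel_size)
  moving <- waterfat_image(shift_img(ph$water, 3, -2) + 0i,
                           shift_img(ph$fat, 3, -2) + 0i, 2, cfg$pixel_size)
  list(ph = ph, fixed = fixed, moving = moving, body = ph$labels > 0)
}

test_that("registration recovers known translations in both channels", {
  fx <- local_phantom_pair()
  px <- 2
  for (sim in c("NMI", "SSD")) {
    rr <- register_pair(fx$moving, fx$fixed, registration_config(similarity = sim))
    expect_lt(abs(mean(rr$field$ux[fx$body]) / px - (-2)), 0.5)
    expect_lt(abs(mean(rr$field$uy[fx$body]) / px - 3), 0.5)
  }
  # identity case
  r0 <- register_pair(fx$fixed, fx$fixed, registration_config())
  expect_lt(mean(sqrt(r0$field$ux^2 + r0$field$uy^2)) / px, 0.1)
})

test_that("an uninformative fat channel does not break translation recovery", {
  fx <- local_phantom_pair()
  set.seed(4)
  noise1 <- matrix(runif(128^2), 128, 128)
  noise2 <- matrix(runif(128^2), 128, 128)
  mov <- waterfat_image(fx$moving$water, noise1 + 0i, 2, 2)
  fix <- waterfat_image(fx$fixed$water, noise2 + 0i, 1, 2)
  rr <- register_pair(mov, fix, registration_config())
  expect_lt(abs(mean(rr$field$ux[fx$body]) / 2 - (-2)), 1)
  expect_lt(abs(mean(rr$field$uy[fx$body]) / 2 - 3), 1)
})

test_that("the stored cost decomposes into its weighted terms", {
  fx <- local_phantom_pair()
  rr <- register_pair(fx$moving, fx$fixed, registration_config(iterations = 20L))
  expect_equal(rr$cost,
               rr$w * rr$sim_water + (1 - rr$w) * rr$sim_fat + rr$r * rr$reg,
               tolerance = 1e-9)
})

test_that("a constant fixed channel falls back to the informative one", {
  fx <- local_phantom_pair()
  fix <- waterfat_image(fx$fixed$water, matrix(0i, 128, 128), 1, 2)
  expect_warning(rr <- register_pair(fx$moving, fix,
                                     registration_config(iterations = 30L)),
                 "constant")
  expect_equal(rr$w, 1)
})

test_that("NMI of an image with itself beats any translated copy", {
  ph <- build_phantom(phantom_config(grid_shape = c(64L, 64L)))
  img <- ph$water / max(ph$water)
  self <- nmi_neg_grad_cpp(as.vector(img), as.vector(img), 32L)$nmi
  for (sh in list(c(1, 0), c(0, 2), c(-3, 1), c(5, -5))) {
    tr <- nmi_neg_grad_cpp(as.vector(shift_img(img, sh[1], sh[2])),
                           as.vector(img), 32L)$nmi
    expect_gte(self, tr)
  }
})

test_that("registration is inverse-consistent on translations", {
  fx <- local_phantom_pair()
  cfgr <- registration_config(similarity = "SSD")
  ab <- register_pair(fx$moving, fx$fixed, cfgr)$field
  ba <- register_pair(fx$fixed, fx$moving, cfgr)$field
  rms <- sqrt(mean((ab$ux[fx$body] + ba$ux[fx$body])^2 +
                     (ab$uy[fx$body] + ba$uy[fx$body])^2)) / 2
  expect_lt(rms, 0.5)
})

test_that("select_reference picks the prevalent half-range", {
  cfg <- phantom_config()
  t <- seq(0, 60, 0.04)
  wave <- resp_waveform(t, cfg)
  expect_equal(select_reference(wave), "end_exhale")
  expect_equal(select_reference(max(wave) - wave), "end_inhale")
  expect_equal(select_reference(c(0, 1)), "end_exhale")  # tie
})

test_that("model building zeroes the reference and orders diaphragm motion", {
  cfg <- moving_config(grid = 64L, amp = 12)
  ph <- build_phantom(cfg)
  # synthetic motion-resolved series from ground-truth states
  amps <- c(0, 3, 6, 9, 12)
  series <- lapply(seq_along(amps), function(i) {
    d <- deform(ph, amps[i], 0)
    waterfat_image(d$water + 0i, d$fat + 0i, i, cfg$pixel_size)
  })
  model <- build_model(series, reference = 1L,
                       registration_config(similarity = "SSD"), "respiratory")
  expect_true(is_zero_field(model$fields[[1]]))
  # mean superior-inferior displacement in the diaphragm region is monotone
  band <- ph$labels == tissue_labels[["lung"]]
  uy <- vapply(model$fields, function(f) mean(f$uy[band]), 0)
  expect_true(all(diff(uy) > 0))
  # two identical bins give a near-zero field
  m2 <- build_model(list(series[[1]], series[[1]]), 1L,
                    registration_config(similarity = "SSD"), "respiratory")
  expect_lt(max(abs(m2$fields[[2]]$uy)), 0.5)
})

test_that("concatenation composes fields in the documented order", {
  cfg <- phantom_config(grid_shape = c(64L, 64L))
  px <- cfg$pixel_size
  zf <- zero_field(c(64, 64), px)
  tr <- function(dx, dy) displacement_field(matrix(dx, 64, 64),
                                            matrix(dy, 64, 64), px)
  resp <- motion_model(list(zf, tr(4, -2)), 1L, "respiratory")
  card0 <- motion_model(list(zf, zf), 1L, "cardiac")
  cr <- concatenate_models(resp, card0)
  expect_length(cr$fields, 4)
  expect_equal(cr$fields[[crbin_index(2, 1, 2)]]$ux[30, 30], 4)
  expect_equal(cr$fields[[crbin_index(2, 2, 2)]]$uy[30, 30], -2)
  # translations add
  card <- motion_model(list(zf, tr(-1, 3)), 1L, "cardiac")
  cr2 <- concatenate_models(resp, card)
  f <- cr2$fields[[crbin_index(2, 2, 2)]]
  expect_lt(max(abs(f$ux[10:50, 10:50] - 3)), 1e-6)
  expect_lt(max(abs(f$uy[10:50, 10:50] - 1)), 1e-6)
  # against the phantom ground truth
  ph <- build_phantom(phantom_config())
  gt_r <- deform(ph, 10, 0)$gt; gt_c <- deform(ph, 0, 0.35)$gt
  mm_r <- motion_model(list(zero_field(c(128, 128), 2), gt_r), 1L, "respiratory")
  mm_c <- motion_model(list(zero_field(c(128, 128), 2), gt_c), 1L, "cardiac")
  crg <- concatenate_models(mm_r, mm_c)
  gt_rc <- deform(ph, 10, 0.35)$gt
  f <- crg$fields[[crbin_index(2, 2, 2)]]
  rms <- sqrt(mean((f$ux - gt_rc$ux)^2 + (f$uy - gt_rc$uy)^2)) / 2
  expect_lt(rms, 0.5)
})

test_that("belt alignment finds a constructed delay", {
  cfg <- phantom_config(duration = 300, mr_window = c(0, 300), belt_lag = 0,
                        belt_noise_sd = 0, selfnav_noise_sd = 0)
  s <- generate_surrogates(cfg)
  expect_equal(align_belt(s$time, s$belt, s$belt), 0)
  nav <- interp_trace(s$time, s$belt, s$time - 0.4)  # nav = belt delayed 0.4 s
  sh <- align_belt(s$time, s$belt, nav, max_shift = 2)
  expect_lt(abs(sh - 0.4), 0.05)
  expect_lt(abs(sh), cfg$resp_period)
  expect_error(align_belt(s$time, s$belt, nav, max_shift = 200), "half")
})

test_that("the extension mapper is consistent inside the MR window and clamps", {
  cfg <- moving_config()
  ph <- build_phantom(cfg)
  s <- generate_surrogates(cfg)
  mrc <- mr_sequence_config(spokes_total = 600L, samples_per_spoke = 64L,
                            spoke_interval = 0.19)
  traj <- make_trajectory(mrc, c(0, 120), cfg$pixel_size)
  ks <- simulate_acquisition(ph, s, mrc, traj)
  bn <- bin_kspace(ks, s, binning_spec(6, 12), "respiratory")
  map <- extend_mapper(bn$thresholds, s, traj$times, shift = 0, n_card = 12L)
  expect_equal(map$resp_bin, bn$bin_of)
  # above-threshold amplitudes land in the last bin
  s2 <- s; s2$belt <- s$belt
  hi <- extend_mapper(bn$thresholds, s2, traj$times[1], shift = 0)
  expect_true(hi$resp_bin[1] >= 1)
  # stationary statistics: occupancy outside the window matches inside
  inside <- table(factor(map$resp_bin, levels = 1:6)) / length(map$resp_bin)
  t_out <- seq(130, 235, by = 0.05)
  out <- extend_mapper(bn$thresholds, s, t_out, shift = 0, n_card = 12L)
  outside <- table(factor(out$resp_bin, levels = 1:6)) / nrow(out)
  expect_true(all(abs(outside - inside) < 0.1))
})
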