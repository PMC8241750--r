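test_that("golden-angle trajectory follows its conventions", {
  mrc <- mr_sequence_config(spokes_total = 10L, samples_per_spoke = 32L)
  traj <- make_trajectory(mrc, c(5, 20), 2)
  dang <- (traj$angles[2] - traj$angles[1]) %% pi
  expect_equal(dang, pi * (3 - sqrt(5)), tolerance = 1e-12)
  expect_equal(traj$times[1], 5)
  expect_equal(diff(traj$times)[1], mrc$TR / 1000)
  expect_lte(max(abs(traj$k)), 1 / (2 * 2) + 1e-12)
  big <- mr_sequence_config(spokes_total = 10000L, samples_per_spoke = 32L)
  expect_error(make_trajectory(big, c(0, 10), 2), "overflow")
})

test_that("acquisition signal model honours the chemical-shift term", {
  fx <- static_kspace()
  ph <- fx$phantom  # water-only
  ks <- fx$ks
  mags <- vapply(ks$data, function(m) sum(Mod(m)), 0)
  expect_equal(mags[1], mags[2], tolerance = 1e-9)
  expect_equal(mags[2], mags[3], tolerance = 1e-9)

  # fat-only phantom: phase difference between echoes is 2 pi df (TE2-TE1)
  cfg <- static_config()
  phf <- build_phantom(cfg)
  phf$fat <- phf$water; phf$water <- 0 * phf$water
  ksf <- simulate_acquisition(phf, fx$surr, fx$config, fx$traj)
  i <- which(Mod(ksf$data[[1]]) > max(Mod(ksf$data[[1]])) / 10)
  dphi <- Arg(ksf$data[[2]][i] / ksf$data[[1]][i])
  expected <- (2 * pi * fx$config$delta_f * diff(fx$config$TE[1:2]) / 1000)
  expected <- ((expected + pi) %% (2 * pi)) - pi
  expect_equal(mean(dphi), expected, tolerance = 1e-6)

  # DC sample equals the spatial sum
  dc_idx <- which.min(abs(fx$traj$k))
  ce <- exp(2i * pi * fx$config$delta_f * fx$config$TE[1] / 1000)
  expect_equal(Mod(ks$data[[1]][dc_idx, 1]),
               Mod(sum(ph$water) + ce * sum(ph$fat)), tolerance = 1e-6)
})

test_that("k-space simulation is linear and deterministic", {
  fx <- static_kspace()
  cfg <- static_config()
  pha <- build_phantom(cfg); pha$fat[] <- 0
  phb <- build_phantom(cfg)
  phb$water <- 0.5 * phb$water; phb$fat <- 0.3 * phb$fat
  ksa <- simulate_acquisition(pha, fx$surr, fx$config, fx$traj)
  ksb <- simulate_acquisition(phb, fx$surr, fx$config, fx$traj)
  phc <- pha; phc$water <- pha$water + phb$water; phc$fat <- pha$fat + phb$fat
  ksc <- simulate_acquisition(phc, fx$surr, fx$config, fx$traj)
  expect_equal(ksc$data[[2]], ksa$data[[2]] + ksb$data[[2]], tolerance = 1e-9)
  expect_identical(simulate_acquisition(pha, fx$surr, fx$config, fx$traj, seed = 3L),
                   simulate_acquisition(pha, fx$surr, fx$config, fx$traj, seed = 3L))
})

test_that("binning partitions spokes as specified", {
  cfg <- moving_config()
  ph <- build_phantom(cfg)
  s <- generate_surrogates(cfg)
  mrc <- mr_sequence_config(spokes_total = 600L, samples_per_spoke = 64L,
                            spoke_interval = 0.19)
  traj <- make_trajectory(mrc, c(0, 120), cfg$pixel_size)
  ks <- simulate_acquisition(ph, s, mrc, traj)

  bn <- bin_kspace(ks, s, binning_spec(6, 12), "respiratory")
  expect_equal(sum(bn$occupancy), 600)
  expect_true(all(abs(bn$occupancy - 100) <= 1))
  expect_length(bn$thresholds, 5)

  bc <- bin_kspace(ks, s, binning_spec(6, 12), "cardiac")
  expect_equal(sum(bc$occupancy), 600)
  expect_true(all(unlist(bc$spokes) %in% seq_len(600)))
  expect_equal(sort(unlist(bc$spokes)), seq_len(600))

  # constant belt signal: a single respiratory bin takes everything
  s2 <- s; s2$belt[] <- 1
  expect_warning(bn2 <- bin_kspace(ks, s2, binning_spec(6, 12), "respiratory"),
                 "empty")
  expect_equal(sum(bn2$occupancy > 0), 1)
})

test_that("water/fat reconstruction recovers a static phantom", {
  fx <- static_kspace()
  bn <- suppressWarnings(bin_kspace(fx$ks, fx$surr, binning_spec(1, 12),
                                    "respiratory"))
  wf <- suppressWarnings(
    reconstruct_waterfat(bn, mr_recon_config(iterations = 120L, lambda = 1e-5,
                                             tol = 0))[[1]])
  expect_lt(relerr(Mod(wf$water), fx$phantom$water), 0.02)
  expect_lt(mean(Mod(wf$fat)) / mean(Mod(wf$water)), 0.02)
  expect_true(all(diff(attr(wf, "resid")) <= 1e-9))

  # identity motion model reproduces the per-bin reconstruction
  idm <- identity_model(1, dim(fx$phantom$water), 2)
  wfm <- suppressWarnings(
    reconstruct_waterfat(bn, mr_recon_config(iterations = 40L, lambda = 1e-5,
                                             tol = 0), motion = idm))
  wf40 <- suppressWarnings(
    reconstruct_waterfat(bn, mr_recon_config(iterations = 40L, lambda = 1e-5,
                                             tol = 0))[[1]])
  expect_lt(relerr(Mod(wfm$water), Mod(wf40$water)), 1e-6)
})

test_that("gridding reconstruction correlates with the true image", {
  fx <- static_kspace()
  gr <- gridding_recon(fx$ks, 1)
  expect_gt(cor(as.vector(Mod(gr)), as.vector(fx$phantom$water)), 0.95)
})

test_that("two-echo in/opposed-phase data matches the closed-form separation", {
  cfg <- phantom_config(grid_shape = c(24L, 24L), resp_amplitude = 0,
                        cardiac_contraction_fraction = 0, duration = 120,
                        mr_window = c(0, 60), plaque_diameter = 2, seed = 11L)
  ph <- build_phantom(cfg)
  s <- generate_surrogates(cfg)
  # TEs chosen so the fat phasor is exactly +1 and -1
  te1 <- 1000 / 428
  mrc <- mr_sequence_config(TE = c(te1, 1.5 * te1), spokes_total = 120L,
                            samples_per_spoke = 24L, noise_sd = 0,
                            spoke_interval = 59 / 120)
  traj <- make_trajectory(mrc, c(0, 60), cfg$pixel_size)
  ks <- simulate_acquisition(ph, s, mrc, traj)
  bn <- suppressWarnings(bin_kspace(ks, s, binning_spec(1, 12), "respiratory"))
  # run CGLS to Krylov termination; the data are consistent, so the
  # least-squares solution is the closed-form half-sum/half-difference of
  # the in-phase and opposed-phase images
  rc <- mr_recon_config(iterations = 1500L, lambda = 0, tol = 1e-13)
  wf <- suppressWarnings(reconstruct_waterfat(bn, rc)[[1]])
  u1 <- ph$water + ph$fat       # in-phase image
  u2 <- ph$water - ph$fat       # opposed-phase image
  expect_lt(relerr(Re(wf$water), (u1 + u2) / 2), 1e-6)
  expect_lt(relerr(Re(wf$fat), (u1 - u2) / 2), 1e-6)
})
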