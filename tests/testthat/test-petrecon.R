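uniform_disc_sim <- function() {
  geom <- pet_geometry(n_angles = 60L, n_radial = 64L, pixel_size = 2)
  disc <- outer(1:64, 1:64,
                function(r, c) ((r - 32.5)^2 + (c - 32.5)^2) <= 18^2) * 1
  mu <- mu_map(disc * 0.0975, 2)
  expected <- attenuation_factors(mu, geom) * project(disc, geom)
  sinos <- structure(list(counts = list(expected), expected = list(expected),
                          occupancy = 1, scatter = NULL,
                          bin_table = data.frame(bin = 1L, resp = 1L, card = 1L),
                          geometry = geom, activity_scale = 1,
                          n_resp = 1L, n_card = 1L, grid = c(64L, 64L),
                          pixel_size = 2),
                     class = "sinogram_set")
  list(disc = disc, mu = mu, sinos = sinos, geom = geom)
}

test_that("OSEM recovers a noiseless uniform disc", {
  fx <- uniform_disc_sim()
  img <- osem_avg(fx$sinos, fx$mu, osem_config(subsets = 20L, iterations = 10L,
                                               postfilter_fwhm = 0))
  inside <- fx$disc > 0
  nrmse <- sqrt(mean((img$data[inside] - 1)^2))
  expect_lt(nrmse, 0.05)
  expect_true(all(img$data >= 0))
})

test_that("doubling the counts doubles the noiseless reconstruction", {
  fx <- uniform_disc_sim()
  cfg <- osem_config(subsets = 10L, iterations = 3L, postfilter_fwhm = 0)
  img1 <- osem_avg(fx$sinos, fx$mu, cfg)
  sinos2 <- fx$sinos
  sinos2$counts <- list(2 * fx$sinos$counts[[1]])
  img2 <- osem_avg(sinos2, fx$mu, cfg)
  expect_equal(img2$data, 2 * img1$data, tolerance = 1e-6)
})

test_that("an identity motion model reduces MCIR to the AVG reconstruction", {
  cfg <- phantom_config(grid_shape = c(64L, 64L), resp_amplitude = 8,
                        duration = 300, mr_window = c(0, 150), seed = 13L)
  ph <- build_phantom(cfg)
  s <- generate_surrogates(cfg)
  thr <- stats::quantile(s$belt, c(1, 2) / 3, names = FALSE)
  sinos <- simulate_pet(ph, s, thr, n_card = 4L,
                        plan = acquisition_plan(total_counts = 3e5,
                                                duration = 300, seed = 2L))
  mu <- mu_map(ph$mu, 2)
  ocfg <- osem_config(subsets = 12L, iterations = 2L)
  avg <- osem_avg(sinos, mu, ocfg)
  idm <- identity_model(3L * 4L, c(64L, 64L), 2)
  mcir <- osem_mcir(sinos, idm, mu, ocfg)
  expect_lt(relerr(mcir$data, avg$data), 1e-6)
})

test_that("the post-filter is calibrated and conservative", {
  delta <- matrix(0, 65, 65); delta[33, 33] <- 1
  img <- pet_image(delta, "activity", "AVG", 2)
  expect_identical(postfilter(img, 0)$data, delta)
  ps <- postfilter(img, 4)
  expect_lt(abs(sum(ps$data) - 1), 1e-9)
  fit <- fit_profile((0:64) * 2, ps$data[33, ] + 1e-12)
  expect_equal(fit$D, 4, tolerance = 1)
  set.seed(5)
  rnd <- pet_image(matrix(runif(64^2), 64, 64), "activity", "AVG", 2)
  expect_lt(abs(sum(postfilter(rnd, 6)$data) - sum(rnd$data)) / sum(rnd$data),
            1e-9)
})

test_that("SUV conversion is a checked global rescale", {
  set.seed(6)
  img <- pet_image(matrix(runif(32^2), 32, 32), "activity", "AVG", 2)
  expect_equal(to_suv(img, dose = 5, weight = 5)$data, img$data)
  expect_equal(to_suv(img, dose = 2, weight = 7)$units, "SUV")
  img2 <- img; img2$data <- 2 * img$data
  expect_equal(to_suv(img2, 3, 4)$data, 2 * to_suv(img, 3, 4)$data)
  expect_error(to_suv(img, 0, 1), "dose")
  expect_error(to_suv(img, 1, -2), "weight")
  # TBR/CBR invariance
  suv <- to_suv(img, 2, 9)
  roi_p <- c(5, 12, 5, 12); roi_b <- c(20, 28, 20, 28)
  s1 <- plaque_signal(img, roi_p); b1 <- background_stats(img, roi_b)
  s2 <- plaque_signal(suv, roi_p); b2 <- background_stats(suv, roi_b)
  expect_equal(tbr_cbr(s1, b1[["b"]], b1[["sigma_b"]]),
               tbr_cbr(s2, b2[["b"]], b2[["sigma_b"]]), tolerance = 1e-12)
})
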