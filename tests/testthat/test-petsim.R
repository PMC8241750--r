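test_that("the projector respects symmetry, positivity and the zero image", {
  geom <- pet_geometry(n_angles = 24L, n_radial = 64L, pixel_size = 2)
  # smooth rotationally-symmetric blob: every angle sees the same profile
  blob <- outer(1:64, 1:64,
                function(r, c) exp(-((r - 32.5)^2 + (c - 32.5)^2) / (2 * 8^2)))
  sino <- project(blob, geom)
  mp <- rowMeans(sino)
  dev <- apply(sino, 2, function(col) sqrt(sum((col - mp)^2)) / sqrt(sum(mp^2)))
  # per-angle profiles differ only by the sub-pixel interpolation blur of
  # the pixel-driven projector
  expect_lt(max(dev), 0.08)
  expect_true(all(project(matrix(0, 64, 64), geom) == 0))
  expect_error(project(matrix(-1, 4, 4), pet_geometry(4L, 8L, 2)), "negative")
})

test_that("attenuation factors follow the analytic chord formula", {
  geom <- pet_geometry(n_angles = 12L, n_radial = 64L, pixel_size = 2)
  muv <- 0.0975
  R_px <- 15
  disc <- outer(1:64, 1:64,
                function(r, c) ((r - 32.5)^2 + (c - 32.5)^2) <= R_px^2) * muv
  mu <- mu_map(disc, 2)
  af <- attenuation_factors(mu, geom)
  expect_true(all(af > 0 & af <= 1))
  expect_true(all(attenuation_factors(mu_map(disc * 0, 2), geom) == 1))
  # central ray: chord 2R -> exp(-mu * 2R), R in cm
  centre <- af[32, 1]  # detector bin at t ~ -0.5 px of centre
  chord_cm <- 2 * sqrt(R_px^2 - 0.25) * 2 / 10
  expect_equal(-log(centre), muv * chord_cm, tolerance = 0.05)
  # monotone in mu
  af2 <- attenuation_factors(mu_map(disc * 2, 2), geom)
  expect_true(all(af2 <= af + 1e-12))
})

local_sim <- function(amp = 0, counts = 2e5, sf = 0, seed = 1L,
                      contraction = 0.12) {
  cfg <- phantom_config(grid_shape = c(64L, 64L), resp_amplitude = amp,
                        cardiac_contraction_fraction = contraction,
                        duration = 300, mr_window = c(0, 150), seed = 13L)
  ph <- build_phantom(cfg)
  s <- generate_surrogates(cfg)
  thr <- stats::quantile(s$belt, c(1, 2) / 3, names = FALSE)
  sinos <- simulate_pet(ph, s, thr, n_card = 4L,
                        plan = acquisition_plan(total_counts = counts,
                                                duration = 300,
                                                scatter_fraction = sf,
                                                seed = seed))
  list(ph = ph, s = s, thr = thr, sinos = sinos)
}

test_that("simulated counts follow the plan", {
  fx <- local_sim(amp = 10, counts = 2e5)
  tot <- sum(vapply(fx$sinos$counts, sum, 0))
  expect_lt(abs(tot - 2e5), 4 * sqrt(2e5))
  expect_equal(sum(fx$sinos$occupancy), 1, tolerance = 1e-12)
  # zero activity gives zero counts
  ph0 <- fx$ph; ph0$activity[] <- 0
  s0 <- simulate_pet(ph0, fx$s, fx$thr, n_card = 4L,
                     plan = acquisition_plan(total_counts = 1e4,
                                             duration = 300))
  expect_equal(sum(vapply(s0$counts, sum, 0)), 0)
})

test_that("a static phantom yields occupancy-proportional expected sinograms", {
  fx <- local_sim(amp = 0, contraction = 0)
  norm <- lapply(seq_along(fx$sinos$expected),
                 function(i) fx$sinos$expected[[i]] / fx$sinos$occupancy[i])
  for (i in seq_along(norm)[-1])
    expect_equal(norm[[i]], norm[[1]], tolerance = 1e-9)
})

test_that("counts are Poisson around the expected sinogram", {
  fx0 <- local_sim(amp = 10)
  set.seed(17)
  probe <- cbind(sample(nrow(fx0$sinos$expected[[1]]), 10, replace = TRUE),
                 sample(ncol(fx0$sinos$expected[[1]]), 10, replace = TRUE))
  nrep <- 20
  lam <- fx0$sinos$expected[[1]][probe]
  acc <- matrix(0, nrep, 10)
  for (r in seq_len(nrep)) {
    fx <- local_sim(amp = 10, seed = 100L + r)
    acc[r, ] <- fx$sinos$counts[[1]][probe]
  }
  se <- sqrt(lam / nrep)
  keep <- lam > 0
  expect_true(all(abs(colMeans(acc)[keep] - lam[keep]) <= 3 * se[keep] + 1e-9))
})

test_that("occupancies reproduce the belt histogram through the thresholds", {
  fx <- local_sim(amp = 10)
  t <- seq(0, 300, by = 0.25)
  map <- extend_mapper(fx$thr, fx$s, t, shift = 0, n_card = 4L)
  occ_resp <- tapply(fx$sinos$occupancy,
                     fx$sinos$bin_table$resp, sum)
  hist_resp <- table(factor(map$resp_bin, levels = 1:3)) / nrow(map)
  expect_equal(as.numeric(occ_resp), as.numeric(hist_resp), tolerance = 1e-9)
})
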