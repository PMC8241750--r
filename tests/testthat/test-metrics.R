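test_that("plaque signal applies the exhaustive Otsu rule on the 5x5 patch", {
  img <- matrix(1, 20, 20)
  img[8:12, 8:12] <- 1
  img[10, 10] <- 4; img[10, 11] <- 4; img[9, 10] <- 4; img[11, 10] <- 4
  img[10, 9] <- 4
  pet <- pet_image(img, "SUV", "AVG", 2)
  # patch holds 5 pixels at 4.0 and 20 at 1.0: Otsu splits at the gap
  expect_equal(plaque_signal(pet, c(6, 14, 6, 14)), 4.0)
  # constant patch: mean rule
  flat <- pet_image(matrix(2.5, 20, 20), "SUV", "AVG", 2)
  expect_equal(plaque_signal(flat, c(6, 14, 6, 14)), 2.5)
  # argmax on the image border clips the patch with a warning
  img2 <- matrix(1, 20, 20); img2[1, 1] <- 9
  pet2 <- pet_image(img2, "SUV", "AVG", 2)
  expect_warning(s <- plaque_signal(pet2, c(1, 5, 1, 5)), "clipped")
  expect_equal(s, 9)
  expect_error(plaque_signal(pet, c(0, 5, 1, 5)), "bounds")
})

test_that("background statistics use the sample SD", {
  img <- matrix(0, 10, 10)
  img[2, 2] <- 1; img[2, 3] <- 3
  pet <- pet_image(img, "SUV", "AVG", 2)
  bs <- background_stats(pet, c(2, 2, 2, 3))
  expect_equal(bs[["b"]], 2)
  expect_equal(bs[["sigma_b"]], sqrt(2))
  flat <- background_stats(pet_image(matrix(4, 5, 5), "SUV", "AVG", 2),
                           c(1, 3, 1, 3))
  expect_equal(unname(flat), c(4, 0))
  expect_error(roi_spec(c(1, 5, 1, 5), c(3, 8, 2, 6)), "disjoint")
})

test_that("TBR and CBR follow their definitions", {
  expect_equal(unname(tbr_cbr(2, 2, 0.5)), c(1, 0))
  expect_equal(tbr_cbr(3.1 * 1.3, 1.3, 0.4)[["TBR"]], 3.1)
  expect_equal(tbr_cbr(5, 2, 0.5)[["CBR"]], 6)
  expect_error(tbr_cbr(1, 0, 1), "background mean")
  expect_error(tbr_cbr(1, 1, 0), "SD")
})

test_that("profile fitting recovers generator parameters", {
  x <- seq(0, 30, length.out = 61)
  y <- 2.5 * exp(-(x - 14)^2 / (2 * 2^2)) + 0 * x + 0.5
  fit <- fit_profile(x, y)
  expect_equal(fit$c, 2, tolerance = 0.01)
  expect_equal(fit$D, 2 * sqrt(2 * log(2)) * 2, tolerance = 0.01)
  expect_equal(fit$e, 0.5, tolerance = 0.02)
  # amplitude rescale leaves D unchanged
  fit10 <- fit_profile(x, 10 * y)
  expect_equal(fit10$D, fit$D, tolerance = 1e-6)
  # pure line: fitted Gaussian amplitude is negligible
  yl <- 0.3 * x + 1
  fitl <- suppressWarnings(fit_profile(x, yl))
  expect_lt(fitl$a, 0.01 * diff(range(yl)))
  # strict single-square-exponent mode keeps its own FWHM identity
  ys <- 2 * exp(-(x - 12)^2 / 3^2) + 0.2
  fs <- fit_profile(x, ys, gaussian = "strict")
  expect_equal(fs$D, 2 * sqrt(log(2)) * 3, tolerance = 0.01)
  expect_error(fit_profile(1:5, 1:5), "8 samples")
})

test_that("measure_plaque is the identity-safe view average", {
  set.seed(8)
  base <- matrix(0.5 + runif(64^2, 0, 0.05), 64, 64)
  base[30:34, 30:34] <- base[30:34, 30:34] + 2 * exp(-as.matrix(dist(expand.grid(1:5, 1:5)))[13, ])
  img <- pet_image(base, "SUV", "AVG", 2)
  roi <- roi_spec(c(26, 38, 26, 38), c(5, 15, 5, 15),
                  profile = list(p0 = c(62, 40), p1 = c(62, 86), n = 41L))
  row <- measure_plaque(img, img, roi)
  expect_equal(row$TBR_ratio, 0)
  expect_equal(row$CBR_ratio, 0)
  expect_equal(row$FWHM_ratio, 0)
  expect_equal(row$TBR_stat, row$TBR_dual)
  # single view: the average is that view
  s <- plaque_signal(img, roi$plaque)
  bg <- background_stats(img, roi$background)
  expect_equal(row$TBR_stat, unname(tbr_cbr(s, bg[["b"]], bg[["sigma_b"]])[["TBR"]]))
})

test_that("the exact Wilcoxon test equals sign-pattern enumeration", {
  brute <- function(d) {
    d <- d[d != 0]
    r <- rank(abs(d)); n <- length(d)
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    ws <- signs %*% r
    w <- sum(r[d > 0])
    min(1, 2 * min(mean(ws <= w), mean(ws >= w)))
  }
  set.seed(10)
  for (n in c(6, 8, 10, 12)) {
    d <- round(rnorm(n), 2)
    expect_equal(wilcoxon_signed_rank(d)$p.value, brute(d), tolerance = 1e-12)
  }
  # with ties
  d <- c(1, -1, 2, -2, 3, 3, 4, -5, 2)
  expect_equal(wilcoxon_signed_rank(d)$p.value, brute(d), tolerance = 1e-12)
  # antisymmetric differences: statistic is at the null centre
  d <- c(0.3, -0.3, 0.7, -0.7, 1.1, -1.1)
  expect_equal(wilcoxon_signed_rank(d)$p.value, 1)
  expect_error(wilcoxon_signed_rank(rep(0, 6)), "zero")
  # agreement with the independent base-R implementation (no ties)
  set.seed(11)
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(wilcoxon_signed_rank(x, y)$p.value,
               wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("study summaries reproduce the reference table conventions", {
  tb <- plaque_study_table()
  expect_equal(nrow(tb), 10)
  # ratios are integer percents of the printed values
  expect_true(all(tb$TBR_ratio == round(tb$TBR_ratio)))
  ss <- summarize_study(tb)
  expect_equal(unname(ss$mean["TBR_stat"]), 1.67)
  expect_equal(unname(ss$sd["TBR_stat"]), 0.63)
  expect_equal(unname(ss$mean["FWHM_ratio"]), -22.60)
  expect_error(summarize_study(tb[1, ]), "2 rows")
})
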