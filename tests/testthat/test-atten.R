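phantom_wf <- function(cfg = phantom_config()) {
  ph <- build_phantom(cfg)
  list(ph = ph,
       wf = waterfat_image(ph$water + 0i, ph$fat + 0i, "reference",
                           cfg$pixel_size))
}

test_that("k-means segmentation recovers the phantom tissue classes", {
  fx <- phantom_wf()
  tcm <- segment_tissues(fx$wf)
  truth <- fx$ph$labels
  expected <- ifelse(truth == tissue_labels[["air"]], ac_classes[["air"]],
              ifelse(truth == tissue_labels[["lung"]], ac_classes[["lung"]],
              ifelse(truth == tissue_labels[["fat"]], ac_classes[["fat"]],
                     ac_classes[["soft"]])))
  expect_gte(mean(tcm$classes == expected), 0.99)
  # identification is centroid-based, hence seed-invariant
  tcm2 <- segment_tissues(fx$wf, seed = 99L)
  expect_gte(mean(tcm$classes == tcm2$classes), 0.999)
  # degenerate input
  z <- waterfat_image(matrix(0i, 16, 16), matrix(0i, 16, 16), 1, 2)
  expect_error(segment_tissues(z), "distinct")
})

test_that("stent voids are inpainted to the surrounding class, idempotently", {
  fx <- phantom_wf(phantom_config(stent_enabled = TRUE))
  tcm <- segment_tissues(fx$wf)
  stent_px <- fx$ph$labels == tissue_labels[["stent_void"]]
  # before inpainting the void segments as air (no MR signal)
  expect_true(all(tcm$classes[stent_px] == ac_classes[["air"]]))
  inp <- inpaint_stent(tcm)
  expect_true(all(inp$classes[stent_px] == ac_classes[["soft"]]))
  # mu under the stent no longer zero
  mu_b <- assign_mu(tcm); mu_a <- assign_mu(inp)
  expect_true(all(mu_b$mu[stent_px] == 0))
  expect_true(all(mu_a$mu[stent_px] > 0))
  # lungs unchanged
  lung_px <- fx$ph$labels == tissue_labels[["lung"]]
  expect_gte(mean(inp$classes[lung_px] == ac_classes[["lung"]]), 0.98)
  # idempotent; and identity when no voids exist
  expect_identical(inpaint_stent(inp)$classes, inp$classes)
  clean <- segment_tissues(phantom_wf()$wf)
  expect_identical(inpaint_stent(clean)$classes, clean$classes)
})

test_that("mu assignment honours the class table", {
  fx <- phantom_wf()
  tcm <- segment_tissues(fx$wf)
  mu <- assign_mu(tcm)
  expect_true(all(mu$mu[tcm$classes == ac_classes[["air"]]] == 0))
  expect_setequal(unique(as.vector(mu$mu)),
                  c(0, 0.0224, 0.0864, 0.0975))
  tab <- mu_assignment(air = 0, lung = 0.03, fat = 0.09, soft = 0.1)
  mu2 <- assign_mu(tcm, tab)
  expect_setequal(unique(as.vector(mu2$mu)), c(0, 0.03, 0.09, 0.1))
  expect_true(all(mu2$mu >= 0 & mu2$mu <= max(tab)))
  expect_error(mu_assignment(fat = 0.2), "ordering")
})

test_that("warped mu-maps track the deformed anatomy", {
  cfg <- phantom_config()
  ph <- build_phantom(cfg)
  tcm <- segment_tissues(phantom_wf(cfg)$wf)
  mu <- assign_mu(tcm)
  # zero field: identity
  expect_equal(warp_mu(mu, zero_field(c(128, 128), 2))$mu, mu$mu)
  # integer-pixel translation: exact shift
  tr <- displacement_field(matrix(2 * 2, 128, 128), matrix(0, 128, 128), 2)
  shifted <- warp_mu(mu, tr)$mu
  expect_equal(shifted[, 1:126], mu$mu[, 3:128], tolerance = 1e-12)
  # warp to a motion state vs segmenting that state directly: lung Dice
  st <- deform(ph, 10, 0)
  inv <- invert_field(st$gt)
  mu_warp <- warp_mu(mu, inv, bin_id = 1)
  wf_st <- waterfat_image(st$water + 0i, st$fat + 0i, 1, 2)
  tcm_st <- segment_tissues(wf_st)
  lung_w <- abs(mu_warp$mu - 0.0224) < 0.01
  lung_d <- tcm_st$classes == ac_classes[["lung"]]
  dice <- 2 * sum(lung_w & lung_d) / (sum(lung_w) + sum(lung_d))
  expect_gt(dice, 0.95)
  expect_error(warp_mu(mu, zero_field(c(64, 64), 2)), "mismatch")
})
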