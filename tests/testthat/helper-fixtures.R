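# Shared fixtures. Heavier objects are memoised so several test files can
# reuse them without recomputation.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, fn) {
  if (!exists(name, envir = .fixtures)) assign(name, fn(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# small static phantom (no motion) with matching surrogates
static_config <- function(grid = 64L) {
  phantom_config(grid_shape = c(grid, grid), resp_amplitude = 0,
                 cardiac_contraction_fraction = 0, duration = 120,
                 mr_window = c(0, 60), seed = 11L)
}

moving_config <- function(grid = 64L, amp = 10) {
  phantom_config(grid_shape = c(grid, grid), resp_amplitude = amp,
                 duration = 240, mr_window = c(0, 120), seed = 11L)
}

# integer-pixel image shift (zero fill), used as a registration oracle
shift_img <- function(img, dy, dx) {
  out <- img * 0
  src_r <- seq_len(nrow(img)) - dy
  src_c <- seq_len(ncol(img)) - dx
  ok_r <- src_r >= 1 & src_r <= nrow(img)
  ok_c <- src_c >= 1 & src_c <= ncol(img)
  out[which(ok_r), which(ok_c)] <- img[src_r[ok_r], src_c[ok_c]]
  out
}

relerr <- function(a, b) sqrt(sum((a - b)^2)) / sqrt(sum(b^2))

# noiseless static k-space of the small water-only phantom
static_kspace <- function() memo("static_ks", function() {
  cfg <- static_config()
  ph <- build_phantom(cfg)
  ph$fat[] <- 0
  s <- generate_surrogates(cfg)
  mrc <- mr_sequence_config(spokes_total = 300L, samples_per_spoke = 64L,
                            noise_sd = 0, spoke_interval = 0.19)
  traj <- make_trajectory(mrc, c(0, 60), cfg$pixel_size)
  list(phantom = ph, surr = s, config = mrc, traj = traj,
       ks = simulate_acquisition(ph, s, mrc, traj))
})

# full default-conditions pipeline run (the paper-scale study conditions:
# 15 mm respiration, 12% cardiac contraction, 2e6 counts, seed 0);
# shared by the end-to-end acceptance checks
acceptance_run <- function() memo("acceptance_run", function() {
  suppressWarnings(run_full(run_config(seed = 0L), verbose = FALSE))
})
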