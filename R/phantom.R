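#' Tissue label codes of the dynamic thorax phantom
#'
#' Integer codes used in phantom label maps: air 0, lung 1, soft 2, fat 3,
#' myocardium 4, blood 5, plaque 6, stent_void 7.
#' @export
tissue_labels <- c(air = 0L, lung = 1L, soft = 2L, fat = 3L,
                   myocardium = 4L, blood = 5L, plaque = 6L, stent_void = 7L)

#' Configuration of the dynamic thorax phantom
#'
#' Defines the geometry, motion physiology and surrogate-signal properties of
#' a 2D coronal-like thorax slice containing lungs, diaphragm, heart (with a
#' small coronary plaque on the epicardial border adjacent to the lung) and
#' chest fat. Respiration moves the diaphragm and heart in the
#' superior-inferior direction with a smooth taper to zero at the lung apex
#' and chest wall; the cardiac cycle contracts the heart radially about its
#' centroid.
#'
#' @param grid_shape image grid in pixels (rows, cols)
#' @param pixel_size pixel edge length, mm
#' @param resp_amplitude peak diaphragm displacement, mm
#' @param resp_period respiratory period, s
#' @param cardiac_rr_mean,cardiac_rr_sd mean and SD of the RR interval, s
#' @param cardiac_contraction_fraction peak radial shrink of the heart
#'   (dimensionless)
#' @param plaque_diameter plaque diameter, mm
#' @param plaque_to_blood_activity_ratio activity of the plaque relative to
#'   blood (> 1)
#' @param stent_enabled add a stented region: an MR signal void with
#'   soft-tissue attenuation and plaque-level tracer uptake
#' @param duration total scan duration, s (PET window)
#' @param mr_window start/end of the simultaneous MR acquisition, s
#' @param belt_lag lag of the respiratory belt behind the heart motion, s
#' @param belt_noise_sd,selfnav_noise_sd additive noise SD of the surrogate
#'   traces, as a fraction of the respiratory amplitude
#' @param belt_fs surrogate sampling rate, Hz
#' @param seed master seed; all phantom randomness derives from it
#' @return object of class \code{phantom_config}
#' @export
phantom_config <- function(grid_shape = c(128L, 128L), pixel_size = 2.0,
                           resp_amplitude = 15, resp_period = 4.0,
                           cardiac_rr_mean = 1.0, cardiac_rr_sd = 0.05,
                           cardiac_contraction_fraction = 0.12,
                           plaque_diameter = 3.0,
                           plaque_to_blood_activity_ratio = 3.0,
                           stent_enabled = FALSE,
                           duration = 2700, mr_window = c(0, 720),
                           belt_lag = 0.3, belt_noise_sd = 0.02,
                           selfnav_noise_sd = 0.02, belt_fs = 25,
                           seed = 1L) {
  cfg <- list(grid_shape = as.integer(grid_shape), pixel_size = pixel_size,
              resp_amplitude = resp_amplitude, resp_period = resp_period,
              cardiac_rr_mean = cardiac_rr_mean, cardiac_rr_sd = cardiac_rr_sd,
              cardiac_contraction_fraction = cardiac_contraction_fraction,
              plaque_diameter = plaque_diameter,
              plaque_to_blood_activity_ratio = plaque_to_blood_activity_ratio,
              stent_enabled = isTRUE(stent_enabled),
              duration = duration, mr_window = as.numeric(mr_window),
              belt_lag = belt_lag, belt_noise_sd = belt_noise_sd,
              selfnav_noise_sd = selfnav_noise_sd, belt_fs = belt_fs,
              seed = as.integer(seed))
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  chk <- function(ok, field, why)
    if (!ok) stop(sprintf("invalid phantom config: field '%s' %s", field, why),
                  call. = FALSE)
  chk(length(cfg$grid_shape) == 2 && all(cfg$grid_shape >= 16),
      "grid_shape", "must be two integers >= 16")
  chk(cfg$pixel_size > 0, "pixel_size", "must be > 0")
  chk(cfg$resp_amplitude >= 0, "resp_amplitude", "must be >= 0")
  extent <- min(cfg$grid_shape) * cfg$pixel_size
  chk(cfg$resp_amplitude < extent / 4, "resp_amplitude",
      sprintf("must be < grid extent/4 (%.1f mm)", extent / 4))
  chk(cfg$resp_period > 0, "resp_period", "must be > 0")
  chk(cfg$cardiac_rr_mean > 0, "cardiac_rr_mean", "must be > 0")
  chk(cfg$cardiac_rr_sd >= 0, "cardiac_rr_sd", "must be >= 0")
  chk(cfg$cardiac_contraction_fraction >= 0 &&
        cfg$cardiac_contraction_fraction < 0.5,
      "cardiac_contraction_fraction", "must be in [0, 0.5)")
  chk(cfg$plaque_diameter >= cfg$pixel_size, "plaque_diameter",
      "must be at least one pixel")
  chk(cfg$plaque_to_blood_activity_ratio > 1,
      "plaque_to_blood_activity_ratio", "must be > 1")
  chk(cfg$duration > 0, "duration", "must be > 0")
  chk(length(cfg$mr_window) == 2 && cfg$mr_window[1] >= 0 &&
        cfg$mr_window[2] > cfg$mr_window[1] &&
        cfg$mr_window[2] <= cfg$duration,
      "mr_window", "must be an interval inside [0, duration]")
  chk(cfg$belt_fs > 0, "belt_fs", "must be > 0")
  invisible(cfg)
}

# Per-label tissue properties. Activities model late-phase [18F]NaF: blood
# pool sets the background, myocardium takes up very little tracer, and the
# calcified plaque concentrates at the configured multiple of blood.
tissue_tables <- function(cfg) {
  act <- c(air = 0, lung = 0.15, soft = 0.4, fat = 0.15, myocardium = 0.25,
           blood = 1.0, plaque = cfg$plaque_to_blood_activity_ratio * 1.0,
           stent_void = cfg$plaque_to_blood_activity_ratio * 1.0)
  wat <- c(air = 0, lung = 0.15, soft = 0.70, fat = 0.10, myocardium = 0.80,
           blood = 0.90, plaque = 0.75, stent_void = 0)
  fat <- c(air = 0, lung = 0.02, soft = 0.15, fat = 0.90, myocardium = 0.07,
           blood = 0.05, plaque = 0.08, stent_void = 0)
  mu  <- c(air = 0, lung = 0.0224, soft = 0.0975, fat = 0.0864,
           myocardium = 0.0975, blood = 0.0975, plaque = 0.0975,
           stent_void = 0.0975)
  list(activity = act, water = wat, fat = fat, mu = mu)
}

# Normalised (row, col) coordinate grids in [0, 1].
norm_coords <- function(cfg) {
  ny <- cfg$grid_shape[1]; nx <- cfg$grid_shape[2]
  list(rn = matrix((seq_len(ny) - 0.5) / ny, ny, nx),
       cn = matrix(rep((seq_len(nx) - 0.5) / nx, each = ny), ny, nx))
}

# Anatomy landmarks in normalised coordinates.
phantom_geometry <- function(cfg) {
  list(body_c = c(0.54, 0.50), body_r = c(0.40, 0.42),
       llung_c = c(0.37, 0.30), llung_r = c(0.26, 0.15),
       rlung_c = c(0.37, 0.68), rlung_r = c(0.28, 0.17),
       heart_c = c(0.50, 0.42), heart_r = 0.13, myo_frac = 0.65,
       plaque_dir = c(-1, -1) / sqrt(2),
       stent_c = c(0.80, 0.35),
       taper_top = 0.10, taper_full = 0.34,
       lat_in = c(0.25, 0.75), lat_out = c(0.08, 0.92))
}

#' Build the dynamic thorax phantom
#'
#' Constructs the reference tissue label map, activity map, MR water/fat
#' parameter maps, attenuation map, and attaches the analytic motion
#' generators. Deterministic for a fixed seed.
#'
#' @param config a \code{\link{phantom_config}}
#' @return object of class \code{dynamic_phantom} with elements
#'   \code{labels}, \code{activity}, \code{water}, \code{fat}, \code{mu},
#'   \code{config}
#' @export
build_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  cfg <- config
  g <- phantom_geometry(cfg)
  nc <- norm_coords(cfg)
  rn <- nc$rn; cn <- nc$cn
  ny <- cfg$grid_shape[1]; nx <- cfg$grid_shape[2]
  scale_mm <- min(ny, nx) * cfg$pixel_size  # normalised unit -> mm

  inside_ell <- function(ctr, rad)
    ((rn - ctr[1]) / rad[1])^2 + ((cn - ctr[2]) / rad[2])^2
  lab <- matrix(tissue_labels[["air"]], ny, nx)
  body <- inside_ell(g$body_c, g$body_r)
  lab[body <= 1] <- tissue_labels[["soft"]]
  lab[body <= 1 & body >= 0.85] <- tissue_labels[["fat"]]
  lab[inside_ell(g$llung_c, g$llung_r) <= 1 & body < 0.85] <- tissue_labels[["lung"]]
  lab[inside_ell(g$rlung_c, g$rlung_r) <= 1 & body < 0.85] <- tissue_labels[["lung"]]
  dh <- sqrt((rn - g$heart_c[1])^2 + (cn - g$heart_c[2])^2)
  lab[dh <= g$heart_r] <- tissue_labels[["myocardium"]]
  lab[dh <= g$heart_r * g$myo_frac] <- tissue_labels[["blood"]]
  # plaque: small disc centred on the epicardial border facing the left lung
  pl_ctr <- g$heart_c + g$plaque_dir * g$heart_r * 0.96
  pl_r_n <- (cfg$plaque_diameter / 2) / scale_mm
  dp <- sqrt((rn - pl_ctr[1])^2 + (cn - pl_ctr[2])^2)
  lab[dp <= pl_r_n] <- tissue_labels[["plaque"]]
  if (cfg$stent_enabled) {
    ds <- sqrt((rn - g$stent_c[1])^2 + (cn - g$stent_c[2])^2)
    lab[ds <= 2.5 / scale_mm] <- tissue_labels[["stent_void"]]
  }
  storage.mode(lab) <- "integer"

  tt <- tissue_tables(cfg)
  lut <- function(tbl) matrix(tbl[lab + 1L], ny, nx)
  names(tt$activity) <- names(tt$water) <- names(tt$fat) <- names(tt$mu) <- NULL
  ph <- structure(list(labels = lab,
                       activity = lut(tt$activity),
                       water = lut(tt$water),
                       fat = lut(tt$fat),
                       mu = lut(tt$mu),
                       geometry = g, config = cfg),
                  class = "dynamic_phantom")
  ph
}

#' @export
print.dynamic_phantom <- function(x, ...) {
  cat(sprintf("<dynamic_phantom %dx%d px (%.1f mm), labels: %s>\n",
              nrow(x$labels), ncol(x$labels), x$config$pixel_size,
              paste(names(tissue_labels)[sort(unique(as.vector(x$labels))) + 1],
                    collapse = ", ")))
  invisible(x)
}

# Respiratory taper: 0 at the lung apex/above, 1 from just above the heart
# down through the diaphragm, attenuated towards the lateral chest wall.
resp_taper <- function(rn, cn, g) {
  tr <- smoothstep((rn - g$taper_top) / (g$taper_full - g$taper_top))
  tc <- smoothstep((cn - g$lat_out[1]) / (g$lat_in[1] - g$lat_out[1])) *
    smoothstep((g$lat_out[2] - cn) / (g$lat_out[2] - g$lat_in[2]))
  tr * tc
}

# Cardiac contraction envelope: sin^2 over the cycle, zero at phase 0
# (end-diastole reference).
cardiac_envelope <- function(phase) sin(pi * phase)^2

# Analytic forward displacement (mm) of the composed cardiorespiratory map
# at arbitrary normalised coordinates. Cardiac contraction innermost,
# respiratory translation outermost.
phantom_displacement <- function(cfg, g, rn, cn, resp_disp, cardiac_phase) {
  scale_mm <- min(cfg$grid_shape) * cfg$pixel_size
  # cardiac: radial contraction about the heart centroid
  kappa <- cfg$cardiac_contraction_fraction * cardiac_envelope(cardiac_phase)
  dr <- rn - g$heart_c[1]; dc <- cn - g$heart_c[2]
  rad <- sqrt(dr^2 + dc^2)
  beta <- 1 - smoothstep((rad - g$heart_r) / (g$heart_r * 0.45))
  ucr <- -kappa * beta * dr   # normalised units
  ucc <- -kappa * beta * dc
  # respiratory: SI translation with taper, evaluated at the
  # cardiac-displaced position
  tap <- resp_taper(rn + ucr, cn + ucc, g)
  ury <- resp_disp / scale_mm * tap
  list(uy = (ucr + ury) * scale_mm, ux = ucc * scale_mm)  # mm
}

#' Deform the phantom into a motion state
#'
#' Evaluates the analytic cardiorespiratory deformation at the requested
#' diaphragm displacement and cardiac phase and resamples the reference
#' maps: labels with nearest-neighbour pull-back, continuous maps with
#' linear interpolation. The activity map additionally carries the Jacobian
#' determinant of the forward map so that total tracer activity is
#' conserved under deformation.
#'
#' @param phantom a \code{dynamic_phantom}
#' @param resp_disp instantaneous diaphragm displacement, mm (0 =
#'   end-exhale reference; must not exceed the configured amplitude)
#' @param cardiac_phase cardiac phase in [0, 1); 0 is the end-diastole
#'   reference
#' @return list with \code{labels}, \code{activity}, \code{water},
#'   \code{fat}, \code{mu} and \code{gt} (the ground-truth
#'   \code{\link{displacement_field}} mapping reference to state
#'   coordinates, mm)
#' @export
deform <- function(phantom, resp_disp, cardiac_phase = 0) {
  stopifnot(inherits(phantom, "dynamic_phantom"))
  cfg <- phantom$config
  if (resp_disp < 0 || resp_disp > cfg$resp_amplitude + 1e-9)
    stop(sprintf("resp_disp %.2f mm outside configured range [0, %.2f]",
                 resp_disp, cfg$resp_amplitude))
  cardiac_phase <- cardiac_phase %% 1
  g <- phantom$geometry
  nc <- norm_coords(cfg)
  ny <- cfg$grid_shape[1]; nx <- cfg$grid_shape[2]
  px <- cfg$pixel_size
  scale_mm <- min(ny, nx) * px

  u_at <- function(rn, cn)
    phantom_displacement(cfg, g, rn, cn, resp_disp, cardiac_phase)

  # ground truth: forward displacement on the reference grid
  u <- u_at(nc$rn, nc$cn)
  gt <- displacement_field(u$ux, u$uy, px)

  # inverse map by fixed-point iteration on the analytic field:
  # find x with x + u(x) = y for every grid point y
  xr <- nc$rn; xc <- nc$cn
  for (i in 1:15) {
    ui <- u_at(xr, xc)
    xr <- nc$rn - ui$uy / scale_mm
    xc <- nc$cn - ui$ux / scale_mm
  }
  # pull-back sampling coordinates in pixels (1-based)
  sr <- xr * ny + 0.5
  sc <- xc * nx + 0.5

  labels_t <- sample_nearest(phantom$labels, sr, sc, fill = tissue_labels[["air"]])
  water_t <- sample_bilinear(phantom$water, sr, sc)
  fat_t <- sample_bilinear(phantom$fat, sr, sc)
  mu_t <- sample_bilinear(phantom$mu, sr, sc)
  act_t <- sample_bilinear(phantom$activity, sr, sc)
  # mass preservation: the Jacobian of the inverse map rescales local
  # concentration (volume compression raises it), act_t(y) = act(x)/|det J(x)|
  act_t <- act_t / det_jacobian(u_at, xr, xc, scale_mm)
  list(labels = labels_t, activity = act_t, water = water_t, fat = fat_t,
       mu = mu_t, gt = gt)
}

# |det(I + grad u)| of the analytic forward map, central differences in
# normalised coordinates.
det_jacobian <- function(u_at, rn, cn, scale_mm) {
  eps <- 1e-4
  up <- u_at(rn + eps, cn); um <- u_at(rn - eps, cn)
  dudy_y <- (up$uy - um$uy) / (2 * eps * scale_mm)
  dudx_y <- (up$ux - um$ux) / (2 * eps * scale_mm)
  vp <- u_at(rn, cn + eps); vm <- u_at(rn, cn - eps)
  dudy_x <- (vp$uy - vm$uy) / (2 * eps * scale_mm)
  dudx_x <- (vp$ux - vm$ux) / (2 * eps * scale_mm)
  abs((1 + dudy_y) * (1 + dudx_x) - dudy_x * dudx_y)
}

sample_bilinear <- function(img, sr, sc) {
  ny <- nrow(img); nx <- ncol(img)
  ux <- sc - matrix(rep(seq_len(nx), each = ny), ny, nx)
  uy <- sr - matrix(seq_len(ny), ny, nx)
  warp_pull_cpp(img, ux, uy)
}

sample_nearest <- function(img, sr, sc, fill = 0L) {
  ny <- nrow(img); nx <- ncol(img)
  ux <- sc - matrix(rep(seq_len(nx), each = ny), ny, nx)
  uy <- sr - matrix(seq_len(ny), ny, nx)
  storage.mode(img) <- "integer"
  warp_nearest_cpp(img, ux, uy, as.integer(fill))
}

#' Respiratory waveform of the phantom
#'
#' Rectified cosine-power (cos^4) diaphragm displacement: zero (end-exhale)
#' is the prevalent state, peaks at the configured amplitude once per
#' respiratory period.
#'
#' @param t time, s
#' @param config a \code{phantom_config}
#' @return diaphragm displacement, mm
#' @export
resp_waveform <- function(t, config) {
  config$resp_amplitude * cos(pi * t / config$resp_period)^4
}

#' Generate physiological surrogate signals
#'
#' Produces the respiratory belt trace (a lagged, noisy copy of the true
#' diaphragm displacement), the MR self-navigator trace (noisy heart
#' superior-inferior displacement, available only during the MR window
#' conceptually but sampled throughout), and the ECG R-peak times with
#' Gaussian RR variability. Deterministic for a fixed config seed.
#'
#' @param config a \code{\link{phantom_config}} (duration must exceed 10 s)
#' @return object of class \code{surrogate_set}: \code{time}, \code{belt},
#'   \code{selfnav}, \code{rpeaks}, \code{mr_window}, and the hidden ground
#'   truth trace \code{true_disp} used by the simulators
#' @export
generate_surrogates <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  if (config$duration <= 10) stop("invalid phantom config: field 'duration' must be > 10 s")
  cfg <- config
  set.seed(derive_seed(cfg$seed, 1L))
  time <- seq(0, cfg$duration, by = 1 / cfg$belt_fs)
  n <- length(time)
  disp <- resp_waveform(time, cfg)
  belt <- resp_waveform(time - cfg$belt_lag, cfg) +
    stats::rnorm(n, 0, cfg$belt_noise_sd * cfg$resp_amplitude)
  selfnav <- disp + stats::rnorm(n, 0, cfg$selfnav_noise_sd * cfg$resp_amplitude)
  rr <- stats::rnorm(ceiling(cfg$duration / cfg$cardiac_rr_mean * 1.5) + 10,
                     cfg$cardiac_rr_mean, cfg$cardiac_rr_sd)
  rr <- pmax(rr, 0.3 * cfg$cardiac_rr_mean)
  rpeaks <- cumsum(c(0, rr))
  rpeaks <- rpeaks[rpeaks <= cfg$duration]
  structure(list(time = time, belt = belt, selfnav = selfnav,
                 rpeaks = rpeaks, mr_window = cfg$mr_window,
                 true_disp = disp, fs = cfg$belt_fs, config = cfg),
            class = "surrogate_set")
}

#' Cardiac phase at arbitrary timestamps
#'
#' Phase is the elapsed fraction of the current RR interval,
#' \code{(t - previous R-peak) / RR}. Timestamps before the first R-peak
#' wrap around using the first RR interval; timestamps after the last use
#' the last interval extrapolated.
#'
#' @param t timestamps, s
#' @param rpeaks strictly increasing R-peak times, s
#' @return phase values in [0, 1)
#' @export
cardiac_phase_at <- function(t, rpeaks) {
  if (length(rpeaks) < 2) stop("need at least two R-peaks")
  idx <- findInterval(t, rpeaks)
  rr1 <- rpeaks[2] - rpeaks[1]
  rr_last <- rpeaks[length(rpeaks)] - rpeaks[length(rpeaks) - 1]
  phase <- numeric(length(t))
  pre <- idx == 0
  phase[pre] <- ((t[pre] - rpeaks[1]) %% rr1) / rr1
  post <- idx == length(rpeaks)
  phase[post] <- ((t[post] - rpeaks[length(rpeaks)]) %% rr_last) / rr_last
  mid <- !pre & !post
  i <- idx[mid]
  phase[mid] <- (t[mid] - rpeaks[i]) / (rpeaks[i + 1] - rpeaks[i])
  phase %% 1
}

#' Write phantom reference maps as NIfTI and surrogates as CSV
#'
#' @param phantom a \code{dynamic_phantom}
#' @param surrogates a \code{surrogate_set} (optional)
#' @param dir output directory (created if needed)
#' @export
write_phantom <- function(phantom, surrogates = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  px <- phantom$config$pixel_size
  for (nm in c("labels", "activity", "water", "fat", "mu"))
    write_map_nifti(phantom[[nm]], file.path(dir, paste0(nm, ".nii.gz")), px)
  yaml::write_yaml(unclass(phantom$config), file.path(dir, "phantom_config.yaml"))
  if (!is.null(surrogates)) {
    utils::write.csv(data.frame(time_s = surrogates$time, belt = surrogates$belt,
                                selfnav = surrogates$selfnav),
                     file.path(dir, "surrogates.csv"), row.names = FALSE)
    utils::write.csv(data.frame(rpeak_s = surrogates$rpeaks),
                     file.path(dir, "rpeaks.csv"), row.names = FALSE)
  }
  invisible(dir)
}
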