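#' 2D parallel-beam PET geometry
#'
#' @param n_angles projection angles over 180 degrees
#' @param n_radial radial detector bins (pitch equals the pixel size)
#' @param pixel_size mm
#' @export
pet_geometry <- function(n_angles = 180L, n_radial = 128L, pixel_size = 2.0) {
  if (n_angles < 1) stop("pet geometry: n_angles must be >= 1")
  structure(list(n_angles = as.integer(n_angles),
                 n_radial = as.integer(n_radial),
                 angles = (seq_len(n_angles) - 1) * pi / n_angles,
                 pixel_size = pixel_size),
            class = "pet_geometry")
}

#' Forward-project an activity image
#'
#' Length-weighted line integrals (pixel-driven, linear detector-bin
#' splitting), units activity x mm. Exact adjoint pair with
#' \code{\link{backproject}}.
#'
#' @param image non-negative activity matrix
#' @param geometry a \code{\link{pet_geometry}}
#' @param subset optional angle index subset
#' @export
project <- function(image, geometry, subset = NULL) {
  if (any(image < 0)) stop("project: negative input")
  ang <- if (is.null(subset)) geometry$angles else geometry$angles[subset]
  proj_forward_cpp(image, ang, geometry$n_radial) * geometry$pixel_size
}

#' Adjoint of \code{\link{project}}
#' @param sino sinogram matrix (radial x angles)
#' @param geometry a \code{pet_geometry}
#' @param dim image dimensions
#' @param subset optional angle index subset matching the sinogram columns
#' @export
backproject <- function(sino, geometry, dim, subset = NULL) {
  ang <- if (is.null(subset)) geometry$angles else geometry$angles[subset]
  proj_adjoint_cpp(sino, ang, dim[1], dim[2]) * geometry$pixel_size
}

#' Attenuation (survival-probability) factors for a mu-map
#'
#' \code{exp(-line integral of mu)} with mu in 1/cm and path length in cm;
#' values in (0, 1].
#'
#' @param mu a \code{mu_map}
#' @param geometry a \code{pet_geometry}
#' @param subset optional angle subset
#' @export
attenuation_factors <- function(mu, geometry, subset = NULL) {
  stopifnot(inherits(mu, "mu_map"))
  exp(-project(mu$mu, geometry, subset) / 10)  # mm -> cm
}

#' PET acquisition plan
#'
#' @param total_counts expected true coincidences over the scan
#' @param duration scan duration, s
#' @param scatter_fraction uniform scatter background fraction in [0, 0.5]
#' @param frame_dt surrogate-sampling frame length for bin assignment, s
#' @param seed RNG seed for the Poisson draw
#' @export
acquisition_plan <- function(total_counts = 2e6, duration = 2700,
                             scatter_fraction = 0, frame_dt = 0.25,
                             seed = 1L) {
  if (total_counts <= 0) stop("acquisition plan: total_counts must be > 0")
  if (scatter_fraction < 0 || scatter_fraction > 0.5)
    stop("acquisition plan: scatter_fraction must be in [0, 0.5]")
  structure(list(total_counts = total_counts, duration = duration,
                 scatter_fraction = scatter_fraction, frame_dt = frame_dt,
                 seed = as.integer(seed)),
            class = "acquisition_plan")
}

#' Simulate per-motion-bin PET emission sinograms
#'
#' The scan is partitioned into short frames; each frame is assigned a
#' (respiratory, cardiac) bin through the shifted belt signal and the ECG.
#' Each occupied bin's expected sinogram is its occupancy times the
#' attenuated projection of the phantom activity deformed to the bin's
#' representative motion state (the occupancy-weighted mean state of its
#' frames), scaled so the expected total equals the planned counts, plus
#' an optional flat scatter background. Counts are Poisson.
#'
#' @param phantom a \code{dynamic_phantom}
#' @param surrogates a \code{surrogate_set}
#' @param thresholds respiratory amplitude thresholds from the MR binning
#' @param n_card number of cardiac bins
#' @param belt_shift global belt time shift, s
#' @param geometry a \code{pet_geometry}
#' @param plan an \code{\link{acquisition_plan}}
#' @param mu_mode "dynamic" uses the true deformed attenuation per bin;
#'   "reference" attenuates every bin with the reference-state map
#' @return object of class \code{sinogram_set}: \code{counts} and
#'   \code{expected} (lists over occupied bins), \code{occupancy},
#'   \code{bin_table} (resp/card ids), \code{scatter} (flat expected
#'   scatter sinogram or NULL), \code{geometry},
#'   \code{activity_scale} (expected counts per unit projected activity)
#' @export
simulate_pet <- function(phantom, surrogates, thresholds, n_card = 12L,
                         belt_shift = 0, geometry = NULL,
                         plan = acquisition_plan(),
                         mu_mode = c("dynamic", "reference")) {
  mu_mode <- match.arg(mu_mode)
  stopifnot(inherits(phantom, "dynamic_phantom"))
  cfg <- phantom$config
  if (is.null(geometry))
    geometry <- pet_geometry(n_radial = max(cfg$grid_shape),
                             pixel_size = cfg$pixel_size)
  tfr <- seq(0, min(plan$duration, cfg$duration), by = plan$frame_dt)
  map <- extend_mapper(thresholds, surrogates, tfr, belt_shift, n_card)
  disp <- interp_trace(surrogates$time, surrogates$true_disp, tfr)
  disp <- pmin(pmax(disp, 0), cfg$resp_amplitude)
  phase <- cardiac_phase_at(tfr, surrogates$rpeaks)
  n_resp <- length(thresholds) + 1L
  key <- crbin_index(map$resp_bin, map$card_bin, n_card)
  bins <- sort(unique(key))
  occ <- as.numeric(table(factor(key, levels = bins))) / length(key)

  expected <- vector("list", length(bins))
  bin_table <- data.frame(bin = bins,
                          resp = (bins - 1) %/% n_card + 1L,
                          card = (bins - 1) %% n_card + 1L)
  mu_ref <- mu_map(phantom$mu, cfg$pixel_size, "true reference")
  for (i in seq_along(bins)) {
    idx <- key == bins[i]
    st <- deform(phantom, mean(disp[idx]), mean(phase[idx]))
    att <- if (mu_mode == "dynamic")
      attenuation_factors(mu_map(st$mu, cfg$pixel_size), geometry)
    else attenuation_factors(mu_ref, geometry)
    expected[[i]] <- occ[i] * att * project(st$activity, geometry)
  }
  tot <- sum(vapply(expected, sum, 0))
  scale <- if (tot > 0)
    plan$total_counts * (1 - plan$scatter_fraction) / tot else 0
  expected <- lapply(expected, function(e) e * scale)
  scatter <- NULL
  if (plan$scatter_fraction > 0) {
    flat <- matrix(1, geometry$n_radial, geometry$n_angles)
    flat <- flat / sum(flat) * plan$total_counts * plan$scatter_fraction
    scatter <- flat  # per-bin share proportional to occupancy
  }
  set.seed(derive_seed(plan$seed, 4L))
  counts <- vector("list", length(bins))
  for (i in seq_along(bins)) {
    lam <- expected[[i]]
    if (!is.null(scatter)) lam <- lam + occ[i] * scatter
    counts[[i]] <- matrix(stats::rpois(length(lam), lam), nrow(lam), ncol(lam))
  }
  structure(list(counts = counts, expected = expected, occupancy = occ,
                 bin_table = bin_table, scatter = scatter,
                 geometry = geometry, activity_scale = scale,
                 n_resp = n_resp, n_card = n_card,
                 grid = cfg$grid_shape, pixel_size = cfg$pixel_size),
            class = "sinogram_set")
}

#' @export
print.sinogram_set <- function(x, ...) {
  cat(sprintf("<sinogram_set %d occupied bins (%dx%d lattice), %.3g counts>\n",
              length(x$counts), x$n_resp, x$n_card,
              sum(vapply(x$counts, sum, 0))))
  invisible(x)
}

#' Export a thin listmode-style event table (event, frame, bin)
#' @param sinos a \code{sinogram_set}
#' @param path CSV output path
#' @param max_events cap on exported events
#' @export
write_listmode_csv <- function(sinos, path, max_events = 1e5) {
  per_bin <- vapply(sinos$counts, sum, 0)
  n <- min(sum(per_bin), max_events)
  frac <- n / sum(per_bin)
  rows <- do.call(rbind, lapply(seq_along(sinos$counts), function(i) {
    k <- round(per_bin[i] * frac)
    if (k == 0) return(NULL)
    data.frame(event = seq_len(k), bin = sinos$bin_table$bin[i],
               resp = sinos$bin_table$resp[i], card = sinos$bin_table$card[i])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
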