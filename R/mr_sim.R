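GOLDEN_ANGLE <- pi * (3 - sqrt(5))  # 111.246 degrees

#' Multi-echo Dixon MR sequence configuration
#'
#' Parameters of the simulated T1-weighted multi-echo gradient-echo (Dixon)
#' acquisition on a 2D golden-angle radial trajectory. The fat resonance is
#' modelled as a single spectral peak offset by \code{delta_f} from water;
#' echo signals mix water and fat as \code{W + F exp(i 2 pi delta_f TE)}.
#'
#' @param TR repetition time, ms (metadata; spoke pacing can be overridden
#'   with \code{spoke_interval})
#' @param TE echo times, ms (strictly increasing, at least two)
#' @param flip_angle excitation flip angle, degrees (metadata only)
#' @param delta_f water-fat chemical shift, Hz (negative at 3 T)
#' @param noise_sd complex Gaussian noise SD per k-space sample, as a
#'   fraction of the reference DC magnitude
#' @param spokes_total number of radial spokes acquired
#' @param samples_per_spoke readout samples per spoke
#' @param spoke_interval time between consecutive spokes, s; defaults to
#'   TR/1000. Setting it larger simulates a uniformly thinned subsample of
#'   the readout stream so a long acquisition window can be covered with a
#'   desk-scale spoke count.
#' @return object of class \code{mr_sequence_config}
#' @export
mr_sequence_config <- function(TR = 7.57, TE = c(2.62, 4.13, 5.64),
                               flip_angle = 15, delta_f = -428,
                               noise_sd = 0.001, spokes_total = 3600L,
                               samples_per_spoke = 128L,
                               spoke_interval = NULL) {
  if (length(TE) < 2) stop("invalid MR config: field 'TE' needs at least 2 echoes")
  if (any(diff(TE) <= 0)) stop("invalid MR config: field 'TE' must be strictly increasing")
  if (TR <= 0) stop("invalid MR config: field 'TR' must be > 0")
  if (spokes_total < 1) stop("invalid MR config: field 'spokes_total' must be >= 1")
  if (samples_per_spoke < 8) stop("invalid MR config: field 'samples_per_spoke' must be >= 8")
  structure(list(TR = TR, TE = TE, flip_angle = flip_angle, delta_f = delta_f,
                 noise_sd = noise_sd, spokes_total = as.integer(spokes_total),
                 samples_per_spoke = as.integer(samples_per_spoke),
                 spoke_interval = spoke_interval),
            class = "mr_sequence_config")
}

# chemical-shift mixing coefficients per echo, TE in ms
echo_coeffs <- function(config) exp(2i * pi * config$delta_f * config$TE / 1000)

#' Golden-angle radial trajectory
#'
#' Spoke angles advance by the golden angle (about 111.246 degrees) modulo
#' pi; timestamps advance by the spoke interval from the window start.
#' Radial k-space coordinates span the grid Nyquist range symmetrically.
#'
#' @param config an \code{\link{mr_sequence_config}}
#' @param window acquisition time interval c(start, end), s
#' @param pixel_size image pixel size, mm (sets the Nyquist frequency)
#' @return object of class \code{mr_trajectory}: \code{angles} (rad),
#'   \code{times} (s), \code{k} (cycles/mm, per sample)
#' @export
make_trajectory <- function(config, window, pixel_size) {
  stopifnot(inherits(config, "mr_sequence_config"))
  if (diff(window) <= 0) stop("trajectory window must have positive length")
  dt <- if (is.null(config$spoke_interval)) config$TR / 1000 else config$spoke_interval
  span <- (config$spokes_total - 1) * dt
  if (span > diff(window))
    stop(sprintf(paste0("trajectory overflow: %d spokes at %.4g s per spoke ",
                        "need %.1f s but the window is %.1f s"),
                 config$spokes_total, dt, span, diff(window)))
  i <- seq_len(config$spokes_total) - 1
  S <- config$samples_per_spoke
  structure(list(angles = (i * GOLDEN_ANGLE) %% pi,
                 times = window[1] + i * dt,
                 k = (seq_len(S) - 1 - S / 2) / (S * pixel_size),
                 pixel_size = pixel_size, config = config),
            class = "mr_trajectory")
}

# 1D DFT matrix from detector-bin positions to the spoke k-coordinates.
# Shared by every spoke (identical radial sampling); detector bins have the
# pixel pitch and are centred like the projector bins.
spoke_dft_matrix <- function(trajectory, nbins) {
  px <- trajectory$pixel_size
  t_mm <- ((seq_len(nbins) - 1) - (nbins - 1) / 2) * px
  exp(-2i * pi * outer(trajectory$k, t_mm))
}

proj_forward_c <- function(img, angles, nbins) {
  if (is.complex(img))
    proj_forward_cpp(Re(img), angles, nbins) +
      1i * proj_forward_cpp(Im(img), angles, nbins)
  else proj_forward_cpp(img, angles, nbins)
}

proj_adjoint_c <- function(sino, angles, ny, nx) {
  if (is.complex(sino))
    proj_adjoint_cpp(Re(sino), angles, ny, nx) +
      1i * proj_adjoint_cpp(Im(sino), angles, ny, nx)
  else proj_adjoint_cpp(sino, angles, ny, nx)
}

#' Radial Fourier encoding of a complex image
#'
#' Forward non-uniform Fourier sampling along radial spokes, implemented
#' through the central-slice identity: the k-space samples on a spoke equal
#' the 1D DFT of the image projection at the spoke angle. The operator and
#' \code{\link{mr_encode_adjoint}} form an exact adjoint pair.
#'
#' @param img complex (or real) image matrix
#' @param trajectory an \code{mr_trajectory}
#' @param spoke_idx which spokes to evaluate (default all)
#' @return complex matrix, samples x spokes
#' @export
mr_encode_forward <- function(img, trajectory, spoke_idx = NULL) {
  if (is.null(spoke_idx)) spoke_idx <- seq_along(trajectory$angles)
  nbins <- nrow(img)
  D <- spoke_dft_matrix(trajectory, nbins)
  P <- proj_forward_c(img, trajectory$angles[spoke_idx], nbins)
  D %*% P
}

#' Adjoint of the radial Fourier encoding
#' @param ksp complex matrix, samples x spokes
#' @param trajectory an \code{mr_trajectory}
#' @param dim image dimensions c(ny, nx)
#' @param spoke_idx which spokes the columns of \code{ksp} correspond to
#' @export
mr_encode_adjoint <- function(ksp, trajectory, dim, spoke_idx = NULL) {
  if (is.null(spoke_idx)) spoke_idx <- seq_along(trajectory$angles)
  nbins <- dim[2]
  D <- spoke_dft_matrix(trajectory, nbins)
  P <- Conj(t(D)) %*% ksp
  proj_adjoint_c(P, trajectory$angles[spoke_idx], dim[1], dim[2])
}

#' Simulate the multi-echo radial MR acquisition of the moving phantom
#'
#' For every spoke, the phantom is deformed to the motion state given by
#' the ground-truth respiratory displacement and cardiac phase at the spoke
#' timestamp, and each echo samples the chemical-shift-mixed water/fat
#' image along the spoke, plus complex Gaussian noise. Motion states are
#' quantised (0.5 mm respiratory, 1/24 cardiac cycle) so that deformations
#' can be cached across spokes.
#'
#' @param phantom a \code{dynamic_phantom}
#' @param surrogates a \code{surrogate_set} covering the trajectory times
#' @param config an \code{mr_sequence_config}
#' @param trajectory an \code{mr_trajectory}
#' @param seed RNG seed for the noise stream
#' @return object of class \code{mr_kspace}: \code{data} (list per echo of
#'   samples x spokes complex matrices), \code{trajectory}, \code{config},
#'   \code{noise_sd_abs}
#' @export
simulate_acquisition <- function(phantom, surrogates, config, trajectory,
                                 seed = phantom$config$seed) {
  stopifnot(inherits(phantom, "dynamic_phantom"),
            inherits(surrogates, "surrogate_set"),
            inherits(config, "mr_sequence_config"),
            inherits(trajectory, "mr_trajectory"))
  tt <- trajectory$times
  if (min(tt) < min(surrogates$time) - 1e-9 || max(tt) > max(surrogates$time) + 1e-9)
    stop("trajectory timestamps outside surrogate support")
  disp <- interp_trace(surrogates$time, surrogates$true_disp, tt)
  disp <- pmin(pmax(disp, 0), phantom$config$resp_amplitude)
  phase <- cardiac_phase_at(tt, surrogates$rpeaks)
  # quantised motion states -> cached deformations
  dq <- round(disp / 0.5) * 0.5
  pq <- (round(phase * 24) %% 24) / 24
  state_key <- paste(dq, pq)
  keys <- unique(state_key)
  nbins <- nrow(phantom$water)
  D <- spoke_dft_matrix(trajectory, nbins)
  ce <- echo_coeffs(config)
  ne <- length(ce)
  data <- replicate(ne, matrix(0i, config$samples_per_spoke, config$spokes_total),
                    simplify = FALSE)
  for (ky in keys) {
    idx <- which(state_key == ky)
    st <- deform(phantom, dq[idx[1]], pq[idx[1]])
    PW <- proj_forward_cpp(st$water, trajectory$angles[idx], nbins)
    PF <- proj_forward_cpp(st$fat, trajectory$angles[idx], nbins)
    for (e in seq_len(ne))
      data[[e]][, idx] <- D %*% (PW + ce[e] * PF)
  }
  dc_ref <- abs(sum(phantom$water) + sum(phantom$fat))
  sd_abs <- config$noise_sd * dc_ref
  if (sd_abs > 0) {
    set.seed(derive_seed(seed, 2L))
    for (e in seq_len(ne)) {
      n <- length(data[[e]])
      data[[e]] <- data[[e]] +
        matrix(stats::rnorm(n, 0, sd_abs) + 1i * stats::rnorm(n, 0, sd_abs),
               nrow(data[[e]]), ncol(data[[e]]))
    }
  }
  structure(list(data = data, trajectory = trajectory, config = config,
                 noise_sd_abs = sd_abs, grid = dim(phantom$water),
                 pixel_size = phantom$config$pixel_size),
            class = "mr_kspace")
}

#' @export
print.mr_kspace <- function(x, ...) {
  cat(sprintf("<mr_kspace %d echoes, %d samples x %d spokes, noise sd %.3g>\n",
              length(x$data), nrow(x$data[[1]]), ncol(x$data[[1]]),
              x$noise_sd_abs))
  invisible(x)
}
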