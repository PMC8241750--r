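#' Registration configuration
#'
#' Parameters of the non-rigid B-spline registration that drives motion
#' model estimation. The cost is
#' \code{C(m) = w*S(W_mov o m, W_ref) + (1-w)*S(F_mov o m, F_ref) + r*R(m)}
#' with S either negative normalised mutual information (default) or mean
#' squared difference, and R the bending energy of the B-spline
#' coefficients. Water and fat channels are weighted equally by default.
#'
#' @param w water-channel weight in [0, 1]; the fat channel gets 1 - w
#' @param r regularisation weight (>= 0). The default was calibrated once
#'   so the bending term contributes about 10 percent of the initial
#'   similarity magnitude on the default phantom.
#' @param similarity "NMI" or "SSD"
#' @param nmi_bins histogram bins for NMI
#' @param cp_spacing control-point spacing, mm (must exceed the pixel size)
#' @param levels multiresolution levels (coarse-to-fine, factor 2)
#' @param iterations gradient-descent iterations per level
#' @param step0 initial trial step, mm
#' @export
registration_config <- function(w = 0.5, r = NULL,
                                similarity = c("NMI", "SSD"),
                                nmi_bins = 32L, cp_spacing = 16,
                                levels = 3L, iterations = 60L, step0 = 1.0) {
  similarity <- match.arg(similarity)
  if (w < 0 || w > 1) stop("registration config: w must be in [0,1]")
  if (is.null(r)) r <- if (similarity == "NMI") 3e-4 else 2e-4
  if (r < 0) stop("registration config: r must be >= 0")
  structure(list(w = w, r = r, similarity = similarity,
                 nmi_bins = as.integer(nmi_bins), cp_spacing = cp_spacing,
                 levels = as.integer(levels), iterations = as.integer(iterations),
                 step0 = step0),
            class = "registration_config")
}

# cubic B-spline FFD basis matrix for a pixel axis of length n with control
# spacing delta (pixels); control points extend past the image so the basis
# sums to one everywhere inside
bspline_basis <- function(n, delta) {
  m <- ceiling((n - 1) / delta) + 3
  ctr <- ((seq_len(m)) - 2) * delta
  x <- seq_len(n) - 1
  B <- outer(x, ctr, function(xi, cj) {
    u <- abs(xi - cj) / delta
    ifelse(u < 1, (4 - 6 * u^2 + 3 * u^3) / 6,
           ifelse(u < 2, (2 - u)^3 / 6, 0))
  })
  B
}

# bending energy of coefficient matrices (sum over both displacement
# components) and its gradient; plain second differences on the lattice
bending_energy <- function(Cx, Cy) {
  d2 <- function(M, dim) {
    if (dim == 1) diff(M, differences = 2)
    else t(diff(t(M), differences = 2))
  }
  dxy <- function(M) diff(t(diff(t(M))))
  val <- 0; gx <- 0 * Cx; gy <- 0 * Cy
  for (comp in list(list(C = Cx, g = "x"), list(C = Cy, g = "y"))) {
    C <- comp$C
    arr <- d2(C, 1); acc <- 0 * C
    acc[1:(nrow(C) - 2), ] <- acc[1:(nrow(C) - 2), ] + 2 * arr
    acc[2:(nrow(C) - 1), ] <- acc[2:(nrow(C) - 1), ] - 4 * arr
    acc[3:nrow(C), ] <- acc[3:nrow(C), ] + 2 * arr
    v <- sum(arr^2)
    arr <- d2(C, 2)
    acc[, 1:(ncol(C) - 2)] <- acc[, 1:(ncol(C) - 2)] + 2 * arr
    acc[, 2:(ncol(C) - 1)] <- acc[, 2:(ncol(C) - 1)] - 4 * arr
    acc[, 3:ncol(C)] <- acc[, 3:ncol(C)] + 2 * arr
    v <- v + sum(arr^2)
    arr <- dxy(C)
    acc[1:(nrow(C) - 1), 1:(ncol(C) - 1)] <- acc[1:(nrow(C) - 1), 1:(ncol(C) - 1)] + 4 * arr
    acc[1:(nrow(C) - 1), 2:ncol(C)] <- acc[1:(nrow(C) - 1), 2:ncol(C)] - 4 * arr
    acc[2:nrow(C), 1:(ncol(C) - 1)] <- acc[2:nrow(C), 1:(ncol(C) - 1)] - 4 * arr
    acc[2:nrow(C), 2:ncol(C)] <- acc[2:nrow(C), 2:ncol(C)] + 4 * arr
    v <- v + 2 * sum(arr^2)
    val <- val + v
    if (comp$g == "x") gx <- acc else gy <- acc
  }
  n <- length(Cx)
  list(value = val / n, gx = gx / n, gy = gy / n)
}

# joint 1st-99th percentile normalisation of a channel across both images
norm_pair <- function(a, b) {
  q <- stats::quantile(c(a, b), c(0.01, 0.99), names = FALSE)
  if (q[2] <= q[1]) q[2] <- q[1] + 1
  list(a = pmin(pmax((a - q[1]) / (q[2] - q[1]), 0), 1),
       b = pmin(pmax((b - q[1]) / (q[2] - q[1]), 0), 1))
}

central_grad <- function(img) {
  ny <- nrow(img); nx <- ncol(img)
  gy <- img * 0; gx <- img * 0
  gy[2:(ny - 1), ] <- (img[3:ny, ] - img[1:(ny - 2), ]) / 2
  gx[, 2:(nx - 1)] <- (img[, 3:nx] - img[, 1:(nx - 2)]) / 2
  list(gx = gx, gy = gy)
}

downsample2 <- function(img, times) {
  for (i in seq_len(times)) {
    img <- conv_sep_reflect_cpp(img, c(0.25, 0.5, 0.25))
    ny <- nrow(img); nx <- ncol(img)
    img <- img[seq(1, ny, by = 2), seq(1, nx, by = 2)]
  }
  img
}

# similarity value + gradient wrt the warped moving intensities
similarity_grad <- function(warped, fixed, cfg) {
  if (cfg$similarity == "NMI") {
    out <- nmi_neg_grad_cpp(as.vector(warped), as.vector(fixed), cfg$nmi_bins)
    list(value = out$value,
         grad = matrix(out$grad, nrow(warped), ncol(warped)))
  } else {
    d <- warped - fixed
    list(value = mean(d^2), grad = 2 * d / length(d))
  }
}

#' Register a moving water/fat image pair to a fixed pair
#'
#' Minimises the dual-channel cost over a cubic B-spline-parameterised
#' displacement field by multiresolution gradient descent with
#' backtracking. Complex images enter as magnitudes. If one channel of the
#' fixed image is constant (zero entropy, NMI undefined) that channel is
#' dropped with a warning and the other carries full weight.
#'
#' @param moving,fixed \code{waterfat_image}s on the same grid
#' @param config a \code{\link{registration_config}}
#' @return object of class \code{registration_result}: \code{field} (a
#'   \code{\link{displacement_field}}, reference-to-state, mm),
#'   \code{cost}, \code{sim_water}, \code{sim_fat}, \code{reg} and the
#'   weights used
#' @export
register_pair <- function(moving, fixed, config = registration_config()) {
  stopifnot(inherits(moving, "waterfat_image"), inherits(fixed, "waterfat_image"))
  if (!all(dim(moving$water) == dim(fixed$water))) stop("register_pair: grid mismatch")
  cfg <- config
  px0 <- moving$pixel_size
  movW0 <- Mod(moving$water); movF0 <- Mod(moving$fat)
  fixW0 <- Mod(fixed$water); fixF0 <- Mod(fixed$fat)
  w <- cfg$w
  wf <- c(w, 1 - w)
  if (cfg$similarity == "NMI") {
    if (stats::sd(fixW0) == 0 && wf[1] > 0) {
      warning("fixed water channel is constant; using fat channel only")
      wf <- c(0, 1)
    }
    if (stats::sd(fixF0) == 0 && wf[2] > 0) {
      warning("fixed fat channel is constant; using water channel only")
      wf <- c(1, 0)
    }
  }
  nW <- norm_pair(movW0, fixW0); nF <- norm_pair(movF0, fixF0)

  factors <- rev(2^(seq_len(cfg$levels) - 1))
  Cx <- Cy <- NULL
  for (f in factors) {
    lev <- log2(f)
    movW <- downsample2(nW$a, lev); fixW <- downsample2(nW$b, lev)
    movF <- downsample2(nF$a, lev); fixF <- downsample2(nF$b, lev)
    px <- px0 * f
    ny <- nrow(movW); nx <- ncol(movW)
    delta <- max(cfg$cp_spacing / px, 1.5)
    By <- bspline_basis(ny, delta); Bx <- bspline_basis(nx, delta)
    my <- ncol(By); mx <- ncol(Bx)
    if (is.null(Cx)) { Cx <- matrix(0, my, mx); Cy <- matrix(0, my, mx) }
    else { # lattice is fixed in mm, so coefficients carry over if the
           # lattice size matches; re-fit by padding/cropping otherwise
      Cx <- resize_lattice(Cx, my, mx); Cy <- resize_lattice(Cy, my, mx)
    }
    gW <- central_grad(movW); gF <- central_grad(movF)

    cost_fn <- function(Cx, Cy, want_grad = TRUE) {
      ux <- (By %*% Cx %*% t(Bx)) / px   # px units
      uy <- (By %*% Cy %*% t(Bx)) / px
      fld <- displacement_field(ux, uy, 1)
      be <- bending_energy(Cx, Cy)
      sims <- numeric(2); Gx <- 0; Gy <- 0
      for (ch in 1:2) {
        if (wf[ch] == 0) { sims[ch] <- 0; next }
        mv <- if (ch == 1) movW else movF
        fx <- if (ch == 1) fixW else fixF
        gr <- if (ch == 1) gW else gF
        wmv <- warp_image(mv, fld)
        sg <- similarity_grad(wmv, fx, cfg)
        sims[ch] <- sg$value
        if (want_grad) {
          gxw <- warp_image(gr$gx, fld, clamp = TRUE)
          gyw <- warp_image(gr$gy, fld, clamp = TRUE)
          Gx <- Gx + wf[ch] * sg$grad * gxw
          Gy <- Gy + wf[ch] * sg$grad * gyw
        }
      }
      total <- wf[1] * sims[1] + wf[2] * sims[2] + cfg$r * be$value
      out <- list(cost = total, sims = sims, reg = be$value)
      if (want_grad) {
        # chain to coefficients; intensity gradients are per pixel, the
        # field is in mm: d(u_px)/d(C_mm) = B/px
        out$gCx <- t(By) %*% (Gx / px) %*% Bx + cfg$r * be$gx
        out$gCy <- t(By) %*% (Gy / px) %*% Bx + cfg$r * be$gy
      }
      out
    }

    # Adam: per-coefficient adaptive steps cope with the uneven gradient
    # scales of boundary vs interior control points
    mx1 <- my1 <- vx1 <- vy1 <- matrix(0, my, mx)
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-12
    lr <- cfg$step0 * 0.4
    best <- list(cost = Inf, Cx = Cx, Cy = Cy)
    for (it in seq_len(cfg$iterations)) {
      cur <- cost_fn(Cx, Cy)
      if (cur$cost < best$cost) best <- list(cost = cur$cost, Cx = Cx, Cy = Cy)
      mx1 <- b1 * mx1 + (1 - b1) * cur$gCx
      my1 <- b1 * my1 + (1 - b1) * cur$gCy
      vx1 <- b2 * vx1 + (1 - b2) * cur$gCx^2
      vy1 <- b2 * vy1 + (1 - b2) * cur$gCy^2
      bc1 <- 1 - b1^it; bc2 <- 1 - b2^it
      Cx <- Cx - lr * (mx1 / bc1) / (sqrt(vx1 / bc2) + eps + 1e-6 * sqrt(mean(vx1 / bc2)))
      Cy <- Cy - lr * (my1 / bc1) / (sqrt(vy1 / bc2) + eps + 1e-6 * sqrt(mean(vy1 / bc2)))
    }
    cur <- cost_fn(Cx, Cy, want_grad = FALSE)
    if (cur$cost < best$cost) best <- list(cost = cur$cost, Cx = Cx, Cy = Cy)
    Cx <- best$Cx; Cy <- best$Cy
  }
  ny <- nrow(movW0); nx <- ncol(movW0)
  delta <- max(cfg$cp_spacing / px0, 1.5)
  By <- bspline_basis(ny, delta); Bx <- bspline_basis(nx, delta)
  ux <- By %*% Cx %*% t(Bx); uy <- By %*% Cy %*% t(Bx)  # mm
  be <- bending_energy(Cx, Cy)
  fin <- {
    fld <- displacement_field(ux / px0, uy / px0, 1)
    sims <- numeric(2)
    for (ch in 1:2) {
      if (wf[ch] == 0) next
      mv <- if (ch == 1) nW$a else nF$a
      fx <- if (ch == 1) nW$b else nF$b
      sims[ch] <- similarity_grad(warp_image(mv, fld), fx, cfg)$value
    }
    sims
  }
  structure(list(field = displacement_field(ux, uy, px0),
                 cost = wf[1] * fin[1] + wf[2] * fin[2] + cfg$r * be$value,
                 sim_water = fin[1], sim_fat = fin[2], reg = be$value,
                 w = wf[1], r = cfg$r),
            class = "registration_result")
}

resize_lattice <- function(C, my, mx) {
  out <- matrix(0, my, mx)
  ry <- seq_len(min(my, nrow(C))); rx <- seq_len(min(mx, ncol(C)))
  out[ry, rx] <- C[ry, rx]
  out
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result cost %.5g = %.2g*%.4g + %.2g*%.4g + %.2g*%.4g>\n",
              x$cost, x$w, x$sim_water, 1 - x$w, x$sim_fat, x$r, x$reg))
  invisible(x)
}

#' Non-rigid motion model
#'
#' Ordered displacement fields, one per motion bin, in the pull-back
#' convention (reference coordinates to state coordinates, mm); the field
#' at the reference bin is identically zero.
#'
#' @param fields list of \code{displacement_field}
#' @param reference reference bin index
#' @param type "respiratory", "cardiac" or "cardiorespiratory"
#' @param thresholds respiratory amplitude thresholds carried over from the
#'   binning (for extension beyond the MR window)
#' @param belt_shift global belt time shift, s
#' @export
motion_model <- function(fields, reference, type, thresholds = NULL,
                         belt_shift = 0) {
  stopifnot(length(fields) >= 1, reference >= 1, reference <= length(fields))
  if (!is_zero_field(fields[[reference]], tol = 1e-9))
    stop("motion model: reference-bin field must be zero")
  structure(list(fields = fields, reference = reference, type = type,
                 thresholds = thresholds, belt_shift = belt_shift),
            class = "motion_model")
}

#' @export
print.motion_model <- function(x, ...) {
  mags <- vapply(x$fields, function(f) max(sqrt(f$ux^2 + f$uy^2)), 0)
  cat(sprintf("<motion_model %s, %d bins, ref %d, max |u| %.2f mm>\n",
              x$type, length(x$fields), x$reference, max(mags)))
  invisible(x)
}

#' Identity (all-zero) motion model
#' @param n_bins number of bins
#' @param dim grid dimensions
#' @param pixel_size mm
#' @param type model type tag
#' @export
identity_model <- function(n_bins, dim, pixel_size, type = "respiratory") {
  motion_model(replicate(n_bins, zero_field(dim, pixel_size), simplify = FALSE),
               reference = 1L, type = type)
}

#' Build a motion model from a motion-resolved image series
#'
#' Registers every bin image to the reference bin image. Bins flagged empty
#' receive a copy of the nearest nonempty neighbour's field (flagged in the
#' result's \code{copied} attribute).
#'
#' With \code{temporal_model = "amplitude"} the per-bin fields are
#' projected onto a surrogate-scaled model: one spatial deformation
#' pattern scaled by each bin's amplitude relative to the reference
#' (least-squares fit over bins). Respiratory motion is
#' amplitude-proportional to good approximation, and the projection
#' suppresses the incoherent per-bin errors that independent
#' registrations of undersampled bin images produce.
#' \code{temporal_model = "cyclic"} instead applies a cyclic [1, 2, 1]/4
#' smoothing across neighbouring bins (appropriate for cardiac phases).
#'
#' @param series list of \code{waterfat_image}, one per bin
#' @param reference reference bin index
#' @param config a \code{registration_config}
#' @param type model type tag
#' @param thresholds optional respiratory thresholds to carry
#' @param temporal_model "none", "amplitude" or "cyclic"
#' @param amplitudes per-bin surrogate amplitudes (required for
#'   \code{temporal_model = "amplitude"})
#' @return a \code{\link{motion_model}}
#' @export
build_model <- function(series, reference, config = registration_config(),
                        type = "respiratory", thresholds = NULL,
                        temporal_model = c("none", "amplitude", "cyclic"),
                        amplitudes = NULL) {
  temporal_model <- match.arg(temporal_model)
  stopifnot(length(series) >= 2)
  dim <- dim(series[[reference]]$water)
  px <- series[[reference]]$pixel_size
  empty <- vapply(series, function(s) isTRUE(attr(s, "empty")), FALSE)
  if (empty[reference]) stop("reference bin is empty")
  fields <- vector("list", length(series))
  fields[[reference]] <- zero_field(dim, px)
  for (b in seq_along(series)) {
    if (b == reference || empty[b]) next
    fields[[b]] <- register_pair(series[[b]], series[[reference]], config)$field
  }
  copied <- integer(0)
  if (any(empty)) {
    nonempty <- which(!empty)
    for (b in which(empty)) {
      nb <- nonempty[which.min(abs(nonempty - b))]
      fields[[b]] <- fields[[nb]]
      copied <- c(copied, b)
    }
  }
  if (temporal_model == "amplitude") {
    if (is.null(amplitudes) || length(amplitudes) != length(series))
      stop("temporal_model = 'amplitude' needs one amplitude per bin")
    a <- amplitudes - amplitudes[reference]
    den <- sum(a^2)
    if (den > 0) {
      Ux <- Uy <- matrix(0, dim[1], dim[2])
      for (b in seq_along(fields)) {
        if (b == reference) next
        Ux <- Ux + a[b] * fields[[b]]$ux
        Uy <- Uy + a[b] * fields[[b]]$uy
      }
      Ux <- Ux / den; Uy <- Uy / den
      for (b in seq_along(fields))
        fields[[b]] <- displacement_field(a[b] * Ux, a[b] * Uy, px)
    }
  } else if (temporal_model == "cyclic") {
    n <- length(fields)
    sm <- fields
    for (j in seq_len(n)) {
      jm <- ((j - 2) %% n) + 1; jp <- (j %% n) + 1
      sm[[j]] <- displacement_field(
        (fields[[jm]]$ux + 2 * fields[[j]]$ux + fields[[jp]]$ux) / 4,
        (fields[[jm]]$uy + 2 * fields[[j]]$uy + fields[[jp]]$uy) / 4, px)
    }
    sm[[reference]] <- zero_field(dim, px)
    fields <- sm
  }
  m <- motion_model(fields, reference, type, thresholds)
  attr(m, "copied") <- copied
  attr(m, "temporal_model") <- temporal_model
  m
}

#' Choose the respiratory reference state
#'
#' Returns the half-range of the belt amplitude (below or above the
#' midpoint of its extremes) containing more samples; ties break to
#' end-exhale.
#'
#' @param belt belt values inside the MR window
#' @return "end_exhale" or "end_inhale"
#' @export
select_reference <- function(belt) {
  if (length(belt) == 0) stop("select_reference: empty belt")
  mid <- (min(belt) + max(belt)) / 2
  n_lo <- sum(belt < mid)
  n_hi <- sum(belt > mid)
  if (n_hi > n_lo) "end_inhale" else "end_exhale"
}

#' Concatenate respiratory and cardiac motion models
#'
#' For every bin pair (i, j) the combined field is the composition with the
#' cardiac transformation innermost:
#' \code{m_cr(x) = m_card_j(x) + m_resp_i(x + m_card_j(x))}. Bins are
#' ordered respiratory-major: combined index \code{(i-1)*n_card + j}.
#'
#' @param resp respiratory \code{motion_model}
#' @param card cardiac \code{motion_model}
#' @return a cardiorespiratory \code{motion_model} with
#'   \code{n_resp * n_card} bins
#' @export
concatenate_models <- function(resp, card) {
  stopifnot(inherits(resp, "motion_model"), inherits(card, "motion_model"))
  d1 <- dim(resp$fields[[1]]$ux); d2 <- dim(card$fields[[1]]$ux)
  if (!all(d1 == d2) ||
      !isTRUE(all.equal(resp$fields[[1]]$pixel_size, card$fields[[1]]$pixel_size)))
    stop("concatenate: grid mismatch")
  nr <- length(resp$fields); nc <- length(card$fields)
  fields <- vector("list", nr * nc)
  for (i in seq_len(nr))
    for (j in seq_len(nc))
      fields[[(i - 1) * nc + j]] <- compose_fields(resp$fields[[i]], card$fields[[j]])
  ref <- (resp$reference - 1) * nc + card$reference
  # the composed reference field may carry interpolation dust; pin it to zero
  fields[[ref]] <- zero_field(d1, resp$fields[[1]]$pixel_size)
  motion_model(fields, ref, "cardiorespiratory",
               thresholds = resp$thresholds, belt_shift = resp$belt_shift)
}

#' Combined cardiorespiratory bin index
#' @param resp_bin,card_bin individual bin indices
#' @param n_card number of cardiac bins
#' @export
crbin_index <- function(resp_bin, card_bin, n_card) {
  (resp_bin - 1L) * n_card + card_bin
}

#' Align the belt signal to the MR self-navigator
#'
#' Finds the time shift of the belt trace maximising the normalised
#' cross-correlation with the self-navigator over the overlapping support;
#' the shift is then applied globally to the belt when extending the motion
#' model beyond the MR window. The search range must not exceed half the
#' overlap.
#'
#' @param time common time axis, s
#' @param belt,selfnav surrogate traces on \code{time}
#' @param max_shift search half-range, s (should not exceed one
#'   respiratory period)
#' @return shift in seconds; positive means the belt lags the navigator,
#'   and \code{belt(t - shift)} is the aligned trace
#' @export
align_belt <- function(time, belt, selfnav, max_shift = 4) {
  stopifnot(length(time) == length(belt), length(belt) == length(selfnav))
  span <- diff(range(time))
  if (max_shift > span / 2) stop("align_belt: search range exceeds half the overlap")
  dt <- stats::median(diff(time))
  shifts <- seq(-max_shift, max_shift, by = dt)
  cc <- vapply(shifts, function(s) {
    b <- interp_trace(time, belt, time - s)
    keep <- time - s >= min(time) & time - s <= max(time)
    if (sum(keep) < 10) return(-Inf)
    suppressWarnings(stats::cor(b[keep], selfnav[keep]))
  }, 0)
  # near-periodic signals tie at period-shifted aliases; prefer the
  # physiologically small shift. Constant traces have no defined maximum.
  cc[is.na(cc)] <- -Inf
  if (all(!is.finite(cc))) return(0)
  best <- which(cc >= max(cc) - 1e-12)
  shifts[best[which.min(abs(shifts[best]))]]
}

#' Map arbitrary timestamps to motion bins beyond the MR window
#'
#' Applies the stored respiratory amplitude thresholds to the
#' globally-shifted belt signal and the ECG phase rule to assign every
#' timestamp a (respiratory, cardiac) bin pair, extending the motion model
#' over the full scan. Amplitudes outside the MR-window range clamp to the
#' edge bins and are counted.
#'
#' @param thresholds respiratory amplitude thresholds (from
#'   \code{\link{bin_kspace}})
#' @param surrogates a \code{surrogate_set}
#' @param t timestamps, s
#' @param shift global belt time shift from \code{\link{align_belt}}, s
#' @param n_card number of cardiac bins
#' @return data frame with \code{resp_bin}, \code{card_bin},
#'   \code{clamped}; the clamp count is in attribute \code{n_clamped}
#' @export
extend_mapper <- function(thresholds, surrogates, t, shift = 0, n_card = 12L) {
  belt <- interp_trace(surrogates$time, surrogates$belt, t - shift)
  resp_bin <- findInterval(belt, thresholds) + 1L
  clamped <- belt < min(surrogates$belt) | belt > max(surrogates$belt)
  phase <- cardiac_phase_at(t, surrogates$rpeaks)
  card_bin <- pmin(floor(phase * n_card), n_card - 1L) + 1L
  out <- data.frame(resp_bin = resp_bin, card_bin = card_bin, clamped = clamped)
  attr(out, "n_clamped") <- sum(clamped)
  out
}

#' Write a motion model as per-bin NIfTI displacement fields plus YAML
#' @param model a \code{motion_model}
#' @param dir output directory
#' @export
write_motion_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  px <- model$fields[[1]]$pixel_size
  for (b in seq_along(model$fields)) {
    write_map_nifti(model$fields[[b]]$ux,
                    file.path(dir, sprintf("field_%03d_ux.nii.gz", b)), px)
    write_map_nifti(model$fields[[b]]$uy,
                    file.path(dir, sprintf("field_%03d_uy.nii.gz", b)), px)
  }
  yaml::write_yaml(list(type = model$type, reference = model$reference,
                        convention = "reference-to-state, mm",
                        thresholds = as.numeric(model$thresholds),
                        belt_shift = model$belt_shift),
                   file.path(dir, "motion_model.yaml"))
  invisible(dir)
}
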