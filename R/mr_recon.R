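#' Motion-binning specification
#'
#' Respiratory bins are equal-count amplitude quantiles of the belt signal
#' (balancing per-bin undersampling); cardiac bins are equal-width fractions
#' of the RR interval.
#'
#' @param n_resp number of respiratory bins
#' @param n_card number of cardiac bins
#' @export
binning_spec <- function(n_resp = 6L, n_card = 12L) {
  if (n_resp < 1 || n_card < 1) stop("binning spec: bin counts must be >= 1")
  structure(list(n_resp = as.integer(n_resp), n_card = as.integer(n_card),
                 resp_scheme = "equal_count", card_scheme = "equal_width"),
            class = "binning_spec")
}

#' Bin k-space spokes by surrogate motion state
#'
#' Respiratory mode assigns each spoke to one of \code{n_resp} equal-count
#' amplitude bins of the belt values at the spoke timestamps (thresholds
#' are stored for reuse outside the MR window); cardiac mode assigns spokes
#' to \code{n_card} equal-width cardiac-phase bins, with phase measured as
#' the elapsed fraction of the current RR interval. Spokes before the first
#' R-peak wrap around the first interval. Empty bins are retained with a
#' warning.
#'
#' @param kspace an \code{mr_kspace}
#' @param surrogates a \code{surrogate_set}
#' @param spec a \code{\link{binning_spec}}
#' @param mode "respiratory" or "cardiac"
#' @return object of class \code{binned_kspace}: \code{kspace},
#'   \code{bin_of} (bin id per spoke), \code{spokes} (list of spoke index
#'   vectors), \code{occupancy}, \code{thresholds} (respiratory mode),
#'   \code{mode}
#' @export
bin_kspace <- function(kspace, surrogates, spec, mode = c("respiratory", "cardiac")) {
  mode <- match.arg(mode)
  stopifnot(inherits(kspace, "mr_kspace"), inherits(surrogates, "surrogate_set"))
  tt <- kspace$trajectory$times
  if (min(tt) < min(surrogates$time) - 1e-9 || max(tt) > max(surrogates$time) + 1e-9)
    stop("spoke timestamps outside surrogate support")
  thresholds <- NULL
  if (mode == "respiratory") {
    n <- spec$n_resp
    belt <- interp_trace(surrogates$time, surrogates$belt, tt)
    thresholds <- stats::quantile(belt, probs = seq_len(n - 1) / n, names = FALSE)
    bin_of <- findInterval(belt, thresholds) + 1L
  } else {
    n <- spec$n_card
    phase <- cardiac_phase_at(tt, surrogates$rpeaks)
    bin_of <- pmin(floor(phase * n), n - 1L) + 1L
  }
  spokes <- lapply(seq_len(n), function(b) which(bin_of == b))
  occ <- lengths(spokes)
  if (any(occ == 0))
    warning(sprintf("%d empty %s bin(s) retained", sum(occ == 0), mode))
  structure(list(kspace = kspace, bin_of = bin_of, spokes = spokes,
                 occupancy = occ, thresholds = thresholds, mode = mode,
                 spec = spec),
            class = "binned_kspace")
}

#' Water/fat image pair for one motion state
#' @param water,fat complex image matrices
#' @param bin_id integer bin id or "reference"
#' @param pixel_size mm
#' @export
waterfat_image <- function(water, fat, bin_id, pixel_size) {
  stopifnot(all(dim(water) == dim(fat)))
  if (!all(is.finite(Mod(water))) || !all(is.finite(Mod(fat))))
    stop("waterfat_image must be finite")
  structure(list(water = water, fat = fat, bin_id = bin_id,
                 pixel_size = pixel_size),
            class = "waterfat_image")
}

#' @export
print.waterfat_image <- function(x, ...) {
  cat(sprintf("<waterfat_image bin %s, %dx%d px, mean |W| %.3g |F| %.3g>\n",
              as.character(x$bin_id), nrow(x$water), ncol(x$water),
              mean(Mod(x$water)), mean(Mod(x$fat))))
  invisible(x)
}

#' Iterative water/fat reconstruction configuration
#'
#' @param iterations conjugate-gradient (CGLS) iterations
#' @param tol relative normal-equation residual for early stopping
#' @param lambda quadratic (Tikhonov) regularisation weight, relative to
#'   the scale of the normal operator
#' @param density_compensation solve the ramp-weighted least-squares
#'   problem (radial sampling-density compensation); greatly accelerates
#'   convergence and leaves the solution of consistent (noiseless) data
#'   unchanged
#' @export
mr_recon_config <- function(iterations = 30L, tol = 1e-8, lambda = 1e-3,
                            density_compensation = TRUE) {
  if (iterations < 1) stop("mr recon config: iterations must be >= 1")
  if (lambda < 0) stop("mr recon config: lambda must be >= 0")
  structure(list(iterations = as.integer(iterations), tol = tol,
                 lambda = lambda,
                 density_compensation = isTRUE(density_compensation)),
            class = "mr_recon_config")
}

warp_c <- function(img, field) {
  if (is.complex(img))
    warp_image(Re(img), field) + 1i * warp_image(Im(img), field)
  else warp_image(img, field)
}
warp_adj_c <- function(img, field) {
  if (is.complex(img))
    warp_adjoint(Re(img), field) + 1i * warp_adjoint(Im(img), field)
  else warp_adjoint(img, field)
}

# CGLS on min ||A x - b||^2 + lambda ||x||^2 for x = list(W, F).
# A_fwd(x) -> list of data blocks; A_adj(blocks) -> list(W, F).
cgls_wf <- function(A_fwd, A_adj, b, dim, lambda, iterations, tol) {
  zero <- matrix(0i, dim[1], dim[2])
  x <- list(W = zero, F = zero)
  r <- b
  s <- A_adj(r)
  gamma <- sum(Mod(s$W)^2) + sum(Mod(s$F)^2)
  gamma0 <- gamma
  p <- s
  resid <- numeric(0)
  converged <- FALSE
  for (it in seq_len(iterations)) {
    q <- A_fwd(p)
    delta <- sum(vapply(q, function(m) sum(Mod(m)^2), 0)) +
      lambda * (sum(Mod(p$W)^2) + sum(Mod(p$F)^2))
    if (delta == 0) { converged <- TRUE; break }
    alpha <- gamma / delta
    x$W <- x$W + alpha * p$W
    x$F <- x$F + alpha * p$F
    r <- mapply(function(rb, qb) rb - alpha * qb, r, q, SIMPLIFY = FALSE)
    s <- A_adj(r)
    s$W <- s$W - lambda * x$W
    s$F <- s$F - lambda * x$F
    gnew <- sum(Mod(s$W)^2) + sum(Mod(s$F)^2)
    resid <- c(resid, sqrt(sum(vapply(r, function(m) sum(Mod(m)^2), 0)) +
                             lambda * (sum(Mod(x$W)^2) + sum(Mod(x$F)^2))))
    if (gnew <= tol^2 * gamma0) { converged <- TRUE; break }
    beta <- gnew / gamma
    gamma <- gnew
    p <- list(W = s$W + beta * p$W, F = s$F + beta * p$F)
  }
  list(x = x, resid = resid, converged = converged)
}

#' Reconstruct water/fat images from binned k-space
#'
#' Solves the linear least-squares problem for the complex water and fat
#' images under the encoding model: optional warp of the reference images
#' into each bin's motion state, chemical-shift mixing per echo, and radial
#' Fourier sampling on that bin's spokes; conjugate-gradient (CGLS) solver
#' with quadratic regularisation. Without a motion model each nonempty bin
#' is reconstructed independently (motion-resolved series); with a motion
#' model all bins jointly determine a single reference-state image.
#'
#' @param binned a \code{\link{bin_kspace}} result
#' @param config an \code{\link{mr_recon_config}}
#' @param motion optional \code{motion_model} whose bins match the binning
#' @return a list of \code{waterfat_image} (one per bin), or a single
#'   reference \code{waterfat_image} when \code{motion} is supplied.
#'   Solver diagnostics are attached as attributes \code{resid} and
#'   \code{converged}.
#' @export
reconstruct_waterfat <- function(binned, config = mr_recon_config(),
                                 motion = NULL) {
  stopifnot(inherits(binned, "binned_kspace"))
  ks <- binned$kspace
  if (all(binned$occupancy == 0)) stop("all bins are empty")
  traj <- ks$trajectory
  dim <- ks$grid
  ce <- echo_coeffs(ks$config)
  ne <- length(ce)

  recon_one <- function(spoke_idx, inv_fields = NULL) {
    # data blocks: one per (bin-chunk, echo); here a single chunk unless
    # motion-resolved joint recon
    nbins <- dim[2]
    # ramp (density-compensation) weights along the spoke; sqrt applied on
    # both data and operator so the weighted LS problem stays symmetric
    sw <- if (config$density_compensation) {
      w <- abs(traj$k)
      w <- pmax(w, min(w[w > 0]) / 2)
      sqrt(w / mean(w))
    } else rep(1, length(traj$k))
    D <- spoke_dft_matrix(traj, nbins) * sw
    DH <- Conj(t(D))
    # forward: project W and F once per bin, mix echoes in k-space;
    # adjoint: combine echoes in k-space first, then backproject twice
    if (is.null(inv_fields)) {
      b <- lapply(seq_len(ne), function(e)
        ks$data[[e]][, spoke_idx, drop = FALSE] * sw)
      ang <- traj$angles[spoke_idx]
      A_fwd <- function(x) {
        PW <- D %*% proj_forward_c(x$W, ang, nbins)
        PF <- D %*% proj_forward_c(x$F, ang, nbins)
        lapply(seq_len(ne), function(e) PW + ce[e] * PF)
      }
      A_adj <- function(blocks) {
        YW <- Reduce(`+`, blocks)
        YF <- Reduce(`+`, Map(function(e, blk) Conj(ce[e]) * blk,
                              seq_len(ne), blocks))
        list(W = proj_adjoint_c(DH %*% YW, ang, dim[1], dim[2]),
             F = proj_adjoint_c(DH %*% YF, ang, dim[1], dim[2]))
      }
    } else {
      nb <- length(spoke_idx)  # list of spoke index vectors per bin
      b <- list()
      for (bi in seq_len(nb))
        for (e in seq_len(ne))
          b[[(bi - 1) * ne + e]] <- ks$data[[e]][, spoke_idx[[bi]], drop = FALSE] * sw
      angs <- lapply(spoke_idx, function(ix) traj$angles[ix])
      A_fwd <- function(x) {
        out <- vector("list", nb * ne)
        for (bi in seq_len(nb)) {
          Wb <- warp_c(x$W, inv_fields[[bi]])
          Fb <- warp_c(x$F, inv_fields[[bi]])
          PW <- D %*% proj_forward_c(Wb, angs[[bi]], nbins)
          PF <- D %*% proj_forward_c(Fb, angs[[bi]], nbins)
          for (e in seq_len(ne))
            out[[(bi - 1) * ne + e]] <- PW + ce[e] * PF
        }
        out
      }
      A_adj <- function(blocks) {
        W <- matrix(0i, dim[1], dim[2]); F <- W
        for (bi in seq_len(nb)) {
          blk <- blocks[((bi - 1) * ne + 1):(bi * ne)]
          YW <- Reduce(`+`, blk)
          YF <- Reduce(`+`, Map(function(e, bb) Conj(ce[e]) * bb,
                                seq_len(ne), blk))
          accW <- proj_adjoint_c(DH %*% YW, angs[[bi]], dim[1], dim[2])
          accF <- proj_adjoint_c(DH %*% YF, angs[[bi]], dim[1], dim[2])
          W <- W + warp_adj_c(accW, inv_fields[[bi]])
          F <- F + warp_adj_c(accF, inv_fields[[bi]])
        }
        list(W = W, F = F)
      }
    }
    # relative Tikhonov weight: lambda times a Rayleigh-quotient estimate
    # of ||A^H A||, so the regulariser scale tracks the operator scale
    lam <- 0
    if (config$lambda > 0) {
      ahb <- A_adj(b)
      nrm2 <- sum(Mod(ahb$W)^2) + sum(Mod(ahb$F)^2)
      if (nrm2 > 0) {
        q <- A_fwd(ahb)
        lam <- config$lambda *
          sum(vapply(q, function(m) sum(Mod(m)^2), 0)) / nrm2
      }
    }
    sol <- cgls_wf(A_fwd, A_adj, b, dim, lam, config$iterations, config$tol)
    if (!sol$converged && config$tol > 0)
      warning(sprintf("CGLS did not reach tol within %d iterations (residual %.3g)",
                      config$iterations, utils::tail(sol$resid, 1)))
    sol
  }

  if (is.null(motion)) {
    out <- vector("list", length(binned$spokes))
    for (bi in seq_along(binned$spokes)) {
      if (binned$occupancy[bi] == 0) {
        z <- matrix(0i, dim[1], dim[2])
        wf <- waterfat_image(z, z, bi, ks$pixel_size)
        attr(wf, "empty") <- TRUE
        out[[bi]] <- wf
        next
      }
      sol <- recon_one(binned$spokes[[bi]])
      wf <- waterfat_image(sol$x$W, sol$x$F, bi, ks$pixel_size)
      attr(wf, "resid") <- sol$resid
      attr(wf, "converged") <- sol$converged
      out[[bi]] <- wf
    }
    out
  } else {
    stopifnot(inherits(motion, "motion_model"))
    nb <- length(binned$spokes)
    if (length(motion$fields) != nb)
      stop("motion model bin count does not match binning")
    keep <- which(binned$occupancy > 0)
    inv_fields <- lapply(motion$fields[keep], invert_field)
    sol <- recon_one(binned$spokes[keep], inv_fields)
    wf <- waterfat_image(sol$x$W, sol$x$F, "reference", ks$pixel_size)
    attr(wf, "resid") <- sol$resid
    attr(wf, "converged") <- sol$converged
    wf
  }
}

#' Density-compensated gridding reconstruction (adjoint with ramp weights)
#'
#' Fast approximate per-echo reconstruction used for sanity checks and
#' initialisation: the encoding adjoint applied to ramp-weighted k-space.
#'
#' @param kspace an \code{mr_kspace}
#' @param echo which echo
#' @param spoke_idx subset of spokes (default all)
#' @export
gridding_recon <- function(kspace, echo = 1, spoke_idx = NULL) {
  traj <- kspace$trajectory
  if (is.null(spoke_idx)) spoke_idx <- seq_along(traj$angles)
  w <- pmax(abs(traj$k), min(abs(traj$k)[abs(traj$k) > 0]) / 2)
  y <- kspace$data[[echo]][, spoke_idx, drop = FALSE] * w
  mr_encode_adjoint(y, traj, kspace$grid, spoke_idx)
}

#' Write a water/fat image pair as NIfTI volumes with a YAML sidecar
#' @param wf a \code{waterfat_image}
#' @param dir output directory
#' @param prefix file name prefix
#' @export
write_waterfat <- function(wf, dir, prefix = "wf") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  px <- wf$pixel_size
  write_map_nifti(Mod(wf$water), file.path(dir, paste0(prefix, "_water_mag.nii.gz")), px)
  write_map_nifti(Arg(wf$water), file.path(dir, paste0(prefix, "_water_phase.nii.gz")), px)
  write_map_nifti(Mod(wf$fat), file.path(dir, paste0(prefix, "_fat_mag.nii.gz")), px)
  write_map_nifti(Arg(wf$fat), file.path(dir, paste0(prefix, "_fat_phase.nii.gz")), px)
  yaml::write_yaml(list(bin_id = as.character(wf$bin_id), pixel_size_mm = px,
                        representation = "magnitude+phase"),
                   file.path(dir, paste0(prefix, "_meta.yaml")))
  invisible(dir)
}
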