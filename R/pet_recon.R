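#' OSEM reconstruction configuration
#'
#' Ordered-subset expectation maximisation with interleaved angle subsets.
#' When the subset count does not divide the angle count the subsets are
#' interleaved strata of two neighbouring sizes (e.g. 21 subsets over 180
#' angles gives strata of 9 and 8).
#'
#' @param subsets number of angle subsets
#' @param iterations full iterations (each visits every subset once)
#' @param postfilter_fwhm Gaussian post-filter FWHM, mm (0 disables)
#' @param epsilon nonnegativity guard added to denominators
#' @export
osem_config <- function(subsets = 21L, iterations = 3L, postfilter_fwhm = 4,
                        epsilon = 1e-10) {
  if (iterations < 1) stop("osem config: iterations must be >= 1")
  if (subsets < 1) stop("osem config: subsets must be >= 1")
  structure(list(subsets = as.integer(subsets),
                 iterations = as.integer(iterations),
                 postfilter_fwhm = postfilter_fwhm, epsilon = epsilon),
            class = "osem_config")
}

# interleaved angle subsets: subset s takes angles s, s+S, s+2S, ...
osem_subsets <- function(n_angles, n_subsets) {
  lapply(seq_len(n_subsets), function(s) seq(s, n_angles, by = n_subsets))
}

#' Reconstructed PET image
#' @param data non-negative activity matrix
#' @param units "activity" or "SUV"
#' @param mode "AVG", "r-MCIR" or "cr-MCIR"
#' @param pixel_size mm
#' @param config snapshot of the \code{osem_config} used
#' @export
pet_image <- function(data, units, mode, pixel_size, config = NULL) {
  if (any(!is.finite(data)) || any(data < 0))
    stop("pet image must be finite and non-negative")
  structure(list(data = data, units = units, mode = mode,
                 pixel_size = pixel_size, config = config),
            class = "pet_image")
}

#' @export
print.pet_image <- function(x, ...) {
  cat(sprintf("<pet_image %s [%s], %dx%d px, max %.3g>\n",
              x$mode, x$units, nrow(x$data), ncol(x$data), max(x$data)))
  invisible(x)
}

fov_mask <- function(dim) {
  ny <- dim[1]; nx <- dim[2]
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  r <- min(ny, nx) / 2
  outer(seq_len(ny), seq_len(nx),
        function(i, j) ((i - cy)^2 + (j - cx)^2) <= r^2)
}

#' Motion-averaged OSEM reconstruction
#'
#' All bins are summed into one sinogram and reconstructed with standard
#' OSEM; attenuation factors from the supplied reference mu-map enter the
#' system model. Initialisation is uniform inside the field-of-view
#' circle. The Gaussian post-filter is applied after the final iteration.
#'
#' @param sinos a \code{sinogram_set}
#' @param mu_ref reference \code{mu_map}
#' @param config an \code{\link{osem_config}}
#' @return a \code{\link{pet_image}} (mode "AVG")
#' @export
osem_avg <- function(sinos, mu_ref, config = osem_config()) {
  stopifnot(inherits(sinos, "sinogram_set"), inherits(mu_ref, "mu_map"))
  if (length(sinos$counts) == 0) stop("empty sinogram set")
  geom <- sinos$geometry
  y <- Reduce(`+`, sinos$counts)
  if (sum(y) == 0) stop("empty sinogram: no counts")
  scat <- if (!is.null(sinos$scatter)) sinos$scatter else 0
  dim <- sinos$grid
  subs <- osem_subsets(geom$n_angles, config$subsets)
  att <- attenuation_factors(mu_ref, geom)
  x <- matrix(0, dim[1], dim[2]); x[fov_mask(dim)] <- 1
  eps <- config$epsilon
  for (it in seq_len(config$iterations)) {
    for (sub in subs) {
      a <- att[, sub, drop = FALSE]
      q <- a * project(x, geom, sub) +
        (if (is.matrix(scat)) scat[, sub, drop = FALSE] else 0) + eps
      ratio <- y[, sub, drop = FALSE] / q
      num <- backproject(a * ratio, geom, dim, sub)
      sens <- backproject(a, geom, dim, sub)
      x <- x * num / (sens + eps)
    }
  }
  if (config$postfilter_fwhm > 0)
    x <- gaussian_smooth(x, config$postfilter_fwhm, sinos$pixel_size)
  pet_image(x, "activity", "AVG", sinos$pixel_size, config)
}

#' Motion-corrected OSEM reconstruction (MCIR)
#'
#' During each subset update the reference-frame image estimate is warped
#' into every occupied motion state, projected with that state's warped
#' attenuation map (weighted by the bin occupancy), and compared with that
#' bin's measured sinogram. The backprojected ratios pass through the warp
#' adjoint and are divided by the matching sensitivity image, yielding one
#' motion-free image consistent with all emission data.
#'
#' @param sinos a \code{sinogram_set}
#' @param model a \code{motion_model} whose (resp, card) lattice covers
#'   the sinogram bins
#' @param mu_ref reference-state \code{mu_map}
#' @param config an \code{\link{osem_config}}
#' @param mode tag recorded in the result ("cr-MCIR" by default)
#' @param dynamic_ac if TRUE (default) the reference mu-map is warped into
#'   each motion state along with the image estimate; if FALSE the
#'   supplied map attenuates every bin unchanged (a breath-hold-style
#'   static attenuation correction)
#' @return a \code{\link{pet_image}}
#' @export
osem_mcir <- function(sinos, model, mu_ref, config = osem_config(),
                      mode = "cr-MCIR", dynamic_ac = TRUE) {
  stopifnot(inherits(sinos, "sinogram_set"), inherits(model, "motion_model"),
            inherits(mu_ref, "mu_map"))
  geom <- sinos$geometry
  dim <- sinos$grid
  nb <- length(sinos$counts)
  if (any(sinos$bin_table$bin > length(model$fields)))
    stop("sinogram bin without a motion field")
  scat <- sinos$scatter
  # per-bin inverse fields (reference -> state warps) and warped mu maps
  inv_fields <- lapply(sinos$bin_table$bin, function(b) {
    f <- model$fields[[b]]
    if (is_zero_field(f)) f else invert_field(f)
  })
  atts <- lapply(seq_len(nb), function(i) {
    mu_b <- if (!dynamic_ac || is_zero_field(inv_fields[[i]])) mu_ref
    else warp_mu(mu_ref, inv_fields[[i]], sinos$bin_table$bin[i])
    attenuation_factors(mu_b, geom)
  })
  subs <- osem_subsets(geom$n_angles, config$subsets)
  x <- matrix(0, dim[1], dim[2]); x[fov_mask(dim)] <- 1
  eps <- config$epsilon
  occ <- sinos$occupancy
  for (it in seq_len(config$iterations)) {
    for (sub in subs) {
      num <- matrix(0, dim[1], dim[2])
      sens <- matrix(0, dim[1], dim[2])
      for (i in seq_len(nb)) {
        zf <- is_zero_field(inv_fields[[i]])
        xb <- if (zf) x else warp_image(x, inv_fields[[i]])
        a <- occ[i] * atts[[i]][, sub, drop = FALSE]
        q <- a * project(xb, geom, sub) +
          (if (is.matrix(scat)) occ[i] * scat[, sub, drop = FALSE] else 0) + eps
        ratio <- sinos$counts[[i]][, sub, drop = FALSE] / q
        bp_num <- backproject(a * ratio, geom, dim, sub)
        bp_sens <- backproject(a, geom, dim, sub)
        if (zf) {
          num <- num + bp_num
          sens <- sens + bp_sens
        } else {
          num <- num + warp_adjoint(bp_num, inv_fields[[i]])
          sens <- sens + warp_adjoint(bp_sens, inv_fields[[i]])
        }
      }
      x <- x * num / (sens + eps)
    }
  }
  if (config$postfilter_fwhm > 0)
    x <- gaussian_smooth(x, config$postfilter_fwhm, sinos$pixel_size)
  pet_image(x, "activity", mode, sinos$pixel_size, config)
}

#' Gaussian post-filter
#'
#' Convolution with a normalised Gaussian kernel of the requested FWHM
#' (sigma = FWHM / (2 sqrt(2 ln 2))), reflecting boundary; the image sum
#' is conserved.
#'
#' @param image a \code{pet_image}
#' @param fwhm mm; 0 returns the input unchanged
#' @export
postfilter <- function(image, fwhm) {
  stopifnot(inherits(image, "pet_image"))
  if (fwhm < 0) stop("postfilter: fwhm must be >= 0")
  if (fwhm == 0) return(image)
  image$data <- gaussian_smooth(image$data, fwhm, image$pixel_size)
  image
}

#' Convert a PET image to standardised uptake values
#'
#' SUV = concentration x body weight / injected dose; with consistent
#' units the transform is a global positive rescale, so ratio metrics
#' (TBR, CBR) are unaffected.
#'
#' @param image a \code{pet_image}
#' @param dose injected dose (activity units matching the image)
#' @param weight body weight (mass units matching the dose normalisation)
#' @export
to_suv <- function(image, dose, weight) {
  stopifnot(inherits(image, "pet_image"))
  if (dose <= 0) stop("to_suv: dose must be > 0")
  if (weight <= 0) stop("to_suv: weight must be > 0")
  image$data <- image$data * weight / dose
  image$units <- "SUV"
  image
}

#' Write a PET image as NIfTI plus a YAML sidecar
#' @param image a \code{pet_image}
#' @param dir output directory
#' @param prefix file prefix
#' @export
write_pet_image <- function(image, dir, prefix = "pet") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_map_nifti(image$data, file.path(dir, paste0(prefix, ".nii.gz")),
                  image$pixel_size)
  yaml::write_yaml(list(units = image$units, mode = image$mode,
                        pixel_size_mm = image$pixel_size),
                   file.path(dir, paste0(prefix, "_meta.yaml")))
  invisible(dir)
}
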