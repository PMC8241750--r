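#' @useDynLib petmoco, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Displacement field
#'
#' A dense 2D displacement field in millimetres, pull-back convention:
#' a field \code{u} attached to a grid maps reference coordinates \code{x}
#' to state coordinates \code{x + u(x)}; sampling a state image at
#' \code{x + u(x)} brings it back to the reference frame.
#'
#' @param ux,uy matrices of x (column) and y (row) displacement components, mm
#' @param pixel_size pixel edge length in mm
#' @return an object of class \code{displacement_field}
#' @export
displacement_field <- function(ux, uy, pixel_size) {
  stopifnot(is.matrix(ux), is.matrix(uy), all(dim(ux) == dim(uy)),
            is.finite(pixel_size), pixel_size > 0)
  if (!all(is.finite(ux)) || !all(is.finite(uy)))
    stop("displacement field must be finite")
  structure(list(ux = ux, uy = uy, pixel_size = pixel_size),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  mag <- sqrt(x$ux^2 + x$uy^2)
  cat(sprintf("<displacement_field %dx%d px, %.3g mm/px, |u| mean %.3g max %.3g mm>\n",
              nrow(x$ux), ncol(x$ux), x$pixel_size, mean(mag), max(mag)))
  invisible(x)
}

#' All-zero displacement field
#' @param dim grid dimensions c(ny, nx)
#' @param pixel_size mm
#' @export
zero_field <- function(dim, pixel_size) {
  z <- matrix(0, dim[1], dim[2])
  displacement_field(z, z, pixel_size)
}

#' Test whether a displacement field is (numerically) zero
#' @param field a \code{displacement_field}
#' @param tol per-component tolerance in mm
#' @export
is_zero_field <- function(field, tol = 0) {
  all(abs(field$ux) <= tol) && all(abs(field$uy) <= tol)
}

#' Warp an image by a displacement field
#'
#' Pull-back interpolation: \code{out(x) = img(x + u(x))}. Linear
#' interpolation for continuous images (out-of-grid samples read as
#' \code{fill}), nearest-neighbour for integer label maps.
#'
#' @param img numeric or integer matrix
#' @param field a \code{\link{displacement_field}} (mm)
#' @param method "linear" or "nearest"
#' @param fill fill value for out-of-grid samples (nearest mode)
#' @param clamp if TRUE, out-of-grid samples read the clamped edge value
#'   instead of zero (used for displacement-field algebra)
#' @return warped matrix of the same shape
#' @export
warp_image <- function(img, field, method = c("linear", "nearest"), fill = 0L,
                       clamp = FALSE) {
  method <- match.arg(method)
  stopifnot(all(dim(img) == dim(field$ux)))
  px <- field$pixel_size
  if (method == "nearest") {
    storage.mode(img) <- "integer"
    warp_nearest_cpp(img, field$ux / px, field$uy / px, as.integer(fill))
  } else {
    warp_pull_cpp(img, field$ux / px, field$uy / px, clamp)
  }
}

#' Adjoint of the linear-interpolation warp
#'
#' The exact matrix transpose of \code{\link{warp_image}} (linear mode):
#' interpolation weights are scattered rather than gathered. This is the
#' operator pair used inside iterative reconstructions; it is not the warp
#' along the inverse field.
#'
#' @inheritParams warp_image
#' @export
warp_adjoint <- function(img, field) {
  stopifnot(all(dim(img) == dim(field$ux)))
  px <- field$pixel_size
  warp_pull_adjoint_cpp(img, field$ux / px, field$uy / px)
}

#' Invert a displacement field
#'
#' Fixed-point inversion of \code{x -> x + u(x)}: finds \code{v} with
#' \code{v(y) = -u(y + v(y))}, valid when the deformation is a contraction
#' (displacement gradients below 1, true for all configured phantom
#' amplitudes).
#'
#' @param field a \code{displacement_field}
#' @param iterations fixed-point iterations
#' @return the inverse \code{displacement_field}
#' @export
invert_field <- function(field, iterations = 20) {
  px <- field$pixel_size
  vx <- -field$ux
  vy <- -field$uy
  for (i in seq_len(iterations)) {
    f <- displacement_field(vx, vy, px)
    vx <- -warp_image(field$ux, f, clamp = TRUE)
    vy <- -warp_image(field$uy, f, clamp = TRUE)
  }
  displacement_field(vx, vy, px)
}

#' Compose two displacement fields
#'
#' Returns the field of the composed map \code{x -> x + u_inner(x) +
#' u_outer(x + u_inner(x))}, i.e. \code{inner} applied first. Evaluation of
#' the outer field at displaced coordinates uses linear interpolation.
#'
#' @param outer,inner \code{displacement_field}s on the same grid
#' @export
compose_fields <- function(outer, inner) {
  if (!all(dim(outer$ux) == dim(inner$ux)) ||
      !isTRUE(all.equal(outer$pixel_size, inner$pixel_size)))
    stop("compose_fields: grid mismatch")
  ox <- warp_image(outer$ux, inner, clamp = TRUE)
  oy <- warp_image(outer$uy, inner, clamp = TRUE)
  displacement_field(inner$ux + ox, inner$uy + oy, outer$pixel_size)
}

#' Gaussian convolution kernel for a given FWHM
#' @param fwhm_mm full width at half maximum, mm
#' @param pixel_size pixel size, mm
#' @keywords internal
gaussian_kernel <- function(fwhm_mm, pixel_size) {
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / pixel_size
  if (sigma <= 0) return(1)
  h <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-h:h)^2) / (2 * sigma^2))
  k / sum(k)
}

#' Smooth a matrix with a Gaussian of given FWHM (reflecting boundary)
#' @param img matrix
#' @param fwhm_mm full width at half maximum, mm
#' @param pixel_size pixel size, mm
#' @export
gaussian_smooth <- function(img, fwhm_mm, pixel_size) {
  k <- gaussian_kernel(fwhm_mm, pixel_size)
  if (length(k) == 1) return(img)
  conv_sep_reflect_cpp(img, k)
}

smoothstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x * x * (3 - 2 * x)
}

# Deterministic derivation of per-module RNG streams from one master seed.
derive_seed <- function(seed, k) {
  as.integer(((as.numeric(seed) %% 2147483647) * 7919 + 104729 * k) %% 2147483647)
}

#' Linear interpolation of a uniformly sampled trace at arbitrary times
#' @param time sample times, s
#' @param values trace values at \code{time}
#' @param t query times, s (clamped to the trace support)
#' @export
interp_trace <- function(time, values, t) {
  stats::approx(time, values, xout = t, rule = 2)$y
}

#' Write a 2D map as a single-slice NIfTI volume
#' @param img matrix
#' @param path output path
#' @param pixel_size pixel size in mm, encoded in the NIfTI affine
#' @export
write_map_nifti <- function(img, path, pixel_size) {
  arr <- array(img, dim = c(dim(img), 1L))
  RNifti::writeNifti(RNifti::asNifti(arr, pixdim = c(pixel_size, pixel_size, 1)),
                     file = path)
  invisible(path)
}

#' Read a 2D map stored as a single-slice NIfTI volume
#' @param path NIfTI file
#' @export
read_map_nifti <- function(path) {
  arr <- RNifti::readNifti(path)
  matrix(arr[, , 1], nrow = dim(arr)[1], ncol = dim(arr)[2])
}
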