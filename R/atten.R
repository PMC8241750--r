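#' Attenuation tissue class codes
#'
#' Classes of the 4-tissue attenuation map: air 0, lung 1, fat 2, soft 3.
#' @export
ac_classes <- c(air = 0L, lung = 1L, fat = 2L, soft = 3L)

#' Attenuation coefficients per tissue class
#'
#' Linear attenuation coefficients at 511 keV in 1/cm. Defaults are
#' standard literature values for PET attenuation correction.
#'
#' @param air,lung,fat,soft class coefficients, 1/cm
#' @export
mu_assignment <- function(air = 0.0, lung = 0.0224, fat = 0.0864, soft = 0.0975) {
  tab <- c(air = air, lung = lung, fat = fat, soft = soft)
  if (any(tab < 0)) stop("mu values must be >= 0")
  if (!(soft > fat && fat > lung && lung >= air))
    stop("mu ordering must satisfy soft > fat > lung > air")
  structure(tab, class = "mu_assignment")
}

#' Segment a water/fat image into the 4 attenuation tissue classes
#'
#' k-means (k = 4) clustering in the (|water|, |fat|) feature plane.
#' Initial centroids are chosen deterministically from the joint feature
#' histogram: every 4-subset of the highest-mass histogram bins is scored
#' by a weighted Lloyd pass and the lowest-inertia seeding wins (a plain
#' farthest-point seeding routinely places two seeds inside the broad
#' soft-tissue mode and merges air with lung). The winning centroids then
#' initialise \code{stats::kmeans} on the full data. Cluster identities
#' are assigned post hoc from the centroids: air is the smallest
#' total-magnitude centroid, lung the second smallest, and of the two
#' remaining the one with the larger fat fraction is fat.
#'
#' @param image a \code{waterfat_image}
#' @param seed RNG seed (tie-breaking only; the procedure is deterministic)
#' @return object of class \code{tissue_class_map}: \code{classes}
#'   (integer matrix of \code{\link{ac_classes}} codes), \code{centroids}
#'   (4 x 2), \code{pixel_size}
#' @export
segment_tissues <- function(image, seed = 1L) {
  stopifnot(inherits(image, "waterfat_image"))
  W <- Mod(image$water); F <- Mod(image$fat)
  if (!all(is.finite(W)) || !all(is.finite(F))) stop("non-finite magnitudes")
  feats <- cbind(as.vector(W), as.vector(F))
  if (nrow(unique(feats)) < 4)
    stop("fewer than 4 distinct feature values; cannot segment")
  set.seed(derive_seed(seed, 3L))
  init <- histogram_kmeans_seeds(feats, k = 4L, nbins = 48L, top = 12L)
  km <- stats::kmeans(feats, centers = init, iter.max = 100)
  cen <- km$centers
  tot <- rowSums(cen)
  ord <- order(tot)
  ident <- integer(4)
  ident[ord[1]] <- ac_classes[["air"]]
  ident[ord[2]] <- ac_classes[["lung"]]
  rest <- ord[3:4]
  fatfrac <- cen[rest, 2] / pmax(rowSums(cen[rest, , drop = FALSE]), 1e-12)
  ident[rest[which.max(fatfrac)]] <- ac_classes[["fat"]]
  ident[rest[which.min(fatfrac)]] <- ac_classes[["soft"]]
  classes <- matrix(ident[km$cluster], nrow(W), ncol(W))
  storage.mode(classes) <- "integer"
  cen_named <- cen[order(ident[seq_len(4)]), , drop = FALSE]
  rownames(cen_named) <- names(sort(ac_classes))
  colnames(cen_named) <- c("W", "F")
  structure(list(classes = classes, centroids = cen_named,
                 pixel_size = image$pixel_size),
            class = "tissue_class_map")
}

#' @export
print.tissue_class_map <- function(x, ...) {
  tab <- table(factor(x$classes, levels = ac_classes, labels = names(ac_classes)))
  cat("<tissue_class_map ", paste(names(tab), tab, sep = ":", collapse = " "), ">\n")
  invisible(x)
}

# Deterministic k-means seeding from the 2D feature histogram: weighted
# Lloyd over the binned features for every k-subset of the top-mass bins;
# the lowest-inertia subset provides the initial centroids.
histogram_kmeans_seeds <- function(feats, k = 4L, nbins = 48L, top = 12L) {
  rng <- apply(feats, 2, range)
  span <- pmax(rng[2, ] - rng[1, ], 1e-12)
  bx <- pmin(floor((feats[, 1] - rng[1, 1]) / span[1] * (nbins - 1)), nbins - 1)
  by <- pmin(floor((feats[, 2] - rng[1, 2]) / span[2] * (nbins - 1)), nbins - 1)
  key <- bx * nbins + by
  tab <- table(key)
  keys <- as.integer(names(tab))
  w <- as.numeric(tab)
  pts <- cbind(rng[1, 1] + (keys %/% nbins + 0.5) / nbins * span[1],
               rng[1, 2] + (keys %% nbins + 0.5) / nbins * span[2])
  # replace bin centres by the weighted mean of their members
  pts[, 1] <- vapply(keys, function(kk) mean(feats[key == kk, 1]), 0)
  pts[, 2] <- vapply(keys, function(kk) mean(feats[key == kk, 2]), 0)
  cand <- order(w, decreasing = TRUE)[seq_len(min(top, length(w)))]
  lloyd <- function(cen) {
    for (it in 1:25) {
      d <- outer(pts[, 1], cen[, 1], "-")^2 + outer(pts[, 2], cen[, 2], "-")^2
      a <- max.col(-d)
      for (j in seq_len(k)) {
        m <- a == j
        if (any(m)) cen[j, ] <- c(stats::weighted.mean(pts[m, 1], w[m]),
                                  stats::weighted.mean(pts[m, 2], w[m]))
      }
    }
    d <- outer(pts[, 1], cen[, 1], "-")^2 + outer(pts[, 2], cen[, 2], "-")^2
    list(cen = cen, inertia = sum(w * d[cbind(seq_len(nrow(d)), max.col(-d))]))
  }
  best <- NULL
  for (sub in utils::combn(cand, k, simplify = FALSE)) {
    res <- lloyd(pts[sub, , drop = FALSE])
    if (is.null(best) || res$inertia < best$inertia) best <- res
  }
  cen <- best$cen
  # guard against duplicate rows, which stats::kmeans rejects
  cen + outer(seq_len(k), c(1e-9, 1e-9))
}

# 4-connected components of a logical matrix (row, col flood fill)
label_components <- function(mask) {
  EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
}

#' Inpaint stent-induced signal voids in a tissue class map
#'
#' MR signal voids near metallic stents segment as air or lung inside the
#' body. Air/lung components that are fully enclosed by the hole-filled
#' body mask and smaller than \code{max_area_mm2} are reassigned to the
#' majority class of their one-pixel-dilated boundary ring. Lungs are left
#' untouched (large components). The operation is idempotent.
#'
#' @param tcm a \code{tissue_class_map}
#' @param max_area_mm2 maximum void area considered a stent artefact
#' @return the inpainted \code{tissue_class_map}
#' @export
inpaint_stent <- function(tcm, max_area_mm2 = 200) {
  stopifnot(inherits(tcm, "tissue_class_map"))
  cls <- tcm$classes
  px_area <- tcm$pixel_size^2
  body <- cls != ac_classes[["air"]]
  lab_body <- label_components(body)
  if (max(lab_body) == 0) return(tcm)
  sizes <- tabulate(lab_body[lab_body > 0])
  body_main <- lab_body == which.max(sizes)
  body_fill <- EBImage::fillHull(matrix(as.numeric(body_main), nrow(cls), ncol(cls))) > 0
  cand <- (cls == ac_classes[["air"]] | cls == ac_classes[["lung"]]) & body_fill
  lab <- label_components(cand)
  n <- max(lab)
  if (n == 0) return(tcm)
  out <- cls
  for (i in seq_len(n)) {
    comp <- lab == i
    area <- sum(comp) * px_area
    if (area > max_area_mm2) next
    # fully enclosed: no component pixel touches the complement of the
    # filled body mask (or the image border)
    ring <- EBImage::dilate(matrix(as.numeric(comp), nrow(cls), ncol(cls)),
                            EBImage::makeBrush(3, "box")) > 0
    if (any(ring & !body_fill)) next
    boundary <- ring & !comp
    votes <- table(out[boundary])
    votes <- votes[!(names(votes) %in% as.character(c(ac_classes[["air"]])))]
    if (length(votes) == 0) next
    out[comp] <- as.integer(names(votes)[which.max(votes)])
  }
  tcm$classes <- out
  tcm
}

#' Attenuation map
#' @param mu matrix of attenuation coefficients, 1/cm
#' @param pixel_size mm
#' @param provenance free-text provenance tag
#' @export
mu_map <- function(mu, pixel_size, provenance = "reference") {
  if (any(!is.finite(mu)) || any(mu < 0)) stop("mu map must be finite and >= 0")
  structure(list(mu = mu, pixel_size = pixel_size, provenance = provenance),
            class = "mu_map")
}

#' Assign attenuation coefficients to tissue classes
#' @param tcm a \code{tissue_class_map}
#' @param table a \code{\link{mu_assignment}}
#' @return a \code{\link{mu_map}}
#' @export
assign_mu <- function(tcm, table = mu_assignment()) {
  stopifnot(inherits(tcm, "tissue_class_map"))
  idx <- match(tcm$classes, ac_classes)
  if (any(is.na(idx))) stop("class missing from mu table")
  mu_map(matrix(table[idx], nrow(tcm$classes), ncol(tcm$classes)),
         tcm$pixel_size, "reference")
}

#' Warp an attenuation map along a displacement field
#'
#' Linear interpolation along the field; out-of-field samples fill with 0
#' (air).
#'
#' @param mu a \code{mu_map}
#' @param field a \code{displacement_field} on the same grid
#' @param bin_id provenance tag for the target bin
#' @export
warp_mu <- function(mu, field, bin_id = NULL) {
  stopifnot(inherits(mu, "mu_map"))
  if (!all(dim(mu$mu) == dim(field$ux))) stop("warp_mu: grid mismatch")
  out <- warp_image(mu$mu, field)
  out[out < 0] <- 0
  mu_map(out, mu$pixel_size,
         if (is.null(bin_id)) "warped" else paste0("warped-to-bin ", bin_id))
}
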