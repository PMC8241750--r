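#' Region-of-interest specification for plaque quantification
#'
#' Rectangles are pixel index bounds \code{c(r0, r1, c0, c1)} (inclusive).
#' The plaque ROI marks the hotspot; the background ROI samples the
#' left-ventricle blood pool and must be disjoint from the plaque ROI.
#' The profile line is given by two endpoints in mm (y, x relative to the
#' first pixel centre), perpendicular to the vessel.
#'
#' @param plaque plaque rectangle
#' @param background background rectangle
#' @param profile list with \code{p0}, \code{p1} (mm endpoints) and
#'   optional \code{n} samples (default 41)
#' @export
roi_spec <- function(plaque, background, profile = NULL) {
  stopifnot(length(plaque) == 4, length(background) == 4)
  if (plaque[1] > plaque[2] || plaque[3] > plaque[4] ||
      background[1] > background[2] || background[3] > background[4])
    stop("roi_spec: malformed rectangle")
  overlap <- !(plaque[2] < background[1] || background[2] < plaque[1] ||
                 plaque[4] < background[3] || background[4] < plaque[3])
  if (overlap) stop("roi_spec: plaque and background ROIs must be disjoint")
  if (!is.null(profile)) {
    stopifnot(length(profile$p0) == 2, length(profile$p1) == 2)
    if (is.null(profile$n)) profile$n <- 41L
  }
  structure(list(plaque = plaque, background = background, profile = profile),
            class = "roi_spec")
}

# exhaustive Otsu threshold on a small value set: maximises between-class
# variance over all splits; returns a threshold strictly between classes
otsu_threshold <- function(v) {
  u <- sort(unique(v))
  if (length(u) < 2) return(NA_real_)
  cand <- (u[-1] + u[-length(u)]) / 2
  bcv <- vapply(cand, function(th) {
    lo <- v[v <= th]; hi <- v[v > th]
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    w0 * w1 * (mean(lo) - mean(hi))^2
  }, 0)
  cand[which.max(bcv)]
}

#' Plaque signal from a 5x5 patch with Otsu foreground selection
#'
#' Locates the maximum-SUV pixel inside the plaque ROI, takes the 5x5
#' patch centred on it, computes an Otsu threshold over the patch values
#' and returns the mean of the values strictly above the threshold. A
#' constant patch returns its mean. The patch is clipped at the ROI: the
#' rectangle stands in for the observer's plaque delineation, and letting
#' the patch sample beyond it can capture adjacent bright structures (the
#' blood pool) instead of the plaque. Clipping at the image border is
#' additionally warned about.
#'
#' @param image a \code{pet_image}
#' @param roi plaque rectangle \code{c(r0, r1, c0, c1)}
#' @param aggregate "mean" (default) averages supra-threshold pixels;
#'   "max" returns the patch maximum
#' @return plaque signal s
#' @export
plaque_signal <- function(image, roi, aggregate = c("mean", "max")) {
  aggregate <- match.arg(aggregate)
  img <- image$data
  r <- roi[1]:roi[2]; c <- roi[3]:roi[4]
  if (min(r) < 1 || max(r) > nrow(img) || min(c) < 1 || max(c) > ncol(img))
    stop("plaque ROI outside image bounds")
  sub <- img[r, c, drop = FALSE]
  if (length(sub) == 0) stop("empty plaque ROI")
  pk <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  pr <- r[pk[1]]; pc <- c[pk[2]]
  at_border <- pr - 2 < 1 || pr + 2 > nrow(img) || pc - 2 < 1 || pc + 2 > ncol(img)
  if (at_border) warning("5x5 patch clipped at image border")
  rr <- max(1, roi[1], pr - 2):min(nrow(img), roi[2], pr + 2)
  cc <- max(1, roi[3], pc - 2):min(ncol(img), roi[4], pc + 2)
  patch <- as.vector(img[rr, cc])
  if (aggregate == "max") return(max(patch))
  th <- otsu_threshold(patch)
  if (is.na(th)) return(mean(patch))
  mean(patch[patch > th])
}

#' Background mean and standard deviation from the blood-pool ROI
#'
#' @param image a \code{pet_image}
#' @param roi background rectangle \code{c(r0, r1, c0, c1)}
#' @return c(b, sigma_b): mean and sample SD (n - 1)
#' @export
background_stats <- function(image, roi) {
  img <- image$data
  r <- roi[1]:roi[2]; c <- roi[3]:roi[4]
  if (min(r) < 1 || max(r) > nrow(img) || min(c) < 1 || max(c) > ncol(img))
    stop("background ROI outside image bounds")
  v <- as.vector(img[r, c])
  if (length(v) == 0) stop("empty background ROI")
  c(b = mean(v), sigma_b = stats::sd(v))
}

#' Target- and contrast-to-background ratios
#'
#' TBR = s/b; CBR = |s - b| / sigma_b. Both are invariant under global
#' positive rescaling of the image.
#'
#' @param s plaque signal
#' @param b background mean (> 0)
#' @param sigma_b background SD (> 0 for CBR)
#' @export
tbr_cbr <- function(s, b, sigma_b) {
  if (b <= 0) stop("tbr_cbr: background mean must be > 0")
  if (sigma_b <= 0) stop("tbr_cbr: background SD must be > 0")
  c(TBR = s / b, CBR = abs(s - b) / sigma_b)
}

# bilinear sample of an image at (row, col) pixel coordinates
sample_points <- function(img, rr, cc) {
  r0 <- floor(rr); c0 <- floor(cc)
  fr <- rr - r0; fc <- cc - c0
  get <- function(r, c) {
    ok <- r >= 1 & r <= nrow(img) & c >= 1 & c <= ncol(img)
    out <- numeric(length(r))
    out[ok] <- img[cbind(r[ok], c[ok])]
    out
  }
  get(r0, c0) * (1 - fr) * (1 - fc) + get(r0 + 1, c0) * fr * (1 - fc) +
    get(r0, c0 + 1) * (1 - fr) * fc + get(r0 + 1, c0 + 1) * fr * fc
}

#' Extract an intensity profile along a line
#'
#' @param image a \code{pet_image}
#' @param p0,p1 line endpoints in mm, (y, x) relative to the first pixel
#'   centre
#' @param n samples
#' @return data frame with \code{x} (mm along the line) and \code{value}
#' @export
extract_profile <- function(image, p0, p1, n = 41L) {
  px <- image$pixel_size
  t <- seq(0, 1, length.out = n)
  rr <- (p0[1] + t * (p1[1] - p0[1])) / px + 1
  cc <- (p0[2] + t * (p1[2] - p0[2])) / px + 1
  len <- sqrt(sum((p1 - p0)^2))
  data.frame(x = t * len, value = sample_points(image$data, rr, cc))
}

#' Fit a Gaussian-plus-linear model to a hotspot line profile
#'
#' Constrained nonlinear least squares of
#' \code{l(x) = a exp(-(x - b)^2 / (2 c^2)) + d x + e} with
#' \code{a, b, c, e >= 0} and \code{d} in [-1, 1]; the hotspot width is the
#' Gaussian full width at half maximum \code{D = 2 sqrt(2 ln 2) c}. A
#' strict single-c-squared exponent mode (\code{l(x) = a exp(-(x-b)^2/c^2)},
#' \code{D = 2 sqrt(ln 2) c}) is available for sensitivity checks; both
#' conventions report the same FWHM for the same fitted curve.
#'
#' @param x sample positions, mm (at least 8)
#' @param y sampled profile values
#' @param gaussian "fwhm" (default, 2c^2 exponent) or "strict" (c^2)
#' @return object of class \code{profile_fit} with fields \code{a},
#'   \code{b}, \code{c}, \code{d}, \code{e}, \code{D}, \code{residual},
#'   \code{converged}
#' @export
fit_profile <- function(x, y, gaussian = c("fwhm", "strict")) {
  gaussian <- match.arg(gaussian)
  if (length(x) < 8) stop("fit_profile: need at least 8 samples")
  stopifnot(length(x) == length(y))
  expo <- if (gaussian == "fwhm") 2 else 1
  dwidth <- if (gaussian == "fwhm") 2 * sqrt(2 * log(2)) else 2 * sqrt(log(2))
  span <- diff(range(x))
  # width start from the observed half-maximum width of the peak
  above <- y - min(y) > (max(y) - min(y)) / 2
  hw <- (diff(range(x[above])) + stats::median(diff(sort(x)))) / 2
  c0 <- min(max(hw / sqrt(expo * log(2)), span / 50), span / 3)
  start <- list(a = max(y) - min(y), b = x[which.max(y)],
                c = c0, d = 0, e = max(min(y), 0))
  if (start$a <= 0) start$a <- 1e-6
  # c is capped at the profile span: a Gaussian wider than the whole
  # profile is indistinguishable from the linear background
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-(x - b)^2 / (expo * c^2)) + d * x + e,
                      start = start,
                      lower = c(a = 0, b = 0, c = 1e-6, d = -1, e = 0),
                      upper = c(a = Inf, b = max(x) + span, c = span, d = 1,
                                e = Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit) && stats::coef(fit)[["c"]] > 0.95 * span) {
    warning("profile fit: width parameter at its bound; no localised peak")
    lf <- stats::lm(y ~ x)
    d0 <- min(max(stats::coef(lf)[[2]], -1), 1)
    e0 <- max(stats::coef(lf)[[1]], 0)
    return(structure(list(a = 0, b = start$b, c = span, d = d0, e = e0,
                          D = dwidth * span,
                          residual = sqrt(mean((e0 + d0 * x - y)^2)),
                          converged = TRUE, gaussian = gaussian),
                     class = "profile_fit"))
  }
  if (is.null(fit)) {
    out <- c(start$a, start$b, start$c, 0, start$e)
    names(out) <- c("a", "b", "c", "d", "e")
    res <- sqrt(mean((out[["a"]] * exp(-(x - out[["b"]])^2 /
                                         (expo * out[["c"]]^2)) +
                        out[["e"]] - y)^2))
    return(structure(list(a = out[["a"]], b = out[["b"]], c = out[["c"]],
                          d = 0, e = out[["e"]], D = dwidth * out[["c"]],
                          residual = res, converged = FALSE,
                          gaussian = gaussian),
                     class = "profile_fit"))
  }
  co <- stats::coef(fit)
  structure(list(a = co[["a"]], b = co[["b"]], c = co[["c"]], d = co[["d"]],
                 e = co[["e"]], D = dwidth * co[["c"]],
                 residual = sqrt(mean(stats::resid(fit)^2)),
                 converged = TRUE, gaussian = gaussian),
            class = "profile_fit")
}

#' @export
print.profile_fit <- function(x, ...) {
  cat(sprintf("<profile_fit a=%.3g b=%.3g c=%.3g d=%.3g e=%.3g D=%.3g mm%s>\n",
              x$a, x$b, x$c, x$d, x$e, x$D,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Compare one plaque between motion-averaged and motion-corrected images
#'
#' Computes TBR and CBR per view, averages them over views, fits the line
#' profile on each image for the hotspot width D, and reports
#' motion-corrected-over-averaged change ratios as integer percents.
#'
#' @param img_avg,img_mcir \code{pet_image}s on the same grid
#' @param rois a single \code{\link{roi_spec}} or a list of them (one per
#'   view)
#' @return one-row data frame with columns TBR_stat, TBR_dual, TBR_ratio,
#'   CBR_stat, CBR_dual, CBR_ratio, FWHM_stat, FWHM_dual, FWHM_ratio
#' @export
measure_plaque <- function(img_avg, img_mcir, rois) {
  stopifnot(all(dim(img_avg$data) == dim(img_mcir$data)))
  if (inherits(rois, "roi_spec")) rois <- list(rois)
  per_img <- function(img) {
    tbrs <- cbrs <- ds <- numeric(0)
    for (v in rois) {
      s <- plaque_signal(img, v$plaque)
      bg <- background_stats(img, v$background)
      tc <- tbr_cbr(s, bg[["b"]], bg[["sigma_b"]])
      tbrs <- c(tbrs, tc[["TBR"]]); cbrs <- c(cbrs, tc[["CBR"]])
      if (!is.null(v$profile)) {
        pr <- extract_profile(img, v$profile$p0, v$profile$p1, v$profile$n)
        ds <- c(ds, fit_profile(pr$x, pr$value)$D)
      }
    }
    c(TBR = mean(tbrs), CBR = mean(cbrs),
      D = if (length(ds)) mean(ds) else NA_real_)
  }
  a <- per_img(img_avg); m <- per_img(img_mcir)
  ratio <- function(stat, dual) round(100 * (dual - stat) / stat)
  data.frame(TBR_stat = a[["TBR"]], TBR_dual = m[["TBR"]],
             TBR_ratio = ratio(a[["TBR"]], m[["TBR"]]),
             CBR_stat = a[["CBR"]], CBR_dual = m[["CBR"]],
             CBR_ratio = ratio(a[["CBR"]], m[["CBR"]]),
             FWHM_stat = a[["D"]], FWHM_dual = m[["D"]],
             FWHM_ratio = ratio(a[["D"]], m[["D"]]))
}

#' Exact Wilcoxon signed-rank test
#'
#' Two-sided p value from the exact permutation distribution of the
#' positive-rank sum: zero differences are dropped before ranking
#' (Wilcoxon's original treatment), tied absolute differences receive
#' average ranks, and the null distribution enumerates all 2^n sign
#' assignments (computed by convolution over the doubled rank values,
#' which is algebraically identical to full enumeration).
#'
#' With \code{method = "normal"} the large-sample normal approximation
#' with tie and continuity corrections is used instead (the convention of
#' common statistics software for ten or more pairs).
#'
#' @param x,y paired samples, or differences in \code{x} if \code{y}
#'   is NULL
#' @param method "exact" (default) or "normal"
#' @return list with \code{statistic} (positive-rank sum W), \code{n}
#'   (nonzero differences) and \code{p.value}
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, method = c("exact", "normal")) {
  method <- match.arg(method)
  d <- if (is.null(y)) x else x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("wilcoxon_signed_rank: all differences are zero")
  if (n < 5) warning("fewer than 5 nonzero differences; exact p is coarse")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (method == "normal") {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sig2)
    return(list(statistic = w, n = n,
                p.value = min(1, 2 * stats::pnorm(-abs(z)))))
  }
  # doubled ranks are integers even with .5 average ranks
  r2 <- as.integer(round(2 * r))
  tot <- sum(r2)
  # dist[k+1] = number of sign assignments with doubled positive-rank sum k
  dist <- numeric(tot + 1)
  dist[1] <- 1
  for (ri in r2) {
    shifted <- c(numeric(ri), dist[seq_len(tot + 1 - ri)])
    dist <- dist + shifted
  }
  dist <- dist / 2^n
  w2 <- round(2 * w)
  p_lo <- sum(dist[seq_len(w2 + 1)])
  p_hi <- sum(dist[(w2 + 1):(tot + 1)])
  list(statistic = w, n = n, p.value = min(1, 2 * min(p_lo, p_hi)))
}

#' Summary statistics for a multi-plaque study table
#'
#' Column means and sample standard deviations (n - 1), rounded to 2
#' decimals, plus exact Wilcoxon signed-rank p values comparing the
#' motion-averaged and motion-corrected columns of TBR, CBR and FWHM.
#'
#' @param table data frame with the nine \code{\link{measure_plaque}}
#'   columns (additional columns are ignored)
#' @param method p-value method passed to
#'   \code{\link{wilcoxon_signed_rank}}
#' @return list with \code{mean}, \code{sd} (named numeric vectors) and
#'   \code{p} (TBR, CBR, FWHM)
#' @export
summarize_study <- function(table, method = c("exact", "normal")) {
  method <- match.arg(method)
  cols <- c("TBR_stat", "TBR_dual", "TBR_ratio", "CBR_stat", "CBR_dual",
            "CBR_ratio", "FWHM_stat", "FWHM_dual", "FWHM_ratio")
  if (!all(cols %in% names(table))) stop("summarize_study: missing columns")
  if (nrow(table) < 2) stop("summarize_study: need at least 2 rows")
  m <- round(vapply(table[cols], mean, 0), 2)
  s <- round(vapply(table[cols], stats::sd, 0), 2)
  p <- c(TBR = wilcoxon_signed_rank(table$TBR_stat, table$TBR_dual,
                                    method = method)$p.value,
         CBR = wilcoxon_signed_rank(table$CBR_stat, table$CBR_dual,
                                    method = method)$p.value,
         FWHM = wilcoxon_signed_rank(table$FWHM_stat, table$FWHM_dual,
                                     method = method)$p.value)
  list(mean = m, sd = s, p = p)
}

#' Reference per-plaque study table
#'
#' Published per-plaque TBR, CBR and hotspot width (FWHM, mm) measurements
#' for motion-averaged ("stat") and cardiorespiratory motion-corrected
#' ("dual") reconstructions of 10 coronary plaques from a 10-patient
#' [18F]NaF PET/MR study, with change ratios in percent. Used to validate
#' the summary-statistics conventions of \code{\link{summarize_study}}.
#'
#' @return data frame with Patient plus the nine metric columns
#' @export
plaque_study_table <- function() {
  utils::read.csv(system.file("extdata", "plaque_study_table.csv",
                              package = "petmoco"))
}
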