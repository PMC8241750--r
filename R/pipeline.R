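#' Full-pipeline run configuration
#'
#' Bundles the per-module configurations of the complete reconstruction
#' workflow: phantom and surrogates, multi-echo radial MR acquisition,
#' motion-resolved water/fat reconstruction, respiratory and cardiac
#' motion models, attenuation mapping, PET simulation, and
#' motion-averaged plus motion-corrected OSEM.
#'
#' @param phantom a \code{\link{phantom_config}}
#' @param mr an \code{\link{mr_sequence_config}}; its spoke interval is set
#'   to cover the MR window exactly
#' @param binning a \code{\link{binning_spec}}
#' @param mr_recon an \code{\link{mr_recon_config}}
#' @param registration a \code{\link{registration_config}}
#' @param mu_table a \code{\link{mu_assignment}}
#' @param plan an \code{\link{acquisition_plan}}
#' @param osem an \code{\link{osem_config}}
#' @param mode "avg" reconstructs only the motion-averaged PET image,
#'   "r-mcir" adds respiratory-only correction, "cr-mcir" (default) the
#'   full cardiorespiratory correction
#' @param seed master seed; every stage derives its own stream
#' @export
run_config <- function(phantom = phantom_config(),
                       mr = mr_sequence_config(spokes_total = 3000L),
                       binning = binning_spec(),
                       mr_recon = mr_recon_config(iterations = 18L),
                       registration = registration_config(),
                       mu_table = mu_assignment(),
                       plan = acquisition_plan(),
                       osem = osem_config(),
                       mode = c("cr-mcir", "r-mcir", "avg"),
                       seed = 1L) {
  mode <- match.arg(mode)
  structure(list(phantom = phantom, mr = mr, binning = binning,
                 mr_recon = mr_recon, registration = registration,
                 mu_table = mu_table, plan = plan, osem = osem,
                 mode = mode, seed = as.integer(seed)),
            class = "run_config")
}

obj_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

# per-stage cache: deterministic resumption from persisted artifacts
stage_cache <- function(outdir, name, key, fn) {
  if (is.null(outdir)) return(fn())
  dir.create(file.path(outdir, "cache"), recursive = TRUE, showWarnings = FALSE)
  path <- file.path(outdir, "cache", paste0(name, "_", key, ".rds"))
  if (file.exists(path)) return(readRDS(path))
  val <- fn()
  saveRDS(val, path, version = 2)
  val
}

#' Default plaque/background/profile ROIs for the phantom geometry
#'
#' Places the plaque ROI around the known plaque position, the background
#' ROI inside the left-ventricle blood pool, and a profile line through
#' the plaque along the radial direction from the heart centre
#' (perpendicular to the vessel course).
#'
#' @param phantom a \code{dynamic_phantom}
#' @param profile_len profile length, mm
#' @export
default_rois <- function(phantom, profile_len = 28) {
  g <- phantom$geometry
  cfg <- phantom$config
  ny <- cfg$grid_shape[1]; nx <- cfg$grid_shape[2]
  px <- cfg$pixel_size
  pl_n <- g$heart_c + g$plaque_dir * g$heart_r * 0.96
  pl_px <- c(pl_n[1] * ny, pl_n[2] * nx)        # pixel coords
  h_px <- c(g$heart_c[1] * ny, g$heart_c[2] * nx)
  # plaque ROI: centred slightly outside the plaque (away from the blood
  # pool, whose signal would otherwise dominate the patch maximum)
  half <- max(2L, round(0.025 * min(ny, nx)))
  ctr <- pl_px + g$plaque_dir * 1.5
  plaque <- round(c(ctr[1] - half, ctr[1] + half,
                    ctr[2] - half, ctr[2] + half))
  bg_half <- max(1L, round(g$heart_r * g$myo_frac * 0.42 * min(ny, nx)))
  background <- round(c(h_px[1] - bg_half, h_px[1] + bg_half,
                        h_px[2] - bg_half, h_px[2] + bg_half))
  # profile perpendicular to the (radial) plaque axis: it crosses the
  # hotspot along the myocardial band and never enters the blood pool
  dirn <- c(-g$plaque_dir[2], g$plaque_dir[1])
  p_mm <- (pl_px - 1) * px
  p0 <- p_mm - dirn * profile_len / 2
  p1 <- p_mm + dirn * profile_len / 2
  roi_spec(plaque, background, profile = list(p0 = p0, p1 = p1, n = 61L))
}

# joint motion-compensated recon helper: spoke groups with their fields
subset_binned <- function(binned, spoke_subsets) {
  binned$spokes <- spoke_subsets
  binned$occupancy <- lengths(spoke_subsets)
  binned
}

# internal: motion-model container for joint recons whose bin list is an
# ad-hoc spoke grouping (the reference-zero-field invariant is not
# meaningful there)
raw_model <- function(fields, type = "cardiorespiratory") {
  structure(list(fields = fields, reference = 1L, type = type,
                 thresholds = NULL, belt_shift = 0),
            class = "motion_model")
}

#' Run the full motion-compensation workflow
#'
#' Executes phantom construction, surrogate generation, MR acquisition
#' simulation, respiratory binning and motion-resolved reconstruction,
#' respiratory model estimation, respiration-corrected cardiac-resolved
#' reconstruction, cardiac model estimation, model concatenation, the
#' cardiorespiratory motion-corrected MR reconstruction, attenuation-map
#' segmentation with stent inpainting, belt-navigator alignment, PET
#' emission simulation over the full scan, motion-averaged and
#' motion-corrected OSEM, and plaque quantification.
#'
#' @param config a \code{\link{run_config}}
#' @param outdir optional artifact directory; when set, every stage is
#'   cached and a manifest with file hashes is written, and a rerun with
#'   the same configuration resumes from the persisted artifacts
#' @param verbose print stage progress
#' @return list with the phantom, surrogates, motion models, attenuation
#'   map, sinograms, PET images (\code{pet_avg}, \code{pet_mcir}),
#'   \code{study_row} (the plaque metrics), and \code{manifest}
#' @export
run_full <- function(config = run_config(), outdir = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  t_start <- Sys.time()
  say <- function(...) if (verbose) message(sprintf(...))
  pcfg <- config$phantom
  key0 <- obj_hash(config[c("phantom", "mr", "binning", "mr_recon",
                            "registration", "seed")])

  say("[1/9] phantom + surrogates")
  ph <- build_phantom(pcfg)
  surr <- generate_surrogates(pcfg)

  say("[2/9] MR acquisition (%d spokes)", config$mr$spokes_total)
  mrw <- pcfg$mr_window
  mr_cfg <- config$mr
  mr_cfg$spoke_interval <- diff(mrw) * 0.999 / mr_cfg$spokes_total
  traj <- make_trajectory(mr_cfg, mrw, pcfg$pixel_size)
  ks <- stage_cache(outdir, "kspace", key0, function()
    simulate_acquisition(ph, surr, mr_cfg, traj, seed = config$seed))

  say("[3/9] respiratory binning + motion-resolved recon")
  bn_r <- bin_kspace(ks, surr, config$binning, "respiratory")
  wf_resp <- stage_cache(outdir, "wf_resp", key0, function()
    reconstruct_waterfat(bn_r, config$mr_recon))

  say("[4/9] respiratory motion model")
  belt_mr <- interp_trace(surr$time, surr$belt, traj$times)
  ref_state <- select_reference(belt_mr)
  ref_resp <- if (ref_state == "end_exhale") 1L else config$binning$n_resp
  # a degenerate belt can leave the intended reference bin empty (all
  # spokes collapse into one bin); fall back to the nearest occupied bin
  if (bn_r$occupancy[ref_resp] == 0) {
    occ_bins <- which(bn_r$occupancy > 0)
    ref_resp <- occ_bins[which.min(abs(occ_bins - ref_resp))]
  }
  resp_amp <- vapply(seq_along(bn_r$spokes), function(b)
    if (length(bn_r$spokes[[b]])) mean(belt_mr[bn_r$spokes[[b]]]) else NA_real_,
    0)
  resp_amp[is.na(resp_amp)] <- 0
  resp_model <- stage_cache(outdir, "resp_model", key0, function()
    build_model(wf_resp, ref_resp, config$registration, "respiratory",
                thresholds = bn_r$thresholds,
                temporal_model = "amplitude", amplitudes = resp_amp))

  say("[5/9] cardiac binning + respiration-corrected recon")
  bn_c <- bin_kspace(ks, surr, config$binning, "cardiac")
  wf_card <- stage_cache(outdir, "wf_card", key0, function() {
    lapply(seq_len(config$binning$n_card), function(j) {
      groups <- lapply(bn_r$spokes, function(sp) intersect(sp, bn_c$spokes[[j]]))
      keep <- lengths(groups) > 0
      if (!any(keep)) {
        z <- matrix(0i, ks$grid[1], ks$grid[2])
        wfj <- waterfat_image(z, z, j, ks$pixel_size)
        attr(wfj, "empty") <- TRUE
        return(wfj)
      }
      sub_model <- raw_model(resp_model$fields[keep], "respiratory")
      wfj <- reconstruct_waterfat(
        subset_binned(bn_r, groups[keep]), config$mr_recon, sub_model)
      wfj$bin_id <- j
      wfj
    })
  })

  say("[6/9] cardiac motion model + concatenation")
  ref_card <- 1L  # end-diastole: phase 0 is the R-peak reference
  card_model <- stage_cache(outdir, "card_model", key0, function()
    build_model(wf_card, ref_card, config$registration, "cardiac"))
  cr_model <- concatenate_models(resp_model, card_model)

  say("[7/9] cr-MCIR MR reconstruction + attenuation map")
  wf_cr <- stage_cache(outdir, "wf_cr", key0, function() {
    groups <- list(); fields <- list(); k <- 0
    for (i in seq_len(config$binning$n_resp))
      for (j in seq_len(config$binning$n_card)) {
        sp <- intersect(bn_r$spokes[[i]], bn_c$spokes[[j]])
        if (length(sp) == 0) next
        k <- k + 1
        groups[[k]] <- sp
        fields[[k]] <- cr_model$fields[[crbin_index(i, j, config$binning$n_card)]]
      }
    reconstruct_waterfat(subset_binned(bn_r, groups), config$mr_recon,
                         raw_model(fields))
  })
  tcm <- inpaint_stent(segment_tissues(wf_cr, seed = config$seed))
  ac_map <- assign_mu(tcm, config$mu_table)

  say("[8/9] PET simulation + reconstruction")
  shift <- align_belt(surr$time[surr$time <= mrw[2] & surr$time >= mrw[1]],
                      surr$belt[surr$time <= mrw[2] & surr$time >= mrw[1]],
                      surr$selfnav[surr$time <= mrw[2] & surr$time >= mrw[1]],
                      max_shift = min(pcfg$resp_period / 2, diff(mrw) / 4))
  plan <- config$plan
  plan$seed <- derive_seed(config$seed, 5L)
  sinos <- stage_cache(outdir, "sinos", obj_hash(list(key0, plan)), function()
    simulate_pet(ph, surr, bn_r$thresholds, config$binning$n_card,
                 belt_shift = shift, plan = plan))
  osem <- config$osem
  pet_avg <- stage_cache(outdir, "pet_avg", obj_hash(list(key0, plan, osem)),
                         function() osem_avg(sinos, ac_map, osem))
  pet_mcir <- NULL
  if (config$mode != "avg") {
    model_used <- if (config$mode == "r-mcir") {
      # respiratory-only: repeat each respiratory field over cardiac bins
      fields <- list()
      for (i in seq_len(config$binning$n_resp))
        for (j in seq_len(config$binning$n_card))
          fields[[crbin_index(i, j, config$binning$n_card)]] <-
        resp_model$fields[[i]]
      fields[[crbin_index(ref_resp, 1L, config$binning$n_card)]] <-
        zero_field(ks$grid, ks$pixel_size)
      motion_model(fields, crbin_index(ref_resp, 1L, config$binning$n_card),
                   "respiratory", bn_r$thresholds, shift)
    } else cr_model
    pet_mcir <- stage_cache(outdir, "pet_mcir",
                            obj_hash(list(key0, plan, osem, config$mode)),
                            function()
                              osem_mcir(sinos, model_used, ac_map, osem,
                                        mode = toupper(config$mode)))
  }

  say("[9/9] plaque quantification")
  rois <- default_rois(ph)
  study_row <- if (!is.null(pet_mcir))
    measure_plaque(pet_avg, pet_mcir, rois) else NULL

  manifest <- list(config_hash = obj_hash(config),
                   seed = config$seed,
                   reference_state = ref_state,
                   belt_shift_s = shift,
                   stages = c("phantom", "mrsim", "mrrecon-resp",
                              "resp-model", "mrrecon-card", "card-model",
                              "cr-mr+acmap", "petsim+recon", "metrics"),
                   package_version = as.character(utils::packageVersion("petmoco")),
                   wall_time_s = as.numeric(difftime(Sys.time(), t_start,
                                                     units = "secs")))
  out <- list(phantom = ph, surrogates = surr, kspace = ks,
              wf_resp = wf_resp, wf_card = wf_card, wf_cr = wf_cr,
              resp_model = resp_model, card_model = card_model,
              cr_model = cr_model, tissue_classes = tcm, ac_map = ac_map,
              belt_shift = shift, sinos = sinos,
              pet_avg = pet_avg, pet_mcir = pet_mcir,
              rois = rois, study_row = study_row, manifest = manifest)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_phantom(ph, surr, file.path(outdir, "phantom"))
    write_waterfat(wf_cr, file.path(outdir, "mr"), "cr_mcir")
    write_motion_model(cr_model, file.path(outdir, "motion"))
    write_map_nifti(ac_map$mu, file.path(outdir, "mu_map.nii.gz"),
                    ac_map$pixel_size)
    write_pet_image(pet_avg, file.path(outdir, "pet"), "avg")
    if (!is.null(pet_mcir))
      write_pet_image(pet_mcir, file.path(outdir, "pet"),
                      tolower(config$mode))
    if (!is.null(study_row))
      utils::write.csv(study_row, file.path(outdir, "study_row.csv"),
                       row.names = FALSE)
    files <- list.files(outdir, recursive = TRUE, full.names = TRUE)
    files <- files[!grepl("manifest[.]yaml$", files)]
    manifest$files <- as.list(tools::md5sum(files))
    yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  }
  out$manifest <- manifest
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a
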