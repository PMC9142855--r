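# Orchestration: from a manifest of volumes (plus optional bend curves)
# to a tidy per-specimen results table with group statistics appended.

# identity calibration: attenuation already stored in mgHA cm^-3
identity_calibration <- function() {
  structure(list(slope = 1e-3, intercept = 0,
                 phantom_densities = c(0.25, 0.75),
                 phantom_means = c(250, 750)),
            class = "calibration_curve")
}

resolve_calibration <- function(calibration) {
  if (is.null(calibration)) return(identity_calibration())
  if (inherits(calibration, "calibration_curve")) return(calibration)
  if (is.list(calibration) && length(calibration) == 2L) {
    vols <- lapply(calibration, function(p)
      if (is_gray_volume(p)) p else read_volume(p, voxel_size_um = NULL))
    return(fit_calibration(vols))
  }
  stop("`calibration` must be NULL, a calibration_curve, or two phantom ",
       "volumes/paths")
}

#' Automatic compartment segmentation of one specimen volume
#'
#' Runs the full chain on an attenuation volume: density calibration,
#' Otsu binarisation, largest-component despeckle, periosteal
#' shrink-wrap, pore-space XOR, the morphological escalator, compartment
#' separation, and calibrated binarisation of the bone within each
#' compartment.
#'
#' @param vol attenuation [gray_volume()].
#' @param cfg a [pipeline_config()].
#' @param calibration a `calibration_curve` (`NULL` = attenuation is
#'   already in mgHA cm^-3).
#' @return list with `density` volume and masks: `roi`, `marrow`,
#'   `trabecular_mask`, `cortical_mask`, `bone`, `trab_bone`, `cort_bone`.
#' @export
segment_specimen <- function(vol, cfg = pipeline_config(),
                             calibration = NULL) {
  curve <- resolve_calibration(calibration)
  density <- apply_calibration(vol, curve)
  raw <- otsu_threshold_3d(vol)
  raw <- largest_component(raw, 26)
  roi <- shrink_wrap(raw, cfg$shrinkwrap_hole_radius_px)
  pores <- xor_pores(roi, raw)
  params <- escalator_params(cfg$escalator_kernel_schedule,
                             cfg$shrinkwrap_hole_radius_px,
                             cfg$speckle_min_voxels)
  marrow <- morphological_escalator(pores, params)
  comps <- separate_compartments(density, marrow, roi)
  bone <- binarize_calibrated(density, cfg, within = roi)
  trab_bone <- same_geom_mask(as.logical(bone) &
                                as.logical(comps$trabecular_mask), bone)
  cort_bone <- same_geom_mask(as.logical(bone) &
                                as.logical(comps$cortical_mask), bone)
  list(density = density, roi = roi, marrow = marrow,
       trabecular_mask = comps$trabecular_mask,
       cortical_mask = comps$cortical_mask,
       bone = bone, trab_bone = trab_bone, cort_bone = cort_bone)
}

analyze_specimen <- function(row, cfg, curve,
                             segmentation = "compartments") {
  vol <- read_volume(row$volume_path,
                     voxel_size_um = if (grepl("\\.nii", row$volume_path))
                       NULL else cfg$voxel_size_um)
  meta <- data.frame(specimen_id = row$specimen_id, group = row$group,
                     time_weeks = row$time_weeks)
  if (segmentation == "trabecular_voi") {
    # the volume already is a trabecular VOI: binarisation chain only
    density <- apply_calibration(vol, curve)
    bone <- binarize_calibrated(density, cfg)
    trab <- trabecular_summary(bone, density = density)
    return(list(trabecular = cbind(meta, region = "trabecular", trab),
                cortical = NULL))
  }
  seg <- segment_specimen(vol, cfg, curve)
  trab <- trabecular_summary(seg$trab_bone, voi = seg$marrow,
                             density = seg$density)
  cort <- cortical_summary(seg$cort_bone, roi = seg$roi,
                           density = seg$density)
  mech <- NULL
  if (!is.null(row$curve_path) && !is.na(row$curve_path) &&
      nzchar(row$curve_path)) {
    curve_fd <- parse_curve(row$curve_path, preload_N = cfg$preload_N)
    sp <- structural_properties(curve_fd)
    geo <- bending_I_and_c(seg$cort_bone)
    mp <- material_properties(sp, span_mm = cfg$span_mm,
                              I_mm4 = geo$I_mm4, c_mm = geo$c_mm)
    mech <- data.frame(max_load_N = sp$max_load_N,
                       stiffness_N_mm = sp$stiffness_N_mm,
                       energy_Nmm = sp$energy_Nmm,
                       elastic_modulus_MPa = mp$elastic_modulus_MPa,
                       ultimate_stress_MPa = mp$ultimate_stress_MPa)
  }
  trab_row <- cbind(meta, region = "trabecular", trab)
  cort_row <- cbind(meta, region = "cortical", cort)
  if (!is.null(mech)) cort_row <- cbind(cort_row, mech)
  list(trabecular = trab_row, cortical = cort_row)
}

#' Run the full analysis pipeline over a manifest
#'
#' For every specimen: reads the volume, calibrates, segments the
#' trabecular and cortical compartments automatically, computes the
#' trabecular and cortical morphometric/densitometric summaries, and
#' (when a bend curve is listed) the structural and beam-theory material
#' properties. Returns one row per specimen and VOI. When at least two
#' groups are present, per-metric SCI-vs-SHAM effect summaries are
#' attached as `attr(result, "stats")` and written alongside the results
#' CSV.
#'
#' Deterministic: contains no randomness, so identical inputs give
#' identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param manifest data.frame (or CSV path) with columns `specimen_id`,
#'   `group`, `time_weeks`, `volume_path`, optional `curve_path`.
#' @param calibration `NULL` (attenuation in mgHA cm^-3), a
#'   `calibration_curve`, or two calibration phantom volumes/paths.
#' @param segmentation `"compartments"` (full automatic trabecular /
#'   cortical separation) or `"trabecular_voi"` (the volume already is a
#'   trabecular VOI; only the binarisation chain is applied).
#' @param out_dir optional output directory for `results.csv`,
#'   `stats.csv` and `config.yaml`.
#' @return data.frame of per-specimen, per-VOI metrics.
#' @export
run_pipeline <- function(config = pipeline_config(), manifest,
                         calibration = NULL,
                         segmentation = c("compartments", "trabecular_voi"),
                         out_dir = NULL) {
  segmentation <- match.arg(segmentation)
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  curve <- resolve_calibration(calibration)
  if (nrow(manifest) == 0L) {
    res <- data.frame()
    attr(res, "stats") <- NULL
    return(res)
  }
  missing <- !file.exists(manifest$volume_path)
  if (any(missing))
    stop("missing volume for specimen(s): ",
         paste(manifest$specimen_id[missing], collapse = ", "))
  trab_rows <- list(); cort_rows <- list()
  for (r in seq_len(nrow(manifest))) {
    out <- analyze_specimen(manifest[r, ], config, curve, segmentation)
    trab_rows[[r]] <- out$trabecular
    if (!is.null(out$cortical)) cort_rows[[length(cort_rows) + 1L]] <-
      out$cortical
  }
  trab <- do.call(rbind, trab_rows)
  cort <- NULL
  if (length(cort_rows)) {
    cort_cols <- unique(unlist(lapply(cort_rows, names)))
    cort <- do.call(rbind, lapply(cort_rows, function(d) {
      for (nm in setdiff(cort_cols, names(d))) d[[nm]] <- NA_real_
      d[cort_cols]
    }))
  }
  all_cols <- union(names(trab), names(cort))
  pad <- function(d) {
    for (nm in setdiff(all_cols, names(d))) d[[nm]] <- NA_real_
    d[all_cols]
  }
  res <- if (is.null(cort)) pad(trab) else rbind(pad(trab), pad(cort))
  res <- res[order(match(res$specimen_id, manifest$specimen_id),
                   res$region), ]
  rownames(res) <- NULL
  stats_tab <- NULL
  if (length(unique(manifest$group)) >= 2 &&
      all(c("SCI", "SHAM") %in% manifest$group)) {
    times <- sort(unique(manifest$time_weeks[manifest$time_weeks > 0]))
    stats_tab <- do.call(rbind, lapply(split(res, res$region),
                                       function(d) {
      rep <- cohort_report(d, times = times)
      cbind(region = d$region[1], rep)
    }))
    rownames(stats_tab) <- NULL
    attr(res, "stats") <- stats_tab
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(res, file.path(out_dir, "results.csv"),
                     row.names = FALSE)
    if (!is.null(stats_tab))
      utils::write.csv(stats_tab, file.path(out_dir, "stats.csv"),
                       row.names = FALSE)
    write_config(config, file.path(out_dir, "config.yaml"))
  }
  res
}
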