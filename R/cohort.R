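# Synthetic cohorts: per-animal metaphyseal phantoms around group presets,
# with lognormal inter-animal variation, plus a fast scalar-outcome
# simulator for calibrating the statistics layer.

#' Metaphyseal phantom: cortical shell with a trabecular lattice inside
#'
#' Convenience wrapper building a [cortical_phantom_spec()] whose marrow
#' cavity holds a rod-lattice insert — the geometry the automatic
#' compartment segmentation is designed for.
#'
#' The geometry must respect the escalator's operating envelope, which is
#' set in voxels by the kernel schedule: the shell thicker than the
#' largest kernel radius (16 voxels by default, else the pore closing
#' bridges the cortex), the marrow cavity several times wider than that
#' radius (the final opening laterally amplifies endosteal dents, so a
#' small lumen loses a boundary ring), and the air margin wider than the
#' shrink-wrap radius. The defaults respect all three at 10 um voxels.
#'
#' @param trab a [trabecular_phantom_spec()] for the insert.
#' @param outer_radius_mm periosteal radius of the (circular) shell.
#' @param shell_thickness_mm cortical thickness.
#' @param ellipse_axis_ratio minor/major ratio of the section.
#' @param n_slices,voxel_size_um,noise_sd,seed volume parameters; densities
#'   are taken from `trab`.
#' @param margin_mm air margin around the shell; must exceed the
#'   shrink-wrap closing radius (0.32 mm at 10 um voxels).
#' @return A `cortical_phantom_spec`.
#' @export
metaphyseal_phantom_spec <- function(trab = trabecular_phantom_spec(
                                       rod_spacing_mm = 0.25,
                                       rod_diameter_mm = 0.07),
                                     outer_radius_mm = 0.75,
                                     shell_thickness_mm = 0.20,
                                     ellipse_axis_ratio = 1,
                                     n_slices = 32,
                                     voxel_size_um = 10,
                                     margin_mm = 0.33,
                                     noise_sd = trab$noise_sd,
                                     seed = trab$seed) {
  r_i <- outer_radius_mm - shell_thickness_mm
  # the air margin must exceed the shrink-wrap closing radius, or the
  # periosteal ROI bulges against the volume border
  cortical_phantom_spec(
    outer_area_mm2 = pi * outer_radius_mm^2 * ellipse_axis_ratio,
    marrow_area_mm2 = pi * r_i^2 * ellipse_axis_ratio,
    ellipse_axis_ratio = ellipse_axis_ratio,
    n_slices = n_slices,
    voxel_size_um = voxel_size_um,
    tissue_density_mgHA = trab$tissue_density_mgHA,
    marrow_density_mgHA = trab$marrow_density_mgHA,
    noise_sd = noise_sd,
    seed = seed,
    margin_mm = margin_mm,
    insert = trab,
    insert_wall_clearance_mm = 0.12,
    attenuation_map = trab$attenuation_map)
}

#' Cohort design
#'
#' Groups and presets of a longitudinal disuse-osteoporosis study: a
#' baseline group (`Time0`), and SCI / SHAM arms at post-surgery time
#' points. All cells share one skeletally mature baseline phantom (no
#' growth across time); the SCI arm applies, at the weeks listed in
#' `sci_effects`, multiplicative deficits to the measured trabecular
#' number and thickness. Under the rod-lattice model the measured
#' `Tb.N = (BV/TV)/Tb.Th` scales as rod count x rod diameter, so a preset
#' `(tbn_factor, tbth_factor)` is realised by scaling rod retention by
#' `tbn_factor / tbth_factor` and rod diameter by `tbth_factor`.
#'
#' Inter-animal variation is lognormal with the given coefficient of
#' variation on the bone-volume-fraction scale: each animal's lattice
#' scales its rod diameter by the square root of the unit-mean lognormal
#' multiplier (BV/TV goes as diameter squared). Each animal's lattice is
#' also dithered by a random sub-voxel phase offset, as a real bone sits
#' at arbitrary position relative to the scanner grid; with `cv = 0`
#' animals in a cell are exactly identical, dither included.
#'
#' @param n_sci,n_sham,n_time0 animals per cell (SCI cells, SHAM cells,
#'   baseline).
#' @param times post-surgery time points in weeks.
#' @param include_time0 add the baseline cell.
#' @param cv inter-animal coefficient of variation.
#' @param seed cohort seed; per-animal seeds derive from it.
#' @param phantom baseline phantom shared by all cells: either a
#'   [trabecular_phantom_spec()] (a pure trabecular VOI, the default —
#'   the metaphyseal lattice at 0.5 mm spacing, 0.1 mm rods in a 1.28 mm
#'   cube) or a [metaphyseal_phantom_spec()] (lattice inside a cortical
#'   shell, for exercising the compartment segmentation).
#' @param sci_effects named list (names = weeks) of
#'   `list(tbn_factor =, tbth_factor =)` deficits for the SCI arm.
#' @return A `cohort_design` list.
#' @export
cohort_design <- function(n_sci = 8, n_sham = 6, n_time0 = 6,
                          times = c(1, 2, 4),
                          include_time0 = TRUE,
                          cv = 0.08,
                          seed = 1,
                          phantom = trabecular_phantom_spec(noise_sd = 30),
                          sci_effects = list(
                            "4" = list(tbn_factor = 0.57,
                                       tbth_factor = 0.86))) {
  if (n_sci < 1 || n_sham < 1 || (include_time0 && n_time0 < 1))
    stop("every cell needs at least one animal")
  structure(as.list(environment()), class = "cohort_design")
}

# lognormal multiplier with unit mean and the given CV
lognormal_multiplier <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic cohort
#'
#' Builds one metaphyseal phantom per animal around its cell preset,
#' writes the volumes (NIfTI) and a manifest CSV consumable by
#' [run_pipeline()], and returns the per-animal ground truths. The
#' generator is a pure function of the design (including its seed).
#'
#' @param design a [cohort_design()].
#' @param out_dir output directory (created if missing).
#' @return list with `manifest` (data.frame), `truths` (per specimen),
#'   `design`, and `manifest_path`.
#' @export
generate_cohort <- function(design, out_dir = tempfile("cohort")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cells <- list()
  if (design$include_time0)
    cells[[length(cells) + 1L]] <- list(group = "Time0", time = 0,
                                        n = design$n_time0)
  for (tw in design$times) {
    cells[[length(cells) + 1L]] <- list(group = "SCI", time = tw,
                                        n = design$n_sci)
    cells[[length(cells) + 1L]] <- list(group = "SHAM", time = tw,
                                        n = design$n_sham)
  }
  manifest <- NULL
  truths <- list()
  animal <- 0L
  for (cell in cells) {
    eff <- if (cell$group == "SCI")
      design$sci_effects[[as.character(cell$time)]] else NULL
    retention_f <- if (is.null(eff)) 1 else eff$tbn_factor / eff$tbth_factor
    diameter_f <- if (is.null(eff)) 1 else eff$tbth_factor
    for (i in seq_len(cell$n)) {
      animal <- animal + 1L
      aseed <- design$seed * 10000L + animal
      draws <- with_seed(aseed, list(
        mult = lognormal_multiplier(1, design$cv),
        phase = stats::runif(3, 0, 1)))
      spec <- design$phantom
      lattice_only <- inherits(spec, "trabecular_phantom_spec")
      trab <- if (lattice_only) spec else spec$insert
      # CV acts on the BV/TV scale; BV/TV ~ diameter^2
      trab$rod_diameter_mm <- trab$rod_diameter_mm * diameter_f *
        sqrt(draws$mult)
      trab$rod_retention_fraction <-
        min(1, trab$rod_retention_fraction * retention_f)
      if (design$cv > 0)
        trab$phase_offset_mm <- draws$phase * trab$voxel_size_um / 1000
      trab$seed <- aseed
      if (lattice_only) {
        ph <- generate_trabecular_phantom(trab)
      } else {
        spec$insert <- trab
        spec$seed <- aseed
        ph <- generate_cortical_phantom(spec)
      }
      id <- sprintf("%s%s_%02d", cell$group,
                    if (cell$group == "Time0") "" else
                      paste0("_wk", cell$time), i)
      path <- file.path(out_dir, paste0(id, ".nii.gz"))
      write_volume(ph$volume, path)
      manifest <- rbind(manifest, data.frame(
        specimen_id = id, group = cell$group, time_weeks = cell$time,
        volume_path = path))
      tr <- ph$truth
      tr$rod_diameter_mm <- trab$rod_diameter_mm
      tr$rod_retention_fraction <- trab$rod_retention_fraction
      truths[[id]] <- tr
    }
  }
  manifest_path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  list(manifest = manifest, truths = truths, design = design,
       manifest_path = manifest_path)
}

#' Simulate scalar outcome tables from a cohort design
#'
#' Draws per-animal outcome values directly from the cohort's lognormal
#' inter-animal model, without rendering volumes: value =
#' baseline x effect(cell) x lognormal(CV). With no effects this is the
#' null generator used to calibrate the type-I error of the targeted
#' t-tests.
#'
#' @param design a [cohort_design()] (only the cell sizes, times, CV and
#'   seed are used).
#' @param baseline true mean outcome value.
#' @param effects named list (names = weeks) of multiplicative SCI
#'   effects; `NULL` for the null model.
#' @param metric metric label.
#' @param seed overrides the design seed when given.
#' @return An [outcome_table()].
#' @export
simulate_outcome_table <- function(design, baseline = 1, effects = NULL,
                                   metric = "outcome", seed = NULL) {
  if (is.null(seed)) seed <- design$seed
  rows <- list()
  add <- function(group, tw, n, mult) {
    data.frame(group = group, time_weeks = tw, n = n, mult = mult)
  }
  cells <- NULL
  if (design$include_time0)
    cells <- rbind(cells, add("Time0", 0, design$n_time0, 1))
  for (tw in design$times) {
    eff <- if (!is.null(effects)) effects[[as.character(tw)]] else NULL
    cells <- rbind(cells,
                   add("SCI", tw, design$n_sci,
                       if (is.null(eff)) 1 else eff),
                   add("SHAM", tw, design$n_sham, 1))
  }
  n_total <- sum(cells$n)
  mults <- with_seed(seed, lognormal_multiplier(n_total, design$cv))
  k <- 0L
  out <- NULL
  for (r in seq_len(nrow(cells))) {
    n <- cells$n[r]
    vals <- baseline * cells$mult[r] * mults[k + seq_len(n)]
    k <- k + n
    out <- rbind(out, data.frame(
      specimen_id = sprintf("%s_wk%s_%02d", cells$group[r],
                            cells$time_weeks[r], seq_len(n)),
      group = cells$group[r], time_weeks = cells$time_weeks[r],
      metric = metric, value = vals))
  }
  class(out) <- c("outcome_table", "data.frame")
  out
}
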