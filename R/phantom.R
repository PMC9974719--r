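#' Configure the synthetic brain phantom
#'
#' Defines a seeded digital head phantom: a spherical brain with a
#' gray-matter shell and white-matter core, a T2-Flair-like edema region (the
#' GTV) containing a nested hyper-perfused core, the cranial organs at risk
#' (brain stem, eyeballs, lenses, optic nerves, optic chiasm), an
#' insula-analog reference region, and the noisy ASL control/label/PD signal
#' volumes from which CBF is re-quantified downstream.
#'
#' Two scenario presets mirror the two clinical situations the analysis
#' distinguishes: `"unilateral"` places the lesion in the left hemisphere
#' (contralateral mirrored gray matter is a valid rCBF reference; 60 Gy
#' baseline prescription), `"midline"` centres it on the mid-sagittal plane
#' (insula reference; 45--54 Gy baseline).
#'
#' All positions are offsets in mm from the brain centre (the grid's
#' symmetric centre), so the phantom stays anatomically consistent when grid
#' shape or spacing change.  Structures are analytic spheres, ellipsoids,
#' cylinders and capsules rasterized by voxel-centre inclusion, which makes
#' analytic volumes exact oracles for the discretized masks.
#'
#' @param scenario `"unilateral"` (default) or `"midline"`.
#' @param grid_shape voxels per axis (default `c(128, 128, 96)`).
#' @param voxel_spacing mm per axis (default 2 mm isotropic; fine enough to
#'   resolve the lenses).
#' @param brain_radius_mm brain sphere radius (default 80).
#' @param gtv_offset_mm GTV centre offset from the brain centre; scenario
#'   default `c(-46, 24, 18)` (unilateral) or `c(0, 24, 18)` (midline).
#' @param gtv_radius_mm GTV (edema) radius, default 25.  `0` generates a
#'   lesion-free phantom (useful for symmetry checks).
#' @param core_radius_mm hyper-perfused core radius, default 10; the core
#'   must lie strictly inside the GTV.
#' @param core_offset_mm core centre offset from the GTV centre, default
#'   `c(-8, 0, 0)` (off-centre, so the boost abuts the PTV rim as real
#'   hyper-perfused subvolumes abut the edema boundary).
#' @param cbf_gm,cbf_wm,cbf_edema,cbf_core ground-truth CBF levels in
#'   ml/100 g/min (defaults 60 / 25 / 30 / 120; the default core-to-gray
#'   ratio of 2.0 exceeds the 1.4 segmentation threshold, edema's 0.5 does
#'   not).
#' @param noise_sd additive Gaussian noise SD on the control and label
#'   signals (signal units; default 0.5).
#' @param pd_signal proton-density signal per tissue class, named vector
#'   with entries `gm`, `wm`, `edema`, `core`, `head`, `air`.
#' @param label_base_frac label-image baseline as a fraction of PD.
#' @param oar_geometry named list of OAR geometry (see defaults in source);
#'   entries are merged over the defaults.
#' @param seed integer RNG seed; all stochastic draws flow from it.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(scenario = c("unilateral", "midline"),
                           grid_shape = c(128, 128, 96),
                           voxel_spacing = c(2, 2, 2),
                           brain_radius_mm = 80,
                           gtv_offset_mm = NULL,
                           gtv_radius_mm = 25,
                           core_radius_mm = 10,
                           core_offset_mm = c(-8, 0, 0),
                           cbf_gm = 60, cbf_wm = 25,
                           cbf_edema = 30, cbf_core = 120,
                           noise_sd = 0.5,
                           pd_signal = c(gm = 1000, wm = 950, edema = 1050,
                                         core = 1050, head = 800, air = 600),
                           label_base_frac = 0.05,
                           oar_geometry = list(),
                           seed = 1L) {
  scenario <- match.arg(scenario)
  if (is.null(gtv_offset_mm))
    gtv_offset_mm <- if (scenario == "unilateral") c(-46, 24, 18)
                     else c(0, 24, 18)
  voxel_spacing <- as.numeric(voxel_spacing)
  if (length(voxel_spacing) == 1L) voxel_spacing <- rep(voxel_spacing, 3L)
  if (any(voxel_spacing <= 0)) stop("voxel spacing must be positive", call. = FALSE)
  if (length(grid_shape) != 3L || any(grid_shape < 8))
    stop("grid_shape must be 3 values of at least 8 voxels", call. = FALSE)

  default_oars <- list(
    gm_shell_inner_mm = 55,
    head_semiaxes_mm  = c(100, 115, 92),
    brainstem         = list(radius = 8, xy_offset = c(0, 14),
                             z_range = c(-75, -30)),
    eye_offset        = c(32, -85, -10), eye_radius = 12,
    lens_offset       = c(32, -93, -10), lens_radius = 3.5,
    chiasm_offset     = c(0, -25, -20),  chiasm_radius = 5,
    nerve_radius      = 2.5,
    insula_offset     = c(-62, -10, 5),  insula_radius = 8)
  oar_geometry <- utils::modifyList(default_oars, oar_geometry)

  cfg <- structure(list(
    scenario = scenario, grid_shape = as.integer(grid_shape),
    voxel_spacing = voxel_spacing, brain_radius_mm = brain_radius_mm,
    gtv_offset_mm = gtv_offset_mm, gtv_radius_mm = gtv_radius_mm,
    core_radius_mm = core_radius_mm, core_offset_mm = core_offset_mm,
    cbf_gm = cbf_gm, cbf_wm = cbf_wm, cbf_edema = cbf_edema,
    cbf_core = cbf_core, noise_sd = noise_sd, pd_signal = pd_signal,
    label_base_frac = label_base_frac, oar_geometry = oar_geometry,
    seed = as.integer(seed)), class = "phantom_config")
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  with(cfg, {
    if (any(c(cbf_gm, cbf_wm, cbf_edema, cbf_core) <= 0))
      stop("all CBF levels must be positive", call. = FALSE)
    if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
    if (any(pd_signal <= 0)) stop("pd_signal values must be positive", call. = FALSE)
    if (gtv_radius_mm < 0 || core_radius_mm < 0)
      stop("radii must be non-negative", call. = FALSE)
    if (gtv_radius_mm > 0) {
      if (sqrt(sum(core_offset_mm^2)) + core_radius_mm >= gtv_radius_mm)
        stop("the hyper-perfused core must lie strictly inside the GTV",
             call. = FALSE)
      if (sqrt(sum(gtv_offset_mm^2)) + gtv_radius_mm > brain_radius_mm)
        stop("the GTV must lie fully inside the brain", call. = FALSE)
    }
    fov_half <- (grid_shape - 1) * voxel_spacing / 2
    if (any(brain_radius_mm > fov_half))
      stop("the brain sphere exceeds the grid field of view", call. = FALSE)
    if (any(oar_geometry$head_semiaxes_mm > fov_half))
      stop("the head ellipsoid exceeds the grid field of view", call. = FALSE)
  })
  invisible(cfg)
}

# squared physical distance from each voxel centre to a point (mm^2)
dist2_to_point <- function(geom, centre) {
  co <- axis_coords(geom)
  d <- dim(geom$data)
  a <- array((co$x - centre[1])^2, dim = d)
  a <- a + rep((co$y - centre[2])^2, each = d[1])
  a + rep((co$z - centre[3])^2, each = d[1] * d[2])
}

rasterize_sphere <- function(geom, centre, radius) {
  dist2_to_point(geom, centre) <= radius^2
}

rasterize_ellipsoid <- function(geom, centre, semiaxes) {
  co <- axis_coords(geom)
  d <- dim(geom$data)
  a <- array(((co$x - centre[1]) / semiaxes[1])^2, dim = d)
  a <- a + rep(((co$y - centre[2]) / semiaxes[2])^2, each = d[1])
  a <- a + rep(((co$z - centre[3]) / semiaxes[3])^2, each = d[1] * d[2])
  a <= 1
}

# z-aligned cylinder between z0 and z1
rasterize_cylinder_z <- function(geom, xy_centre, radius, z0, z1) {
  co <- axis_coords(geom)
  d <- dim(geom$data)
  r2 <- array((co$x - xy_centre[1])^2, dim = d) +
    rep((co$y - xy_centre[2])^2, each = d[1])
  inz <- rep(co$z >= z0 & co$z <= z1, each = d[1] * d[2])
  r2 <= radius^2 & array(inz, dim = d)
}

# capsule: all voxels within `radius` of the segment a--b
rasterize_capsule <- function(geom, a, b, radius) {
  co <- axis_coords(geom)
  d <- dim(geom$data)
  ab <- b - a
  len2 <- sum(ab^2)
  px <- array(co$x - a[1], dim = d)
  py <- array(rep(co$y - a[2], each = d[1]), dim = d)
  pz <- array(rep(co$z - a[3], each = d[1] * d[2]), dim = d)
  t <- (px * ab[1] + py * ab[2] + pz * ab[3]) / len2
  t <- pmin(pmax(t, 0), 1)
  (px - t * ab[1])^2 + (py - t * ab[2])^2 + (pz - t * ab[3])^2 <= radius^2
}

#' Generate a synthetic brain phantom with ASL acquisitions
#'
#' Rasterizes the configured anatomy, assigns the ground-truth CBF map, and
#' synthesizes ASL control, label and proton-density images so that the
#' closed-form quantification in [compute_cbf()] is an exact inverse of the
#' generation when `noise_sd = 0`: the control-minus-label difference is set
#' voxelwise to `truth_cbf * pd / cbf_scale_factor(params)`.  With
#' `noise_sd > 0`, independent Gaussian noise is added to the control and
#' label images.
#'
#' @param config a [phantom_config()].
#' @param params the [asl_parameters()] assumed by the forward signal model
#'   (use the same parameters for quantification).
#' @return An object of class `asl_phantom`: a list with `truth_cbf`,
#'   `asl_control`, `asl_label`, `asl_pd` ([volume_grid()]s), `tissue_masks`
#'   (`gray`, `white`, `brain`, `body`), `structure_masks` (`gtv`, `core`,
#'   OARs, `insula_ref`), and the `config`.
#' @export
generate_phantom <- function(config = phantom_config(),
                             params = asl_parameters()) {
  validate_phantom_config(config)
  d <- config$grid_shape
  geom <- volume_grid(array(0, dim = d), config$voxel_spacing)
  centre <- geom$origin + (d - 1) * geom$spacing / 2
  og <- config$oar_geometry
  off <- function(o) centre + o

  brain <- rasterize_sphere(geom, centre, config$brain_radius_mm)
  body <- rasterize_ellipsoid(geom, centre, og$head_semiaxes_mm) | brain
  inner <- rasterize_sphere(geom, centre, og$gm_shell_inner_mm)
  white <- inner
  gray <- brain & !inner

  gtv_centre <- off(config$gtv_offset_mm)
  if (config$gtv_radius_mm > 0) {
    gtv <- rasterize_sphere(geom, gtv_centre, config$gtv_radius_mm)
    core <- rasterize_sphere(geom, gtv_centre + config$core_offset_mm,
                             config$core_radius_mm)
  } else {
    gtv <- core <- array(FALSE, dim = d)
  }

  stem <- rasterize_cylinder_z(geom, centre[1:2] + og$brainstem$xy_offset,
                               og$brainstem$radius,
                               centre[3] + og$brainstem$z_range[1],
                               centre[3] + og$brainstem$z_range[2])
  eye_l <- rasterize_sphere(geom, off(og$eye_offset * c(-1, 1, 1)), og$eye_radius)
  eye_r <- rasterize_sphere(geom, off(og$eye_offset), og$eye_radius)
  lens_l <- rasterize_sphere(geom, off(og$lens_offset * c(-1, 1, 1)), og$lens_radius)
  lens_r <- rasterize_sphere(geom, off(og$lens_offset), og$lens_radius)
  chiasm <- rasterize_sphere(geom, off(og$chiasm_offset), og$chiasm_radius)
  nerve_l <- rasterize_capsule(geom, off(og$eye_offset * c(-1, 1, 1)),
                               off(og$chiasm_offset), og$nerve_radius) &
    !eye_l & !chiasm
  nerve_r <- rasterize_capsule(geom, off(og$eye_offset), off(og$chiasm_offset),
                               og$nerve_radius) & !eye_r & !chiasm
  insula <- rasterize_sphere(geom, off(og$insula_offset), og$insula_radius) & gray

  # ground-truth CBF: tissue base, edema and core override inside the brain
  cbf <- array(0, dim = d)
  cbf[white] <- config$cbf_wm
  cbf[gray] <- config$cbf_gm
  cbf[gtv] <- config$cbf_edema
  cbf[core] <- config$cbf_core

  pd <- array(config$pd_signal[["air"]], dim = d)
  pd[body] <- config$pd_signal[["head"]]
  pd[white] <- config$pd_signal[["wm"]]
  pd[gray] <- config$pd_signal[["gm"]]
  pd[gtv] <- config$pd_signal[["edema"]]
  pd[core] <- config$pd_signal[["core"]]

  k <- cbf_scale_factor(params)
  label <- config$label_base_frac * pd
  control <- label + cbf * pd / k

  if (config$noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(config$seed)
    control <- control + array(stats::rnorm(length(control), 0, config$noise_sd), dim = d)
    label <- label + array(stats::rnorm(length(label), 0, config$noise_sd), dim = d)
  }

  sp <- geom$spacing
  mk <- function(name, m) structure_mask(name, m, sp)
  structure(list(
    truth_cbf = volume_grid(cbf, sp),
    asl_control = volume_grid(control, sp),
    asl_label = volume_grid(label, sp),
    asl_pd = volume_grid(pd, sp),
    tissue_masks = list(gray = mk("gray", gray), white = mk("white", white),
                        brain = mk("brain", brain), body = mk("body", body)),
    structure_masks = list(
      gtv = mk("gtv", gtv), core = mk("core", core),
      brainstem = mk("brainstem", stem),
      eye_l = mk("eye_l", eye_l), eye_r = mk("eye_r", eye_r),
      lens_l = mk("lens_l", lens_l), lens_r = mk("lens_r", lens_r),
      optic_nerve_l = mk("optic_nerve_l", nerve_l),
      optic_nerve_r = mk("optic_nerve_r", nerve_r),
      chiasm = mk("chiasm", chiasm),
      insula_ref = mk("insula_ref", insula)),
    config = config, asl_params = params),
    class = "asl_phantom")
}

#' @export
print.asl_phantom <- function(x, ...) {
  cat(sprintf("<asl_phantom> %s scenario, %s grid @ %s mm, seed %d\n",
              x$config$scenario, paste(dim(x$truth_cbf$data), collapse = "x"),
              paste(format(x$config$voxel_spacing, trim = TRUE), collapse = "x"),
              x$config$seed))
  cat(sprintf("  GTV %.1f cc, core %.1f cc, noise sd %.3g\n",
              volume_cc(x$structure_masks$gtv),
              volume_cc(x$structure_masks$core), x$config$noise_sd))
  invisible(x)
}

#' Write all phantom images and masks as NIfTI
#'
#' Files are named `<id>_<role>.nii.gz` in `dir`.
#'
#' @param phantom an [generate_phantom()] result.
#' @param dir output directory (created if needed).
#' @param id file-name prefix.
#' @return Named character vector of paths, invisibly.
#' @export
write_phantom <- function(phantom, dir, id = "phantom") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wv <- function(role, grid) {
    p <- file.path(dir, sprintf("%s_%s.nii.gz", id, role))
    write_volume(grid, p)
    paths[[role]] <<- p
  }
  wv("truth_cbf", phantom$truth_cbf)
  wv("asl_control", phantom$asl_control)
  wv("asl_label", phantom$asl_label)
  wv("asl_pd", phantom$asl_pd)
  for (m in c(phantom$tissue_masks, phantom$structure_masks)) {
    p <- file.path(dir, sprintf("%s_%s.nii.gz", id, m$name))
    write_mask(m, p)
    paths[[m$name]] <- p
  }
  invisible(paths)
}
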