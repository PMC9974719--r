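#' Plan prescription
#'
#' The prescription and escalation rules for the three plan variants:
#' a conventional plan (`plan1`) prescribing the baseline dose to the PTV,
#' and two simultaneous-integrated-boost dose-painting plans escalating the
#' PTV-ASL by `escalation_fraction` on top of plan 1 -- `plan2` with the
#' 110% maximum-dose cap, `plan3` without it.  The boost prescription is
#' always `baseline * (1 + escalation)`; dose is normalized to the mean dose
#' of the PTV in plan 1 and of the PTV-ASL in plans 2--3.
#'
#' @param baseline_dose_gy baseline prescription (typical range 45--60 Gy;
#'   60 for unilateral lesions, 45--54 for midline lesions).
#' @param fraction_dose_gy dose per fraction (1.8--2 Gy typical).
#' @param escalation_fraction boost escalation (0.10--0.20 typical).
#' @param max_dose_cap apply the maximum-dose cap (plans 1--2).
#' @param cap_fraction cap as a fraction of the prescription (default 1.10).
#' @param cap_reference `"local"` (default): the cap applies to the
#'   structure-local prescription, i.e. the boost dose inside the PTV-ASL
#'   and the baseline elsewhere; `"baseline"`: the cap is
#'   `cap_fraction * baseline` everywhere.
#' @param coverage_goal fraction of the PTV the prescription must cover.
#' @return An object of class `plan_prescription` with derived field
#'   `boost_dose_gy`.
#' @export
plan_prescription <- function(baseline_dose_gy = 60, fraction_dose_gy = 2,
                              escalation_fraction = 0.20,
                              max_dose_cap = TRUE, cap_fraction = 1.10,
                              cap_reference = c("local", "baseline"),
                              coverage_goal = 0.95) {
  cap_reference <- match.arg(cap_reference)
  if (baseline_dose_gy <= 0 || fraction_dose_gy <= 0)
    stop("doses must be positive", call. = FALSE)
  if (escalation_fraction < 0)
    stop("escalation_fraction must be non-negative", call. = FALSE)
  if (cap_fraction < 1) stop("cap_fraction must be >= 1", call. = FALSE)
  if (coverage_goal <= 0 || coverage_goal > 1)
    stop("coverage_goal must be in (0, 1]", call. = FALSE)
  structure(list(
    baseline_dose_gy = baseline_dose_gy, fraction_dose_gy = fraction_dose_gy,
    escalation_fraction = escalation_fraction,
    boost_dose_gy = baseline_dose_gy * (1 + escalation_fraction),
    max_dose_cap = max_dose_cap, cap_fraction = cap_fraction,
    cap_reference = cap_reference, coverage_goal = coverage_goal),
    class = "plan_prescription")
}

#' Simplified dose-model configuration
#'
#' Parameters of the Gaussian-penumbra dose model that stands in for a
#' clinical IMRT optimizer and dose engine.  Painted apertures are blurred
#' with an isotropic Gaussian of `penumbra_sigma_mm`; the aperture extends
#' `aperture_margin_sigma * penumbra_sigma_mm` beyond each target, emulating
#' the boundary fluence enhancement a real optimizer uses to carry the
#' prescription out to the target surface.
#'
#' @param penumbra_sigma_mm Gaussian penumbra SD in mm (default 5; `0` gives
#'   the degenerate no-blur limit).
#' @param aperture_margin_sigma aperture margin in units of sigma (default 3).
#' @param dose_grid_spacing_mm optional dose-grid spacing; `NULL` (default)
#'   computes dose on the native image grid.
#' @return An object of class `dose_model_config`.
#' @export
dose_model_config <- function(penumbra_sigma_mm = 5,
                              aperture_margin_sigma = 3,
                              dose_grid_spacing_mm = NULL) {
  if (penumbra_sigma_mm < 0) stop("sigma must be >= 0", call. = FALSE)
  if (aperture_margin_sigma < 0)
    stop("aperture_margin_sigma must be >= 0", call. = FALSE)
  structure(list(penumbra_sigma_mm = penumbra_sigma_mm,
                 aperture_margin_sigma = aperture_margin_sigma,
                 dose_grid_spacing_mm = dose_grid_spacing_mm),
            class = "dose_model_config")
}

#' Organ-at-risk dose-constraint table
#'
#' Default cranial OAR limits: brain stem D0.1cc <= 54 Gy, eyeball
#' Dmax < 45 Gy, lens Dmax < 10 Gy, optic nerve and optic chiasm
#' Dmax <= 55 Gy.
#'
#' @param rows optional data frame with columns `structure`, `metric`
#'   (`"D0.1cc"` or `"Dmax"`), `limit_gy`, `comparator` (`"<="` or `"<"`)
#'   replacing the defaults.
#' @return A data frame of class `oar_constraint_table`.
#' @export
oar_constraint_table <- function(rows = NULL) {
  if (is.null(rows)) {
    rows <- data.frame(
      structure = c("brainstem", "eye_l", "eye_r", "lens_l", "lens_r",
                    "optic_nerve_l", "optic_nerve_r", "chiasm"),
      metric = c("D0.1cc", rep("Dmax", 7)),
      limit_gy = c(54, 45, 45, 10, 10, 55, 55, 55),
      comparator = c("<=", "<", "<", "<", "<", "<=", "<=", "<="),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("structure", "metric", "limit_gy", "comparator") %in%
                  names(rows)))
  if (any(rows$limit_gy <= 0)) stop("limits must be positive", call. = FALSE)
  if (anyDuplicated(rows[c("structure", "metric")]))
    stop("each structure may appear once per metric", call. = FALSE)
  class(rows) <- c("oar_constraint_table", "data.frame")
  rows
}

# separable Gaussian blur with physical spacing; kernel rows renormalized so
# a uniform field is preserved (truncated at 4 sigma)
gaussian_blur3d <- function(a, spacing, sigma) {
  if (sigma <= 0) return(a)
  kmat <- function(n, sp) {
    dd <- outer(seq_len(n), seq_len(n), function(i, j) (i - j) * sp)
    k <- exp(-dd^2 / (2 * sigma^2))
    k[abs(dd) > 4 * sigma] <- 0
    k / rowSums(k)
  }
  d <- dim(a)
  a <- array(kmat(d[1], spacing[1]) %*% matrix(a, d[1]), dim = d)
  a <- aperm(a, c(2, 1, 3))
  a <- array(kmat(d[2], spacing[2]) %*% matrix(a, d[2]), dim = d[c(2, 1, 3)])
  a <- aperm(a, c(2, 1, 3))
  a <- aperm(a, c(3, 2, 1))
  a <- array(kmat(d[3], spacing[3]) %*% matrix(a, d[3]), dim = d[c(3, 2, 1)])
  aperm(a, c(3, 2, 1))
}

#' Structure-local prescription map
#'
#' The voxelwise prescription the cap rule refers to: the boost dose inside
#' the PTV-ASL (for dose-painting variants under the `"local"` cap
#' reference) and the baseline dose elsewhere.
#'
#' @param structures named list of [structure_mask()]s containing `ptv_asl`.
#' @param rx a [plan_prescription()].
#' @param variant `"plan1"`, `"plan2"` or `"plan3"`.
#' @return A [volume_grid()] of prescription dose in Gy.
#' @export
local_prescription <- function(structures, rx, variant = "plan2") {
  geom <- structures$ptv
  p <- array(rx$baseline_dose_gy, dim = dim(geom$data))
  boosted <- variant %in% c("plan2", "plan3") &&
    !is.null(structures$ptv_asl) && any(structures$ptv_asl$data) &&
    rx$cap_reference == "local"
  if (boosted) p[structures$ptv_asl$data] <- rx$boost_dose_gy
  volume_grid(p, geom$spacing, geom$origin)
}

#' Simulate a plan dose distribution
#'
#' Produces a synthetic 3-D dose grid for one of the three plan variants
#' under the Gaussian-penumbra model (an explicit simplified stand-in for a
#' commercial treatment planning system -- see the package vignette for what
#' this does and does not reproduce):
#'
#' * `plan1`: the baseline dose is painted on the PTV aperture (PTV plus the
#'   aperture margin), blurred, and normalized so the mean PTV dose equals
#'   the baseline prescription.
#' * `plan2`/`plan3`: built on plan 1 -- a boost increment is painted on the
#'   PTV-ASL aperture with amplitude chosen so the mean PTV-ASL dose reaches
#'   the boost prescription, then the sum is renormalized multiplicatively
#'   to the mean PTV-ASL dose.
#'
#' For `plan1` and `plan2`, doses are then capped at
#' `cap_fraction * local prescription` and normalization re-verified to
#' within 0.5%, iterating cap and renormalization (at most 20 fixed-point
#' steps); `plan3` applies no cap.  A final coverage trim scales the dose
#' upward within the 0.5% normalization tolerance until the baseline
#' prescription covers `coverage_goal` of the PTV (a mean-normalized blurred
#' field otherwise leaves roughly the outer rim of the PTV marginally below
#' prescription -- the same trade a clinical optimizer makes), re-applying
#' the cap so the cap contract stays exact.  If the PTV-ASL is empty (no
#' hyper-perfusion found) the dose-painting variants degenerate to plan 1
#' with a warning, mirroring the clinical fallback.
#'
#' @param structures named list with at least `ptv` (and `ptv_asl` for
#'   plans 2--3), e.g. from [build_structure_cascade()].
#' @param rx a [plan_prescription()].
#' @param model a [dose_model_config()].
#' @param variant `"plan1"`, `"plan2"` or `"plan3"`.
#' @return A [volume_grid()] of dose in Gy with attributes `variant`,
#'   `normalization` (structure, prescription, achieved mean, residual),
#'   `cap_iterations` and `fallback` (TRUE when a painting variant
#'   degenerated to plan 1).
#' @export
simulate_plan <- function(structures, rx, model = dose_model_config(),
                          variant = c("plan1", "plan2", "plan3")) {
  variant <- match.arg(variant)
  ptv <- structures$ptv
  if (is.null(ptv) || !any(ptv$data))
    stop("structures must contain a nonempty 'ptv'", call. = FALSE)
  sigma <- model$penumbra_sigma_mm
  ap_mm <- model$aperture_margin_sigma * sigma
  paint <- function(target, amplitude) {
    aperture <- if (ap_mm > 0) expand_margin(target, ap_mm) else target
    amplitude * gaussian_blur3d(aperture$data + 0, ptv$spacing, sigma)
  }

  # plan-1 base field, normalized to mean PTV dose = baseline
  base <- paint(ptv, rx$baseline_dose_gy)
  base <- base * rx$baseline_dose_gy / mean(base[ptv$data])

  boosted <- variant != "plan1"
  fallback <- FALSE
  if (boosted) {
    asl <- structures$ptv_asl
    if (is.null(asl) || !any(asl$data)) {
      warning(sprintf(
        "%s requested but the PTV-ASL is empty; falling back to the conventional plan",
        variant), call. = FALSE)
      boosted <- FALSE
      fallback <- TRUE
    }
  }

  if (boosted) {
    inc_amp <- rx$boost_dose_gy - mean(base[asl$data])
    dose <- if (inc_amp > 0) base + paint(asl, inc_amp) else base
    norm_mask <- asl$data
    norm_rx <- rx$boost_dose_gy
    norm_name <- "ptv_asl"
  } else {
    dose <- base
    norm_mask <- ptv$data
    norm_rx <- rx$baseline_dose_gy
    norm_name <- "ptv"
  }

  capped <- rx$max_dose_cap && variant %in% c("plan1", "plan2")
  cap_map <- if (capped)
    rx$cap_fraction * local_prescription(structures, rx, variant)$data

  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    dose <- dose * norm_rx / mean(dose[norm_mask])
    if (!capped) break
    dose <- pmin(dose, cap_map)
    residual <- abs(mean(dose[norm_mask]) - norm_rx) / norm_rx
    if (residual <= 0.005) break
    if (iterations >= 20L)
      stop(paste0("the maximum-dose cap and the mean-dose normalization ",
                  "cannot both be satisfied on this geometry (normalization ",
                  "residual ", format(residual), " after 20 cap/renormalize ",
                  "steps); the coverage goal is unreachable under the cap"),
           call. = FALSE)
  }

  # coverage trim: real optimizers trade the normalization point against the
  # coverage goal; scale up within the 0.5% normalization tolerance until the
  # prescription covers `coverage_goal` of the PTV (re-capping afterwards, so
  # the cap contract is exact).
  vals <- dose[ptv$data]
  if (mean(vals >= rx$baseline_dose_gy) < rx$coverage_goal) {
    dq <- stats::quantile(vals, 1 - rx$coverage_goal, type = 1, names = FALSE)
    s_trim <- min(rx$baseline_dose_gy / dq * (1 + 1e-9), 1.0049)
    if (s_trim > 1) {
      dose <- dose * s_trim
      if (capped) dose <- pmin(dose, cap_map)
    }
    if (mean(dose[ptv$data] >= rx$baseline_dose_gy) < rx$coverage_goal)
      warning(sprintf(
        "%s: prescription coverage goal %.0f%% of the PTV not reachable within the normalization tolerance",
        variant, 100 * rx$coverage_goal), call. = FALSE)
  }

  achieved <- mean(dose[norm_mask])
  out <- volume_grid(dose, ptv$spacing, ptv$origin)
  attr(out, "variant") <- variant
  attr(out, "normalization") <- list(structure = norm_name,
                                     prescription_gy = norm_rx,
                                     achieved_gy = achieved,
                                     residual = abs(achieved - norm_rx) / norm_rx)
  attr(out, "cap_iterations") <- if (capped) iterations else 0L
  attr(out, "fallback") <- fallback
  out
}

#' Check a dose grid against OAR constraints
#'
#' Evaluates each constraint row (D0.1cc or Dmax) on the corresponding
#' structure and reports observed value, limit and verdict.
#'
#' @param dose a [volume_grid()] dose grid in Gy.
#' @param structures named list of [structure_mask()]s; every structure in
#'   the table must be present.
#' @param table an [oar_constraint_table()].
#' @return Data frame with columns `structure`, `metric`, `observed_gy`,
#'   `limit_gy`, `comparator`, `pass`, and attribute `overall_pass`.
#' @export
check_constraints <- function(dose, structures, table = oar_constraint_table()) {
  missing <- setdiff(table$structure, names(structures))
  if (length(missing))
    stop("structures missing from the set: ", paste(missing, collapse = ", "),
         call. = FALSE)
  observed <- mapply(function(s, metric) {
    m <- structures[[s]]
    assert_same_geometry(dose, m, what = "dose and structure")
    if (!any(m$data)) return(NA_real_)
    if (metric == "Dmax") {
      max(dose$data[m$data])
    } else if (metric == "D0.1cc") {
      dose_at_absolute_volume(compute_dvh(dose, m), cc = 0.1)
    } else stop("unknown metric '", metric, "'", call. = FALSE)
  }, table$structure, table$metric)
  pass <- ifelse(table$comparator == "<", observed < table$limit_gy,
                 observed <= table$limit_gy)
  out <- data.frame(structure = table$structure, metric = table$metric,
                    observed_gy = as.numeric(observed),
                    limit_gy = table$limit_gy,
                    comparator = table$comparator, pass = pass,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "overall_pass") <- all(out$pass, na.rm = TRUE)
  out
}

#' Trilinear resampling of a volume to a new spacing
#'
#' Resamples a [volume_grid()] onto a grid with the requested spacing over
#' the same physical extent, interpolating trilinearly between voxel
#' centres (values beyond the outermost centres are clamped to the edge).
#'
#' @param grid a [volume_grid()].
#' @param new_spacing target spacing in mm (scalar or length 3).
#' @return A resampled [volume_grid()].
#' @export
resample_volume <- function(grid, new_spacing) {
  new_spacing <- as.numeric(new_spacing)
  if (length(new_spacing) == 1L) new_spacing <- rep(new_spacing, 3L)
  if (any(new_spacing <= 0)) stop("spacing must be positive", call. = FALSE)
  d <- dim(grid$data)
  extent <- (d - 1) * grid$spacing
  nd <- pmax(2L, as.integer(floor(extent / new_spacing)) + 1L)
  # fractional source indices of the new voxel centres
  idx <- lapply(1:3, function(ax) {
    x <- (seq_len(nd[ax]) - 1) * new_spacing[ax] / grid$spacing[ax] + 1
    pmin(pmax(x, 1), d[ax])
  })
  interp1 <- function(a, ax) {
    x <- idx[[ax]]
    i0 <- pmin(as.integer(floor(x)), dim(a)[ax] - 1L)
    w <- x - i0
    sl <- function(i) {
      args <- rep(list(quote(expr = )), 3)
      args[[ax]] <- i
      do.call(`[`, c(list(a), args, drop = FALSE))
    }
    a0 <- sl(i0)
    a1 <- sl(i0 + 1L)
    warr <- array(rep(w, each = prod(dim(a0)[seq_len(ax - 1)])),
                  dim = dim(a0))
    a0 + warr * (a1 - a0)
  }
  a <- grid$data
  for (ax in 1:3) a <- interp1(a, ax)
  volume_grid(a, new_spacing, grid$origin)
}
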