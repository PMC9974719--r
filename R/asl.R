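#' ASL quantification constants
#'
#' Constants of the single-delay pseudo-continuous ASL quantification model:
#' brain/blood partition coefficient \eqn{\lambda} (ml/g), longitudinal
#' relaxation time of arterial blood \eqn{T_{1,blood}}, labeling efficiency
#' \eqn{\alpha}, label duration \eqn{\tau} and post-labeling delay (PLD).
#' Times are handled internally in seconds; set `time_unit = "ms"` to supply
#' them in milliseconds as vendor consoles print them.  A plausibility guard
#' rejects `t1_blood` outside 0.5--3 s after conversion, so passing
#' millisecond values as seconds fails loudly rather than silently
#' mis-scaling CBF by three orders of magnitude.
#'
#' @param lambda_partition partition coefficient, ml/g.
#' @param t1_blood T1 of blood (s, or ms with `time_unit = "ms"`).
#' @param alpha labeling efficiency in (0, 1].
#' @param tau label duration (same unit as `t1_blood`).
#' @param pld post-labeling delay (same unit as `t1_blood`).
#' @param time_unit `"s"` (default) or `"ms"`.
#' @return An object of class `asl_parameters` with times in seconds.
#' @export
asl_parameters <- function(lambda_partition = 0.9, t1_blood = 1.65,
                           alpha = 0.85, tau = 1.5, pld = 2.025,
                           time_unit = c("s", "ms")) {
  time_unit <- match.arg(time_unit)
  k <- if (time_unit == "ms") 1e-3 else 1
  t1_blood <- t1_blood * k
  tau <- tau * k
  pld <- pld * k
  if (any(c(lambda_partition, t1_blood, alpha, tau, pld) <= 0))
    stop("all ASL parameters must be positive", call. = FALSE)
  if (alpha > 1)
    stop("labeling efficiency 'alpha' cannot exceed 1", call. = FALSE)
  if (t1_blood < 0.5 || t1_blood > 3)
    stop(sprintf(paste0("t1_blood = %g s is outside the plausible 0.5-3 s ",
                        "range; milliseconds must be passed with ",
                        "time_unit = \"ms\""), t1_blood), call. = FALSE)
  structure(list(lambda_partition = lambda_partition, t1_blood = t1_blood,
                 alpha = alpha, tau = tau, pld = pld),
            class = "asl_parameters")
}

#' Scalar coefficient of the CBF quantification equation
#'
#' The closed-form CBF model is linear in the normalized difference signal:
#' \deqn{CBF = K \cdot (SI_{control} - SI_{label}) / SI_{PD}} with
#' \deqn{K = \frac{6000\,\lambda\, e^{PLD/T_{1,blood}}}
#'  {2\,\alpha\, T_{1,blood}\, (1 - e^{-\tau/T_{1,blood}})}.}
#' The factor 6000 converts ml/g/s to the customary ml/100 g/min.  With the
#' default constants K is approximately 1.1e4.
#'
#' @param params an [asl_parameters()] object.
#' @return The scalar K (ml/100 g/min per unit normalized difference signal).
#' @export
cbf_scale_factor <- function(params) {
  6000 * params$lambda_partition * exp(params$pld / params$t1_blood) /
    (2 * params$alpha * params$t1_blood *
       (1 - exp(-params$tau / params$t1_blood)))
}

#' Quantify cerebral blood flow from control/label/PD images
#'
#' Voxelwise closed-form CBF in ml/100 g/min from the time-averaged control
#' and label signal images and a proton-density (M0) image:
#' `CBF = K * (control - label) / pd` with `K = cbf_scale_factor(params)`.
#' Noise-driven negative values are retained by default (clamping biases
#' region means); set `clamp_negative = TRUE` to floor at zero.  Voxels whose
#' PD signal is below `1e-9` of the in-mask median are treated as
#' unquantifiable: the result is `NA` there and their count is attached as
#' attribute `n_masked_pd`.
#'
#' @param control,label,pd [volume_grid()] signal images on one geometry.
#' @param params an [asl_parameters()] object.
#' @param mask optional [structure_mask()] restricting evaluation; outside
#'   the mask the result is `NA`.  Default: all voxels.
#' @param clamp_negative floor negative CBF at zero (default `FALSE`).
#' @return A [volume_grid()] of CBF with attributes `asl_parameters` and
#'   `n_masked_pd`.
#' @export
compute_cbf <- function(control, label, pd, params = asl_parameters(),
                        mask = NULL, clamp_negative = FALSE) {
  assert_same_geometry(control, label, pd, what = "control/label/pd images")
  if (!inherits(params, "asl_parameters"))
    stop("'params' must be created with asl_parameters()", call. = FALSE)
  eval_mask <- if (is.null(mask)) {
    array(TRUE, dim = dim(control$data))
  } else {
    assert_same_geometry(control, mask, what = "image and mask")
    mask$data
  }
  pdv <- pd$data
  n_nonpos <- sum(eval_mask & pdv <= 0)
  if (n_nonpos > 0)
    stop(sprintf("pd image has %d non-positive voxels inside the evaluation mask",
                 n_nonpos), call. = FALSE)
  med <- stats::median(pdv[eval_mask])
  tiny <- eval_mask & (pdv < 1e-9 * med)
  k <- cbf_scale_factor(params)
  cbf <- k * (control$data - label$data) / pdv
  cbf[!eval_mask] <- NA_real_
  cbf[tiny] <- NA_real_
  if (clamp_negative) cbf <- pmax(cbf, 0)
  out <- volume_grid(cbf, control$spacing, control$origin)
  attr(out, "asl_parameters") <- params
  attr(out, "n_masked_pd") <- sum(tiny)
  out
}

#' Relative CBF against a reference region
#'
#' Divides a CBF map by the scalar mean CBF over a reference mask
#' (contralateral mirrored gray matter for unilateral lesions, or an insula
#' gray-matter region for midline lesions), yielding the rCBF map that the
#' hyper-perfusion threshold is applied to.
#'
#' @param cbf a [volume_grid()] CBF map.
#' @param reference a nonempty [structure_mask()] with positive mean CBF.
#' @return A [volume_grid()] of rCBF with attribute `reference_mean_cbf`.
#' @export
relative_cbf <- function(cbf, reference) {
  assert_same_geometry(cbf, reference, what = "CBF map and reference mask")
  if (!any(reference$data))
    stop("reference mask is empty", call. = FALSE)
  m <- mean(cbf$data[reference$data], na.rm = TRUE)
  if (!is.finite(m) || m <= 0)
    stop(sprintf("mean reference CBF (%.3g) must be positive", m),
         call. = FALSE)
  out <- volume_grid(cbf$data / m, cbf$spacing, cbf$origin)
  attr(out, "reference_mean_cbf") <- m
  out
}

#' Build the rCBF reference region
#'
#' For the unilateral scenario, reflects the lesion mask across the grid's
#' mid-sagittal plane (the central x-plane) and intersects it with the
#' gray-matter tissue mask, giving the contralateral mirrored gray matter.
#' For the midline scenario (lesion straddling the midline, where the mirror
#' would overlap the lesion itself), the configured insula-analog
#' gray-matter mask is returned instead.
#'
#' @param mask lesion [structure_mask()] (typically the GTV).
#' @param gray_matter gray-matter tissue [structure_mask()].
#' @param scenario `"unilateral"` or `"midline"`.
#' @param insula insula-analog reference mask, required for `"midline"`.
#' @return A [structure_mask()] named `"rcbf-reference"`.
#' @export
mirror_reference <- function(mask, gray_matter,
                             scenario = c("unilateral", "midline"),
                             insula = NULL) {
  scenario <- match.arg(scenario)
  if (scenario == "midline") {
    if (is.null(insula))
      stop("the midline scenario needs an insula-analog reference mask",
           call. = FALSE)
    out <- mask_intersect(insula, gray_matter, name = "rcbf-reference")
    if (!any(out$data))
      stop("insula-analog reference has no gray-matter voxels", call. = FALSE)
    return(out)
  }
  assert_same_geometry(mask, gray_matter, what = "lesion and gray-matter masks")
  out <- mask_intersect(reflect_mask(mask), gray_matter,
                        name = "rcbf-reference")
  if (!any(out$data))
    stop(paste0("mirrored lesion contains no gray matter; for midline or ",
                "widely diffuse lesions use scenario = \"midline\" with an ",
                "insula reference"), call. = FALSE)
  out
}
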