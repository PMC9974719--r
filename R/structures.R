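#' Segment the hyper-perfusion subvolume (GTV-ASL)
#'
#' Thresholds the relative-CBF map inside the GTV: voxels with
#' `rCBF > threshold` (strictly greater than, by default 1.4) form the
#' GTV-ASL, the automatic analog of the high-perfusion volume used as the
#' dose-painting boost target.  The result is always contained in the GTV.
#' An empty result is not an error: it is returned with attribute
#' `empty = TRUE` and a warning, and downstream planning falls back to the
#' conventional plan.
#'
#' @param relative_cbf a [volume_grid()] rCBF map (see [relative_cbf()]).
#' @param gtv the gross tumor volume [structure_mask()].
#' @param threshold rCBF cut (default 1.4).
#' @param strict use strict `>` (default); `FALSE` switches to `>=` for
#'   sensitivity checks.
#' @return A [structure_mask()] named `"gtv_asl"` with attribute `empty`.
#' @export
segment_hyperperfusion <- function(relative_cbf, gtv, threshold = 1.4,
                                   strict = TRUE) {
  assert_same_geometry(relative_cbf, gtv, what = "rCBF map and GTV")
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  v <- relative_cbf$data
  sel <- if (strict) v > threshold else v >= threshold
  sel[is.na(sel)] <- FALSE
  sel <- sel & gtv$data
  out <- mask_like("gtv_asl", sel, gtv)
  attr(out, "empty") <- !any(sel)
  if (attr(out, "empty"))
    warning("no GTV voxel exceeds the rCBF threshold; GTV-ASL is empty ",
            "and dose-painted plans will fall back to the conventional plan",
            call. = FALSE)
  out
}

#' Margin policy for the target-volume cascade
#'
#' The margins of the clinical cascade: CTV = GTV + 10 mm (microscopic
#' spread), PTV = CTV + 5 mm (setup uncertainty), PTV-ASL = GTV-ASL + 3 mm.
#'
#' @param ctv_margin_mm,ptv_margin_mm,ptv_asl_margin_mm margins in mm.
#' @param clip_to name of the mask targets are clipped to (external-beam
#'   convention: the body), or `NULL` to disable clipping.
#' @return An object of class `margin_policy`.
#' @export
margin_policy <- function(ctv_margin_mm = 10, ptv_margin_mm = 5,
                          ptv_asl_margin_mm = 3, clip_to = "body") {
  if (any(c(ctv_margin_mm, ptv_margin_mm, ptv_asl_margin_mm) < 0))
    stop("margins must be non-negative", call. = FALSE)
  structure(list(ctv_margin_mm = ctv_margin_mm, ptv_margin_mm = ptv_margin_mm,
                 ptv_asl_margin_mm = ptv_asl_margin_mm, clip_to = clip_to),
            class = "margin_policy")
}

#' Isotropic physical-distance margin expansion
#'
#' Expands a mask by a physical margin: the result contains every voxel
#' whose centre lies within `margin_mm` (Euclidean distance in mm, honoring
#' anisotropic spacing) of some mask voxel centre.  Distances are computed
#' with an exact Euclidean distance transform, so the result matches a
#' brute-force all-pairs computation.
#'
#' @param mask a nonempty [structure_mask()].
#' @param margin_mm margin in mm (0 returns the mask unchanged).
#' @param clip optional [structure_mask()]; the result is intersected with it.
#' @param name name for the result.
#' @return A [structure_mask()]; always a superset of `mask` (before
#'   clipping).
#' @export
expand_margin <- function(mask, margin_mm, clip = NULL,
                          name = sprintf("%s+%gmm", mask$name, margin_mm)) {
  if (margin_mm < 0) stop("margin must be non-negative", call. = FALSE)
  if (!any(mask$data)) stop("cannot expand an empty mask", call. = FALSE)
  out <- if (margin_mm == 0) {
    mask$data
  } else {
    d2 <- .edt3d(mask$data, mask$spacing)
    d2 <= margin_mm^2 * (1 + 1e-9) + 1e-9
  }
  res <- mask_like(name, out, mask)
  if (!is.null(clip)) res <- mask_intersect(res, clip, name = name)
  res
}

#' Derive the full target-volume cascade
#'
#' From the GTV and the hyper-perfusion subvolume GTV-ASL, derives
#' GTV-SUB = GTV minus GTV-ASL, CTV = GTV + 10 mm, PTV = CTV + 5 mm,
#' PTV-ASL = GTV-ASL + 3 mm, and PTV-SUB = PTV minus PTV-ASL.  CTV, PTV and
#' PTV-ASL are clipped to the `clip` mask (body, by default) when given.
#' An empty GTV-ASL degenerates gracefully: PTV-ASL is empty and
#' PTV-SUB = PTV.
#'
#' @param gtv GTV [structure_mask()].
#' @param gtv_asl GTV-ASL [structure_mask()] (subset of the GTV).
#' @param policy a [margin_policy()].
#' @param clip optional clipping mask (typically the body).
#' @return Named list of [structure_mask()]s (`gtv`, `gtv_asl`, `gtv_sub`,
#'   `ctv`, `ptv`, `ptv_asl`, `ptv_sub`) with attribute `ptv_asl_ratio`, the
#'   PTV-ASL/PTV volume ratio.
#' @export
build_structure_cascade <- function(gtv, gtv_asl, policy = margin_policy(),
                                    clip = NULL) {
  assert_same_geometry(gtv, gtv_asl, what = "GTV and GTV-ASL")
  if (any(gtv_asl$data & !gtv$data))
    stop("GTV-ASL must be contained in the GTV", call. = FALSE)
  gtv_sub <- mask_subtract(gtv, gtv_asl, name = "gtv_sub")
  ctv <- expand_margin(gtv, policy$ctv_margin_mm, clip = clip, name = "ctv")
  ptv <- expand_margin(ctv, policy$ptv_margin_mm, clip = clip, name = "ptv")
  ptv_asl <- if (any(gtv_asl$data)) {
    expand_margin(gtv_asl, policy$ptv_asl_margin_mm, clip = clip,
                  name = "ptv_asl")
  } else {
    empty <- empty_mask_like("ptv_asl", gtv)
    empty
  }
  ptv_sub <- mask_subtract(ptv, ptv_asl, name = "ptv_sub")
  out <- list(gtv = gtv, gtv_asl = gtv_asl, gtv_sub = gtv_sub, ctv = ctv,
              ptv = ptv, ptv_asl = ptv_asl, ptv_sub = ptv_sub)
  attr(out, "ptv_asl_ratio") <- volume_cc(ptv_asl) / volume_cc(ptv)
  out
}
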