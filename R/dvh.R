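#' Cumulative dose-volume histogram of a structure
#'
#' Bins the in-mask voxel doses on a uniform grid of width `bin_width_gy`
#' and accumulates from the top: `cum_volume_fraction[i]` is the fraction of
#' the structure volume receiving at least `dose_bins[i]`.  The convention
#' is voxel-counting (each voxel wholly in or out of the mask, no sub-voxel
#' weighting), so all absolute volumes derive from the voxel volume.
#'
#' @param dose a [volume_grid()] dose grid in Gy.
#' @param structure a nonempty [structure_mask()] on the same geometry.
#' @param bin_width_gy histogram bin width (default 0.1 Gy).
#' @return An object of class `dvh_curve`: list with `dose_bins` (Gy edges,
#'   starting at 0), `cum_volume_fraction` (non-increasing, 1 at 0 Gy, 0
#'   beyond the maximum dose), `structure_volume_cc` and `structure`.
#' @export
compute_dvh <- function(dose, structure, bin_width_gy = 0.1) {
  assert_same_geometry(dose, structure, what = "dose and structure")
  if (!any(structure$data))
    stop(sprintf("structure '%s' is empty", structure$name), call. = FALSE)
  if (bin_width_gy <= 0) stop("bin width must be positive", call. = FALSE)
  doses <- dose$data[structure$data]
  edges <- seq(0, max(doses, 0) + bin_width_gy, by = bin_width_gy)
  # fraction of voxels receiving at least each edge dose
  cum <- 1 - (stats::ecdf(doses))(edges - bin_width_gy * 1e-9)
  cum[1] <- 1  # every voxel receives at least 0 Gy
  structure(list(dose_bins = edges, cum_volume_fraction = cum,
                 structure_volume_cc = volume_cc(structure),
                 structure = structure$name,
                 min_dose_gy = min(doses), max_dose_gy = max(doses)),
            class = "dvh_curve")
}

#' Dose received by the hottest fraction of a structure (Dx%)
#'
#' `dose_at_volume(dvh, 0.02)` is D2%, the minimum dose received by the
#' hottest 2% of the structure volume.  The cumulative curve is linearly
#' interpolated between bin edges; ties break toward the higher dose so the
#' value reported is a guaranteed-received dose.
#'
#' @param dvh a [compute_dvh()] result.
#' @param volume_fraction fraction in (0, 1].
#' @return Dose in Gy.
#' @export
dose_at_volume <- function(dvh, volume_fraction) {
  if (volume_fraction <= 0 || volume_fraction > 1)
    stop("volume_fraction must be in (0, 1]", call. = FALSE)
  frac <- dvh$cum_volume_fraction
  edges <- dvh$dose_bins
  clamp <- function(d) min(max(d, dvh$min_dose_gy), dvh$max_dose_gy)
  if (volume_fraction >= frac[1]) return(dvh$min_dose_gy)
  i <- which(frac <= volume_fraction)[1]  # first edge at/below the fraction
  if (frac[i] == volume_fraction) {
    # tie: report the highest dose still achieving the fraction
    j <- max(which(frac == volume_fraction))
    return(clamp(edges[j]))
  }
  # interpolate between edges i-1 and i
  f0 <- frac[i - 1]; f1 <- frac[i]
  clamp(edges[i - 1] +
          (f0 - volume_fraction) / (f0 - f1) * (edges[i] - edges[i - 1]))
}

#' Dose received by the hottest absolute volume (DVcc)
#'
#' `dose_at_absolute_volume(dvh, 0.1)` is D0.1cc, the minimum dose received
#' by the hottest 0.1 cc of the structure.  If the requested volume equals
#' or exceeds the structure volume, the minimum structure dose is returned
#' (with a warning when the structure is genuinely smaller than `cc`).
#'
#' @param dvh a [compute_dvh()] result.
#' @param cc absolute volume in cubic centimetres (default 0.1).
#' @return Dose in Gy.
#' @export
dose_at_absolute_volume <- function(dvh, cc = 0.1) {
  if (cc <= 0) stop("cc must be positive", call. = FALSE)
  if (cc >= dvh$structure_volume_cc) {
    if (cc > dvh$structure_volume_cc)
      warning(sprintf("structure '%s' (%.3g cc) is smaller than %g cc; returning its minimum dose",
                      dvh$structure, dvh$structure_volume_cc, cc), call. = FALSE)
    return(dvh$min_dose_gy)
  }
  dose_at_volume(dvh, cc / dvh$structure_volume_cc)
}

#' Conformity index of a plan
#'
#' \deqn{CI = V_{t,ref}^2 / (V_t \cdot V_{ref})} where \eqn{V_t} is the
#' target volume, \eqn{V_{ref}} the volume of all voxels receiving at least
#' the reference dose, and \eqn{V_{t,ref}} the part of the target covered by
#' the reference dose.  CI = 1 means the reference isodose exactly conforms
#' to the target; the index penalizes both under-coverage and spill of the
#' reference dose outside the target.  Returns 0 when no voxel reaches the
#' reference dose.
#'
#' @param dose a [volume_grid()] dose grid.
#' @param target a nonempty [structure_mask()].
#' @param reference_dose_gy positive reference (prescription) dose.
#' @return CI in `[0, 1]`.
#' @export
conformity_index <- function(dose, target, reference_dose_gy) {
  assert_same_geometry(dose, target, what = "dose and target")
  if (!any(target$data)) stop("target is empty", call. = FALSE)
  if (reference_dose_gy <= 0)
    stop("reference dose must be positive", call. = FALSE)
  covered <- dose$data >= reference_dose_gy
  v_ref <- sum(covered)
  if (v_ref == 0) return(0)
  v_t <- sum(target$data)
  v_t_ref <- sum(covered & target$data)
  v_t_ref^2 / (v_t * v_ref)
}

#' Homogeneity index from D2%, D98% and D50%
#'
#' \deqn{HI = (D_{2\%} - D_{98\%}) / D_{50\%}}; 0 indicates a perfectly
#' uniform target dose.
#'
#' @param d2,d98,d50 dose points in Gy (`d2 >= d98`, `d50 > 0`).
#' @return HI (dimensionless, >= 0).
#' @export
homogeneity_index <- function(d2, d98, d50) {
  if (d50 <= 0) stop("D50% must be positive", call. = FALSE)
  if (d2 < d98) stop("D2% cannot be below D98%", call. = FALSE)
  (d2 - d98) / d50
}

#' Target coverage at a prescription dose
#'
#' Fraction of target voxels receiving at least the prescription dose.
#'
#' @param dose a [volume_grid()] dose grid.
#' @param target a nonempty [structure_mask()].
#' @param prescription_gy prescription dose in Gy.
#' @return Fraction in `[0, 1]`.
#' @export
coverage <- function(dose, target, prescription_gy) {
  assert_same_geometry(dose, target, what = "dose and target")
  if (!any(target$data)) stop("target is empty", call. = FALSE)
  mean(dose$data[target$data] >= prescription_gy)
}
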