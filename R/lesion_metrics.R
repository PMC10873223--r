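#' Lesion growth assessment
#'
#' The lesion growth ratio is the follow-up DWI lesion volume divided by
#' the baseline DWI lesion volume; lesion growth is a ratio of at least
#' 1.2 (the margin absorbs vasogenic edema of the follow-up lesion).
#'
#' @param v_base baseline lesion volume, mL (> 0).
#' @param v_fu follow-up lesion volume, mL.
#' @param threshold growth threshold on the ratio (default 1.2,
#'   boundary inclusive).
#' @return list with `baseline_ml`, `followup_ml`, `lesion_growth_ratio`
#'   and logical `growth`.
#' @export
growth_assessment <- function(v_base, v_fu, threshold = 1.2) {
  if (!is.finite(v_base) || v_base <= 0)
    stop("baseline lesion volume must be positive")
  if (!is.finite(v_fu) || v_fu < 0)
    stop("follow-up lesion volume must be nonnegative")
  ratio <- v_fu / v_base
  list(baseline_ml = v_base, followup_ml = v_fu,
       lesion_growth_ratio = ratio, growth = ratio >= threshold)
}

#' Threshold a Tmax map at 6 seconds
#'
#' Voxels with time-to-maximum strictly greater than the threshold are
#' critically hypoperfused; their volume is the conventional penumbra
#' estimate from perfusion imaging.
#'
#' @param tmax_map 3D numeric array of Tmax values in seconds.
#' @param threshold_s threshold in seconds (default 6, strict `>`).
#' @param voxel_size_mm voxel size, mm.
#' @return list with logical `mask` and `volume_ml`.
#' @export
tmax_threshold <- function(tmax_map, threshold_s = 6,
                           voxel_size_mm = c(1, 1, 1)) {
  if (any(tmax_map < 0)) stop("Tmax map contains negative values")
  mask <- tmax_map > threshold_s
  list(mask = mask, volume_ml = mask_volume(mask, voxel_size_mm))
}

#' Match a DWI lesion to the collateral-map phase it best approximates
#'
#' Returns the phase (capillary, early venous, late venous or delay)
#' whose hypoperfusion mask has maximal Dice overlap with the DWI lesion
#' mask; ties break toward the later (smaller, nested) phase.  The match
#' is `"undetermined"` when the best Dice falls below `min_dice`, when
#' all hypoperfusion masks are empty, or when the DWI mask itself is
#' empty -- the situation of good-collateral patients without a
#' hypoperfused lesion approximating their small DWI lesions.
#'
#' @param hypo a `hypoperfusion_set`.
#' @param dwi_mask logical 3D array.
#' @param min_dice minimum acceptable Dice (default 0.2).
#' @return list with `phase` (name or `"undetermined"`) and `dice`.
#' @export
match_phase <- function(hypo, dwi_mask, min_dice = 0.2) {
  stopifnot(inherits(hypo, "hypoperfusion_set"))
  if (!any(dwi_mask)) {
    warning("empty DWI mask; phase undetermined")
    return(list(phase = "undetermined", dice = NA_real_))
  }
  d <- vapply(hypo$masks, dice, numeric(1), b = dwi_mask)
  if (all(vapply(hypo$masks, sum, numeric(1)) == 0) ||
      max(d) < min_dice)
    return(list(phase = "undetermined", dice = max(d)))
  best <- max(which(d == max(d)))  # ties -> later phase
  list(phase = names(hypo$masks)[best], dice = d[[best]])
}

#' Precise and approximate collateral ratios
#'
#' The precise collateral ratio (pCR) is the hypoperfused lesion volume
#' of the phase matching the follow-up DWI lesion divided by that of the
#' phase matching the baseline DWI lesion; the approximate collateral
#' ratio (aCR) is the capillary-phase volume divided by the early
#' venous-phase volume.  When a phase is undetermined or a denominator
#' volume is zero the corresponding ratio falls back to 1.0 (the
#' no-growth value observed in good-collateral patients).
#'
#' @param hypo a `hypoperfusion_set`.
#' @param phase_baseline,phase_fu phase names or `"undetermined"`.
#' @return list with `pcr` and `acr`.
#' @export
collateral_ratios <- function(hypo, phase_baseline, phase_fu) {
  stopifnot(inherits(hypo, "hypoperfusion_set"))
  v <- hypo$volumes_ml
  ratio <- function(num, den) {
    if (identical(num, "undetermined") || identical(den, "undetermined"))
      return(1.0)
    if (v[[den]] <= 0) return(1.0)
    v[[num]] / v[[den]]
  }
  list(pcr = ratio(phase_fu, phase_baseline),
       acr = ratio("capillary", "early_venous"))
}

#' Dichotomise a continuous predictor of lesion growth
#'
#' @param ratio nonnegative predictor value (pCR, aCR or Tmax/DWI
#'   ratio).
#' @param threshold decision threshold (default 1.2, mirroring the
#'   lesion-growth outcome definition; boundary inclusive).
#' @return logical: predicted growth.
#' @export
predict_growth <- function(ratio, threshold = 1.2) {
  if (any(ratio < 0)) stop("predictor ratio must be nonnegative")
  ratio >= threshold
}
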