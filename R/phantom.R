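#' Gamma-variate bolus curve
#'
#' Standard first-pass bolus model for contrast passage: zero before the
#' onset `t0`, then
#' `amplitude * ((t - t0)/tp)^alpha * exp(alpha * (1 - (t - t0)/tp))`
#' with `tp = alpha * beta`, so the curve attains its maximum `amplitude`
#' exactly at `t0 + tp`.
#'
#' @param t time(s) in seconds (vectorised).
#' @param t0 bolus onset in seconds.
#' @param alpha,beta positive shape/scale parameters.
#' @param amplitude peak signal intensity.
#' @return signal intensity at `t`.
#' @export
gamma_variate <- function(t, t0, alpha, beta, amplitude = 1) {
  if (!is.numeric(alpha) || alpha <= 0 || !is.numeric(beta) || beta <= 0)
    stop("gamma_variate: alpha and beta must be positive")
  tp <- alpha * beta
  s <- (t - t0) / tp
  out <- numeric(length(t))
  pos <- s > 0
  out[pos] <- amplitude * s[pos]^alpha * exp(alpha * (1 - s[pos]))
  out
}

# time from onset at which the rising limb reaches `frac` of the peak
gamma_rise_time <- function(alpha, beta, frac) {
  tp <- alpha * beta
  stats::uniroot(function(s) s^alpha * exp(alpha * (1 - s)) - frac,
                 interval = c(1e-9, 1), tol = 1e-10)$root * tp
}

# time from onset at which the falling limb decays to `frac` of the peak
gamma_decay_time <- function(alpha, beta, frac) {
  tp <- alpha * beta
  f <- function(s) s^alpha * exp(alpha * (1 - s)) - frac
  hi <- 2
  while (f(hi) > 0) hi <- hi * 2
  stats::uniroot(f, interval = c(1, hi), tol = 1e-10)$root * tp
}

#' Digital perfusion phantom configuration
#'
#' Defines a 4D dynamic contrast-enhanced MRA-like phantom: a
#' gamma-variate bolus sweeps the contralateral hemisphere on time, each
#' of the 8 ipsilateral MCA regions is delayed by a configurable
#' collateral filling delay, and the superior sagittal sinus ROI carries
#' a venous curve lagging the arterial one.
#'
#' @param grid_shape 3 positive integers, voxel grid (x = left-right).
#' @param voxel_size_mm 3 positive reals, voxel size in mm.
#' @param frame_interval_s frame spacing in seconds.
#' @param n_frames number of time frames.
#' @param arterial_arrival_s bolus onset of the contralateral (normal)
#'   arterial curve, seconds.
#' @param arterial_peak_s optional arterial peak time; when supplied the
#'   bolus scale `beta` is adjusted so the peak falls there, otherwise
#'   the peak is `arterial_arrival_s + alpha * beta`.
#' @param venous_lag_s venous peak = arterial peak + `venous_lag_s`.
#' @param bolus_shape list with `alpha`, `beta`, `amplitude`.
#' @param region_delay_s numeric length 8: collateral filling delay in
#'   seconds for each ipsilateral MCA region (0 = normal perfusion).
#' @param noise_sd standard deviation of i.i.d. Gaussian signal noise.
#' @param baseline_offset constant pre-contrast signal level.
#' @param lesion_spec optional list with integer region-id vectors
#'   `baseline` and `followup` defining the DWI lesion masks as unions of
#'   ipsilateral regions; `NULL` derives them from the delay profile
#'   (baseline = regions hypoperfused through the early venous phase,
#'   follow-up = regions hypoperfused in the capillary phase).
#' @param threshold_fraction relative perfusion threshold used when
#'   computing the ground-truth hypoperfusion profile (matches the
#'   detection default).
#' @param seed integer RNG seed.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(64L, 64L, 32L),
                           voxel_size_mm = c(1.8, 1.8, 4),
                           frame_interval_s = 1,
                           n_frames = 60L,
                           arterial_arrival_s = 8,
                           arterial_peak_s = NULL,
                           venous_lag_s = 4,
                           bolus_shape = list(alpha = 3, beta = 3,
                                              amplitude = 100),
                           region_delay_s = rep(0, 8),
                           noise_sd = 5,
                           baseline_offset = 0,
                           lesion_spec = NULL,
                           threshold_fraction = 0.5,
                           seed = 1L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape > 0),
            all(voxel_size_mm > 0), frame_interval_s > 0, n_frames >= 10,
            venous_lag_s > 0, noise_sd >= 0)
  alpha <- bolus_shape$alpha; beta <- bolus_shape$beta
  if (is.null(alpha) || is.null(beta) || alpha <= 0 || beta <= 0)
    stop("bolus_shape: alpha and beta must be positive")
  if (!is.null(arterial_peak_s)) {
    if (arterial_peak_s <= arterial_arrival_s)
      stop("arterial arrival must precede arterial peak")
    beta <- (arterial_peak_s - arterial_arrival_s) / alpha
    bolus_shape$beta <- beta
  }
  if (arterial_arrival_s <= 0) stop("arterial_arrival_s must be positive")
  region_delay_s <- as.numeric(region_delay_s)
  if (length(region_delay_s) != 8L || any(region_delay_s < 0) ||
      any(!is.finite(region_delay_s)))
    stop("region_delay_s must be 8 nonnegative delays")
  if (!is.null(lesion_spec)) {
    ids <- unlist(lapply(lesion_spec[c("baseline", "followup")],
                         function(sp) if (is.list(sp)) sp$region else sp))
    if (length(ids) && !all(ids %in% 1:8))
      stop("lesion_spec references unknown regions")
  }
  # acquisition must cover the venous half-decay of the slowest curve
  s_half <- gamma_decay_time(alpha, beta, 0.5)
  slowest <- arterial_arrival_s +
    max(max(region_delay_s), venous_lag_s) + s_half
  total <- (n_frames - 1) * frame_interval_s
  if (slowest > total)
    stop(sprintf(paste0("acquisition (%.1f s) does not cover the venous ",
                        "half-decay of the slowest curve (%.1f s)"),
                 total, slowest))
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size_mm = voxel_size_mm,
                 frame_interval_s = frame_interval_s,
                 n_frames = as.integer(n_frames),
                 arterial_arrival_s = arterial_arrival_s,
                 venous_lag_s = venous_lag_s,
                 bolus_shape = bolus_shape,
                 region_delay_s = region_delay_s,
                 noise_sd = noise_sd,
                 baseline_offset = baseline_offset,
                 lesion_spec = lesion_spec,
                 threshold_fraction = threshold_fraction,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

phantom_frame_times <- function(config)
  (seq_len(config$n_frames) - 1) * config$frame_interval_s

# Analytic phase boundaries implied by a config: the landmark/boundary
# rules of detect_bolus()/segment_phases() applied to the continuous
# noiseless curves.
true_phase_windows <- function(config, arrival_fraction = 0.1) {
  a <- config$bolus_shape$alpha; b <- config$bolus_shape$beta
  arr <- config$arterial_arrival_s
  art_arrival <- arr + gamma_rise_time(a, b, arrival_fraction)
  art_peak <- arr + a * b
  ven_t0 <- arr + config$venous_lag_s
  ven_peak <- ven_t0 + a * b
  ven_half <- ven_t0 + gamma_decay_time(a, b, 0.5)
  ven_late <- ven_t0 + gamma_decay_time(a, b, 0.1)
  end <- (config$n_frames - 1) * config$frame_interval_s
  phase_windows(c(art_arrival, art_peak, ven_peak,
                  min(ven_half, end), min(ven_late, end)), end)
}

# Noiseless windowed temporal maximum of a delayed bolus curve, on the
# discrete frame grid (what the max-intensity projection sees).
windowed_bolus_max <- function(config, window, delay) {
  t <- phantom_frame_times(config)
  t <- t[t >= window[1] & t < window[2]]
  if (!length(t)) return(0)
  max(gamma_variate(t, config$arterial_arrival_s + delay,
                    config$bolus_shape$alpha, config$bolus_shape$beta,
                    config$bolus_shape$amplitude))
}

# For each region and scoring phase: is a region with this filling delay
# hypoperfused (windowed max < threshold * contralateral windowed max),
# with the persisting-region rule applied cumulatively.
region_hypo_profile <- function(config, windows = true_phase_windows(config)) {
  phases <- c("capillary", "early_venous", "late_venous", "delay")
  out <- matrix(FALSE, nrow = 8, ncol = length(phases),
                dimnames = list(NULL, phases))
  for (p in phases) {
    w <- unlist(windows$windows[[p]])
    ref <- windowed_bolus_max(config, w, 0)
    for (r in 1:8) {
      hypo <- windowed_bolus_max(config, w, config$region_delay_s[r]) <
        config$threshold_fraction * ref
      prev <- if (p == "capillary") TRUE else
        out[r, match(p, phases) - 1L]
      out[r, p] <- hypo && prev
    }
  }
  out
}

# Smallest filling delay that renders a region hypoperfused in `phase`
# (searched on a 0.25 s grid; NA if unattainable within coverage).
min_delay_for_phase <- function(config, phase,
                                windows = true_phase_windows(config)) {
  w <- unlist(windows$windows[[phase]])
  ref <- windowed_bolus_max(config, w, 0)
  s_half <- gamma_decay_time(config$bolus_shape$alpha,
                             config$bolus_shape$beta, 0.5)
  dmax <- (config$n_frames - 1) * config$frame_interval_s -
    config$arterial_arrival_s - s_half
  for (d in seq(0, dmax, by = 0.25)) {
    if (windowed_bolus_max(config, w, d) < config$threshold_fraction * ref)
      return(d)
  }
  NA_real_
}

#' Region delays realising a target delayed-region count profile
#'
#' Chooses per-region collateral filling delays so that, in the noiseless
#' phantom, exactly `counts["capillary"]` regions are hypoperfused in the
#' capillary phase, `counts["early_venous"]` of those persist into the
#' early venous phase, and `counts["late_venous"]` into the late venous
#' phase.  Delays are placed midway between the phase-boundary delay
#' thresholds for robustness to noise.
#'
#' @param counts named integer vector (capillary, early_venous,
#'   late_venous), non-increasing, each in 0..8.
#' @param config a `phantom_config` providing timing (its delays are
#'   ignored).
#' @return numeric length 8 of delays in seconds.
#' @export
delays_for_counts <- function(counts, config = phantom_config()) {
  cc <- counts[["capillary"]]; ee <- counts[["early_venous"]]
  ll <- counts[["late_venous"]]
  if (!(cc >= ee && ee >= ll) || any(c(cc, ee, ll) < 0) || cc > 8)
    stop("counts must be non-increasing and within 0..8")
  base <- phantom_config(grid_shape = config$grid_shape,
                         voxel_size_mm = config$voxel_size_mm,
                         frame_interval_s = config$frame_interval_s,
                         n_frames = config$n_frames,
                         arterial_arrival_s = config$arterial_arrival_s,
                         venous_lag_s = config$venous_lag_s,
                         bolus_shape = config$bolus_shape,
                         noise_sd = 0,
                         threshold_fraction = config$threshold_fraction)
  w <- true_phase_windows(base)
  d_cap <- min_delay_for_phase(base, "capillary", w)
  d_ev  <- min_delay_for_phase(base, "early_venous", w)
  d_lv  <- min_delay_for_phase(base, "late_venous", w)
  d_dl  <- min_delay_for_phase(base, "delay", w)
  s_half <- gamma_decay_time(base$bolus_shape$alpha,
                             base$bolus_shape$beta, 0.5)
  dmax <- (base$n_frames - 1) * base$frame_interval_s -
    base$arterial_arrival_s - s_half
  if (is.na(d_dl)) d_dl <- dmax
  if (any(is.na(c(d_cap, d_ev, d_lv))))
    stop("acquisition too short to realise the requested profile")
  mid <- function(a, b) (a + b) / 2
  delays <- rep(0, 8)
  k <- 0
  add <- function(n, d) {
    if (n > 0) delays[k + seq_len(n)] <<- d
    k <<- k + n
  }
  add(ll, mid(d_lv, d_dl))
  add(ee - ll, mid(d_ev, d_lv))
  add(cc - ee, mid(d_cap, d_ev))
  delays
}

#' Generate a 4D perfusion phantom with ground truth
#'
#' Builds the 4D dynamic series (contralateral hemisphere and arterial
#' ROI carry the undelayed bolus, each ipsilateral MCA region the bolus
#' shifted by its collateral filling delay, the venous ROI the bolus
#' shifted by the venous lag; Gaussian noise added everywhere), plus the
#' region atlas, DWI-like lesion masks, a Tmax map equal to the
#' configured voxelwise delay, and a ground-truth record (true phase
#' boundaries, per-phase hypoperfusion masks and volumes, intended
#' collateral score, lesion volumes).
#'
#' @param config a [phantom_config()].
#' @return object of class `phantom`: list with `series` (a `series4d`),
#'   `atlas`, `truth`, `dwi_baseline`, `dwi_followup`, `tmax`, `config`.
#' @export
generate_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  atlas <- build_region_atlas(config$grid_shape, config$voxel_size_mm)
  times <- phantom_frame_times(config)
  lab <- atlas$labels
  nvox <- length(lab)

  # onset offset per voxel (relative to arterial arrival); NA = no signal
  offs <- rep(NA_real_, nvox)
  for (r in 1:8) offs[lab == r] <- config$region_delay_s[r]
  offs[lab %in% c(contra_region_labels(), 21L)] <- 0
  offs[lab == 22L] <- config$venous_lag_s
  uoff <- sort(unique(offs[!is.na(offs)]))
  curves <- t(vapply(uoff, function(d)
    gamma_variate(times, config$arterial_arrival_s + d,
                  config$bolus_shape$alpha, config$bolus_shape$beta,
                  config$bolus_shape$amplitude),
    numeric(length(times))))

  M <- matrix(config$baseline_offset, nrow = nvox, ncol = length(times))
  idx <- match(offs, uoff)
  sel <- which(!is.na(idx))
  M[sel, ] <- M[sel, ] + curves[idx[sel], ]
  set.seed(config$seed)
  if (config$noise_sd > 0)
    M <- M + stats::rnorm(length(M), sd = config$noise_sd)
  series <- series4d(array(M, dim = c(config$grid_shape, length(times))),
                     times, config$voxel_size_mm)

  # ground truth
  windows <- true_phase_windows(config)
  # frame-quantized reference boundaries: landmark detection applied to
  # the noiseless frame-sampled curves (the best any frame-sampled
  # detector can recover)
  art_curve <- time_curve(times, config$baseline_offset +
    gamma_variate(times, config$arterial_arrival_s,
                  config$bolus_shape$alpha, config$bolus_shape$beta,
                  config$bolus_shape$amplitude))
  ven_curve <- time_curve(times, config$baseline_offset +
    gamma_variate(times, config$arterial_arrival_s + config$venous_lag_s,
                  config$bolus_shape$alpha, config$bolus_shape$beta,
                  config$bolus_shape$amplitude))
  windows_discrete <- suppressWarnings(
    segment_phases(detect_bolus(art_curve), detect_bolus(ven_curve),
                   acquisition_end = utils::tail(times, 1) +
                     config$frame_interval_s,
                   frame_times = times))
  profile <- region_hypo_profile(config, windows)
  region_mask <- lapply(1:8, function(r) lab == r)
  phase_mask <- function(flags) {
    m <- array(FALSE, dim = config$grid_shape)
    for (r in which(flags)) m <- m | region_mask[[r]]
    m
  }
  true_masks <- lapply(colnames(profile),
                       function(p) phase_mask(profile[, p]))
  names(true_masks) <- colnames(profile)
  vox_ml <- prod(config$voxel_size_mm) / 1000
  true_vols <- vapply(true_masks, sum, numeric(1)) * vox_ml
  counts <- colSums(profile)[c("capillary", "early_venous", "late_venous")]
  intended <- collateral_score(list(counts = counts))

  # lesion masks: unions of ipsilateral regions, or a central sub-region
  # fraction (list(region =, fraction =)) for small non-growing lesions
  sub_region_mask <- function(r, fraction) {
    idx <- which(region_mask[[r]], arr.ind = TRUE)
    ctr <- colMeans(idx)
    half <- (apply(idx, 2, max) - apply(idx, 2, min) + 1) *
      fraction^(1 / 3) / 2
    m <- array(FALSE, dim = config$grid_shape)
    keep <- abs(idx[, 1] - ctr[1]) <= half[1] &
      abs(idx[, 2] - ctr[2]) <= half[2] &
      abs(idx[, 3] - ctr[3]) <= half[3]
    m[idx[keep, , drop = FALSE]] <- TRUE
    m
  }
  lesion_mask <- function(sp) {
    if (is.list(sp)) sub_region_mask(sp$region, sp$fraction)
    else phase_mask(seq_len(8) %in% sp)
  }
  spec <- config$lesion_spec
  if (is.null(spec)) {
    ev_regions <- which(profile[, "early_venous"])
    cap_regions <- which(profile[, "capillary"])
    if (length(ev_regions)) {
      spec <- list(baseline = ev_regions, followup = cap_regions)
    } else {
      # good collaterals: small lesion, no growth
      r <- if (length(cap_regions)) cap_regions[1] else 3L
      small <- list(region = r, fraction = 0.15)
      spec <- list(baseline = small, followup = small)
    }
  }
  dwi_base <- lesion_mask(spec$baseline)
  dwi_fu <- lesion_mask(spec$followup)

  tmax <- array(0, dim = config$grid_shape)
  for (r in 1:8) tmax[lab == r] <- config$region_delay_s[r]

  truth <- list(windows = windows,
                boundaries = attr(windows, "boundaries"),
                boundaries_discrete = attr(windows_discrete,
                                           "boundaries"),
                region_profile = profile,
                hypo_masks = true_masks,
                hypo_volumes_ml = true_vols,
                counts = counts,
                intended_score = intended$score,
                intended_grade = intended$grade,
                lesion_regions = spec,
                lesion_volume_baseline_ml = sum(dwi_base) * vox_ml,
                lesion_volume_followup_ml = sum(dwi_fu) * vox_ml)
  structure(list(series = series, atlas = atlas, truth = truth,
                 dwi_baseline = dwi_base, dwi_followup = dwi_fu,
                 tmax = tmax, config = config),
            class = "phantom")
}

#' Phantom configuration realising a target collateral score
#'
#' Picks a delayed-region count profile canonical for the requested
#' Table-style collateral perfusion score and converts it to per-region
#' delays via [delays_for_counts()].
#'
#' @param score integer 0..5.
#' @param counts optional explicit count profile overriding the canonical
#'   one (must map to `score`).
#' @param ... passed to [phantom_config()].
#' @return a `phantom_config`.
#' @export
phantom_config_for_score <- function(score, counts = NULL, ...) {
  canonical <- list(`5` = c(0, 0, 0), `4` = c(3, 0, 0), `3` = c(4, 2, 0),
                    `2` = c(6, 3, 0), `1` = c(7, 5, 2), `0` = c(8, 6, 5))
  if (!score %in% 0:5) stop("score must be in 0..5")
  if (is.null(counts)) counts <- canonical[[as.character(score)]]
  counts <- stats::setNames(counts,
                            c("capillary", "early_venous", "late_venous"))
  base <- phantom_config(...)
  delays <- delays_for_counts(counts, base)
  cfg <- phantom_config(grid_shape = base$grid_shape,
                        voxel_size_mm = base$voxel_size_mm,
                        frame_interval_s = base$frame_interval_s,
                        n_frames = base$n_frames,
                        arterial_arrival_s = base$arterial_arrival_s,
                        venous_lag_s = base$venous_lag_s,
                        bolus_shape = base$bolus_shape,
                        region_delay_s = delays,
                        noise_sd = base$noise_sd,
                        baseline_offset = base$baseline_offset,
                        lesion_spec = base$lesion_spec,
                        threshold_fraction = base$threshold_fraction,
                        seed = base$seed)
  sc <- collateral_score(list(counts = counts))
  if (sc$score != score)
    stop("count profile does not map to the requested score")
  cfg
}

#' @export
print.phantom_config <- function(x, ...) {
  cat("<phantom_config> grid", paste(x$grid_shape, collapse = "x"),
      "|", x$n_frames, "frames @", x$frame_interval_s, "s\n")
  cat("  arterial arrival", x$arterial_arrival_s, "s, venous lag",
      x$venous_lag_s, "s, noise sd", x$noise_sd, "\n")
  cat("  region delays:", paste(round(x$region_delay_s, 1),
                                collapse = " "), "s\n")
  invisible(x)
}
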