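#' Generate a synthetic patient cohort with known ground truth
#'
#' Emulates a cohort at the patient level: each patient carries a
#' collateral perfusion grade (default mix 16 good / 29 intermediate /
#' 7 poor per 52 patients), a precise collateral ratio (pCR) drawn from
#' a grade-specific log-normal (fixed at 1.0 for good collaterals, whose
#' lesions do not grow), a lesion growth ratio `pCR * (1 + eps)` with
#' Gaussian relative noise `eps`, an approximate collateral ratio with
#' additional noise, and a Tmax/DWI ratio with a configurable positive
#' multiplicative bias emulating the systematic penumbra overestimation
#' of perfusion imaging.
#'
#' @param n number of patients (>= 2).
#' @param effect_spec list overriding any of: `grade_counts` (named
#'   good/intermediate/poor, summing to `n`), `pcr_median` and
#'   `pcr_sdlog` (named intermediate/poor), `epsilon_sd` (relative noise
#'   of the growth ratio around pCR), `acr_noise_sd`, `tmax_bias`
#'   (multiplicative, > 1 overestimates), `tmax_noise_sdlog`,
#'   `baseline_median_ml` and `baseline_sdlog` (per grade),
#'   `growth_threshold`.
#' @param seed integer RNG seed.
#' @return data frame with one row per patient: `patient_id`, `grade`,
#'   `score`, `v_baseline_ml`, `v_followup_ml`, `lesion_growth_ratio`,
#'   `growth`, `pcr`, `acr`, `tmax6_volume_ml`, `tmax_dwi_ratio`.
#' @export
generate_cohort <- function(n = 52L, effect_spec = list(), seed = 1L) {
  if (n < 2) stop("need at least 2 patients")
  spec <- utils::modifyList(list(
    grade_counts = NULL,
    pcr_median = c(intermediate = 2.8, poor = 3.1),
    pcr_sdlog = c(intermediate = 0.5, poor = 0.8),
    epsilon_sd = 0.08,
    acr_noise_sd = 0.15,
    tmax_bias = 3,
    tmax_noise_sdlog = 0.8,
    baseline_median_ml = c(good = 3.1, intermediate = 11.8, poor = 59.7),
    baseline_sdlog = c(good = 0.6, intermediate = 0.8, poor = 0.8),
    growth_threshold = 1.2
  ), effect_spec)
  bad <- setdiff(names(effect_spec), c(
    "grade_counts", "pcr_median", "pcr_sdlog", "epsilon_sd",
    "acr_noise_sd", "tmax_bias", "tmax_noise_sdlog",
    "baseline_median_ml", "baseline_sdlog", "growth_threshold"))
  if (length(bad))
    stop("unknown effect_spec entries: ", paste(bad, collapse = ", "))
  counts <- spec$grade_counts
  if (is.null(counts)) {
    prop <- c(good = 16, intermediate = 29, poor = 7) / 52
    counts <- floor(prop * n)
    rem <- n - sum(counts)
    if (rem > 0) {
      extra <- order(prop * n - counts, decreasing = TRUE)[seq_len(rem)]
      counts[extra] <- counts[extra] + 1L
    }
  }
  if (sum(counts) != n) stop("grade_counts must sum to n")
  grades <- rep(c("good", "intermediate", "poor"),
                counts[c("good", "intermediate", "poor")])
  set.seed(seed)
  grades <- sample(grades)
  score <- vapply(grades, function(g)
    switch(g, good = sample(4:5, 1), intermediate = sample(2:3, 1),
           poor = sample(0:1, 1)), integer(1))
  pcr <- vapply(grades, function(g) {
    if (g == "good") return(1.0)
    max(1.0, stats::rlnorm(1, meanlog = log(spec$pcr_median[[g]]),
                           sdlog = spec$pcr_sdlog[[g]]))
  }, numeric(1))
  eps <- stats::rnorm(n, 0, spec$epsilon_sd)
  growth_ratio <- pmax(pcr * (1 + eps), 0.05)
  acr <- pmax(1.0, pcr * (1 + stats::rnorm(n, 0, spec$acr_noise_sd)))
  acr[grades == "good"] <- 1.0
  v_base <- vapply(grades, function(g)
    stats::rlnorm(1, meanlog = log(spec$baseline_median_ml[[g]]),
                  sdlog = spec$baseline_sdlog[[g]]), numeric(1))
  v_fu <- v_base * growth_ratio
  tmax_ratio <- growth_ratio * spec$tmax_bias *
    stats::rlnorm(n, meanlog = -spec$tmax_noise_sdlog^2 / 2,
                  sdlog = spec$tmax_noise_sdlog)
  data.frame(patient_id = sprintf("P%03d", seq_len(n)),
             grade = grades, score = score,
             v_baseline_ml = v_base, v_followup_ml = v_fu,
             lesion_growth_ratio = growth_ratio,
             growth = growth_ratio >= spec$growth_threshold,
             pcr = pcr, acr = acr,
             tmax6_volume_ml = tmax_ratio * v_base,
             tmax_dwi_ratio = tmax_ratio,
             row.names = NULL, stringsAsFactors = FALSE)
}
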