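#' Count delayed MCA regions per phase
#'
#' A region counts as delayed in a phase when at least
#' `region_fraction_threshold` of its voxels lie in that phase's
#' hypoperfusion mask (the boundary case is counted delayed).  Counts
#' are non-increasing from capillary to early venous to late venous
#' because the masks are nested.
#'
#' @param hypo a `hypoperfusion_set`.
#' @param atlas a `region_atlas`.
#' @param region_fraction_threshold fraction of a region's voxels that
#'   must be hypoperfused (default 0.5).
#' @return object of class `region_delay_profile`: list with `counts`
#'   (named vector over capillary/early_venous/late_venous) and
#'   `fractions` (phases x 8 matrix of delayed-voxel fractions).
#' @export
count_delayed_regions <- function(hypo, atlas,
                                  region_fraction_threshold = 0.5) {
  stopifnot(inherits(hypo, "hypoperfusion_set"),
            inherits(atlas, "region_atlas"))
  phases <- c("capillary", "early_venous", "late_venous")
  region_idx <- lapply(1:8, function(r) which(atlas$labels == r))
  sizes <- lengths(region_idx)
  if (any(sizes == 0)) stop("atlas has an empty MCA region")
  fractions <- t(vapply(phases, function(p)
    vapply(1:8, function(r) sum(hypo$masks[[p]][region_idx[[r]]]),
           numeric(1)) / sizes, numeric(8)))
  counts <- rowSums(fractions >= region_fraction_threshold)
  structure(list(counts = counts, fractions = fractions,
                 region_fraction_threshold = region_fraction_threshold),
            class = "region_delay_profile")
}

#' Collateral perfusion score (0--5) from a delayed-region profile
#'
#' Implements the six-level collateral perfusion grading over the 8
#' ASPECTS regions of the ischemic MCA territory.  "No or small" delay
#' means a delayed-region count of at most `small_max_regions` (default
#' 0: any delay smaller than one of the 8 regions); "more than half of
#' the territory" means more than 4 of the 8 regions; "half or less"
#' means at most 4.  Clauses are evaluated top-down from score 5 and the
#' first match wins:
#' \describe{
#'   \item{5}{no or small delay in the capillary phase (the arterial
#'     phase is disregarded);}
#'   \item{4}{capillary delay of half the territory or less and no or
#'     small delay in the early venous phase;}
#'   \item{3}{capillary and early venous delay each half or less; or
#'     capillary delay more than half with no or small early venous
#'     delay;}
#'   \item{2}{capillary delay more than half, early venous half or
#'     less;}
#'   \item{1}{early venous delay more than half, late venous half or
#'     less;}
#'   \item{0}{late venous delay more than half.}
#' }
#'
#' @param profile a `region_delay_profile`, or any list with a `counts`
#'   vector named capillary/early_venous/late_venous.
#' @param small_max_regions delayed-region count still regarded as
#'   "small" (default 0).
#' @return object of class `collateral_score_result`: `score` (0--5),
#'   `grade` (good/intermediate/poor), `rule_id`, and the counts used.
#' @export
collateral_score <- function(profile, small_max_regions = 0L) {
  counts <- profile$counts
  cc <- counts[["capillary"]]; ee <- counts[["early_venous"]]
  ll <- counts[["late_venous"]]
  if (any(c(cc, ee, ll) < 0) || any(c(cc, ee, ll) > 8))
    stop("delayed-region counts must be within 0..8")
  if (ee > cc || ll > ee)
    stop("delayed-region counts violate mask nesting")
  small <- function(k) k <= small_max_regions
  half_or_less <- function(k) k <= 4
  more_than_half <- function(k) k >= 5
  if (small(cc)) {
    score <- 5L; rule <- "5:no_or_small_capillary"
  } else if (half_or_less(cc) && small(ee)) {
    score <- 4L; rule <- "4:cap<=half,ev_small"
  } else if (half_or_less(cc) && half_or_less(ee)) {
    score <- 3L; rule <- "3a:cap<=half,ev<=half"
  } else if (more_than_half(cc) && small(ee)) {
    score <- 3L; rule <- "3b:cap>half,ev_small"
  } else if (more_than_half(cc) && half_or_less(ee)) {
    score <- 2L; rule <- "2:cap>half,ev<=half"
  } else if (more_than_half(ee) && half_or_less(ll)) {
    score <- 1L; rule <- "1:ev>half,lv<=half"
  } else {
    score <- 0L; rule <- "0:lv>half"
  }
  structure(list(score = score, grade = regroup(score), rule_id = rule,
                 counts = c(capillary = cc, early_venous = ee,
                            late_venous = ll)),
            class = "collateral_score_result")
}

#' Regroup a collateral perfusion score into a three-level grade
#'
#' Scores 5 and 4 are good, 3 and 2 intermediate, 1 and 0 poor.
#'
#' @param score integer 0--5.
#' @return `"good"`, `"intermediate"` or `"poor"`.
#' @export
regroup <- function(score) {
  if (length(score) != 1L || !score %in% 0:5)
    stop("score must be a single integer in 0..5")
  if (score >= 4) "good" else if (score >= 2) "intermediate" else "poor"
}

#' @export
print.collateral_score_result <- function(x, ...) {
  cat("<collateral_score> score", x$score, paste0("(", x$grade, ")"),
      "| counts", paste(x$counts, collapse = "/"), "| rule", x$rule_id,
      "\n")
  invisible(x)
}
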