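test_that("lesion growth ratio and flag follow the 1.2 boundary-inclusive rule", {
  ga <- growth_assessment(10, 10)
  expect_equal(ga$lesion_growth_ratio, 1.0)
  expect_false(ga$growth)
  ga2 <- growth_assessment(10, 12)
  expect_equal(ga2$lesion_growth_ratio, 1.2)
  expect_true(ga2$growth)
  expect_error(growth_assessment(0, 5), "positive")
})

test_that("Tmax thresholding is strict and volume-aware", {
  z <- array(0, dim = c(10, 10, 10))
  expect_equal(tmax_threshold(z, voxel_size_mm = c(1, 1, 1))$volume_ml, 0)
  z[1:5, 1, 1] <- 6.0   # exactly at threshold: excluded
  z[1:5, 2, 1] <- 6.01
  res <- tmax_threshold(z, 6, c(10, 10, 10))
  expect_equal(sum(res$mask), 5)
  expect_equal(res$volume_ml, 5)
  expect_error(tmax_threshold(z - 10), "negative")
})

test_that("phantom Tmax volume equals the delayed region volume", {
  cfg <- test_phantom_config(region_delay_s = c(8, 4, rep(0, 6)),
                             noise_sd = 0)
  ph <- generate_phantom(cfg)
  got <- tmax_threshold(ph$tmax, 6, cfg$voxel_size_mm)$volume_ml
  expect_equal(got, mask_volume(ph$atlas$labels == 1L,
                                cfg$voxel_size_mm))
})

test_that("DWI lesions are matched to the phase with maximal Dice", {
  delays <- delays_for_counts(c(capillary = 5, early_venous = 3,
                                late_venous = 0), test_phantom_config())
  ph <- generate_phantom(test_phantom_config(region_delay_s = delays,
                                             seed = 6))
  res <- analyze_patient(ph$series, ph$atlas, ph$dwi_baseline,
                         ph$dwi_followup)
  mb <- match_phase(res$hypo, res$hypo$masks$early_venous)
  expect_equal(mb$phase, "early_venous")
  expect_equal(mb$dice, 1.0)
  mf <- match_phase(res$hypo, res$hypo$masks$capillary)
  expect_equal(mf$phase, "capillary")
  expect_equal(mf$dice, 1.0)
  # empty hypoperfusion: undetermined
  ph0 <- generate_phantom(test_phantom_config(noise_sd = 0))
  res0 <- analyze_patient(ph0$series, ph0$atlas, ph0$dwi_baseline,
                          ph0$dwi_followup)
  expect_equal(match_phase(res0$hypo, ph0$dwi_baseline)$phase,
               "undetermined")
  expect_warning(
    out <- match_phase(res$hypo, array(FALSE, dim = test_grid)),
    "empty DWI")
  expect_equal(out$phase, "undetermined")
})

test_that("ties between equal masks break toward the later phase", {
  m <- array(FALSE, dim = c(6, 6, 6)); m[1:3, , ] <- TRUE
  hypo <- structure(list(masks = list(capillary = m, early_venous = m,
                                      late_venous = m,
                                      delay = array(FALSE, dim(m))),
                         volumes_ml = c(capillary = 1, early_venous = 1,
                                        late_venous = 1, delay = 0)),
                    class = "hypoperfusion_set")
  expect_equal(match_phase(hypo, m)$phase, "late_venous")
})

test_that("collateral ratios follow their definitions with a unit fallback", {
  hypo <- structure(list(masks = list(), volumes_ml = c(
    capillary = 50, early_venous = 20, late_venous = 5, delay = 0)),
    class = "hypoperfusion_set")
  cr <- collateral_ratios(hypo, "early_venous", "capillary")
  expect_equal(cr$acr, 2.5)
  expect_equal(cr$pcr, cr$acr)  # identical definition in this pairing
  expect_equal(collateral_ratios(hypo, "undetermined",
                                 "undetermined")$pcr, 1.0)
  hypo0 <- hypo; hypo0$volumes_ml[] <- 0
  cr0 <- collateral_ratios(hypo0, "early_venous", "capillary")
  expect_equal(cr0$pcr, 1.0)
  expect_equal(cr0$acr, 1.0)
})

test_that("pCR is at least 1 whenever both phases are determined", {
  set.seed(51)
  for (k in 1:4) {
    cc <- sample(2:8, 1); ee <- sample(1:cc, 1)
    delays <- delays_for_counts(c(capillary = cc, early_venous = ee,
                                  late_venous = 0),
                                test_phantom_config())
    ph <- generate_phantom(test_phantom_config(region_delay_s = delays,
                                               seed = 60 + k))
    res <- analyze_patient(ph$series, ph$atlas, ph$dwi_baseline,
                           ph$dwi_followup)
    expect_gte(res$row$pcr, 1)
    expect_gte(res$row$acr, 1)
  }
})

test_that("the follow-up phase immediately precedes the baseline phase", {
  phases <- c("capillary", "early_venous", "late_venous", "delay")
  # intermediate pattern: baseline in early venous, follow-up capillary
  delays <- delays_for_counts(c(capillary = 6, early_venous = 3,
                                late_venous = 0), test_phantom_config())
  ph <- generate_phantom(test_phantom_config(region_delay_s = delays,
                                             noise_sd = 0))
  res <- analyze_patient(ph$series, ph$atlas, ph$dwi_baseline,
                         ph$dwi_followup)
  expect_equal(res$row$phase_baseline, "early_venous")
  expect_equal(res$row$phase_fu, "capillary")
  # poor pattern: baseline in late venous, follow-up early venous
  delays2 <- delays_for_counts(c(capillary = 7, early_venous = 6,
                                 late_venous = 3), test_phantom_config())
  ph2 <- generate_phantom(test_phantom_config(
    region_delay_s = delays2, noise_sd = 0,
    lesion_spec = list(baseline = 1:3, followup = 1:6)))
  res2 <- analyze_patient(ph2$series, ph2$atlas, ph2$dwi_baseline,
                          ph2$dwi_followup)
  expect_equal(res2$row$phase_baseline, "late_venous")
  expect_equal(res2$row$phase_fu, "early_venous")
  expect_equal(match(res2$row$phase_fu, phases) + 1L,
               match(res2$row$phase_baseline, phases))
})

test_that("growth dichotomisation is boundary inclusive", {
  expect_false(predict_growth(1.0))
  expect_true(predict_growth(2.5))
  expect_true(predict_growth(1.2))
  expect_true(predict_growth(16.6))
  expect_error(predict_growth(-0.1), "nonnegative")
})
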