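test_that("constant series yields all-zero phase maps after subtraction", {
  s <- series4d(array(7, dim = c(8, 8, 4, 20)), 0:19, c(1, 1, 1))
  w <- phase_windows(c(5, 8, 11, 14, 17), 20)
  maps <- build_phase_maps(s, w)
  for (img in maps$images) expect_true(all(img == 0))
})

test_that("a frame exactly on a boundary joins the later window", {
  arr <- array(0, dim = c(4, 4, 2, 10))
  arr[, , , 6] <- 50  # frame time 5 sits exactly on the boundary
  s <- series4d(arr, 0:9, c(1, 1, 1))
  w <- phase_windows(c(1, 2, 5, 7, 8), 10)
  maps <- build_phase_maps(s, w)
  expect_true(all(maps$images$capillary == 0))     # [2, 5)
  expect_true(all(maps$images$early_venous == 50)) # [5, 7)
})

test_that("symmetric noiseless phantom produces empty hypoperfusion masks", {
  ph <- generate_phantom(test_phantom_config(noise_sd = 0))
  res <- analyze_patient(ph$series, ph$atlas, ph$dwi_baseline,
                         ph$dwi_followup)
  expect_equal(unname(res$hypo$volumes_ml), rep(0, 4))
  expect_equal(res$score$score, 5L)
})

test_that("a region delayed through early venous only is recovered with high Dice", {
  delays <- delays_for_counts(c(capillary = 1, early_venous = 1,
                                late_venous = 0), test_phantom_config())
  ph <- generate_phantom(test_phantom_config(region_delay_s = delays,
                                             seed = 8))
  res <- analyze_patient(ph$series, ph$atlas, ph$dwi_baseline,
                         ph$dwi_followup)
  truth <- ph$truth$hypo_masks
  expect_gte(dice(res$hypo$masks$capillary, truth$capillary), 0.9)
  expect_gte(dice(res$hypo$masks$early_venous, truth$early_venous), 0.9)
  expect_equal(res$hypo$volumes_ml[["late_venous"]], 0)
})

test_that("mask volumes convert voxel counts to millilitres", {
  m <- array(FALSE, dim = c(20, 10, 10))
  expect_equal(mask_volume(m, c(1, 1, 1)), 0)
  m[seq_len(1000)] <- TRUE
  expect_equal(mask_volume(m, c(1, 1, 1)), 1.0)
  m2 <- array(FALSE, dim = c(20, 10, 10)); m2[seq_len(2000)] <- TRUE
  expect_equal(mask_volume(m2, c(1, 1, 0.5)), 1.0)
  expect_error(mask_volume(array(0.5, dim = c(2, 2, 2)), c(1, 1, 1)),
               "binary")
  # phantom lesion of whole regions matches ground truth exactly
  ph <- generate_phantom(test_phantom_config(
    noise_sd = 0, lesion_spec = list(baseline = c(1L, 2L),
                                     followup = c(1L, 2L, 3L))))
  expect_equal(mask_volume(ph$dwi_baseline, ph$config$voxel_size_mm),
               ph$truth$lesion_volume_baseline_ml)
})

test_that("lowering the threshold fraction never enlarges any mask", {
  delays <- delays_for_counts(c(capillary = 4, early_venous = 2,
                                late_venous = 0), test_phantom_config())
  ph <- generate_phantom(test_phantom_config(region_delay_s = delays,
                                             seed = 13))
  res <- analyze_patient(ph$series, ph$atlas, ph$dwi_baseline,
                         ph$dwi_followup)
  for (thr in c(0.4, 0.3, 0.2)) {
    lo <- detect_hypoperfusion(res$maps, ph$atlas,
                               threshold_fraction = thr)
    hi <- detect_hypoperfusion(res$maps, ph$atlas,
                               threshold_fraction = thr + 0.1)
    for (p in names(lo$masks))
      expect_true(all(lo$masks[[p]] <= hi$masks[[p]]))
  }
})

test_that("hypoperfusion masks nest and volumes decrease across phases", {
  set.seed(31)
  for (k in 1:5) {
    cc <- sample(1:8, 1); ee <- sample(0:cc, 1); ll <- sample(0:ee, 1)
    delays <- delays_for_counts(c(capillary = cc, early_venous = ee,
                                  late_venous = ll),
                                test_phantom_config())
    ph <- generate_phantom(test_phantom_config(region_delay_s = delays,
                                               seed = 40 + k))
    res <- analyze_patient(ph$series, ph$atlas, ph$dwi_baseline,
                           ph$dwi_followup)
    m <- res$hypo$masks
    expect_true(all(m$early_venous <= m$capillary))
    expect_true(all(m$late_venous <= m$early_venous))
    expect_true(all(m$delay <= m$late_venous))
    expect_true(all(diff(unname(res$hypo$volumes_ml)) <= 1e-12))
  }
})

test_that("early-phase volumes ignore changes to frames in later windows", {
  delays <- delays_for_counts(c(capillary = 3, early_venous = 1,
                                late_venous = 0), test_phantom_config())
  ph <- generate_phantom(test_phantom_config(region_delay_s = delays,
                                             seed = 17))
  res <- analyze_patient(ph$series, ph$atlas, ph$dwi_baseline,
                         ph$dwi_followup)
  s2 <- ph$series
  dl <- res$windows$windows$delay
  late_frames <- which(s2$times >= dl["start"])
  s2$data[, , , late_frames] <- 0
  maps2 <- build_phase_maps(s2, res$windows)
  hypo2 <- detect_hypoperfusion(maps2, ph$atlas)
  for (p in c("capillary", "early_venous", "late_venous"))
    expect_equal(hypo2$volumes_ml[[p]], res$hypo$volumes_ml[[p]])
})

test_that("small connected components are removed from the capillary mask", {
  ph <- generate_phantom(test_phantom_config(noise_sd = 0))
  res <- analyze_patient(ph$series, ph$atlas, ph$dwi_baseline,
                         ph$dwi_followup)
  img <- res$maps$images$capillary
  # carve a tiny artificial cold spot (8 voxels < 27) into the territory
  idx <- which(atlas_mask(ph$atlas, 1L), arr.ind = TRUE)[1:8, ]
  img[idx] <- 0
  maps2 <- res$maps; maps2$images$capillary <- img
  hypo2 <- detect_hypoperfusion(maps2, ph$atlas, min_cluster_voxels = 27L)
  expect_equal(sum(hypo2$masks$capillary), 0)
  hypo3 <- detect_hypoperfusion(maps2, ph$atlas, min_cluster_voxels = 1L)
  expect_equal(sum(hypo3$masks$capillary), 8)
})
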