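small_cfg <- function(...) {
  cohort_config(n_patients = 2, n_cycles = 2, grid_shape = c(40, 40, 40),
                ...)
}

test_that("cohort_config enforces eligibility and positivity invariants", {
  expect_error(cohort_config(lesion_diameter_range = c(20, 40)), "30 mm")
  expect_error(cohort_config(background_counts = 0), "positive")
  expect_error(cohort_config(lesions_per_lobe_range = c(0, 2)), "\\[1, 3\\]")
  expect_error(cohort_config(grid_shape = c(8, 8, 8)), ">= 16")
  expect_error(cohort_config(n_patients = 0), "at least 1")
  expect_warning(cohort_config(n_patients = 1), "paired analyses")
  # a 4 m lesion cannot fit the liver
  expect_error(cohort_config(lesion_diameter_range = c(30, 4000)), "fit")
})

test_that("phantoms satisfy the anatomical invariants", {
  cfg <- small_cfg(seed = 1)
  ph <- build_phantom(cfg, patient_seed = 5, ia_lobe = "left")
  # 1-3 lesions per lobe, all diameters >= 30 mm
  counts <- table(ph$lesions$lobe)
  expect_true(all(counts >= 1 & counts <= 3))
  expect_true(all(ph$lesions$diameter >= 30))
  liver_keys <- paste(ph$liver_mask$indices[, 1], ph$liver_mask$indices[, 2],
                      ph$liver_mask$indices[, 3])
  for (j in seq_along(ph$lesion_vois)) {
    les <- ph$lesion_vois[[j]]
    keys <- paste(les$indices[, 1], les$indices[, 2], les$indices[, 3])
    # lesion voxels lie entirely within the liver
    expect_true(all(keys %in% liver_keys))
    # and entirely within their lobe
    lab <- ph$lobe_labels$values[cbind(les$indices[, 1], les$indices[, 2],
                                       les$indices[, 3])]
    expect_true(all(lab == (if (ph$lesions$lobe[j] == "left") 1L else 2L)))
  }
  # normal VOI: >= 15 mL, control lobe, disjoint from every lesion
  expect_gte(voi_volume_ml(ph$normal_voi), 15)
  nk <- paste(ph$normal_voi$indices[, 1], ph$normal_voi$indices[, 2],
              ph$normal_voi$indices[, 3])
  for (les in ph$lesion_vois) {
    keys <- paste(les$indices[, 1], les$indices[, 2], les$indices[, 3])
    expect_length(intersect(nk, keys), 0)
  }
  nl <- ph$lobe_labels$values[cbind(ph$normal_voi$indices[, 1],
                                    ph$normal_voi$indices[, 2],
                                    ph$normal_voi$indices[, 3])]
  expect_true(all(nl == 2L))  # control lobe is right when ia is left
})

test_that("noise-free voxel values equal the configured expectations", {
  cfg <- small_cfg(noise = FALSE, tn_true_log_mean = log(10),
                   tn_true_log_sd = 0, tn_cycle_log_sd = 0,
                   enhancement_log_mean = 0, enhancement_log_sd = 0,
                   lesions_per_lobe_range = c(1, 1), seed = 2)
  ph <- build_phantom(cfg, patient_seed = 8, ia_lobe = "left")
  bg <- cfg$background_counts
  for (les in ph$lesion_vois) {
    vals <- ph$baseline_volume$values[cbind(les$indices[, 1], les$indices[, 2],
                                            les$indices[, 3])]
    expect_equal(vals, rep(10 * bg, length(vals)))
  }
  # liver background voxels are exactly bg
  nv <- ph$baseline_volume$values[cbind(ph$normal_voi$indices[, 1],
                                        ph$normal_voi$indices[, 2],
                                        ph$normal_voi$indices[, 3])]
  expect_equal(nv, rep(bg, length(nv)))
})

test_that("a 30 mm lesion VOI volume is within one voxel shell of the sphere", {
  cfg <- small_cfg(noise = FALSE, lesion_diameter_range = c(30, 30),
                   lesions_per_lobe_range = c(1, 1), seed = 4)
  ph <- build_phantom(cfg, patient_seed = 3)
  analytic_ml <- 4 / 3 * pi * 15^3 / 1000  # 14.14 mL
  # one voxel shell of a 15 mm sphere at 4 mm spacing: area * spacing
  shell_ml <- 4 * pi * 15^2 * 4 / 1000
  for (les in ph$lesion_vois) {
    expect_lt(abs(voi_volume_ml(les) - analytic_ml), shell_ml)
  }
})

test_that("Poisson noise conserves the expectation within Monte-Carlo error", {
  cfg <- small_cfg(noise = TRUE, tn_true_log_mean = log(10),
                   tn_true_log_sd = 0, tn_cycle_log_sd = 0,
                   enhancement_log_mean = 0, enhancement_log_sd = 0,
                   lesions_per_lobe_range = c(1, 1),
                   lesion_diameter_range = c(40, 40), seed = 6)
  ph <- build_phantom(cfg, patient_seed = 11)
  les <- ph$lesion_vois[[1]]
  vals <- ph$baseline_volume$values[cbind(les$indices[, 1], les$indices[, 2],
                                          les$indices[, 3])]
  lambda <- 10 * cfg$background_counts
  se <- sqrt(lambda / length(vals))
  expect_lt(abs(mean(vals) - lambda), 3 * se)
})

test_that("phantom construction is deterministic in (config, seed)", {
  cfg <- small_cfg(seed = 10)
  a <- build_phantom(cfg, patient_seed = 77)
  b <- build_phantom(cfg, patient_seed = 77)
  expect_equal(a$lesions, b$lesions)
  expect_equal(a$baseline_volume$values, b$baseline_volume$values)
  expect_equal(a$true_enhancement, b$true_enhancement)
})

test_that("impossible lesion placement raises a placement error", {
  cfg <- small_cfg(lesion_diameter_range = c(95, 100), seed = 1)
  expect_error(build_phantom(cfg, patient_seed = 1, max_attempts = 5),
               "attempts|too large")
})

test_that("misaligned cycle grids carry the true transform and stay quantifiable", {
  cfg <- small_cfg(noise = FALSE, misalignment_max_translation = 4,
                   misalignment_max_rotation_deg = 3,
                   enhancement_log_mean = log(1.4), enhancement_log_sd = 0,
                   seed = 12)
  ph <- build_phantom(cfg, patient_seed = 13)
  tf <- ph$baseline_to_cycle_transforms[[1]]
  expect_gt(max(abs(tf$translation)), 0)
  tn <- quantify_phantom(ph)
  m <- tn[tn$basis == "mean" & tn$cycle == 1, ]
  # VOI transfer through the true transform recovers rho up to edge voxels
  expect_equal(m$tn_ia / m$tn_control, 1.4, tolerance = 0.05)
})

test_that("follow-up diameters follow the response profile", {
  cfg <- small_cfg(seed = 20)
  ph <- build_phantom(cfg, patient_seed = 30)
  # degenerate profile: no change at all -> stable disease everywhere
  flat <- tibble::tibble(type = "sd", prob = 1, change_3mo = 0,
                         change_6mo = 0, sd = 0)
  cfg_flat <- small_cfg(response_profile = flat, seed = 20)
  d <- withr::with_seed(1, simulate_followup(ph, cfg_flat))
  expect_equal(d$diameter_3mo, d$diameter_baseline)
  resp <- assess_response(d)
  expect_true(all(resp$category == "SD"))
  # point mass at -35% -> partial response everywhere
  pr <- tibble::tibble(type = "pr", prob = 1, change_3mo = -0.35,
                       change_6mo = -0.35, sd = 0)
  cfg_pr <- small_cfg(response_profile = pr, seed = 20)
  d2 <- withr::with_seed(1, simulate_followup(ph, cfg_pr))
  expect_true(all(assess_response(d2)$category == "PR"))
  expect_error(simulate_followup(ph, small_cfg(response_profile = dplyr::mutate(
    flat, prob = 0.5), seed = 20)), "sum to 1")
})

test_that("default response profile reproduces the expected cohort mix", {
  # the classifier applied to many profile draws recovers the mixture the
  # profile was tuned to: ~25% PR at 3 months; ~35% PR, ~4% PD at 6 months
  cfg <- small_cfg(seed = 40)
  ph <- build_phantom(cfg, patient_seed = 50)
  draws <- withr::with_seed(99, purrr::map_dfr(1:300, function(i) {
    simulate_followup(ph, cfg)
  }))
  draws$patient_id <- rep(seq_len(nrow(draws) / 2), each = 2) # one id per draw
  resp <- assess_response(draws)
  r3 <- resp[resp$timepoint == "3mo", ]
  r6 <- resp[resp$timepoint == "6mo", ]
  expect_equal(mean(r3$category == "PR"), 0.25, tolerance = 0.30)
  expect_equal(mean(r6$category == "PR"), 0.35, tolerance = 0.25)
  expect_equal(mean(r6$category == "PD"), 0.04, tolerance = 0.75)
})

test_that("lab simulation is table-driven and respects the normal ranges", {
  cfg <- small_cfg(lab_abnormal_prob = 0, lab_emergent_prob = 0,
                   lab_drift_sd = 0, seed = 60)
  ph <- build_phantom(cfg, patient_seed = 70)
  labs <- withr::with_seed(5, simulate_labs(ph, cfg))
  rules <- default_grading_rules()
  expect_setequal(unique(labs$analyte), rules$analyte)
  # all values inside normal ranges -> zero treatment-emergent toxicity
  ev <- attribute_toxicity(labs, rules)
  expect_equal(sum(ev$treatment_emergent), 0)
})

test_that("the tabular cohort layer has the configured moments", {
  tn <- simulate_tn_cohort(n_patients = 4000, n_cycles = 1, seed = 123)
  lr <- log(tn$tn_ia) - log(tn$tn_control)
  expect_equal(mean(lr), log(1.17), tolerance = 0.05)
  expect_equal(sd(lr), 0.39, tolerance = 0.05)
  expect_equal(mean(log(tn$tn_control)), log(16.2),
               tolerance = 3 * sqrt(0.9^2 + 0.35^2) / sqrt(4000) / log(16.2) + 0.02)
  # dropout bookkeeping: 2 patients stop after cycle 1, one after cycle 2
  td <- simulate_tn_cohort(n_patients = 27, n_cycles = 4, dropout = TRUE,
                           seed = 5)
  completed <- table(table(td$patient_id))
  expect_equal(unname(completed[c("1", "2", "4")]), c(2, 1, 24),
               ignore_attr = TRUE)
})

test_that("generate_cohort writes a reproducible on-disk dataset", {
  cfg <- cohort_config(n_patients = 2, n_cycles = 1, grid_shape = c(32, 32, 32),
                       seed = 9)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  out1 <- generate_cohort(cfg, d1)
  out2 <- generate_cohort(cfg, d2)
  for (f in c("randomization.csv", "lesions.csv", "diameters.csv", "labs.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # volumes and label maps round trip through NIfTI
  vol <- read_volume(file.path(d1, "P01", "baseline.nii.gz"), "baseline")
  expect_true(all(vol$values >= 0))
  labs <- read_volume(file.path(d1, "P01", "voi_labels.nii.gz"), "baseline")
  expect_gte(length(unique(as.vector(labs$values))), 3)
  expect_true(file.exists(file.path(d1, "config.json")))
})

test_that("a single-patient dataset generates but paired analysis refuses", {
  cfg <- suppressWarnings(
    cohort_config(n_patients = 1, n_cycles = 1, grid_shape = c(32, 32, 32),
                  seed = 3))
  d <- withr::local_tempdir()
  out <- generate_cohort(cfg, d)
  expect_equal(nrow(out$randomization), 1)
  ph <- build_phantom(cfg, patient_seed = 2)
  tn <- quantify_phantom(ph)
  expect_error(paired_t_test(tn), "at least 2")
})
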