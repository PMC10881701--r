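test_that("RECIST thresholds classify exactly at their boundaries", {
  # -30% from baseline is PR, just above it is SD
  expect_equal(recist_classify(100, 70, 100), "PR")
  expect_equal(recist_classify(100, 70.1, 100), "SD")
  # +20% from nadir AND +5 mm absolute is PD
  expect_equal(recist_classify(100, 61, 50), "PD")   # +22%, +11 mm
  expect_equal(recist_classify(100, 60, 50), "PD")   # exactly +20%, +10 mm
  expect_equal(recist_classify(70, 59.9, 50), "SD")  # +19.8% from nadir: no PD
  # the 5 mm absolute clause blocks PD for small sums
  expect_equal(recist_classify(30, 24, 20), "SD")    # +20% but only +4 mm
  expect_equal(recist_classify(30, 25, 20), "PD")    # +25% and exactly +5 mm
  # disappearance is CR; PD takes precedence over PR
  expect_equal(recist_classify(100, 0, 100), "CR")
  expect_equal(recist_classify(100, 66, 50), "PD")   # -34% from baseline but +32% from nadir
  expect_error(recist_classify(100, -1, 100), "non-negative")
  expect_error(recist_classify(100, 80, 110), "nadir")
})

test_that("RECIST is scale-invariant apart from the 5 mm clause", {
  withr::local_seed(16)
  for (i in 1:50) {
    b <- runif(1, 60, 200)
    cur <- b * runif(1, 0.4, 1.6)
    nad <- min(b, cur * runif(1, 0.7, 1))
    k <- runif(1, 2, 5)
    c1 <- recist_classify(b, cur, nad)
    c2 <- recist_classify(k * b, k * cur, k * nad)
    if (cur - nad >= 5) {
      # past the absolute clause every criterion is relative: scale-invariant
      expect_identical(c2, c1)
    } else if (c1 != c2) {
      # upscaling can only flip a classification by unlocking the 5 mm clause
      expect_true(c2 == "PD" && c1 %in% c("SD", "PR"))
    } else {
      expect_identical(c2, c1)
    }
  }
})

test_that("per-lobe assessment derives sums, nadir and categories", {
  d <- tibble::tibble(
    patient_id = "P01", lobe = rep(c("left", "right"), each = 2),
    lesion_id = c("l1", "l2", "r1", "r2"),
    diameter_baseline = c(40, 60, 50, 50),
    diameter_3mo = c(30, 30, 48, 50),
    diameter_6mo = c(28, 28, 70, 65)
  )
  res <- assess_response(d)
  left3 <- res[res$lobe == "left" & res$timepoint == "3mo", ]
  expect_equal(left3$sum_current, 60)
  expect_equal(left3$category, "PR")     # 60/100 = -40%
  right6 <- res[res$lobe == "right" & res$timepoint == "6mo", ]
  expect_equal(right6$sum_nadir, 98)     # 3-month sum was the nadir
  expect_equal(right6$category, "PD")    # 135/98 = +38%, +37 mm
})

test_that("cohort response tables are per-arm with correct column sums", {
  withr::local_seed(17)
  n <- 10
  rand <- tibble::tibble(patient_id = sprintf("P%02d", 1:n),
                         ia_lobe = rep(c("left", "right"), 5))
  d <- purrr::map_dfr(1:n, function(i) {
    tibble::tibble(
      patient_id = sprintf("P%02d", i), lobe = c("left", "right"),
      lesion_id = c("l1", "r1"), diameter_baseline = c(50, 50),
      diameter_3mo = 50 * (1 + runif(2, -0.4, 0.3)),
      diameter_6mo = 50 * (1 + runif(2, -0.5, 0.4)))
  })
  tab <- classify_cohort_response(assess_response(d), rand)
  sums <- tab |> dplyr::group_by(timepoint) |>
    dplyr::summarise(control = sum(control), ia = sum(ia))
  expect_true(all(sums$control == n))
  expect_true(all(sums$ia == n))
  # identical response in both lobes -> identical columns -> Fisher p = 1
  d_same <- d
  d_same$diameter_3mo <- rep(d$diameter_3mo[seq(1, 2 * n, 2)], each = 2)
  d_same$diameter_6mo <- rep(d$diameter_6mo[seq(1, 2 * n, 2)], each = 2)
  tab_same <- classify_cohort_response(assess_response(d_same), rand)
  expect_equal(tab_same$control, tab_same$ia)
  p <- response_table_pvalues(tab_same)
  expect_equal(p$p_value, c(1, 1))
})

test_that("a degenerate all-SD table yields p = 1 and missing lobes are excluded", {
  d <- tibble::tibble(
    patient_id = rep(c("P01", "P02"), each = 2),
    lobe = rep(c("left", "right"), 2), lesion_id = "x",
    diameter_baseline = 50, diameter_3mo = 50, diameter_6mo = 50)
  rand <- tibble::tibble(patient_id = c("P01", "P02"),
                         ia_lobe = c("left", "right"))
  tab <- classify_cohort_response(assess_response(d), rand)
  expect_equal(response_table_pvalues(tab)$p_value, c(1, 1))
  # drop one lobe of P02 entirely
  d_miss <- d[-4, ]
  expect_message(
    tab2 <- classify_cohort_response(assess_response(d_miss), rand),
    "missing one lobe")
  expect_true(all(tab2$control + tab2$ia == 2))
})

test_that("grading is a table-driven threshold scan with closed bounds", {
  rules <- default_grading_rules()
  ggt_uln <- rules$uln[rules$analyte == "ggt"]
  expect_equal(grade_value(ggt_uln, "ggt", rules), 0)
  g3 <- rules$g3[rules$analyte == "ggt"]
  expect_equal(grade_value(g3, "ggt", rules), 3)        # exactly at threshold
  expect_equal(grade_value(g3 - 0.001, "ggt", rules), 2)
  # low-direction analyte: <= comparisons
  g2_hb <- rules$g2[rules$analyte == "haemoglobin"]
  expect_equal(grade_value(g2_hb, "haemoglobin", rules), 2)
  expect_equal(grade_value(g2_hb + 0.001, "haemoglobin", rules), 1)
  expect_error(grade_value(1, "unobtainium", rules), "No grading rule")
  # random values agree with a brute-force scan over the thresholds
  withr::local_seed(18)
  for (i in 1:100) {
    a <- sample(rules$analyte, 1)
    r <- rules[rules$analyte == a, ]
    v <- runif(1, 0, 2 * max(r$g4, r$uln))
    th <- c(r$g1, r$g2, r$g3, r$g4)
    brute <- if (r$direction == "high") sum(v >= th) else sum(v <= th)
    expect_equal(grade_value(v, a, rules), brute)
  }
})

test_that("monotonicity of grading rules is enforced", {
  bad <- default_grading_rules()
  bad$g2[1] <- bad$g4[1] + 1
  expect_error(validate_rules <- write_grading_rules(bad, tempfile()),
               "monotone")
})

test_that("grading rules round trip through JSON", {
  rules <- default_grading_rules()
  f <- withr::local_tempfile(fileext = ".json")
  write_grading_rules(rules, f)
  back <- read_grading_rules(f)
  expect_equal(as.data.frame(back), as.data.frame(rules))
  shipped <- system.file("extdata", "grading_rules_synthetic.json",
                         package = "lobetrial")
  expect_equal(as.data.frame(read_grading_rules(shipped)),
               as.data.frame(rules))
})

test_that("toxicity attribution applies the baseline-delta rule", {
  rules <- default_grading_rules()
  r <- rules[rules$analyte == "ggt", ]
  mk <- function(baseline, followup) {
    tibble::tibble(patient_id = "P01",
                   visit = c("baseline", "cycle_1"),
                   analyte = "ggt", value = c(baseline, followup))
  }
  # baseline grade 3, follow-up grade 4: one treatment-emergent grade-4 event
  ev <- attribute_toxicity(mk(r$g3, r$g4), rules)
  expect_equal(ev$baseline_grade, 3L)
  expect_equal(ev$worst_followup_grade, 4L)
  expect_true(ev$treatment_emergent)
  # same grade at baseline and follow-up: not treatment-emergent
  ev2 <- attribute_toxicity(mk(r$g2, r$g2 * 1.01), rules)
  expect_false(ev2$treatment_emergent)
  # the invariant: emergent iff worst > baseline
  withr::local_seed(19)
  labs <- tidyr::expand_grid(patient_id = sprintf("P%02d", 1:5),
                             visit = c("baseline", "cycle_1", "cycle_2"),
                             analyte = c("ggt", "alat", "haemoglobin"))
  labs$value <- purrr::map_dbl(labs$analyte, function(a) {
    r <- rules[rules$analyte == a, ]
    runif(1, 0, 2 * max(r$g4, r$uln))
  })
  ev3 <- attribute_toxicity(labs, rules)
  expect_equal(ev3$treatment_emergent,
               ev3$worst_followup_grade > ev3$baseline_grade)
  # a missing baseline is an error
  expect_error(attribute_toxicity(mk(r$g3, r$g4)[-1, ], rules), "baseline")
})

test_that("the toxicity table counts patients at their worst emergent grade", {
  rules <- default_grading_rules()
  r <- rules[rules$analyte == "alat", ]
  labs <- tibble::tibble(
    patient_id = rep(c("P01", "P02"), each = 3),
    visit = rep(c("baseline", "cycle_1", "cycle_2"), 2),
    analyte = "alat",
    value = c(10, r$g1, r$g2,    # P01: emerges at grade 2
              10, 12, 11))      # P02: never abnormal
  tab <- toxicity_table(attribute_toxicity(labs, rules))
  expect_equal(tab$grade_2[tab$analyte == "alat"], 1L)
  expect_equal(tab$grade_1[tab$analyte == "alat"], 0L)
})
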