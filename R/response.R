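#' RECIST 1.1 classification of a target-lesion diameter sum
#'
#' Classifies one timepoint from the sum of target-lesion diameters:
#' * CR — the sum is 0 (all target lesions disappeared);
#' * PD — the sum increased by at least 20% from the nadir AND by at least
#'   5 mm in absolute terms (PD takes precedence over PR);
#' * PR — the sum decreased by at least 30% from baseline (and not PD);
#' * SD — otherwise.
#' The nadir is the minimum of all prior sums including baseline.
#'
#' @param sum_baseline,sum_current,sum_nadir Diameter sums in mm.
#' @return One of `"CR"`, `"PR"`, `"SD"`, `"PD"`.
#' @export
recist_classify <- function(sum_baseline, sum_current, sum_nadir) {
  if (any(c(sum_baseline, sum_current, sum_nadir) < 0) ||
        anyNA(c(sum_baseline, sum_current, sum_nadir))) {
    abort("Diameter sums must be non-negative.")
  }
  if (sum_nadir > sum_baseline + 1e-9) {
    abort("The nadir cannot exceed the baseline sum (it includes baseline).")
  }
  if (sum_current == 0) return("CR")
  pd <- sum_current >= 1.2 * sum_nadir && (sum_current - sum_nadir) >= 5
  if (pd) return("PD")
  if (sum_current <= 0.7 * sum_baseline) return("PR")
  "SD"
}

#' Per-lobe RECIST assessment of a follow-up diameter table
#'
#' Sums target-lesion diameters per patient-lobe, derives the nadir sequence
#' (baseline, then 3 months for the 6-month call) and classifies each
#' timepoint with [recist_classify()].
#'
#' @param diameters Tibble as produced by [simulate_followup()]:
#'   `patient_id`, `lobe`, `lesion_id`, `diameter_baseline`, `diameter_3mo`,
#'   `diameter_6mo`.
#' @return Tibble: `patient_id`, `lobe`, `timepoint` (`"3mo"`, `"6mo"`),
#'   `sum_baseline`, `sum_current`, `sum_nadir`, `percent_change_baseline`,
#'   `percent_change_nadir`, `category`.
#' @export
assess_response <- function(diameters) {
  sums <- diameters |>
    dplyr::group_by(.data$patient_id, .data$lobe) |>
    dplyr::summarise(
      s0 = sum(.data$diameter_baseline),
      s3 = sum(.data$diameter_3mo),
      s6 = sum(.data$diameter_6mo), .groups = "drop")
  purrr::map_dfr(seq_len(nrow(sums)), function(i) {
    r <- sums[i, ]
    tibble(
      patient_id = r$patient_id, lobe = r$lobe,
      timepoint = c("3mo", "6mo"),
      sum_baseline = r$s0,
      sum_current = c(r$s3, r$s6),
      sum_nadir = c(r$s0, min(r$s0, r$s3))
    )
  }) |>
    dplyr::mutate(
      percent_change_baseline =
        100 * (.data$sum_current - .data$sum_baseline) / .data$sum_baseline,
      percent_change_nadir =
        100 * (.data$sum_current - .data$sum_nadir) / .data$sum_nadir,
      category = purrr::pmap_chr(
        list(.data$sum_baseline, .data$sum_current, .data$sum_nadir),
        recist_classify)
    )
}

#' Cohort response contingency tables by timepoint
#'
#' Cross-tabulates RECIST categories against the arm (intra-arterially treated
#' vs control lobe) per timepoint, in the shape that feeds
#' [fisher_exact_rxc()]. Patients missing one lobe's assessment at a timepoint
#' are excluded from that timepoint (with a message).
#'
#' @param assessments Output of [assess_response()].
#' @param randomization Tibble with `patient_id` and `ia_lobe`.
#' @return A tibble with one row per timepoint-category and columns
#'   `control`, `ia`, plus the Fisher p-value per timepoint attached by
#'   [response_table_pvalues()].
#' @export
classify_cohort_response <- function(assessments, randomization) {
  x <- dplyr::inner_join(assessments,
                         randomization[, c("patient_id", "ia_lobe")],
                         by = "patient_id")
  x$arm <- ifelse(x$lobe == x$ia_lobe, "ia", "control")
  complete <- x |>
    dplyr::count(.data$patient_id, .data$timepoint) |>
    dplyr::filter(.data$n == 2)
  dropped <- dplyr::anti_join(
    dplyr::distinct(x, .data$patient_id, .data$timepoint), complete,
    by = c("patient_id", "timepoint"))
  if (nrow(dropped) > 0) {
    inform(sprintf("Excluding %d patient-timepoint(s) missing one lobe.",
                   nrow(dropped)))
  }
  x <- dplyr::semi_join(x, complete, by = c("patient_id", "timepoint"))
  x$category <- factor(x$category, levels = c("CR", "PR", "SD", "PD"))
  x |>
    dplyr::count(.data$timepoint, .data$category, .data$arm,
                 .drop = TRUE) |>
    tidyr::pivot_wider(names_from = "arm", values_from = "n",
                       values_fill = 0L) |>
    dplyr::arrange(.data$timepoint, .data$category)
}

#' Fisher p-values of per-timepoint response tables
#'
#' @param response_table Output of [classify_cohort_response()].
#' @return Tibble: `timepoint`, `p_value`. Degenerate single-category tables
#'   return 1.
#' @export
response_table_pvalues <- function(response_table) {
  response_table |>
    dplyr::group_by(.data$timepoint) |>
    dplyr::summarise(p_value = {
      m <- cbind(control = .data$control, ia = .data$ia)
      m <- m[rowSums(m) > 0, , drop = FALSE]
      if (nrow(m) < 2) 1 else fisher_exact_rxc(m)
    }, .groups = "drop")
}

#' Default laboratory grading rules (approximate, synthetic)
#'
#' A table-driven grading rule set covering the hepatic, haematological and
#' renal analytes tracked during follow-up. Thresholds follow the usual
#' multiples-of-limit pattern of adverse-event grading scales but are
#' approximate and synthetic: they ship so the grading engine is runnable out
#' of the box, and real analyses should load a site-validated table via
#' [read_grading_rules()].
#'
#' Columns: `analyte`, `direction` (`"high"` = toxicity is an elevation,
#' graded against the upper limit of normal `uln`; `"low"` = a depression,
#' graded against the lower limit `lln`), `lln`, `uln`, `g1`-`g4` (grade
#' thresholds in analyte units, monotone in grade; comparisons are `>=` for
#' high and `<=` for low).
#'
#' @return A tibble of grading rules.
#' @export
default_grading_rules <- function() {
  # explicit rows: clearer than a formula for a table meant to be edited
  tibble(
    analyte = c("alat", "asat", "ggt", "alp", "bilirubin", "creatinine",
                "urea", "mcv",
                "albumin", "haemoglobin", "thrombocytes", "leukocytes",
                "neutrophils", "lymphocytes", "egfr"),
    direction = c(rep("high", 8), rep("low", 7)),
    lln = c(0, 0, 0, 30, 0, 45, 2.5, 80,
            35, 120, 150, 4.0, 1.8, 1.0, 60),
    uln = c(45, 40, 55, 120, 21, 90, 7.5, 100,
            50, 160, 400, 10, 7.5, 4.0, 120),
    g1 = c(45 * 3, 40 * 3, 55 * 2.5, 120 * 2.5, 21 * 1.5, 90 * 1.5, 7.5 * 1.5,
           105,
           34, 100, 75, 3.0, 1.5, 0.8, 59),
    g2 = c(45 * 5, 40 * 5, 55 * 5, 120 * 5, 21 * 3, 90 * 3, 7.5 * 3,
           115,
           30, 80, 50, 2.0, 1.0, 0.5, 45),
    g3 = c(45 * 20, 40 * 20, 55 * 20, 120 * 20, 21 * 10, 90 * 6, 7.5 * 6,
           130,
           20, 65, 25, 1.0, 0.5, 0.25, 30),
    g4 = c(45 * 40, 40 * 40, 55 * 40, 120 * 40, 21 * 20, 90 * 12, 7.5 * 12,
           150,
           15, 50, 10, 0.5, 0.2, 0.1, 15)
  )
}

#' Read and write grading rule tables as JSON
#'
#' @param path JSON file path.
#' @param rules A grading rule tibble (see [default_grading_rules()]).
#' @return `read_grading_rules()` returns the tibble; `write_grading_rules()`
#'   returns `path` invisibly.
#' @export
read_grading_rules <- function(path) {
  rules <- as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  validate_rules(rules)
  rules
}

#' @rdname read_grading_rules
#' @export
write_grading_rules <- function(rules, path) {
  validate_rules(rules)
  jsonlite::write_json(rules, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

validate_rules <- function(rules) {
  need <- c("analyte", "direction", "lln", "uln", "g1", "g2", "g3", "g4")
  if (!all(need %in% names(rules))) {
    abort(sprintf("Grading rules need columns: %s.", paste(need, collapse = ", ")))
  }
  g <- as.matrix(rules[, c("g1", "g2", "g3", "g4")])
  mono <- ifelse(rules$direction == "high",
                 g[, 1] <= g[, 2] & g[, 2] <= g[, 3] & g[, 3] <= g[, 4],
                 g[, 1] >= g[, 2] & g[, 2] >= g[, 3] & g[, 3] >= g[, 4])
  if (!all(mono)) {
    abort(sprintf("Grade thresholds not monotone for: %s.",
                  paste(rules$analyte[!mono], collapse = ", ")))
  }
  invisible(TRUE)
}

#' Grade a laboratory value against a rule table
#'
#' Returns the highest grade whose threshold the value crosses (closed
#' bounds: `>=` for `"high"` analytes, `<=` for `"low"`), or 0.
#'
#' @param value Numeric value in analyte units.
#' @param analyte Analyte name, matched against the rule table.
#' @param rules Grading rule tibble.
#' @return Integer grade 0-4.
#' @export
grade_value <- function(value, analyte, rules = default_grading_rules()) {
  r <- rules[rules$analyte == analyte, ]
  if (nrow(r) == 0) {
    abort(sprintf("No grading rule for analyte '%s'.", analyte))
  }
  th <- c(r$g1, r$g2, r$g3, r$g4)
  crossed <- if (r$direction == "high") value >= th else value <= th
  if (!any(crossed)) 0L else max(which(crossed))
}

#' Treatment-emergent toxicity with the baseline-delta rule
#'
#' Grades every laboratory value, takes the worst follow-up grade per
#' patient-analyte, and emits a toxicity event only when that grade exceeds
#' the baseline grade: pre-existing abnormalities do not count as
#' treatment-emergent unless they worsen.
#'
#' @param labs Tibble `patient_id`, `visit`, `analyte`, `value` with a
#'   `"baseline"` visit for every patient-analyte.
#' @param rules Grading rule tibble.
#' @return Tibble: `patient_id`, `analyte`, `baseline_grade`,
#'   `worst_followup_grade`, `treatment_emergent`.
#' @export
attribute_toxicity <- function(labs, rules = default_grading_rules()) {
  labs$grade <- purrr::map2_int(labs$value, labs$analyte,
                                function(v, a) as.integer(grade_value(v, a, rules)))
  base <- dplyr::filter(labs, .data$visit == "baseline")
  fup <- dplyr::filter(labs, .data$visit != "baseline")
  missing_base <- dplyr::anti_join(
    dplyr::distinct(fup, .data$patient_id, .data$analyte),
    dplyr::distinct(base, .data$patient_id, .data$analyte),
    by = c("patient_id", "analyte"))
  if (nrow(missing_base) > 0) {
    abort(sprintf("No baseline value for: %s.",
                  paste(unique(missing_base$analyte), collapse = ", ")))
  }
  if (nrow(fup) == 0) {
    abort("At least one follow-up observation per analyte is required.")
  }
  worst <- fup |>
    dplyr::group_by(.data$patient_id, .data$analyte) |>
    dplyr::summarise(worst_followup_grade = max(.data$grade),
                     .groups = "drop")
  out <- dplyr::inner_join(
    dplyr::select(base, "patient_id", "analyte", baseline_grade = "grade"),
    worst, by = c("patient_id", "analyte"))
  out$treatment_emergent <- out$worst_followup_grade > out$baseline_grade
  out
}

#' Worst-grade toxicity summary table
#'
#' Counts patients by worst treatment-emergent follow-up grade per analyte
#' (grades 1-4), the shape of a trial's biochemical toxicity table.
#'
#' @param events Output of [attribute_toxicity()].
#' @param emergent_only Count only treatment-emergent events (default);
#'   otherwise all worst follow-up grades `>= 1`.
#' @return Tibble: `analyte`, `grade_1` ... `grade_4` patient counts.
#' @export
toxicity_table <- function(events, emergent_only = TRUE) {
  x <- if (emergent_only) {
    dplyr::filter(events, .data$treatment_emergent)
  } else {
    dplyr::filter(events, .data$worst_followup_grade >= 1)
  }
  grid <- tidyr::expand_grid(analyte = unique(events$analyte),
                             grade = 1:4)
  counts <- x |>
    dplyr::count(.data$analyte, grade = .data$worst_followup_grade)
  grid |>
    dplyr::left_join(counts, by = c("analyte", "grade")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L)) |>
    tidyr::pivot_wider(names_from = "grade", values_from = "n",
                       names_prefix = "grade_")
}
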