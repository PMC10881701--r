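#' Long format for paired T/N data
#'
#' Pivots a wide paired table (`tn_ia`, `tn_control` per patient-cycle) into
#' the long format used by the mixed models: one row per patient-cycle-arm.
#'
#' @param data Tibble with `patient_id`, `cycle`, `tn_ia`, `tn_control` (and
#'   optionally `basis` and patient-level covariates, which are carried along).
#' @return Tibble with columns `patient_id`, `cycle`, `arm`
#'   (factor, levels `control`, `ia`) and `tn`.
#' @export
tn_long <- function(data) {
  out <- tidyr::pivot_longer(data, c("tn_ia", "tn_control"),
                             names_to = "arm", names_prefix = "tn_",
                             values_to = "tn")
  out$arm <- factor(out$arm, levels = c("control", "ia"))
  out
}

select_pairs <- function(data, cycle, basis) {
  if (!is.null(cycle) && "cycle" %in% names(data)) {
    data <- dplyr::filter(data, .data$cycle %in% !!cycle)
  }
  if (!is.null(basis) && "basis" %in% names(data)) {
    data <- dplyr::filter(data, .data$basis == !!basis)
  }
  complete <- is.finite(data$tn_ia) & is.finite(data$tn_control)
  if (any(!complete)) {
    inform(sprintf("Dropping %d incomplete pair(s).", sum(!complete)))
  }
  data[complete, , drop = FALSE]
}

#' Paired t-test on within-patient T/N differences
#'
#' The primary analysis: a one-sample t-test on the within-patient differences
#' `tn_ia - tn_control` at a single cycle, with a two-sided p-value and 95%
#' confidence interval.
#'
#' @param data Paired tibble with `patient_id`, `cycle`, `tn_ia`,
#'   `tn_control` (and optionally `basis`).
#' @param cycle Which cycle to analyse (default 1); `NULL` keeps all rows.
#' @param basis `"mean"` or `"peak"` when a `basis` column is present.
#' @param conf_level Confidence level.
#' @return An object of class `tn_paired_test`; see [tidy()] and [glance()].
#' @export
paired_t_test <- function(data, cycle = 1L, basis = "mean",
                          conf_level = 0.95) {
  data <- select_pairs(data, cycle, basis)
  n <- nrow(data)
  if (n < 2) abort("The paired t-test requires at least 2 complete pairs.")
  d <- data$tn_ia - data$tn_control
  # variability at floating-point noise level counts as none
  eps <- 1e-12 * max(abs(data$tn_ia), abs(data$tn_control), 1)
  if (sd(d) <= eps) {
    # degenerate: no variability in the differences; a zero mean difference
    # carries no evidence against the null (p = 1), a non-zero one is certain
    m <- mean(d)
    zero <- abs(m) <= eps
    return(structure(
      list(mean_difference = m, ci_low = m, ci_high = m,
           t_statistic = if (zero) 0 else sign(m) * Inf,
           df = n - 1, p_value = if (zero) 1 else 0,
           n = n, conf_level = conf_level,
           method = "paired t-test on T/N differences"),
      class = "tn_paired_test"))
  }
  ht <- stats::t.test(d, conf.level = conf_level)
  structure(
    list(mean_difference = unname(ht$estimate),
         ci_low = ht$conf.int[1], ci_high = ht$conf.int[2],
         t_statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value, n = n, conf_level = conf_level,
         method = "paired t-test on T/N differences"),
    class = "tn_paired_test"
  )
}

#' @export
print.tn_paired_test <- function(x, ...) {
  cat(sprintf(
    "%s (n = %d)\n  mean difference %.3f (%.0f%% CI [%.3f, %.3f]), t(%d) = %.3f, p = %.4g\n",
    x$method, x$n, x$mean_difference, 100 * x$conf_level, x$ci_low, x$ci_high,
    x$df, x$t_statistic, x$p_value))
  invisible(x)
}

#' @export
tidy.tn_paired_test <- function(x, ...) {
  tibble(estimate = x$mean_difference, conf.low = x$ci_low,
         conf.high = x$ci_high, statistic = x$t_statistic,
         df = x$df, p.value = x$p_value)
}

#' @export
glance.tn_paired_test <- function(x, ...) {
  tibble(n = x$n, method = x$method)
}

#' Log-ratio test: multiplicative T/N difference
#'
#' A paired t-test on the natural-log-transformed T/N values; point estimate
#' and confidence bounds are transformed back by exponentiation, so the result
#' is the geometric mean of the within-patient ratios `tn_ia / tn_control`.
#'
#' @inheritParams paired_t_test
#' @return An object of class `tn_ratio_test`.
#' @export
log_ratio_test <- function(data, cycle = 1L, basis = "mean",
                           conf_level = 0.95) {
  data <- select_pairs(data, cycle, basis)
  n <- nrow(data)
  if (n < 2) abort("The log-ratio test requires at least 2 complete pairs.")
  bad <- data$tn_ia <= 0 | data$tn_control <= 0
  if (any(bad)) {
    abort(sprintf("Non-positive T/N in record(s): %s.",
                  paste(data$patient_id[bad], collapse = ", ")))
  }
  d <- log(data$tn_ia) - log(data$tn_control)
  if (sd(d) <= 1e-10 * max(1, abs(mean(d)))) {
    abort("All log-ratios are identical: the test statistic is degenerate (zero variance).")
  }
  ht <- stats::t.test(d, conf.level = conf_level)
  structure(
    list(geometric_ratio = exp(unname(ht$estimate)),
         ci_low = exp(ht$conf.int[1]), ci_high = exp(ht$conf.int[2]),
         t_statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value, n = n, conf_level = conf_level,
         method = "paired t-test on log T/N, back-transformed"),
    class = "tn_ratio_test"
  )
}

#' @export
print.tn_ratio_test <- function(x, ...) {
  cat(sprintf(
    "%s (n = %d)\n  geometric ratio %.3f (%.0f%% CI [%.3f, %.3f]), t(%d) = %.3f, p = %.4g\n",
    x$method, x$n, x$geometric_ratio, 100 * x$conf_level, x$ci_low, x$ci_high,
    x$df, x$t_statistic, x$p_value))
  invisible(x)
}

#' @export
tidy.tn_ratio_test <- function(x, ...) {
  tibble(estimate = x$geometric_ratio, conf.low = x$ci_low,
         conf.high = x$ci_high, statistic = x$t_statistic,
         df = x$df, p.value = x$p_value)
}

#' @export
glance.tn_ratio_test <- function(x, ...) {
  tibble(n = x$n, method = x$method)
}

#' Two-level random-intercept mixed model over all cycles
#'
#' Fits `tn ~ arm + (1 | patient) + (1 | patient:cycle)` by REML: a random
#' intercept per patient (between-patient correlation) and per cycle within
#' patient (the paired-sample design). The fixed arm effect is the adjusted
#' mean T/N difference between the treated and the control lobe; its p-value
#' uses the Satterthwaite degrees-of-freedom approximation.
#'
#' @param data Wide paired tibble (see [paired_t_test()]) or long format as
#'   produced by [tn_long()]; all available cycles are used.
#' @param basis `"mean"` or `"peak"` when a `basis` column is present.
#' @param log_scale Model `log(tn)` instead of `tn`.
#' @param conf_level Confidence level for the Wald interval.
#' @return An object of class `tn_lmm` wrapping the `lmerMod` fit, with the
#'   arm effect, its confidence interval and p-value, and the three variance
#'   components.
#' @export
fit_two_level_lmm <- function(data, basis = "mean", log_scale = FALSE,
                              conf_level = 0.95) {
  if ("tn_ia" %in% names(data)) {
    data <- select_pairs(data, cycle = NULL, basis = basis)
    data <- tn_long(data)
  } else if ("basis" %in% names(data) && !is.null(basis)) {
    data <- dplyr::filter(data, .data$basis == !!basis)
  }
  if (!all(c("patient_id", "cycle", "arm", "tn") %in% names(data))) {
    abort("Long data must have columns patient_id, cycle, arm, tn.")
  }
  data$arm <- factor(data$arm, levels = c("control", "ia"))
  data$y <- if (log_scale) log(data$tn) else data$tn
  # with a single cycle the per-cycle intercept is perfectly confounded with
  # the per-patient intercept; keep only the identifiable term
  single_cycle <- length(unique(data$cycle)) == 1
  form <- if (single_cycle) {
    y ~ arm + (1 | patient_id)
  } else {
    y ~ arm + (1 | patient_id) + (1 | patient_id:cycle)
  }
  fit <- withCallingHandlers(
    lmerTest::lmer(form, data = data, REML = TRUE),
    message = function(m) invokeRestart("muffleMessage")
  )
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  if (any(grepl("failed to converge", msgs, ignore.case = TRUE))) {
    abort(paste("Mixed model failed to converge:",
                paste(msgs, collapse = "; ")))
  }
  if (lme4::isSingular(fit)) {
    inform("Mixed model fit is singular: at least one variance component is at the boundary (0).")
  }
  co <- as.data.frame(summary(fit)$coefficients)["armia", ]
  vc <- as.data.frame(lme4::VarCorr(fit))
  get_vc <- function(grp) {
    v <- vc$vcov[vc$grp == grp]
    if (length(v)) v else 0
  }
  tcrit <- qt(1 - (1 - conf_level) / 2, co$df)
  structure(
    list(fit = fit,
         fixed_effect_arm = co$Estimate, se = co$`Std. Error`,
         df = co$df,
         ci_low = co$Estimate - tcrit * co$`Std. Error`,
         ci_high = co$Estimate + tcrit * co$`Std. Error`,
         p_value = co$`Pr(>|t|)`,
         var_patient = get_vc("patient_id"),
         var_cycle_within_patient = get_vc("patient_id:cycle"),
         var_residual = get_vc("Residual"),
         n_obs = nrow(data), log_scale = log_scale,
         conf_level = conf_level, singular = lme4::isSingular(fit)),
    class = "tn_lmm"
  )
}

#' @export
print.tn_lmm <- function(x, ...) {
  cat(sprintf(
    paste0("Two-level random-intercept model (%s scale, REML, %d rows)\n",
           "  arm effect %.4f (SE %.4f, %.0f%% CI [%.4f, %.4f]), p = %.4g\n",
           "  variance components: patient %.4g, cycle-in-patient %.4g, residual %.4g%s\n"),
    if (x$log_scale) "log" else "natural", x$n_obs,
    x$fixed_effect_arm, x$se, 100 * x$conf_level, x$ci_low, x$ci_high,
    x$p_value, x$var_patient, x$var_cycle_within_patient, x$var_residual,
    if (x$singular) " (singular fit)" else ""))
  invisible(x)
}

#' @export
tidy.tn_lmm <- function(x, ...) {
  tibble(term = "arm (ia vs control)", estimate = x$fixed_effect_arm,
         std.error = x$se, df = x$df, conf.low = x$ci_low,
         conf.high = x$ci_high, p.value = x$p_value)
}

#' @export
glance.tn_lmm <- function(x, ...) {
  tibble(n_obs = x$n_obs, var_patient = x$var_patient,
         var_cycle_within_patient = x$var_cycle_within_patient,
         var_residual = x$var_residual, singular = x$singular,
         log_scale = x$log_scale)
}

#' Effect-modification test for a patient-level covariate
#'
#' Adds the covariate and its interaction with the arm to the two-level mixed
#' model and returns the p-value of the `arm x covariate` interaction: does
#' the covariate modify the intra-arterial uptake effect?
#'
#' @param data Wide or long paired data; must carry the covariate column.
#' @param covariate Name of the covariate column (string).
#' @inheritParams fit_two_level_lmm
#' @return A one-row tibble: `covariate`, `statistic` (F), `p_value`.
#' @export
covariate_test <- function(data, covariate, basis = "mean",
                           log_scale = FALSE) {
  if ("tn_ia" %in% names(data)) {
    data <- select_pairs(data, cycle = NULL, basis = basis)
    data <- tn_long(data)
  }
  if (!covariate %in% names(data)) {
    abort(sprintf("Covariate '%s' not found in the data.", covariate))
  }
  cv <- data[[covariate]]
  if (length(unique(cv[!is.na(cv)])) < 2) {
    abort(sprintf("Covariate '%s' is constant; its effect is not estimable.",
                  covariate))
  }
  data$arm <- factor(data$arm, levels = c("control", "ia"))
  data$y <- if (log_scale) log(data$tn) else data$tn
  data$.cov <- cv
  form <- if (length(unique(data$cycle)) == 1) {
    y ~ arm * .cov + (1 | patient_id)
  } else {
    y ~ arm * .cov + (1 | patient_id) + (1 | patient_id:cycle)
  }
  fit <- withCallingHandlers(
    lmerTest::lmer(form, data = data, REML = TRUE),
    message = function(m) invokeRestart("muffleMessage")
  )
  an <- stats::anova(fit)
  row <- an["arm:.cov", ]
  tibble(covariate = covariate, statistic = row$`F value`,
         p_value = row$`Pr(>F)`)
}

#' Exact Fisher test for r x c contingency tables
#'
#' Exact conditional p-value by complete enumeration of all non-negative
#' integer tables with the observed row and column margins: the p-value is the
#' total multivariate hypergeometric probability of tables no more probable
#' than the observed one.
#'
#' @param table Matrix of non-negative integer counts, at least 2 x 2.
#' @return The exact p-value in (0, 1].
#' @export
fisher_exact_rxc <- function(table) {
  tab <- as.matrix(table)
  if (any(tab < 0) || any(tab != round(tab)) || anyNA(tab)) {
    abort("`table` must contain non-negative integer counts.")
  }
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    abort("`table` must be at least 2 x 2.")
  }
  rs <- rowSums(tab)
  cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) {
    abort("`table` has an empty row or column.")
  }
  n <- sum(tab)
  const <- sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(n)
  logp_obs <- const - sum(lfactorial(tab))
  tol <- 1e-7
  total <- 0
  mass <- 0
  # recurse over rows; within a row over compositions bounded by the
  # remaining column capacity
  recurse_row <- function(i, col_rem, acc_lfact) {
    if (i > nrow(tab)) {
      lp <- const - acc_lfact
      mass <<- mass + exp(lp)
      if (lp <= logp_obs + tol) total <<- total + exp(lp)
      return(invisible())
    }
    if (i == nrow(tab)) {
      # last row is forced by the column margins
      recurse_row(i + 1L, col_rem - col_rem,
                  acc_lfact + sum(lfactorial(col_rem)))
      return(invisible())
    }
    fill_cell <- function(j, left, col_rem, acc_lfact) {
      if (j == ncol(tab)) {
        if (left <= col_rem[j]) {
          col_rem[j] <- col_rem[j] - left
          recurse_row(i + 1L, col_rem, acc_lfact + lfactorial(left))
        }
        return(invisible())
      }
      upper <- min(left, col_rem[j])
      # the remaining cells of this row must be able to absorb the rest
      lower <- max(0L, left - sum(col_rem[(j + 1):ncol(tab)]))
      if (upper < lower) return(invisible())
      for (v in lower:upper) {
        cr <- col_rem
        cr[j] <- cr[j] - v
        fill_cell(j + 1L, left - v, cr, acc_lfact + lfactorial(v))
      }
    }
    fill_cell(1L, rs[i], col_rem, acc_lfact)
  }
  recurse_row(1L, cs, 0)
  # the probabilities over all tables with these margins sum to 1 exactly;
  # normalizing removes accumulated floating error
  min(1, total / mass)
}

#' Proportion of patients with any T/N increase
#'
#' Fraction of complete pairs with `tn_ia` strictly greater than
#' `tn_control`; ties count as no increase.
#'
#' @inheritParams paired_t_test
#' @return One-row tibble: `n_increased`, `n`, `proportion`.
#' @export
proportion_increased <- function(data, cycle = 1L, basis = "mean") {
  data <- select_pairs(data, cycle, basis)
  n_inc <- sum(data$tn_ia > data$tn_control)
  tibble(n_increased = n_inc, n = nrow(data),
         proportion = if (nrow(data) > 0) n_inc / nrow(data) else NA_real_)
}
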