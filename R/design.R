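#' Permuted-block in-patient randomization
#'
#' Generates the left/right treated-lobe assignment sequence from a
#' computer-generated permuted block sequence with block sizes 1 and 2. Each
#' block's size is drawn uniformly from \{1, 2\}; a size-2 block contains one
#' `left` and one `right` in random order, and a size-1 block is a fair coin.
#'
#' @param n_patients Number of assignments to produce (`>= 1`).
#' @param seed Integer seed; the same seed reproduces the same list.
#' @return A list of class `randomization_list` with `assignments` (character
#'   vector of `"left"`/`"right"`), `block_structure` (integer block sizes
#'   summing to `n_patients`) and `seed`.
#' @export
generate_randomization <- function(n_patients, seed = 1L) {
  n_patients <- as.integer(n_patients)
  if (n_patients < 1) abort("`n_patients` must be at least 1.")
  withr::with_seed(as.integer(seed), {
    assignments <- character(0)
    blocks <- integer(0)
    while (length(assignments) < n_patients) {
      remaining <- n_patients - length(assignments)
      size <- sample(1:2, 1)
      # a trailing size-2 block that does not fit degrades to a fair coin
      if (size == 2 && remaining >= 2) {
        assignments <- c(assignments, sample(c("left", "right")))
        blocks <- c(blocks, 2L)
      } else {
        assignments <- c(assignments, sample(c("left", "right"), 1))
        blocks <- c(blocks, 1L)
      }
    }
    structure(list(assignments = assignments[seq_len(n_patients)],
                   block_structure = blocks, seed = as.integer(seed)),
              class = "randomization_list")
  })
}

#' @export
print.randomization_list <- function(x, ...) {
  cat(sprintf("<randomization_list> %d assignments (%d left / %d right), %d blocks, seed %d\n",
              length(x$assignments), sum(x$assignments == "left"),
              sum(x$assignments == "right"), length(x$block_structure), x$seed))
  invisible(x)
}

#' @export
as_tibble.randomization_list <- function(x, ...) {
  tibble(patient = seq_along(x$assignments), ia_lobe = x$assignments,
         block = rep(seq_along(x$block_structure), x$block_structure))
}

#' Exact power of the paired t-test
#'
#' Power of the one-sample t-test on within-patient differences, from the
#' noncentral t distribution with noncentrality `dz * sqrt(n)` and `n - 1`
#' degrees of freedom. `dz` is Cohen's dz: the mean within-pair difference
#' divided by the standard deviation of the differences.
#'
#' @param n Number of pairs (`>= 2`).
#' @param dz Cohen's dz effect size (`> 0`, except in the null check where
#'   `dz = 0` returns `alpha` for the two-sided test).
#' @param alpha Significance level.
#' @param sided `"two"` (default) or `"one"`.
#' @return Power as a probability.
#' @export
power_paired_t <- function(n, dz = 0.65, alpha = 0.05,
                           sided = c("two", "one")) {
  sided <- match.arg(sided)
  n <- as.integer(n)
  if (any(n < 2)) abort("Paired t power requires n >= 2.")
  if (dz < 0) abort("`dz` must be non-negative.")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  ncp <- dz * sqrt(n)
  df <- n - 1
  if (sided == "two") {
    tc <- qt(1 - alpha / 2, df)
    (1 - pt(tc, df, ncp)) + pt(-tc, df, ncp)
  } else {
    tc <- qt(1 - alpha, df)
    1 - pt(tc, df, ncp)
  }
}

#' Minimum number of pairs reaching a target power
#'
#' Smallest `n` with [power_paired_t()] at least `power`.
#'
#' @inheritParams power_paired_t
#' @param power Target power in (0, 1).
#' @param n_max Search bound.
#' @return Integer sample size.
#' @export
min_n_paired_t <- function(dz = 0.65, power = 0.9, alpha = 0.05,
                           sided = c("two", "one"), n_max = 10000L) {
  sided <- match.arg(sided)
  if (dz <= 0) abort("Target power is unreachable at dz = 0.")
  if (power <= 0 || power >= 1) abort("`power` must be in (0, 1).")
  for (n in 2:n_max) {
    if (power_paired_t(n, dz = dz, alpha = alpha, sided = sided) >= power) {
      return(as.integer(n))
    }
  }
  abort(sprintf("No n <= %d reaches power %.2f at dz = %.3f.", n_max, power, dz))
}
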