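#' Standardized difference for a continuous covariate
#'
#' Cohen's d between the two arms: difference in means divided by the
#' pooled standard deviation
#' `sqrt(((n0-1) s0^2 + (n1-1) s1^2) / (n0 + n1 - 2))`.
#' Positive values mean arm 0's mean is larger.  When both arms are
#' constant with equal means the difference is 0; constant arms with
#' unequal means return a signed infinity sentinel.
#'
#' @param x0,x1 Numeric vectors of non-missing values in arm 0 / arm 1
#'   (at least 2 each).
#' @return Signed standardized difference (arm 0 minus arm 1).
#' @examples
#' std_diff_continuous(c(1, 2, 3, 4), c(2, 3, 4, 5))
#' @export
std_diff_continuous <- function(x0, x1) {
  n0 <- length(x0); n1 <- length(x1)
  if (n0 < 2L || n1 < 2L)
    stop_validation("std_diff_continuous needs >= 2 values per arm")
  m0 <- mean(x0); m1 <- mean(x1)
  sp2 <- ((n0 - 1) * stats::var(x0) + (n1 - 1) * stats::var(x1)) / (n0 + n1 - 2)
  if (sp2 == 0) {
    if (m0 == m1) return(0)
    return(sign(m0 - m1) * Inf)
  }
  (m0 - m1) / sqrt(sp2)
}

#' Standardized difference for a binary covariate
#'
#' `(p0 - p1) / sqrt((p0 (1 - p0) + p1 (1 - p1)) / 2)` with
#' `p0 = k0/n0`, `p1 = k1/n1`.  Returns 0 when the proportions are
#' equal; when both arms are degenerate (both proportions 0 or both 1)
#' with unequal proportions the result is a signed infinity sentinel.
#'
#' @param k0,k1 Trait-positive counts in arm 0 / arm 1.
#' @param n0,n1 Arm sizes (>= 1).
#' @return Signed standardized difference (arm 0 minus arm 1).
#' @examples
#' std_diff_binary(8, 10, 2, 10)
#' @export
std_diff_binary <- function(k0, n0, k1, n1) {
  if (n0 < 1L || n1 < 1L) stop_validation("arm sizes must be >= 1")
  if (k0 < 0L || k1 < 0L || k0 > n0 || k1 > n1)
    stop_validation("counts must satisfy 0 <= k <= n")
  p0 <- k0 / n0; p1 <- k1 / n1
  if (p0 == p1) return(0)
  den2 <- (p0 * (1 - p0) + p1 * (1 - p1)) / 2
  if (den2 == 0) return(sign(p0 - p1) * Inf)
  (p0 - p1) / sqrt(den2)
}

#' Risk difference between arms
#'
#' `k0/n0 - k1/n1`: the signed difference in trait proportions, arm 0
#' minus arm 1.
#'
#' @inheritParams std_diff_binary
#' @return Risk difference in `[-1, 1]`.
#' @export
risk_difference <- function(k0, n0, k1, n1) {
  if (n0 < 1L || n1 < 1L) stop_validation("arm sizes must be >= 1")
  if (k0 < 0L || k1 < 0L || k0 > n0 || k1 > n1)
    stop_validation("counts must satisfy 0 <= k <= n")
  k0 / n0 - k1 / n1
}

# closed-form two-sample tests -------------------------------------------
# The sequential engine evaluates one test per active covariate at every
# allocation, so the Welch t and 2x2 chi-square p-values are computed
# directly from sufficient statistics; equivalence with stats::t.test()
# and stats::chisq.test(correct = FALSE) is asserted in the test suite.

welch_p_value <- function(x0, x1) {
  n0 <- length(x0); n1 <- length(x1)
  if (n0 < 2L || n1 < 2L) return(list(statistic = NA_real_, p_value = 1))
  v0 <- stats::var(x0); v1 <- stats::var(x1)
  if (v0 == 0 && v1 == 0) {
    if (mean(x0) == mean(x1)) return(list(statistic = 0, p_value = 1))
    return(list(statistic = sign(mean(x0) - mean(x1)) * Inf, p_value = 0))
  }
  se2 <- v0 / n0 + v1 / n1
  tstat <- (mean(x0) - mean(x1)) / sqrt(se2)
  df <- se2^2 / ((v0 / n0)^2 / (n0 - 1) + (v1 / n1)^2 / (n1 - 1))
  list(statistic = tstat, p_value = 2 * stats::pt(-abs(tstat), df))
}

# 2x2 test of proportions: Pearson chi-square without continuity
# correction, switching to Fisher's exact test when any expected cell
# count is below 5.
prop_p_value <- function(k0, n0, k1, n1) {
  k0 <- as.numeric(k0); n0 <- as.numeric(n0)   # doubles: the chi-square
  k1 <- as.numeric(k1); n1 <- as.numeric(n1)   # products overflow ints
  n <- n0 + n1
  c1 <- k0 + k1          # trait-positive margin
  c2 <- n - c1
  if (c1 == 0 || c2 == 0 || n0 == 0 || n1 == 0)
    return(list(statistic = 0, p_value = 1, test = "none"))
  expected_min <- min(n0 * c1, n0 * c2, n1 * c1, n1 * c2) / n
  if (expected_min < 5) {
    tab <- matrix(c(k0, n0 - k0, k1, n1 - k1), nrow = 2, byrow = TRUE)
    p <- stats::fisher.test(tab)$p.value
    return(list(statistic = NA_real_, p_value = min(p, 1), test = "fisher"))
  }
  stat <- n * (k0 * (n1 - k1) - k1 * (n0 - k0))^2 / (n0 * n1 * c1 * c2)
  list(statistic = stat, p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       test = "chisq")
}

# exact two-sided binomial test of n0 successes in n trials at rate 1/2;
# closed form valid only for the symmetric p = 1/2 case (verified
# against stats::binom.test in the suite).
binom_half_p_value <- function(n0, n1) {
  n <- n0 + n1
  if (n == 0L) return(1)
  k <- min(n0, n1)
  if (2L * k == n) return(1)
  min(1, 2 * stats::pbinom(k, n, 0.5))
}

#' Test one covariate's between-arm imbalance
#'
#' Runs the covariate's imbalance test over the currently randomized
#' units: a Welch two-sample t-test for continuous covariates, a 2x2
#' chi-square test of proportions for binary/categorical ones (Fisher's
#' exact test when any expected cell count falls below 5).  For binary
#' and categorical covariates the test is one-vs-rest on an indicator
#' level — during allocation this is the incoming unit's own level.
#' Units with a missing value are excluded; if either arm contributes
#' no data the report carries `p_value = 1` and no statistic.
#'
#' @param trial An [msb_trial].
#' @param covariate Covariate name.
#' @param level Indicator level for binary/categorical covariates.
#'   Defaults to the last declared level for binary covariates; required
#'   for categorical ones.
#' @param at_index Enrollment index at which the test runs (defaults to
#'   the number of randomized units); the covariate must be active.
#' @return An object of class `balance_report`: covariate, indicator
#'   level, `n_by_arm`, `k_by_arm` (non-continuous), test name,
#'   statistic, `p_value`, `std_diff`, `risk_diff`, and a `vote` slot
#'   (`"none"` until [covariate_vote()] fills it).
#' @export
imbalance_test <- function(trial, covariate, level = NULL,
                           at_index = trial$n_randomized) {
  stopifnot(inherits(trial, "msb_trial"))
  spec <- trial$specs[[covariate]]
  if (is.null(spec)) stop_state(sprintf("unknown covariate '%s'", covariate))
  if (spec$active_from > at_index)
    stop_state(sprintf("covariate '%s' is not active at enrollment index %d",
                       covariate, at_index))
  arm <- trial$units$arm
  vals <- trial$units[[cov_col(covariate)]]
  in0 <- !is.na(arm) & arm == trial$arms[1] & !is.na(vals)
  in1 <- !is.na(arm) & arm == trial$arms[2] & !is.na(vals)

  if (spec$kind == "continuous") {
    x0 <- vals[in0]; x1 <- vals[in1]
    n0 <- length(x0); n1 <- length(x1)
    if (n0 == 0L || n1 == 0L)
      return(balance_report(covariate, NA, c(n0, n1), NULL, "none", NA, 1, NA, NA))
    tst <- welch_p_value(x0, x1)
    d <- if (n0 >= 2L && n1 >= 2L) std_diff_continuous(x0, x1) else NA_real_
    return(balance_report(covariate, NA, c(n0, n1), NULL, "welch_t",
                          tst$statistic, tst$p_value, d, NA,
                          means = c(mean(x0), mean(x1)),
                          pooled_mean = mean(c(x0, x1))))
  }

  if (is.null(level)) {
    if (spec$kind == "binary") level <- spec$levels[2L]
    else stop_state(sprintf("categorical covariate '%s' needs an indicator level", covariate))
  }
  if (!(level %in% spec$levels))
    stop_state(sprintf("'%s' is not a level of covariate '%s'", level, covariate))
  n0 <- sum(in0); n1 <- sum(in1)
  if (n0 == 0L || n1 == 0L)
    return(balance_report(covariate, level, c(n0, n1), c(0L, 0L), "none", NA, 1, NA, NA))
  k0 <- sum(vals[in0] == level); k1 <- sum(vals[in1] == level)
  tst <- prop_p_value(k0, n0, k1, n1)
  balance_report(covariate, level, c(n0, n1), c(k0, k1), tst$test,
                 tst$statistic, tst$p_value,
                 std_diff_binary(k0, n0, k1, n1),
                 risk_difference(k0, n0, k1, n1))
}

balance_report <- function(covariate, level, n_by_arm, k_by_arm, test,
                           statistic, p_value, std_diff, risk_diff,
                           means = NULL, pooled_mean = NULL) {
  structure(
    list(covariate = covariate, level = level, n_by_arm = n_by_arm,
         k_by_arm = k_by_arm, test = test, statistic = statistic,
         p_value = p_value, std_diff = std_diff, risk_diff = risk_diff,
         means = means, pooled_mean = pooled_mean, vote = "none"),
    class = "balance_report"
  )
}

#' @export
print.balance_report <- function(x, ...) {
  cat(sprintf("<balance_report> %s%s: n=(%d,%d), %s p=%.4g, d=%.4g%s, vote=%s\n",
              x$covariate,
              if (!is.na(x$level)) paste0(" [", x$level, "]") else "",
              x$n_by_arm[1], x$n_by_arm[2], x$test, x$p_value, x$std_diff,
              if (!is.na(x$risk_diff)) sprintf(", rd=%.4g", x$risk_diff) else "",
              x$vote))
  invisible(x)
}

#' Which arm would an incoming unit's covariate vote for?
#'
#' Implements the MSB balance criterion for one covariate.  No vote is
#' cast when the imbalance test is not significant
#' (`p_value >= p_threshold`) or the unit's value is missing.
#' Otherwise, for a continuous covariate: a new value above the pooled
#' mean of randomized units votes for the arm with the smaller current
#' mean, below it for the arm with the larger mean (a value exactly at
#' the pooled mean, or equal arm means, casts no vote).  For
#' binary/categorical covariates the unit's own level is the indicator:
#' a unit carrying the trait votes for the arm with the lower current
#' proportion of it, a unit without the trait for the arm with the
#' higher proportion (equal proportions: no vote).  Assigning the unit
#' to the voted arm never increases that covariate's absolute
#' standardized difference relative to the alternative arm.
#'
#' @param report A `balance_report` from [imbalance_test()] whose
#'   indicator level matches the unit's own level for categorical
#'   covariates.
#' @param trial An [msb_trial].
#' @param unit_id Identifier of the (not yet randomized) incoming unit.
#' @return Arm label, or `"none"`.
#' @export
covariate_vote <- function(report, trial, unit_id) {
  stopifnot(inherits(report, "balance_report"), inherits(trial, "msb_trial"))
  if (report$p_value >= trial$config$p_threshold) return("none")
  spec <- trial$specs[[report$covariate]]
  i <- unit_row(trial, unit_id)
  v <- trial$units[[cov_col(report$covariate)]][i]
  if (is.na(v)) return("none")

  if (spec$kind == "continuous") {
    if (is.null(report$means) || report$means[1] == report$means[2]) return("none")
    if (v == report$pooled_mean) return("none")
    smaller <- if (report$means[1] < report$means[2]) trial$arms[1] else trial$arms[2]
    larger  <- setdiff(trial$arms, smaller)
    return(if (v > report$pooled_mean) smaller else larger)
  }

  has_trait <- v == report$level
  p0 <- report$k_by_arm[1] / report$n_by_arm[1]
  p1 <- report$k_by_arm[2] / report$n_by_arm[2]
  if (p0 == p1) return("none")
  lower  <- if (p0 < p1) trial$arms[1] else trial$arms[2]
  higher <- setdiff(trial$arms, lower)
  if (has_trait) lower else higher
}

#' Per-covariate balance reports for a trial
#'
#' Runs [imbalance_test()] for every active covariate and returns one
#' row per covariate (for categorical covariates, one row per level,
#' one-vs-rest).  When `unit_id` names an unrandomized unit, the vote
#' column is filled with [covariate_vote()] against that unit (using
#' the unit's own level for categorical covariates, one row each).
#'
#' @param trial An [msb_trial].
#' @param unit_id Optional incoming unit for vote computation.
#' @return A `data.frame` with columns covariate, level, n0, n1, test,
#'   statistic, p_value, std_diff, risk_diff, vote.
#' @export
balance_reports <- function(trial, unit_id = NULL) {
  stopifnot(inherits(trial, "msb_trial"))
  rows <- list()
  for (s in active_specs(trial, trial$n_randomized)) {
    levels_to_test <- if (s$kind == "continuous") {
      list(NULL)
    } else if (!is.null(unit_id)) {
      v <- trial$units[[cov_col(s$name)]][unit_row(trial, unit_id)]
      if (is.na(v)) {
        if (s$kind == "binary") list(s$levels[2L]) else as.list(s$levels)
      } else list(as.character(v))
    } else if (s$kind == "binary") {
      list(s$levels[2L])
    } else as.list(s$levels)
    for (lev in levels_to_test) {
      rep <- imbalance_test(trial, s$name, level = lev)
      vote <- if (!is.null(unit_id)) covariate_vote(rep, trial, unit_id) else "none"
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = s$name,
        level = if (is.null(lev)) NA_character_ else lev,
        n0 = rep$n_by_arm[1], n1 = rep$n_by_arm[2],
        test = rep$test,
        statistic = rep$statistic, p_value = rep$p_value,
        std_diff = rep$std_diff, risk_diff = rep$risk_diff,
        vote = vote, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Write a balance report table to CSV
#'
#' @param x A `data.frame` from [balance_reports()] or
#'   [summarize_balance()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_balance_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, na = "")
  invisible(path)
}
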