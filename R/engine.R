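#' Arm-size balance vote
#'
#' Exact two-sided binomial test of the arm-0 count among all
#' randomized units at rate 1/2.  If the p-value falls below the
#' configured threshold the smaller arm receives a vote; otherwise no
#' vote.  Consulted only when `size_balance` is enabled in the
#' configuration.
#'
#' @param trial An [msb_trial].
#' @return List with elements `vote` (arm label or `"none"`) and
#'   `p_value`.
#' @export
size_vote <- function(trial) {
  stopifnot(inherits(trial, "msb_trial"))
  arm <- trial$units$arm
  n0 <- sum(!is.na(arm) & arm == trial$arms[1])
  n1 <- sum(!is.na(arm) & arm == trial$arms[2])
  p <- binom_half_p_value(n0, n1)
  vote <- if (p < trial$config$p_threshold && n0 != n1) {
    if (n0 < n1) trial$arms[1] else trial$arms[2]
  } else "none"
  list(vote = vote, p_value = p)
}

#' Turn a vote tally into an allocation probability
#'
#' A strict majority of votes for one arm biases the coin: that arm is
#' favored with probability `biased_probability` (> 0.5).  A tie or an
#' empty tally leaves the coin fair.
#'
#' @param votes_arm0,votes_arm1 Non-negative vote counts.
#' @param config An [msb_config].
#' @return List with `favored_arm` (`"arm0"`, `"arm1"`, or `"none"`)
#'   and `probability` (the probability given to the favored arm, or
#'   0.5).
#' @export
decide_probability <- function(votes_arm0, votes_arm1, config) {
  stopifnot(inherits(config, "msb_config"),
            votes_arm0 >= 0, votes_arm1 >= 0)
  if (votes_arm0 > votes_arm1)
    list(favored_arm = "arm0", probability = config$biased_probability)
  else if (votes_arm1 > votes_arm0)
    list(favored_arm = "arm1", probability = config$biased_probability)
  else
    list(favored_arm = "none", probability = 0.5)
}

#' Randomize one unit by minimal sufficient balance
#'
#' Allocates a ready, not-yet-randomized unit.  During the burn-in
#' (fewer than `burn_in` units randomized) the draw is simple 1:1.
#' Afterwards every active covariate's imbalance is tested
#' ([imbalance_test()]) and votes are collected ([covariate_vote()],
#' plus the arm-size vote when enabled); a strict majority biases the
#' coin to the favored arm with probability `biased_probability`.  One
#' uniform draw from the trial's private stream decides the arm, and
#' the unit's store row is updated (arm, allocation probability,
#' triggering criteria, `source = "algorithm"`, next enrollment index).
#'
#' The allocation record is appended to `trial$allocations` and also
#' available as `trial$last_allocation`.
#'
#' @param trial An [msb_trial].
#' @param unit_id Identifier of a unit present in the trial store.
#' @param keep_reports If `TRUE`, the per-covariate balance reports are
#'   attached to the allocation record (for audit); off by default to
#'   keep long simulations light.
#' @return The updated trial.  Inspect `trial$last_allocation` (class
#'   `allocation_result`) for the arm, the probability given to the
#'   favored arm, the vote tally, the triggering criteria, and the
#'   uniform draw consumed.
#' @export
randomize_unit <- function(trial, unit_id, keep_reports = FALSE) {
  stopifnot(inherits(trial, "msb_trial"))
  i <- unit_row(trial, unit_id)
  if (!is.na(trial$units$arm[i]))
    stop_state(sprintf("unit '%s' is already randomized", unit_id))
  if (!isTRUE(trial$units$ready[i]))
    stop_state(sprintf("unit '%s' is not ready to be randomized", unit_id))
  issues <- validate_unit(trial, unit_id)
  if (length(issues))
    stop_validation(sprintf("unit '%s' failed validation: %s",
                            unit_id, paste(issues, collapse = "; ")))

  k <- trial$n_randomized
  votes <- character(0)
  reports <- list()
  if (k >= trial$config$burn_in) {
    for (s in active_specs(trial, k)) {
      v <- trial$units[[cov_col(s$name)]][i]
      if (is.na(v)) next   # missing optional value: no test, no vote
      rep <- imbalance_test(trial, s$name,
                            level = if (s$kind == "continuous") NULL else as.character(v),
                            at_index = k)
      vote <- covariate_vote(rep, trial, unit_id)
      rep$vote <- vote
      if (keep_reports) reports[[s$name]] <- rep
      if (vote != "none") votes[s$name] <- vote
    }
    if (trial$config$size_balance) {
      sv <- size_vote(trial)
      if (sv$vote != "none") votes["sample_size"] <- sv$vote
    }
  }
  v0 <- sum(votes == trial$arms[1])
  v1 <- sum(votes == trial$arms[2])
  dec <- decide_probability(v0, v1, trial$config)
  favored <- switch(dec$favored_arm,
                    arm0 = trial$arms[1], arm1 = trial$arms[2], NA_character_)
  p_arm0 <- if (is.na(favored)) 0.5
            else if (favored == trial$arms[1]) dec$probability
            else 1 - dec$probability

  drawn <- trial_runif(trial)
  trial <- drawn$trial
  u <- drawn$u
  arm <- if (u < p_arm0) trial$arms[1] else trial$arms[2]
  criteria <- if (is.na(favored)) character(0) else names(votes)

  trial$units$arm[i] <- arm
  trial$units$allocation_probability[i] <- if (arm == trial$arms[1]) p_arm0 else 1 - p_arm0
  trial$units$criteria[i] <- paste(criteria, collapse = ";")
  trial$units$source[i] <- "algorithm"
  trial$units$enrollment_index[i] <- k
  trial$n_randomized <- k + 1L

  res <- structure(
    list(unit_id = unit_id, arm = arm,
         probability_used = dec$probability,
         favored_arm = favored,
         votes_arm0 = v0, votes_arm1 = v1,
         criteria = criteria, rng_draw = u,
         enrollment_index = k, source = "algorithm",
         reports = if (keep_reports) reports else NULL),
    class = "allocation_result"
  )
  trial$allocations[[length(trial$allocations) + 1L]] <- res
  trial$last_allocation <- res
  trial
}

#' @export
print.allocation_result <- function(x, ...) {
  cat(sprintf("<allocation_result> unit %s -> %s (index %d, %s)\n",
              x$unit_id, x$arm, x$enrollment_index, x$source))
  if (!is.na(x$favored_arm))
    cat(sprintf("  favored %s with p = %g; votes %d:%d; criteria: %s\n",
                x$favored_arm, x$probability_used, x$votes_arm0, x$votes_arm1,
                paste(x$criteria, collapse = ", ")))
  else cat(sprintf("  unbiased draw (p = 0.5)\n"))
  invisible(x)
}

allocation_to_list <- function(res) {
  list(unit_id = res$unit_id, arm = res$arm,
       probability_used = res$probability_used,
       favored_arm = if (is.na(res$favored_arm)) NULL else res$favored_arm,
       votes_arm0 = res$votes_arm0, votes_arm1 = res$votes_arm1,
       criteria = as.list(res$criteria), rng_draw = res$rng_draw,
       enrollment_index = res$enrollment_index, source = res$source)
}
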