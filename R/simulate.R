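#' Configure a synthetic enrollment population
#'
#' Describes the marginal distribution of each balancing covariate in a
#' simulated enrollment stream, the fraction of units that are
#' partnered dyads, and optional mid-trial activation overrides.
#' Covariates are drawn independently of one another.
#'
#' Each element of `covariates` is a list with `name`, `kind`
#' (`"continuous"`, `"binary"`, `"categorical"`) and either
#' * `levels` + `probs` (binary/categorical; probabilities summing
#'   to 1), or
#' * `dist = "uniform"` with `min`, `max`, or `dist = "normal"` with
#'   `mean`, `sd` (continuous).
#'
#' @param n_units Number of units to generate.
#' @param covariates List of marginal descriptions (see Details);
#'   defaults to [default_marginals()].
#' @param dyad_fraction Probability a unit is a partnered dyad (two
#'   member record ids).
#' @param activation Named integer vector of `active_from` overrides
#'   per covariate (default: all active from enrollment index 0).
#' @param seed Integer seed for stream generation.
#' @return An object of class `population_config`.
#' @export
population_config <- function(n_units, covariates = default_marginals(),
                              dyad_fraction = 0.3, activation = NULL,
                              seed = 1L) {
  n_units <- as.integer(n_units)
  if (is.na(n_units) || n_units < 0L)
    stop_validation("n_units must be a non-negative integer")
  if (dyad_fraction < 0 || dyad_fraction > 1)
    stop_validation("dyad_fraction must lie in [0, 1]")
  for (cv in covariates) {
    if (is.null(cv$name) || is.null(cv$kind))
      stop_validation("each covariate marginal needs 'name' and 'kind'")
    if (cv$kind %in% c("binary", "categorical")) {
      if (length(cv$levels) != length(cv$probs))
        stop_validation(sprintf("covariate '%s': levels and probs differ in length", cv$name))
      if (any(cv$probs < 0) || any(cv$probs > 1) ||
          abs(sum(cv$probs) - 1) > 1e-9)
        stop_validation(sprintf("covariate '%s': probs must be in [0,1] and sum to 1", cv$name))
    }
  }
  if (!is.null(activation)) {
    bad <- setdiff(names(activation),
                   vapply(covariates, `[[`, character(1), "name"))
    if (length(bad))
      stop_validation(paste("activation overrides name unknown covariates:",
                            paste(bad, collapse = ", ")))
  }
  structure(list(n_units = n_units, covariates = covariates,
                 dyad_fraction = dyad_fraction, activation = activation,
                 seed = as.integer(seed)),
            class = "population_config")
}

#' Default seven-covariate roster
#'
#' The marginals shipped for simulation mirror the roster of balancing
#' covariates of a two-arm HIV-prevention trial in 16-34 year-olds:
#' participation status (3 levels), limited participation (binary),
#' race/ethnicity (4 levels), gender-nonconforming/trans identity
#' (binary), current PrEP use (binary), baseline STI positivity
#' (binary), and age (continuous, uniform on 16-34 years).  The
#' prevalences are deliberately mid-range placeholders — balance
#' behavior, not population prevalence, is what the simulator
#' exercises.
#'
#' @return List of marginal descriptions for [population_config()].
#' @export
default_marginals <- function() {
  list(
    list(name = "status", kind = "categorical",
         levels = c("single", "partnered_alone", "dyad"),
         probs = c(0.5, 0.2, 0.3)),
    list(name = "limited_participation", kind = "binary",
         levels = c("no", "yes"), probs = c(0.8, 0.2)),
    list(name = "race_ethnicity", kind = "categorical",
         levels = c("white", "black", "latino", "other"),
         probs = c(0.4, 0.25, 0.2, 0.15)),
    list(name = "gnc_trans", kind = "binary",
         levels = c("no", "yes"), probs = c(0.85, 0.15)),
    list(name = "prep_use", kind = "binary",
         levels = c("no", "yes"), probs = c(0.65, 0.35)),
    list(name = "sti", kind = "binary",
         levels = c("negative", "positive"), probs = c(0.9, 0.1)),
    list(name = "age", kind = "continuous",
         dist = "uniform", min = 16, max = 34)
  )
}

#' Covariate specifications implied by a population
#'
#' @param pop A [population_config].
#' @return List of [covariate_spec] objects (activation overrides
#'   applied).
#' @export
population_specs <- function(pop) {
  stopifnot(inherits(pop, "population_config"))
  lapply(pop$covariates, function(cv) {
    af <- if (!is.null(pop$activation) && cv$name %in% names(pop$activation))
      pop$activation[[cv$name]] else 0L
    covariate_spec(cv$name, cv$kind,
                   levels = if (cv$kind == "continuous") NULL else cv$levels,
                   active_from = af)
  })
}

#' Generate a synthetic enrollment stream
#'
#' Draws `n_units` ready, unrandomized unit records independently from
#' the configured marginals.  Deterministic under the population seed;
#' the session's RNG state is left untouched.
#'
#' @param pop A [population_config].
#' @return A `data.frame` in the record-store schema (see
#'   [read_store()]), ready to pass to [add_units()] or [run_trial()].
#' @export
generate_stream <- function(pop) {
  stopifnot(inherits(pop, "population_config"))
  n <- pop$n_units
  specs <- population_specs(pop)
  df <- empty_units(specs)
  if (n == 0L) return(df)

  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_rng(old))
  set.seed(pop$seed, kind = "Mersenne-Twister")

  ids <- sprintf("u%05d", seq_len(n))
  dyad <- stats::runif(n) < pop$dyad_fraction
  df <- data.frame(
    unit_id = ids,
    member_record_ids = ifelse(dyad, paste0(ids, "a;", ids, "b"), ids),
    ready = TRUE, arm = NA_character_,
    allocation_probability = NA_real_, criteria = NA_character_,
    source = "unset", enrollment_index = NA_integer_,
    stringsAsFactors = FALSE
  )
  for (cv in pop$covariates) {
    df[[cov_col(cv$name)]] <- if (cv$kind == "continuous") {
      if (identical(cv$dist, "normal"))
        stats::rnorm(n, cv$mean, cv$sd)
      else stats::runif(n, cv$min, cv$max)
    } else {
      sample(cv$levels, n, replace = TRUE, prob = cv$probs)
    }
  }
  df
}

#' Run a full simulated trial
#'
#' Randomizes every ready, unrandomized unit of the stream
#' sequentially, either with the MSB engine ([randomize_unit()]) or by
#' simple 1:1 randomization that ignores covariates.
#'
#' @param trial An [msb_trial] (typically freshly constructed).
#' @param stream Optional unit `data.frame` to add first (e.g. from
#'   [generate_stream()]).
#' @param scheme `"msb"` or `"simple"`.
#' @return The completed trial with full allocation records.
#' @export
run_trial <- function(trial, stream = NULL, scheme = c("msb", "simple")) {
  stopifnot(inherits(trial, "msb_trial"))
  scheme <- match.arg(scheme)
  if (!is.null(stream)) trial <- add_units(trial, stream)
  todo <- which(is.na(trial$units$arm) & trial$units$ready)
  if (scheme == "msb") {
    ids <- trial$units$unit_id
    for (i in todo) trial <- randomize_unit(trial, ids[i])
    return(trial)
  }
  # simple 1:1: one draw per unit from the same private stream
  drawn <- trial_runif(trial, length(todo))
  trial <- drawn$trial
  k <- trial$n_randomized
  for (j in seq_along(todo)) {
    i <- todo[j]
    arm <- if (drawn$u[j] < 0.5) trial$arms[1] else trial$arms[2]
    trial$units$arm[i] <- arm
    trial$units$allocation_probability[i] <- 0.5
    trial$units$criteria[i] <- ""
    trial$units$source[i] <- "algorithm"
    trial$units$enrollment_index[i] <- k
    res <- structure(
      list(unit_id = trial$units$unit_id[i], arm = arm,
           probability_used = 0.5, favored_arm = NA_character_,
           votes_arm0 = 0L, votes_arm1 = 0L, criteria = character(0),
           rng_draw = drawn$u[j], enrollment_index = k,
           source = "algorithm", reports = NULL),
      class = "allocation_result")
    trial$allocations[[length(trial$allocations) + 1L]] <- res
    trial$last_allocation <- res
    k <- k + 1L
  }
  trial$n_randomized <- k
  trial
}

#' End-of-trial covariate balance table
#'
#' One row per covariate: arm sizes used, the standardized difference
#' (arm 0 minus arm 1), and — for binary/categorical covariates — the
#' risk difference.  Categorical covariates are summarized one-vs-rest
#' over their levels and the level with the largest absolute
#' standardized difference is reported (its signed value), so a single
#' worst-case row represents the covariate.
#'
#' @param trial An [msb_trial] with at least 2 randomized units per
#'   arm.
#' @return A `data.frame` with columns covariate, kind, level, n0, n1,
#'   std_diff, risk_diff.
#' @export
summarize_balance <- function(trial) {
  stopifnot(inherits(trial, "msb_trial"))
  arm <- trial$units$arm
  n0_all <- sum(!is.na(arm) & arm == trial$arms[1])
  n1_all <- sum(!is.na(arm) & arm == trial$arms[2])
  if (n0_all < 2L || n1_all < 2L)
    stop_state("balance summary needs at least 2 randomized units per arm")
  rows <- lapply(trial$specs, function(s) {
    vals <- trial$units[[cov_col(s$name)]]
    in0 <- !is.na(arm) & arm == trial$arms[1] & !is.na(vals)
    in1 <- !is.na(arm) & arm == trial$arms[2] & !is.na(vals)
    n0 <- sum(in0); n1 <- sum(in1)
    if (s$kind == "continuous") {
      d <- if (n0 >= 2L && n1 >= 2L) std_diff_continuous(vals[in0], vals[in1]) else NA_real_
      return(data.frame(covariate = s$name, kind = s$kind,
                        level = NA_character_, n0 = n0, n1 = n1,
                        std_diff = d, risk_diff = NA_real_,
                        stringsAsFactors = FALSE))
    }
    levs <- if (s$kind == "binary") s$levels[2L] else s$levels
    ds <- rds <- numeric(length(levs))
    for (j in seq_along(levs)) {
      k0 <- sum(vals[in0] == levs[j]); k1 <- sum(vals[in1] == levs[j])
      ds[j] <- std_diff_binary(k0, n0, k1, n1)
      rds[j] <- risk_difference(k0, n0, k1, n1)
    }
    worst <- which.max(abs(ds))
    data.frame(covariate = s$name, kind = s$kind, level = levs[worst],
               n0 = n0, n1 = n1, std_diff = ds[worst],
               risk_diff = rds[which.max(abs(rds))],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare MSB against simple randomization by simulation
#'
#' Runs `n_reps` paired replicates: each replicate generates one
#' enrollment stream from the population and randomizes it once with
#' the MSB engine and once with simple 1:1 randomization.  For every
#' completed trial the end-of-trial maximum absolute standardized
#' difference across covariates and maximum absolute risk difference
#' across non-continuous covariates are recorded.
#'
#' Replicate-level seeds for the stream and for each scheme's
#' allocation stream are derived deterministically from `pop$seed`.
#'
#' @param pop A [population_config] (its `seed` seeds the whole
#'   comparison).
#' @param n_reps Number of replicates (>= 1).
#' @param config [msb_config] used for the MSB arm of the comparison.
#' @param arms Arm labels.
#' @param d_threshold,rd_threshold Validity thresholds whose exceedance
#'   fraction is reported (conventional d = 0.1 and 10% risk
#'   difference).
#' @return An object of class `msb_scheme_comparison`: `$replicates`
#'   (one row per replicate x scheme) and `$summary` (per scheme: mean
#'   and 95th percentile of the max |d| and max |risk difference|, and
#'   the fraction of replicates exceeding each threshold).
#' @export
compare_schemes <- function(pop, n_reps, config = msb_config(),
                            arms = c("intervention", "control"),
                            d_threshold = 0.1, rd_threshold = 0.1) {
  stopifnot(inherits(pop, "population_config"), n_reps >= 1)
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(pop$seed, kind = "Mersenne-Twister")
  seeds <- matrix(sample.int(.Machine$integer.max, 3L * n_reps), ncol = 3L)
  restore_rng(old)

  specs <- population_specs(pop)
  rows <- vector("list", 2L * n_reps)
  for (r in seq_len(n_reps)) {
    pop_r <- pop; pop_r$seed <- seeds[r, 1L]
    stream <- generate_stream(pop_r)
    for (s in c("msb", "simple")) {
      cfg <- config
      cfg$seed <- if (s == "msb") seeds[r, 2L] else seeds[r, 3L]
      done <- run_trial(msb_trial(arms, specs, cfg), stream, scheme = s)
      bal <- summarize_balance(done)
      rows[[2L * (r - 1L) + (s == "simple") + 1L]] <- data.frame(
        rep = r, scheme = s,
        max_abs_d = max(abs(bal$std_diff), na.rm = TRUE),
        max_abs_rd = max(abs(bal$risk_diff), na.rm = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  reps <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(reps, reps$scheme), function(g) {
    data.frame(
      scheme = g$scheme[1], n_reps = nrow(g),
      mean_max_abs_d = mean(g$max_abs_d),
      p95_max_abs_d = unname(stats::quantile(g$max_abs_d, 0.95)),
      exceed_d = mean(g$max_abs_d > d_threshold),
      mean_max_abs_rd = mean(g$max_abs_rd),
      p95_max_abs_rd = unname(stats::quantile(g$max_abs_rd, 0.95)),
      exceed_rd = mean(g$max_abs_rd > rd_threshold),
      stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(replicates = reps, summary = summ,
                 d_threshold = d_threshold, rd_threshold = rd_threshold),
            class = "msb_scheme_comparison")
}

#' @export
print.msb_scheme_comparison <- function(x, ...) {
  cat(sprintf("Scheme comparison over %d replicates (thresholds: d = %g, rd = %g)\n",
              max(x$replicates$rep), x$d_threshold, x$rd_threshold))
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}
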