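#' Create a two-arm trial state
#'
#' The trial state is the package's central object: the ordered pair of
#' arm labels, the covariate specifications, the algorithm parameters,
#' the unit records (one row per randomization unit — a single
#' individual or a partnered dyad randomized together), and a private
#' seeded random stream consumed in enrollment order.  All allocation,
#' balance and workflow functions take and return this object.
#'
#' The first listed arm is "arm 0" for every sign convention in the
#' package: a positive standardized or risk difference means arm 0's
#' mean or proportion is the larger one.
#'
#' @param arms Character vector of exactly 2 arm labels.
#' @param covariates List of [covariate_spec] objects.
#' @param config An [msb_config].
#' @return An object of class `msb_trial` with an empty unit store.
#' @examples
#' trial <- msb_trial(
#'   arms = c("intervention", "control"),
#'   covariates = list(covariate_spec("age", "continuous")),
#'   config = msb_config(seed = 42)
#' )
#' trial
#' @export
msb_trial <- function(arms, covariates, config = msb_config()) {
  arms <- as.character(arms)
  if (length(arms) != 2L || anyDuplicated(arms) || any(!nzchar(arms)))
    stop_validation("a trial needs exactly 2 distinct, non-empty arm labels")
  if (!all(vapply(covariates, inherits, logical(1), "covariate_spec")))
    stop_validation("covariates must be a list of covariate_spec objects")
  nms <- vapply(covariates, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop_validation("covariate names must be unique")
  if (!inherits(config, "msb_config")) stop_validation("config must be an msb_config")
  names(covariates) <- nms
  structure(
    list(arms = arms,
         specs = covariates,
         config = config,
         units = empty_units(covariates),
         n_randomized = 0L,
         allocations = list(),
         rng_state = fresh_rng_state(config$seed),
         last_allocation = NULL),
    class = "msb_trial"
  )
}

cov_col <- function(name) paste0("covariate.", name)

unit_columns <- c("unit_id", "member_record_ids", "ready", "arm",
                  "allocation_probability", "criteria", "source",
                  "enrollment_index")

empty_units <- function(specs) {
  base <- data.frame(
    unit_id = character(), member_record_ids = character(),
    ready = logical(), arm = character(),
    allocation_probability = numeric(), criteria = character(),
    source = character(), enrollment_index = integer(),
    stringsAsFactors = FALSE
  )
  for (s in specs)
    base[[cov_col(s$name)]] <- if (s$kind == "continuous") numeric() else character()
  base
}

#' Build one unit record
#'
#' A unit is the entity assigned to an arm: a single individual or a
#' partnered dyad randomized together (both members receive the same
#' allocation; supply both record identifiers).  Covariates are given
#' at the unit level as a named list.
#'
#' @param unit_id Unique unit identifier.
#' @param covariates Named list of covariate values: numbers for
#'   continuous covariates, level labels otherwise.  Omitted names are
#'   treated as missing.
#' @param ready Logical randomization indicator; only ready units may be
#'   allocated.
#' @param member_record_ids Record identifiers of the 1-2 members.
#'   Defaults to `unit_id`.
#' @return An object of class `unit_record`.
#' @export
unit_record <- function(unit_id, covariates = list(), ready = TRUE,
                        member_record_ids = unit_id) {
  if (!is.character(unit_id) || length(unit_id) != 1L || !nzchar(unit_id))
    stop_validation("unit_id must be a non-empty string")
  member_record_ids <- as.character(member_record_ids)
  if (length(member_record_ids) < 1L || length(member_record_ids) > 2L)
    stop_validation("a unit has 1 or 2 member record ids")
  structure(list(unit_id = unit_id, covariates = covariates,
                 ready = isTRUE(ready),
                 member_record_ids = member_record_ids),
            class = "unit_record")
}

#' Add unrandomized units to a trial
#'
#' @param trial An [msb_trial].
#' @param units A single [unit_record], a list of them, or a
#'   `data.frame` in the record-store schema (see [read_store()]).
#' @return The updated trial.
#' @export
add_units <- function(trial, units) {
  stopifnot(inherits(trial, "msb_trial"))
  if (inherits(units, "unit_record")) units <- list(units)
  if (is.data.frame(units)) {
    df <- units
  } else {
    df <- do.call(rbind, lapply(units, function(u) {
      row <- empty_units(trial$specs)[0, ]
      row[1, "unit_id"] <- u$unit_id
      row[1, "member_record_ids"] <- paste(u$member_record_ids, collapse = ";")
      row[1, "ready"] <- u$ready
      row[1, "source"] <- "unset"
      for (s in trial$specs) {
        v <- u$covariates[[s$name]]
        if (!is.null(v) && !is.na(v))
          row[1, cov_col(s$name)] <- if (s$kind == "continuous") as.numeric(v) else as.character(v)
      }
      row
    }))
  }
  missing_cols <- setdiff(names(empty_units(trial$specs)), names(df))
  if (length(missing_cols))
    stop_validation(paste("unit data is missing columns:",
                          paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(c(trial$units$unit_id, df$unit_id)))
    stop_validation("duplicate unit_id")
  df$source[is.na(df$source) | df$source == ""] <- "unset"
  trial$units <- rbind(trial$units, df[, names(trial$units)])
  rownames(trial$units) <- NULL
  trial
}

unit_row <- function(trial, unit_id) {
  i <- match(unit_id, trial$units$unit_id)
  if (is.na(i)) stop_state(sprintf("unknown unit '%s'", unit_id))
  i
}

#' Check a unit's covariates against the trial's specifications
#'
#' Returns (never raises) the list of data problems that would block
#' randomization: missing required covariates, categorical values
#' outside the declared levels, non-numeric continuous values.  An
#' empty character vector means the unit conforms.  The check is
#' deterministic and independent of covariate order.
#'
#' @param trial An [msb_trial].
#' @param unit_id Identifier of a unit already added to the trial.
#' @return Character vector of issues (length 0 if none).
#' @export
validate_unit <- function(trial, unit_id) {
  stopifnot(inherits(trial, "msb_trial"))
  i <- unit_row(trial, unit_id)
  issues <- character()
  for (s in trial$specs) {
    v <- trial$units[[cov_col(s$name)]][i]
    if (is.na(v)) {
      if (s$required)
        issues <- c(issues, sprintf("missing required covariate '%s'", s$name))
      next
    }
    if (s$kind == "continuous") {
      if (!is.finite(v))
        issues <- c(issues, sprintf("covariate '%s' is not a finite number", s$name))
    } else if (!(v %in% s$levels)) {
      issues <- c(issues, sprintf(
        "covariate '%s' value '%s' not among levels {%s}",
        s$name, v, paste(s$levels, collapse = ", ")))
    }
  }
  issues
}

active_specs <- function(trial, at_index) {
  Filter(function(s) s$active_from <= at_index, trial$specs)
}

randomized_mask <- function(trial) {
  !is.na(trial$units$arm)
}

# private random stream ---------------------------------------------------
# The trial carries its own RNG state so that the full allocation
# sequence replays bit-for-bit under a fixed seed, independent of any
# other randomness in the session.

fresh_rng_state <- function(seed) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_rng(old))
  set.seed(seed, kind = "Mersenne-Twister")
  get(".Random.seed", globalenv())
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, globalenv())
}

# Draw uniforms from the trial's stream; returns list(trial, u).
trial_runif <- function(trial, n = 1L) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  assign(".Random.seed", trial$rng_state, globalenv())
  u <- stats::runif(n)
  trial$rng_state <- get(".Random.seed", globalenv())
  restore_rng(old)
  list(trial = trial, u = u)
}

# methods -----------------------------------------------------------------

#' @export
print.msb_trial <- function(x, ...) {
  n <- nrow(x$units)
  k <- x$n_randomized
  cat(sprintf("<msb_trial> arms: %s vs %s\n", x$arms[1], x$arms[2]))
  cat(sprintf("  covariates: %s\n",
              paste(vapply(x$specs, `[[`, character(1), "name"), collapse = ", ")))
  cat(sprintf("  units: %d (%d randomized", n, k))
  if (k > 0L) {
    n0 <- sum(x$units$arm == x$arms[1], na.rm = TRUE)
    cat(sprintf(": %d %s / %d %s", n0, x$arms[1], k - n0, x$arms[2]))
  }
  cat(")\n")
  cat(sprintf("  config: p_threshold=%g, biased_probability=%g, burn_in=%d, size_balance=%s\n",
              x$config$p_threshold, x$config$biased_probability,
              x$config$burn_in, x$config$size_balance))
  invisible(x)
}

#' Summarize arm balance of a trial
#'
#' Computes the per-covariate balance table (standardized differences
#' and, for non-continuous covariates, risk differences) over the
#' currently randomized units; see [summarize_balance()] for the table's
#' definition.
#'
#' @param object An [msb_trial].
#' @param ... Unused.
#' @return An object of class `summary.msb_trial`.
#' @export
summary.msb_trial <- function(object, ...) {
  tab <- summarize_balance(object)
  n0 <- sum(object$units$arm == object$arms[1], na.rm = TRUE)
  n1 <- sum(object$units$arm == object$arms[2], na.rm = TRUE)
  structure(list(arms = object$arms, n_by_arm = c(n0, n1), balance = tab),
            class = "summary.msb_trial")
}

#' @export
print.summary.msb_trial <- function(x, ...) {
  cat(sprintf("Arm sizes: %s = %d, %s = %d\n\n",
              x$arms[1], x$n_by_arm[1], x$arms[2], x$n_by_arm[2]))
  cat("Covariate balance (standardized differences):\n")
  print(x$balance, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Plot covariate balance
#'
#' Dot chart of per-covariate absolute standardized differences with a
#' reference line at the conventional d = 0.1 validity threshold.
#'
#' @param x An [msb_trial] with at least 2 randomized units per arm.
#' @param threshold Reference line position (default 0.1).
#' @param ... Passed to [graphics::dotchart()].
#' @return `x`, invisibly.
#' @export
plot.msb_trial <- function(x, threshold = 0.1, ...) {
  tab <- summarize_balance(x)
  graphics::dotchart(abs(tab$std_diff), labels = tab$covariate,
                     xlab = "|standardized difference|",
                     xlim = c(0, max(threshold, abs(tab$std_diff)) * 1.1), ...)
  graphics::abline(v = threshold, lty = 2)
  invisible(x)
}
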