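#' Declare a balancing covariate
#'
#' A covariate specification names one variable the randomization
#' algorithm balances, its measurement type, and from which enrollment
#' index onward it participates in balance testing.  Covariates can be
#' activated mid-trial (e.g. a baseline test added after enrollment has
#' started) by setting `active_from` to the enrollment index of the
#' first allocation that should consult it.
#'
#' @param name Covariate name (non-empty string, unique within a trial).
#' @param kind One of `"continuous"`, `"binary"`, `"categorical"`.
#' @param levels Ordered character vector of level labels.  Required for
#'   binary (exactly 2) and categorical (at least 2) covariates; must be
#'   absent for continuous ones.
#' @param active_from Non-negative integer enrollment index from which
#'   the covariate is consulted; `0` means active from the first
#'   allocation.
#' @param required If `TRUE`, a missing value blocks randomization of
#'   the unit; if `FALSE` the unit is allocated but contributes nothing
#'   to this covariate's test or vote.
#' @return An object of class `covariate_spec`.
#' @examples
#' covariate_spec("age", "continuous")
#' covariate_spec("prep_use", "binary", levels = c("no", "yes"))
#' @export
covariate_spec <- function(name, kind = c("continuous", "binary", "categorical"),
                           levels = NULL, active_from = 0L, required = TRUE) {
  kind <- match.arg(kind)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_validation("covariate name must be a non-empty string")
  if (kind == "continuous") {
    if (!is.null(levels))
      stop_validation(sprintf("continuous covariate '%s' must not declare levels", name))
  } else {
    levels <- as.character(levels)
    if (kind == "binary" && length(levels) != 2L)
      stop_validation(sprintf("binary covariate '%s' must have exactly 2 levels, got %d",
                              name, length(levels)))
    if (kind == "categorical" && length(levels) < 2L)
      stop_validation(sprintf("categorical covariate '%s' must have >= 2 levels", name))
    if (anyDuplicated(levels))
      stop_validation(sprintf("covariate '%s' has duplicated levels", name))
  }
  active_from <- as.integer(active_from)
  if (is.na(active_from) || active_from < 0L)
    stop_validation(sprintf("covariate '%s': active_from must be a non-negative integer", name))
  structure(
    list(name = name, kind = kind, levels = levels,
         active_from = active_from, required = isTRUE(required)),
    class = "covariate_spec"
  )
}

#' @export
print.covariate_spec <- function(x, ...) {
  lev <- if (is.null(x$levels)) "" else paste0(" {", paste(x$levels, collapse = ", "), "}")
  cat(sprintf("<covariate_spec> %s: %s%s, active_from=%d, %s\n",
              x$name, x$kind, lev, x$active_from,
              if (x$required) "required" else "optional"))
  invisible(x)
}

#' Algorithm parameters for minimal sufficient balance
#'
#' Tuning parameters of the MSB allocation engine.  A covariate casts a
#' vote only when its imbalance test's p-value falls below
#' `p_threshold`; when a strict majority of votes favors one arm, that
#' arm receives the allocation with probability `biased_probability`
#' (otherwise 1:1).  The first `burn_in` units are always allocated by
#' simple 1:1 randomization so the imbalance tests operate on a
#' non-trivial sample.
#'
#' @param p_threshold Per-covariate test significance cutoff, in (0, 1).
#' @param biased_probability Probability given to the favored arm when
#'   balance criteria trigger, in (0.5, 1).
#' @param burn_in Number of initial simple 1:1 allocations (>= 0).
#' @param size_balance If `TRUE`, arm-size imbalance (exact binomial
#'   test at rate 1/2) casts a vote on equal footing with covariates.
#' @param seed Integer seed for the trial's private random stream.
#' @return An object of class `msb_config`.
#' @export
msb_config <- function(p_threshold = 0.3, biased_probability = 0.7,
                       burn_in = 20L, size_balance = TRUE, seed = 1L) {
  if (!is.numeric(p_threshold) || p_threshold <= 0 || p_threshold >= 1)
    stop_validation("p_threshold must lie in (0, 1)")
  if (!is.numeric(biased_probability) || biased_probability <= 0.5 || biased_probability >= 1)
    stop_validation("biased_probability must lie in (0.5, 1)")
  burn_in <- as.integer(burn_in)
  if (is.na(burn_in) || burn_in < 0L)
    stop_validation("burn_in must be a non-negative integer")
  structure(
    list(p_threshold = as.numeric(p_threshold),
         biased_probability = as.numeric(biased_probability),
         burn_in = burn_in,
         size_balance = isTRUE(size_balance),
         seed = as.integer(seed)),
    class = "msb_config"
  )
}

#' @export
print.msb_config <- function(x, ...) {
  cat(sprintf(
    "<msb_config> p_threshold=%g, biased_probability=%g, burn_in=%d, size_balance=%s, seed=%d\n",
    x$p_threshold, x$biased_probability, x$burn_in, x$size_balance, x$seed))
  invisible(x)
}

#' Load a run configuration from JSON
#'
#' Reads a JSON run configuration naming the two arms, the balancing
#' covariates, and (optionally) the MSB parameters, and returns an
#' empty trial state ready to receive units.  The schema is:
#'
#' ```json
#' {
#'   "arms": ["intervention", "control"],
#'   "covariates": [
#'     {"name": "age", "kind": "continuous"},
#'     {"name": "prep_use", "kind": "binary", "levels": ["no", "yes"],
#'      "active_from": 0, "required": true}
#'   ],
#'   "msb": {"p_threshold": 0.3, "biased_probability": 0.7,
#'           "burn_in": 20, "size_balance": true, "seed": 1}
#' }
#' ```
#'
#' Omitted `msb` fields take the documented defaults
#' (`p_threshold = 0.3`, `biased_probability = 0.7`, `burn_in = 20`,
#' `size_balance = TRUE`).
#'
#' @param path Path to the JSON configuration file.
#' @return An [msb_trial] with no units.
#' @seealso [write_run_config()] for the inverse.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop_parse(sprintf("config file not found: %s", path))
  cfg <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop_parse(sprintf("malformed JSON in %s: %s",
                                                         path, conditionMessage(e))))
  arms <- unlist(cfg$arms, use.names = FALSE)
  if (length(arms) != 2L)
    stop_parse("config key 'arms' must list exactly 2 arm labels")
  if (is.null(cfg$covariates) || length(cfg$covariates) == 0L)
    stop_parse("config key 'covariates' must list at least one covariate")
  specs <- lapply(cfg$covariates, function(cv) {
    if (is.null(cv$name)) stop_parse("covariate entry missing key 'name'")
    if (is.null(cv$kind)) stop_parse(sprintf("covariate '%s' missing key 'kind'", cv$name))
    covariate_spec(
      name = cv$name, kind = cv$kind,
      levels = if (!is.null(cv$levels)) unlist(cv$levels, use.names = FALSE),
      active_from = if (is.null(cv$active_from)) 0L else cv$active_from,
      required = if (is.null(cv$required)) TRUE else isTRUE(cv$required)
    )
  })
  m <- cfg$msb
  config <- msb_config(
    p_threshold = if (is.null(m$p_threshold)) 0.3 else m$p_threshold,
    biased_probability = if (is.null(m$biased_probability)) 0.7 else m$biased_probability,
    burn_in = if (is.null(m$burn_in)) 20L else m$burn_in,
    size_balance = if (is.null(m$size_balance)) TRUE else isTRUE(m$size_balance),
    seed = if (is.null(m$seed)) 1L else m$seed
  )
  msb_trial(arms = as.character(arms), covariates = specs, config = config)
}

#' Write a run configuration to JSON
#'
#' Serializes a trial's arms, covariate specifications, and MSB
#' parameters to the JSON schema read by [load_run_config()].  Units are
#' not written; use [write_store()] for the record store.
#'
#' @param trial An [msb_trial].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(trial, path) {
  stopifnot(inherits(trial, "msb_trial"))
  covs <- lapply(trial$specs, function(s) {
    out <- list(name = s$name, kind = s$kind)
    if (!is.null(s$levels)) out$levels <- s$levels
    out$active_from <- s$active_from
    out$required <- s$required
    out
  })
  doc <- list(arms = trial$arms, covariates = covs,
              msb = unclass(trial$config))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

# condition helpers -------------------------------------------------------

stop_validation <- function(msg) {
  stop(errorCondition(msg, class = c("msb_validation_error", "msb_error")))
}
stop_parse <- function(msg) {
  stop(errorCondition(msg, class = c("msb_parse_error", "msb_error")))
}
stop_state <- function(msg) {
  stop(errorCondition(msg, class = c("msb_state_error", "msb_error")))
}
stop_conflict <- function(msg) {
  stop(errorCondition(msg, class = c("msb_conflict_error", "msb_error")))
}
stop_io <- function(msg) {
  stop(errorCondition(msg, class = c("msb_io_error", "msb_error")))
}
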