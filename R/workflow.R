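#' Parse a data-entry-trigger payload
#'
#' Electronic data capture systems notify a configured endpoint with an
#' HTTP POST whose body is a URL-encoded key-value query string naming
#' the project, the record, and the instrument (form) that was saved.
#' This parses that dialect: keys `project_id`, `record` and
#' `instrument` are required; any other keys are preserved in `$extra`.
#'
#' @param raw URL-encoded key-value string, e.g.
#'   `"project_id=12&record=A7&instrument=randomization"`.
#' @return An object of class `trigger_payload` with fields
#'   `project_id`, `record_id`, `instrument`, `raw`, `extra`.
#' @export
parse_trigger <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L)
    stop_parse("trigger payload must be a single string")
  pairs <- strsplit(raw, "&", fixed = TRUE)[[1]]
  pairs <- pairs[nzchar(pairs)]
  kv <- list()
  for (p in pairs) {
    eq <- regexpr("=", p, fixed = TRUE)
    key <- if (eq > 0) substr(p, 1L, eq - 1L) else p
    val <- if (eq > 0) substr(p, eq + 1L, nchar(p)) else ""
    kv[[utils::URLdecode(key)]] <- utils::URLdecode(chartr("+", " ", val))
  }
  for (need in c("project_id", "record", "instrument"))
    if (is.null(kv[[need]]) || !nzchar(kv[[need]]))
      stop_parse(sprintf("trigger payload missing required key '%s'", need))
  structure(
    list(project_id = kv$project_id, record_id = kv$record,
         instrument = kv$instrument, raw = raw,
         extra = kv[setdiff(names(kv), c("project_id", "record", "instrument"))]),
    class = "trigger_payload"
  )
}

#' @export
print.trigger_payload <- function(x, ...) {
  cat(sprintf("<trigger_payload> project %s, record %s, instrument '%s'\n",
              x$project_id, x$record_id, x$instrument))
  invisible(x)
}

#' Does a trigger require a randomization?
#'
#' Checks, in order: the payload's project matches the expected one;
#' the saved instrument is the configured randomization form
#' (case-insensitive); the record belongs to a known unit; the unit's
#' randomization indicator is set; and the unit has no allocation yet.
#' The record id may be the unit id or either member's record id.
#'
#' @param snapshot A `store_snapshot` from [read_store()].
#' @param payload A `trigger_payload`.
#' @param expected_project Project identifier this workflow serves.
#' @param form_name Name of the randomization instrument (default
#'   `"randomization"`).
#' @return List with `ok` (logical), `reason` (an audit outcome code
#'   when `ok` is `FALSE`), `unit_id` (when the unit was found), and
#'   `detail`.
#' @export
should_randomize <- function(snapshot, payload, expected_project,
                             form_name = "randomization") {
  stopifnot(inherits(snapshot, "store_snapshot"),
            inherits(payload, "trigger_payload"))
  if (!identical(as.character(payload$project_id), as.character(expected_project)))
    return(list(ok = FALSE, reason = "ignored_wrong_project", unit_id = NA_character_,
                detail = sprintf("trigger from project %s, expected %s",
                                 payload$project_id, expected_project)))
  if (tolower(payload$instrument) != tolower(form_name))
    return(list(ok = FALSE, reason = "ignored_wrong_instrument", unit_id = NA_character_,
                detail = sprintf("instrument '%s' is not the randomization form",
                                 payload$instrument)))
  units <- snapshot$units
  i <- match(payload$record_id, units$unit_id)
  if (is.na(i)) {
    members <- strsplit(units$member_record_ids, ";", fixed = TRUE)
    hit <- which(vapply(members, function(m) payload$record_id %in% m, logical(1)))
    if (length(hit)) i <- hit[1]
  }
  if (is.na(i))
    return(list(ok = FALSE, reason = "failed_error", unit_id = NA_character_,
                detail = sprintf("record '%s' not found in store", payload$record_id)))
  uid <- units$unit_id[i]
  if (!is.na(units$arm[i]))
    return(list(ok = FALSE, reason = "ignored_already_randomized", unit_id = uid,
                detail = sprintf("unit '%s' already allocated to '%s'", uid, units$arm[i])))
  if (!isTRUE(units$ready[i]))
    return(list(ok = FALSE, reason = "ignored_not_ready", unit_id = uid,
                detail = sprintf("unit '%s' randomization indicator not set", uid)))
  list(ok = TRUE, reason = NA_character_, unit_id = uid, detail = "")
}

audit_entry <- function(outcome, record_id = NA_character_,
                        unit_id = NA_character_, detail = "",
                        allocation = NULL) {
  structure(
    list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         record_id = record_id, unit_id = unit_id,
         outcome = outcome, detail = detail,
         allocation = allocation),
    class = "audit_entry"
  )
}

#' Append an entry to a JSON-lines audit log
#'
#' @param entry An `audit_entry`.
#' @param log_path Path of the log file (created if absent); one JSON
#'   object per line with keys timestamp, record_id, unit_id, outcome,
#'   detail, and (for successful allocations) allocation.
#' @return `entry`, invisibly.
#' @export
append_audit <- function(entry, log_path) {
  stopifnot(inherits(entry, "audit_entry"))
  line <- jsonlite::toJSON(unclass(entry), auto_unbox = TRUE, null = "null",
                           na = "null", digits = NA)
  cat(line, "\n", sep = "", file = log_path, append = TRUE)
  invisible(entry)
}

#' Read a JSON-lines audit log
#'
#' @param log_path Path written by [append_audit()].
#' @return List of entries (each a list); empty list if the file does
#'   not exist.
#' @export
read_audit_log <- function(log_path) {
  if (!file.exists(log_path)) return(list())
  lines <- readLines(log_path, warn = FALSE)
  lapply(lines[nzchar(lines)], jsonlite::fromJSON, simplifyVector = FALSE)
}

#' Handle one data-entry trigger end to end
#'
#' The automation loop run whenever the randomization form is saved:
#' parse the payload, read the store, decide whether a randomization is
#' required ([should_randomize()]), validate the unit's covariates,
#' allocate with the MSB engine ([randomize_unit()]), persist the
#' allocation back to the store ([write_allocation()], with optimistic
#' concurrency against the snapshot read), and append exactly one
#' audit-log entry describing the outcome.  Any failure (including a
#' store-write failure) yields a `failed_error` entry and leaves the
#' unit unallocated in the store; re-delivering a trigger after a
#' successful allocation is idempotent (`ignored_already_randomized`,
#' no state change).
#'
#' The trial state is rebuilt from the store on every trigger; the
#' allocation draw is seeded deterministically from the configured seed
#' plus the number of already-randomized units, so a given store state
#' always replays to the same allocation.
#'
#' @param store_path Path to the unit record store.
#' @param trigger A raw payload string or a parsed `trigger_payload`.
#' @param template An [msb_trial] carrying the arms, covariate
#'   specifications and configuration (units are taken from the store).
#' @param expected_project Project identifier this workflow serves.
#' @param log_path Audit log path.
#' @param form_name Randomization instrument name.
#' @param .write Store writer, `write_allocation` by default
#'   (injectable for fault testing).
#' @return The `audit_entry` describing what happened.
#' @export
handle_trigger <- function(store_path, trigger, template, expected_project,
                           log_path, form_name = "randomization",
                           .write = write_allocation) {
  stopifnot(inherits(template, "msb_trial"))
  payload <- tryCatch(
    if (inherits(trigger, "trigger_payload")) trigger else parse_trigger(trigger),
    error = function(e) e)
  if (inherits(payload, "error"))
    return(append_audit(audit_entry("failed_error",
                                    detail = conditionMessage(payload)), log_path))
  record_id <- payload$record_id

  out <- tryCatch({
    snap <- read_store(store_path, specs = template$specs)
    dec <- should_randomize(snap, payload, expected_project, form_name)
    if (!dec$ok)
      return(append_audit(audit_entry(dec$reason, record_id = record_id,
                                      unit_id = dec$unit_id, detail = dec$detail),
                          log_path))
    trial <- template
    trial$units <- empty_units(template$specs)
    trial <- add_units(trial, snap$units)
    trial$n_randomized <- sum(!is.na(trial$units$arm))
    trial$rng_state <- fresh_rng_state(trial$config$seed + trial$n_randomized)

    issues <- validate_unit(trial, dec$unit_id)
    if (length(issues))
      return(append_audit(audit_entry("rejected_validation", record_id = record_id,
                                      unit_id = dec$unit_id,
                                      detail = paste(issues, collapse = "; ")),
                          log_path))
    trial <- randomize_unit(trial, dec$unit_id)
    res <- trial$last_allocation
    .write(store_path, dec$unit_id, res, expected_version = snap$version)
    append_audit(audit_entry("randomized", record_id = record_id,
                             unit_id = dec$unit_id,
                             detail = sprintf("allocated to '%s'", res$arm),
                             allocation = allocation_to_list(res)),
                 log_path)
  }, error = function(e) {
    append_audit(audit_entry("failed_error", record_id = record_id,
                             detail = conditionMessage(e)), log_path)
  })
  out
}

#' Pre-generate a static back-up randomization list
#'
#' A contingency for outages of the automated pipeline: `n` independent
#' 1:1 draws, deterministic under the seed, that unblinded personnel
#' can consult when the trigger workflow is unavailable.  Consumed
#' allocations are later reconciled into the algorithm's state with
#' [apply_backup_allocation()].
#'
#' @param n List length (>= 1).
#' @param seed Integer seed.
#' @param arms Pair of arm labels.
#' @return An object of class `backup_list` with `$entries`,
#'   `$next_index` (number of consumed entries, starts at 0), `$seed`,
#'   `$arms`.
#' @export
generate_backup_list <- function(n, seed, arms = c("intervention", "control")) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop_validation("backup list length must be >= 1")
  if (length(arms) != 2L) stop_validation("backup list needs exactly 2 arms")
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_rng(old))
  set.seed(seed, kind = "Mersenne-Twister")
  entries <- ifelse(stats::runif(n) < 0.5, arms[1], arms[2])
  structure(list(entries = entries, next_index = 0L,
                 seed = as.integer(seed), arms = as.character(arms)),
            class = "backup_list")
}

#' Write / read a back-up list as CSV
#'
#' Columns `index` (1-based) and `arm`.  The consumption pointer is not
#' part of the file; on read it is set to `next_index` (default 0).
#'
#' @param backup A `backup_list`.
#' @param path CSV path.
#' @return `path`, invisibly (write); a `backup_list` (read).
#' @export
write_backup_list <- function(backup, path) {
  stopifnot(inherits(backup, "backup_list"))
  utils::write.csv(
    data.frame(index = seq_along(backup$entries), arm = backup$entries),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_backup_list
#' @param next_index Number of already-consumed entries.
#' @param seed Seed to record on the reconstructed object.
#' @export
read_backup_list <- function(path, next_index = 0L, seed = NA_integer_) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("index", "arm") %in% names(df)))
    stop_io("backup list CSV needs columns 'index' and 'arm'")
  structure(list(entries = df$arm, next_index = as.integer(next_index),
                 seed = seed, arms = unique(df$arm)),
            class = "backup_list")
}

#' Allocate a unit from the back-up list
#'
#' Assigns the next unconsumed back-up entry to a ready, unrandomized
#' unit (`source = "backup_list"`, allocation probability 0.5, no
#' triggering criteria) and advances the consumption pointer.  The unit
#' is thereafter counted among randomized units by every balance
#' computation, so subsequent algorithmic allocations are informed by
#' it exactly as if the engine had produced the same arm.
#'
#' @param trial An [msb_trial].
#' @param unit_id Unit to allocate.
#' @param backup A `backup_list` with unconsumed entries.
#' @return List with the updated `$trial` (its `last_allocation` set)
#'   and `$backup` (pointer advanced).
#' @export
apply_backup_allocation <- function(trial, unit_id, backup) {
  stopifnot(inherits(trial, "msb_trial"), inherits(backup, "backup_list"))
  if (backup$next_index >= length(backup$entries))
    stop_state("back-up list exhausted")
  i <- unit_row(trial, unit_id)
  if (!is.na(trial$units$arm[i]))
    stop_state(sprintf("unit '%s' is already randomized", unit_id))
  if (!isTRUE(trial$units$ready[i]))
    stop_state(sprintf("unit '%s' is not ready to be randomized", unit_id))
  arm <- backup$entries[backup$next_index + 1L]
  if (!(arm %in% trial$arms))
    stop_state(sprintf("back-up entry '%s' is not an arm of this trial", arm))
  k <- trial$n_randomized
  trial$units$arm[i] <- arm
  trial$units$allocation_probability[i] <- 0.5
  trial$units$criteria[i] <- ""
  trial$units$source[i] <- "backup_list"
  trial$units$enrollment_index[i] <- k
  trial$n_randomized <- k + 1L
  res <- structure(
    list(unit_id = unit_id, arm = arm, probability_used = 0.5,
         favored_arm = NA_character_, votes_arm0 = 0L, votes_arm1 = 0L,
         criteria = character(0), rng_draw = NA_real_,
         enrollment_index = k, source = "backup_list", reports = NULL),
    class = "allocation_result")
  trial$allocations[[length(trial$allocations) + 1L]] <- res
  trial$last_allocation <- res
  backup$next_index <- backup$next_index + 1L
  list(trial = trial, backup = backup)
}

#' Scan a store and audit log for inconsistencies
#'
#' Startup consistency check: every allocated unit in the store should
#' have a corresponding `randomized` or `backup_used` audit entry (the
#' store write precedes the log append, so a crash between the two
#' surfaces here).
#'
#' @param store_path Path to the record store.
#' @param log_path Path to the audit log.
#' @return Character vector of warnings (length 0 if consistent).
#' @export
check_consistency <- function(store_path, log_path) {
  snap <- read_store(store_path)
  log <- read_audit_log(log_path)
  logged <- vapply(log, function(e) {
    if (!is.null(e$outcome) && e$outcome %in% c("randomized", "backup_used") &&
        !is.null(e$unit_id)) as.character(e$unit_id) else NA_character_
  }, character(1))
  allocated <- snap$units$unit_id[!is.na(snap$units$arm)]
  missing <- setdiff(allocated, logged[!is.na(logged)])
  if (length(missing))
    sprintf("unit '%s' has an allocation in the store but no audit entry", missing)
  else character(0)
}
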