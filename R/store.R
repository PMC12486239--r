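#' Read a unit record store
#'
#' The record store holds one row per randomization unit with the base
#' columns `unit_id`, `member_record_ids` (semicolon-joined),
#' `ready`, `arm`, `allocation_probability`, `criteria`
#' (semicolon-joined), `source`, `enrollment_index`, plus one
#' `covariate.<name>` column per covariate.  Two equivalent on-disk
#' forms are supported, chosen by extension: CSV (UTF-8, comma
#' separated, header row, RFC 4180 quoting; empty cells are missing)
#' and JSON (a document with keys `version` and `units`).
#'
#' Stores carry a version counter that increments by 1 on every
#' successful write, used for optimistic concurrency control in
#' [write_allocation()].  The JSON form stores it in the document; the
#' CSV form keeps it in a sidecar file `<path>.version` (absent sidecar
#' means version 0).
#'
#' @param path Store path (`.csv` or `.json`).
#' @param specs Optional list of [covariate_spec]s used to coerce
#'   covariate column types.
#' @return An object of class `store_snapshot`: `$units` (data.frame),
#'   `$version`, `$path`.
#' @export
read_store <- function(path, specs = NULL) {
  if (!file.exists(path)) stop_io(sprintf("store file not found: %s", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    doc <- jsonlite::read_json(path, simplifyVector = FALSE)
    units <- json_units_to_df(doc$units, specs)
    version <- if (is.null(doc$version)) 0L else as.integer(doc$version)
  } else {
    units <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                             colClasses = "character")
    missing_cols <- setdiff(unit_columns, names(units))
    if (length(missing_cols))
      stop_io(paste("store is missing columns:", paste(missing_cols, collapse = ", ")))
    units$ready <- as.logical(units$ready)
    units$allocation_probability <- as.numeric(units$allocation_probability)
    units$enrollment_index <- as.integer(units$enrollment_index)
    for (col in grep("^covariate\\.", names(units), value = TRUE)) {
      nm <- sub("^covariate\\.", "", col)
      spec <- if (!is.null(specs)) Filter(function(s) s$name == nm, specs) else list()
      if (length(spec) && spec[[1]]$kind == "continuous")
        units[[col]] <- as.numeric(units[[col]])
      else if (!length(spec) && !anyNA(suppressWarnings(as.numeric(units[[col]][!is.na(units[[col]])]))))
        units[[col]] <- as.numeric(units[[col]])
    }
    version <- store_version_csv(path)
  }
  if (anyDuplicated(units$unit_id))
    stop_io("store has duplicated unit_id values")
  units$source[is.na(units$source)] <- "unset"
  # empty criteria cells on allocated rows mean "no criteria triggered"
  units$criteria[is.na(units$criteria) & !is.na(units$arm)] <- ""
  rownames(units) <- NULL
  structure(list(units = units, version = version, path = path),
            class = "store_snapshot")
}

store_version_csv <- function(path) {
  vp <- paste0(path, ".version")
  if (!file.exists(vp)) return(0L)
  as.integer(readLines(vp, warn = FALSE)[1])
}

json_units_to_df <- function(units, specs = NULL) {
  base <- data.frame(
    unit_id = character(), member_record_ids = character(),
    ready = logical(), arm = character(),
    allocation_probability = numeric(), criteria = character(),
    source = character(), enrollment_index = integer(),
    stringsAsFactors = FALSE)
  if (length(units) == 0L) {
    if (!is.null(specs)) for (s in specs)
      base[[cov_col(s$name)]] <- if (s$kind == "continuous") numeric() else character()
    return(base)
  }
  rows <- lapply(units, function(u) {
    row <- list(
      unit_id = u$unit_id,
      member_record_ids = paste(unlist(u$member_record_ids), collapse = ";"),
      ready = isTRUE(u$ready),
      arm = if (is.null(u$arm)) NA_character_ else u$arm,
      allocation_probability = if (is.null(u$allocation_probability))
        NA_real_ else as.numeric(u$allocation_probability),
      criteria = if (is.null(u$criteria)) NA_character_
                 else paste(unlist(u$criteria), collapse = ";"),
      source = if (is.null(u$source)) "unset" else u$source,
      enrollment_index = if (is.null(u$enrollment_index))
        NA_integer_ else as.integer(u$enrollment_index))
    for (nm in names(u$covariates)) {
      v <- u$covariates[[nm]]
      row[[cov_col(nm)]] <- if (is.null(v)) NA else v
    }
    row
  })
  cols <- unique(unlist(lapply(rows, names)))
  out <- do.call(rbind, lapply(rows, function(r) {
    r[setdiff(cols, names(r))] <- NA
    as.data.frame(r[cols], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

df_units_to_json <- function(units) {
  cov_cols <- grep("^covariate\\.", names(units), value = TRUE)
  lapply(seq_len(nrow(units)), function(i) {
    u <- list(
      unit_id = units$unit_id[i],
      member_record_ids = as.list(strsplit(units$member_record_ids[i], ";", fixed = TRUE)[[1]]),
      ready = units$ready[i])
    if (!is.na(units$arm[i])) u$arm <- units$arm[i]
    if (!is.na(units$allocation_probability[i]))
      u$allocation_probability <- units$allocation_probability[i]
    if (!is.na(units$criteria[i]))
      u$criteria <- as.list(strsplit(units$criteria[i], ";", fixed = TRUE)[[1]])
    u$source <- units$source[i]
    if (!is.na(units$enrollment_index[i]))
      u$enrollment_index <- units$enrollment_index[i]
    covs <- list()
    for (col in cov_cols) {
      v <- units[[col]][i]
      if (!is.na(v)) covs[[sub("^covariate\\.", "", col)]] <- v
    }
    u$covariates <- covs
    u
  })
}

#' Write a unit record store
#'
#' Serializes units to the CSV or JSON store form (by extension) and
#' bumps the version counter.  The write is atomic: the new content is
#' written to a temporary file in the same directory and renamed over
#' the target, so a failure leaves the previous file untouched.
#'
#' @param units A unit `data.frame` or a `store_snapshot`.
#' @param path Output path (`.csv` or `.json`).
#' @param version Version to record; defaults to the stored version + 1
#'   (or 1 for a new file).
#' @return The new version, invisibly.
#' @export
write_store <- function(units, path, version = NULL) {
  if (inherits(units, "store_snapshot")) units <- units$units
  json <- grepl("\\.json$", path, ignore.case = TRUE)
  if (is.null(version)) {
    version <- if (!file.exists(path)) 1L
    else if (json) {
      doc <- jsonlite::read_json(path, simplifyVector = FALSE)
      (if (is.null(doc$version)) 0L else as.integer(doc$version)) + 1L
    } else store_version_csv(path) + 1L
  }
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  if (json) {
    jsonlite::write_json(list(version = version, units = df_units_to_json(units)),
                         tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    file.rename(tmp, path)
  } else {
    utils::write.csv(units, tmp, row.names = FALSE, na = "")
    file.rename(tmp, path)
    writeLines(as.character(version), paste0(path, ".version"))
  }
  invisible(version)
}

#' Persist one allocation to the store
#'
#' Compare-and-write: re-reads the store, verifies the version still
#' matches `expected_version` (optimistic concurrency — a conflicting
#' writer raises an `msb_conflict_error` and nothing is written),
#' verifies the unit exists and is still unallocated, then atomically
#' rewrites the store with the unit's allocation fields filled from the
#' result.  All other rows are unchanged.
#'
#' @param path Store path.
#' @param unit_id Unit to update.
#' @param result An `allocation_result` (from [randomize_unit()] or
#'   [apply_backup_allocation()]).
#' @param expected_version Version observed when the caller read the
#'   store; `NULL` skips the check.
#' @return The new store version, invisibly.
#' @export
write_allocation <- function(path, unit_id, result, expected_version = NULL) {
  stopifnot(inherits(result, "allocation_result"))
  snap <- read_store(path)
  if (!is.null(expected_version) && snap$version != expected_version)
    stop_conflict(sprintf(
      "store version changed (expected %d, found %d); re-read before writing",
      expected_version, snap$version))
  i <- match(unit_id, snap$units$unit_id)
  if (is.na(i)) stop_state(sprintf("unknown unit '%s'", unit_id))
  if (!is.na(snap$units$arm[i]))
    stop_state(sprintf("unit '%s' already has an allocation", unit_id))
  snap$units$arm[i] <- result$arm
  snap$units$allocation_probability[i] <-
    if (result$arm == result$favored_arm && !is.na(result$favored_arm))
      result$probability_used
    else if (!is.na(result$favored_arm)) 1 - result$probability_used
    else 0.5
  snap$units$criteria[i] <- paste(result$criteria, collapse = ";")
  snap$units$source[i] <- result$source
  snap$units$enrollment_index[i] <- result$enrollment_index
  write_store(snap$units, path, version = snap$version + 1L)
}
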