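# end-to-end fixtures: a small store on disk plus a matching template

workflow_fixture <- function(dir, n_ready = 3, seed = 11) {
  specs <- list(covariate_spec("age", "continuous"),
                binary_spec("prep", levels = c("no", "yes")))
  template <- msb_trial(ARMS, specs, msb_config(seed = seed, burn_in = 0L))
  set.seed(seed)
  units <- do.call(rbind, lapply(seq_len(n_ready), function(i) {
    trial <- add_units(template,
                       unit_record(sprintf("u%02d", i),
                                   list(age = runif(1, 16, 34),
                                        prep = sample(c("no", "yes"), 1)),
                                   member_record_ids =
                                     if (i == 1) c("u01", "u01b") else sprintf("u%02d", i)))
    trial$units
  }))
  store <- file.path(dir, "store.csv")
  write_store(units, store)
  list(template = template, store = store,
       log = file.path(dir, "audit.jsonl"))
}

test_that("trigger payloads parse the URL-encoded dialect", {
  p <- parse_trigger("project_id=12&record=A7&instrument=randomization")
  expect_identical(p$project_id, "12")
  expect_identical(p$record_id, "A7")
  expect_identical(p$instrument, "randomization")
  # percent- and plus-encoded values decode
  p <- parse_trigger("project_id=12&record=A%207&instrument=My+Form&extra=1")
  expect_identical(p$record_id, "A 7")
  expect_identical(p$instrument, "My Form")
  expect_identical(p$extra$extra, "1")
  expect_error(parse_trigger("record=A7&instrument=f"), "project_id",
               class = "msb_parse_error")
  expect_error(parse_trigger("project_id=1&record=A7"), "instrument",
               class = "msb_parse_error")
})

test_that("should_randomize applies the readiness checks in order", {
  dir <- withr::local_tempdir()
  fx <- workflow_fixture(dir)
  snap <- read_store(fx$store, fx$template$specs)
  pay <- function(record, project = "9", form = "randomization")
    parse_trigger(sprintf("project_id=%s&record=%s&instrument=%s",
                          project, record, form))

  expect_identical(should_randomize(snap, pay("u02", project = "8"), "9")$reason,
                   "ignored_wrong_project")
  expect_identical(should_randomize(snap, pay("u02", form = "intake"), "9")$reason,
                   "ignored_wrong_instrument")
  expect_identical(should_randomize(snap, pay("ghost"), "9")$reason,
                   "failed_error")
  ok <- should_randomize(snap, pay("u02"), "9")
  expect_true(ok$ok)
  expect_identical(ok$unit_id, "u02")
  # a dyad member's record id resolves to its unit
  expect_identical(should_randomize(snap, pay("u01b"), "9")$unit_id, "u01")
  # form name matching is case-insensitive
  expect_true(should_randomize(snap, pay("u02", form = "Randomization"), "9")$ok)

  snap$units$ready[2] <- FALSE
  expect_identical(should_randomize(snap, pay("u02"), "9")$reason,
                   "ignored_not_ready")
  snap$units$arm[2] <- "A"
  expect_identical(should_randomize(snap, pay("u02"), "9")$reason,
                   "ignored_already_randomized")
})

test_that("a valid trigger randomizes, writes back, and logs exactly once", {
  dir <- withr::local_tempdir()
  fx <- workflow_fixture(dir)
  trig <- "project_id=9&record=u02&instrument=randomization"
  entry <- handle_trigger(fx$store, trig, fx$template, "9", fx$log)
  expect_identical(entry$outcome, "randomized")
  expect_false(is.null(entry$allocation))
  snap <- read_store(fx$store, fx$template$specs)
  i <- match("u02", snap$units$unit_id)
  expect_true(snap$units$arm[i] %in% ARMS)
  expect_identical(snap$units$source[i], "algorithm")
  expect_equal(snap$units$allocation_probability[i], 0.5)  # burn-in-free but balanced
  log <- read_audit_log(fx$log)
  expect_length(log, 1L)

  # replaying the same trigger is idempotent
  before <- readLines(fx$store)
  entry2 <- handle_trigger(fx$store, trig, fx$template, "9", fx$log)
  expect_identical(entry2$outcome, "ignored_already_randomized")
  expect_null(entry2$allocation)
  expect_identical(readLines(fx$store), before)
  expect_length(read_audit_log(fx$log), 2L)  # one log entry per trigger

  # consistency scan is clean
  expect_length(check_consistency(fx$store, fx$log), 0L)
})

test_that("a deterministic replay produces the same allocation for a given store state", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  fx1 <- workflow_fixture(dir1); fx2 <- workflow_fixture(dir2)
  trig <- "project_id=9&record=u03&instrument=randomization"
  e1 <- handle_trigger(fx1$store, trig, fx1$template, "9", fx1$log)
  e2 <- handle_trigger(fx2$store, trig, fx2$template, "9", fx2$log)
  expect_identical(e1$allocation, e2$allocation)
})

test_that("ignored and malformed triggers each leave one log entry and no state change", {
  dir <- withr::local_tempdir()
  fx <- workflow_fixture(dir)
  before <- readLines(fx$store)
  triggers <- c("project_id=8&record=u02&instrument=randomization",
                "project_id=9&record=u02&instrument=intake",
                "project_id=9&record=ghost&instrument=randomization",
                "record=u02")
  outcomes <- vapply(triggers, function(tr)
    handle_trigger(fx$store, tr, fx$template, "9", fx$log)$outcome, character(1))
  expect_identical(unname(outcomes),
                   c("ignored_wrong_project", "ignored_wrong_instrument",
                     "failed_error", "failed_error"))
  expect_identical(readLines(fx$store), before)
  expect_length(read_audit_log(fx$log), length(triggers))
})

test_that("units failing covariate validation are rejected, not allocated", {
  dir <- withr::local_tempdir()
  fx <- workflow_fixture(dir)
  snap <- read_store(fx$store, fx$template$specs)
  snap$units[[cov_col_name("age")]][2] <- NA
  write_store(snap$units, fx$store)
  entry <- handle_trigger(fx$store, "project_id=9&record=u02&instrument=randomization",
                          fx$template, "9", fx$log)
  expect_identical(entry$outcome, "rejected_validation")
  expect_match(entry$detail, "age")
  snap <- read_store(fx$store)
  expect_true(is.na(snap$units$arm[match("u02", snap$units$unit_id)]))
})

test_that("a store-write failure is audited and leaves the unit unallocated", {
  dir <- withr::local_tempdir()
  fx <- workflow_fixture(dir)
  before <- readLines(fx$store)
  boom <- function(...) stop("disk on fire")
  entry <- handle_trigger(fx$store, "project_id=9&record=u02&instrument=randomization",
                          fx$template, "9", fx$log, .write = boom)
  expect_identical(entry$outcome, "failed_error")
  expect_match(entry$detail, "disk on fire")
  expect_identical(readLines(fx$store), before)
  expect_length(read_audit_log(fx$log), 1L)
})

test_that("back-up lists are deterministic, balanced, and serializable", {
  expect_identical(generate_backup_list(20, seed = 5),
                   generate_backup_list(20, seed = 5))
  one <- generate_backup_list(1, seed = 5)
  expect_length(one$entries, 1L)
  big <- generate_backup_list(10000, seed = 5, arms = ARMS)
  share <- mean(big$entries == "A")
  expect_lt(abs(share - 0.5), 3 * sqrt(0.25 / 10000))
  path <- withr::local_tempfile(fileext = ".csv")
  write_backup_list(big, path)
  back <- read_backup_list(path)
  expect_identical(back$entries, big$entries)
  expect_error(generate_backup_list(0, seed = 1), class = "msb_validation_error")
})

test_that("back-up allocations consume the list in order and reconcile into balance", {
  trial <- binary_state(8, 10, 2, 10)
  backup <- generate_backup_list(2, seed = 9, arms = ARMS)
  uid <- new_unit_id(trial)
  out <- apply_backup_allocation(trial, uid, backup)
  expect_identical(out$trial$last_allocation$arm, backup$entries[1])
  expect_identical(out$trial$units$source[match(uid, out$trial$units$unit_id)],
                   "backup_list")
  expect_equal(out$backup$next_index, 1L)
  # the backup-assigned unit is counted by subsequent balance tests
  before <- imbalance_test(trial, "trait", level = "yes")$n_by_arm
  after <- imbalance_test(out$trial, "trait", level = "yes")$n_by_arm
  expect_equal(sum(after), sum(before) + 1L)

  # exhaustion: state unchanged
  t2 <- build_trial(list(binary_spec()), list(trait = c("yes")), NULL,
                    config = msb_config(seed = 1))
  exhausted <- generate_backup_list(1, seed = 9, arms = ARMS)
  exhausted$next_index <- 1L
  expect_error(apply_backup_allocation(t2, t2$units$unit_id[1], exhausted),
               class = "msb_state_error")
  expect_true(is.na(t2$units$arm[1]))
})

test_that("no interleaving can allocate a unit twice", {
  trial <- binary_state(8, 10, 2, 10)
  backup <- generate_backup_list(5, seed = 9, arms = ARMS)
  uid <- new_unit_id(trial)
  # algorithm first, then backup: second attempt errors without change
  t_alg <- randomize_unit(trial, uid)
  expect_error(apply_backup_allocation(t_alg, uid, backup),
               class = "msb_state_error")
  # backup first, then algorithm
  t_bak <- apply_backup_allocation(trial, uid, backup)$trial
  expect_error(randomize_unit(t_bak, uid), class = "msb_state_error")
})

test_that("a backup allocation is indistinguishable from an algorithmic one downstream", {
  mk_next <- function(trial) {
    # append a fresh incoming unit and randomize it algorithmically
    trial <- add_units(trial, unit_record("next", list(trait = "yes")))
    randomize_unit(trial, "next")
  }
  trial <- binary_state(8, 10, 2, 10)
  uid <- new_unit_id(trial)
  backup <- generate_backup_list(1, seed = 9, arms = ARMS)
  via_backup <- apply_backup_allocation(trial, uid, backup)$trial
  via_engine <- trial
  i <- match(uid, via_engine$units$unit_id)
  via_engine$units$arm[i] <- backup$entries[1]
  via_engine$units$allocation_probability[i] <- 0.5
  via_engine$units$criteria[i] <- ""
  via_engine$units$source[i] <- "algorithm"
  via_engine$units$enrollment_index[i] <- via_engine$n_randomized
  via_engine$n_randomized <- via_engine$n_randomized + 1L
  a <- mk_next(via_backup)$last_allocation
  b <- mk_next(via_engine)$last_allocation
  expect_identical(a, b)
})

test_that("the consistency scan flags allocations missing from the log", {
  dir <- withr::local_tempdir()
  fx <- workflow_fixture(dir)
  snap <- read_store(fx$store, fx$template$specs)
  snap$units$arm[1] <- "A"
  snap$units$source[1] <- "algorithm"
  write_store(snap$units, fx$store)
  warnings <- check_consistency(fx$store, fx$log)
  expect_length(warnings, 1L)
  expect_match(warnings, "u01")
})
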