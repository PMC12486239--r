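# Shared fixture builders: trials constructed directly with pre-assigned
# arms, so engine behavior can be probed from known states.

ARMS <- c("A", "B")

# Build a trial whose unit store is constructed from vectors.
# cov_values: named list of length-n vectors (numeric or level labels);
# arm: length-n vector of arm labels (NA = unrandomized).
build_trial <- function(specs, cov_values = list(), arm = NULL,
                        config = msb_config(seed = 1), arms = ARMS,
                        ready = TRUE) {
  n <- if (length(cov_values)) length(cov_values[[1]]) else length(arm)
  trial <- msb_trial(arms, specs, config)
  if (n == 0L) return(trial)
  if (is.null(arm)) arm <- rep(NA_character_, n)
  randomized <- !is.na(arm)
  df <- data.frame(
    unit_id = sprintf("x%04d", seq_len(n)),
    member_record_ids = sprintf("x%04d", seq_len(n)),
    ready = rep(ready, length.out = n),
    arm = arm,
    allocation_probability = ifelse(randomized, 0.5, NA_real_),
    criteria = ifelse(randomized, "", NA_character_),
    source = ifelse(randomized, "algorithm", "unset"),
    enrollment_index = NA_integer_,
    stringsAsFactors = FALSE
  )
  df$enrollment_index[randomized] <- seq_len(sum(randomized)) - 1L
  for (nm in names(cov_values)) df[[cov_col_name(nm)]] <- cov_values[[nm]]
  for (s in specs) {
    col <- cov_col_name(s$name)
    if (is.null(df[[col]]))
      df[[col]] <- if (s$kind == "continuous") NA_real_ else NA_character_
  }
  trial$units <- df[, names(trial$units)]
  trial$n_randomized <- sum(randomized)
  trial
}

cov_col_name <- function(name) paste0("covariate.", name)

binary_spec <- function(name = "trait", levels = c("no", "yes"), ...)
  covariate_spec(name, "binary", levels = levels, ...)

# A post-burn-in state with one binary covariate: k0/n0 trait-positive in
# arm A, k1/n1 in arm B, plus one unrandomized incoming unit whose trait
# status is `new_positive`.  Burn-in 0 and size vote off unless given.
binary_state <- function(k0, n0, k1, n1, new_positive = TRUE,
                         config = msb_config(seed = 1, burn_in = 0L,
                                             size_balance = FALSE)) {
  vals <- c(rep("yes", k0), rep("no", n0 - k0),
            rep("yes", k1), rep("no", n1 - k1),
            if (new_positive) "yes" else "no")
  arm <- c(rep("A", n0), rep("B", n1), NA)
  build_trial(list(binary_spec()), list(trait = vals), arm, config = config)
}

new_unit_id <- function(trial) {
  trial$units$unit_id[is.na(trial$units$arm)][1]
}

# Count violations of the vote-direction property over random small
# instances: when a vote is cast, hypothetically assigning the incoming
# unit to the voted arm must not leave a larger |standardized
# difference| than assigning it to the other arm.
vote_direction_check <- function(n_instances, seed) {
  set.seed(seed)
  checked <- 0L
  violations <- 0L
  for (i in seq_len(n_instances)) {
    continuous <- runif(1) < 0.5
    n0 <- sample(3:25, 1); n1 <- sample(3:25, 1)
    cfg <- msb_config(seed = i, burn_in = 0L, size_balance = FALSE,
                      p_threshold = 0.9)  # wide gate so votes occur often
    if (continuous) {
      spec <- covariate_spec("x", "continuous")
      vals <- c(rnorm(n0, mean = runif(1, -2, 2)), rnorm(n1), rnorm(1, sd = 2))
      trial <- build_trial(list(spec), list(x = vals),
                           c(rep("A", n0), rep("B", n1), NA), config = cfg)
      rep_ <- imbalance_test(trial, "x")
    } else {
      spec <- binary_spec("x")
      p <- runif(1, 0.1, 0.9)
      vals <- c(sample(c("no", "yes"), n0, replace = TRUE, prob = c(1 - p, p)),
                sample(c("no", "yes"), n1, replace = TRUE, prob = c(p, 1 - p)),
                sample(c("no", "yes"), 1))
      trial <- build_trial(list(spec), list(x = vals),
                           c(rep("A", n0), rep("B", n1), NA), config = cfg)
      rep_ <- imbalance_test(trial, "x",
                             level = vals[length(vals)])
    }
    uid <- new_unit_id(trial)
    vote <- covariate_vote(rep_, trial, uid)
    if (vote == "none") next
    checked <- checked + 1L
    d_after <- vapply(c("A", "B"), function(a) {
      t2 <- trial
      i2 <- match(uid, t2$units$unit_id)
      t2$units$arm[i2] <- a
      vals2 <- t2$units[[cov_col_name("x")]]
      in0 <- !is.na(t2$units$arm) & t2$units$arm == "A"
      in1 <- !is.na(t2$units$arm) & t2$units$arm == "B"
      if (continuous) {
        abs(std_diff_continuous(vals2[in0], vals2[in1]))
      } else {
        lev <- vals[length(vals)]
        abs(std_diff_binary(sum(vals2[in0] == lev), sum(in0),
                            sum(vals2[in1] == lev), sum(in1)))
      }
    }, numeric(1))
    other <- setdiff(c("A", "B"), vote)
    if (d_after[[vote]] > d_after[[other]] + 1e-12)
      violations <- violations + 1L
  }
  list(checked = checked, violations = violations)
}
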