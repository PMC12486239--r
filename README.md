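# msbrand

Covariate-adaptive randomization for two-arm clinical trials using the
**minimal sufficient balance (MSB)** algorithm, plus the operational
pieces a real deployment needs: a trigger-driven allocation workflow
with audit logging and a static back-up list, a CSV/JSON unit record
store, balance reporting, and a Monte-Carlo enrollment simulator that
compares MSB against simple randomization.

It is written for trial biostatisticians and data managers who need
adaptive randomization to run automatically when study staff save a
"ready to randomize" form — and who need the allocation sequence to be
auditable and replayable afterwards.

## The algorithm

For each incoming randomization unit (an individual or a partnered
dyad randomized together), every active balancing covariate is tested
for between-arm imbalance over the already-randomized units:
Welch's t-test for continuous covariates; a 2x2 chi-square test of
proportions (Fisher's exact test when any expected cell count < 5)
for binary/categorical ones, one-vs-rest on the incoming unit's own
level. A covariate whose test has p < η (default 0.3) casts a **vote**
for the arm that would reduce its imbalance:

* continuous — a value above the pooled mean votes for the arm with
  the smaller current mean, below it for the arm with the larger mean;
* binary/categorical — a unit carrying the trait votes for the arm
  with the lower current proportion of it, and vice versa.

Arm-size imbalance (exact binomial test at rate ½) may also vote. If a
strict majority of votes favors one arm, that arm is allocated with
probability p_b = 0.7 (> ½); otherwise — and always during the initial
burn-in of 20 units — the coin is fair. Imbalance is summarized by the
standardized difference, d = (mean₀ − mean₁)/s_pooled for continuous
covariates and (p₀ − p₁)/√((p₀(1−p₀) + p₁(1−p₁))/2) for proportions,
against the conventional validity bounds d = 0.1 and a 10% risk
difference.

## Worked example

Simulate a 500-unit enrollment over the shipped seven-covariate
population and randomize it with MSB:

```r
library(msbrand)

pop   <- population_config(500, seed = 42)
trial <- msb_trial(c("intervention", "control"), population_specs(pop),
                   msb_config(seed = 42))
trial <- run_trial(trial, generate_stream(pop), scheme = "msb")
summary(trial)
```

```
Arm sizes: intervention = 260, control = 240

Covariate balance (standardized differences):
             covariate        kind           level  n0  n1  std_diff risk_diff
                status categorical partnered_alone 260 240  0.032702  0.012821
 limited_participation      binary             yes 260 240 -0.059034 -0.023077
        race_ethnicity categorical           black 260 240  0.085362 -0.036218
             gnc_trans      binary             yes 260 240  0.000908  0.000321
              prep_use      binary             yes 260 240 -0.023069 -0.010897
                   sti      binary        positive 260 240  0.080518  0.026282
                   age  continuous            <NA> 260 240  0.054828  NA
```

Every covariate's end-of-trial standardized difference sits well
inside the d = 0.1 validity bound (categorical rows show the
worst-balanced level, one-vs-rest). Each allocation record documents
what drove it:

```r
biased <- Filter(function(a) !is.na(a$favored_arm), trial$allocations)
biased[[1]]
```

```
<allocation_result> unit u00021 -> control (index 20, algorithm)
  favored intervention with p = 0.7; votes 1:0; criteria: sample_size
```

— at enrollment index 20 (the first post-burn-in allocation) the
arm-size criterion had triggered, so the smaller arm was favored at
probability 0.7; the recorded uniform draw still sent the unit to
`control`, which is exactly the point: MSB biases the coin, it does
not force it.

The same engine runs behind the trigger workflow
(`handle_trigger()` parses a `project_id=..&record=..&instrument=..`
payload, checks readiness, allocates, writes back to the store, and
appends one audit-log line per trigger), with
`generate_backup_list()` / `apply_backup_allocation()` covering
outages. A thin command-line front end over these functions ships in
`inst/cli/msb`.

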