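---
title: "Minimal sufficient balance randomization: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimal sufficient balance randomization: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msbrand)
```

## The problem

Simple 1:1 randomization guarantees comparability of trial arms only in
expectation. In any single trial — even a large one — prognostic
covariates can drift apart between arms by chance (*accidental bias*),
which complicates interpretation and costs power. Covariate-adaptive
randomization algorithms counter this by looking at the imbalance
among already-randomized participants, and at the incoming
participant's own covariates, before flipping the coin.

`msbrand` implements one such algorithm, **minimal sufficient balance
(MSB)**, for two-arm trials, together with the operational scaffolding
that real electronic-data-capture deployments need: a trigger-driven
allocation workflow with auditing and a static back-up list, a CSV/JSON
record store, and a Monte-Carlo enrollment simulator.

## The allocation model

Let the two arms be indexed 0 and 1 (the first listed arm is always
arm 0 in every sign convention). When a unit arrives for
randomization, each *active* covariate is tested for between-arm
imbalance over the units randomized so far:

* **continuous** — Welch's unequal-variance two-sample t-test;
* **binary / categorical** — a 2x2 chi-square test of proportions
  without continuity correction, switching to Fisher's exact test when
  any expected cell count falls below 5. Categorical covariates are
  reduced to the incoming unit's own level, one-vs-rest, because MSB
  needs a *direction* and an omnibus test has none.

A covariate casts a **vote** only when its test's p-value falls below
the threshold `p_threshold` and the incoming unit's value gives the
vote a direction:

* continuous: a value above the pooled mean of randomized units votes
  for the arm with the smaller current mean, a value below it for the
  arm with the larger mean; a value exactly at the pooled mean, or
  equal arm means, casts no vote;
* binary/categorical: a unit carrying the indicator trait votes for
  the arm with the lower current proportion of that trait, a unit
  without it for the arm with the higher proportion; equal proportions
  cast no vote.

These rules aim at the defining MSB property — assigning the unit to
the voted arm should leave that covariate's absolute standardized
difference no larger than assigning it to the other arm would — and a
property-style test exercises exactly that claim over randomized
instances. For binary indicators the rule is monotone and the
property holds throughout. For continuous covariates the pooled-mean
comparison is the standard rule but remains a *heuristic*: when the
incoming value falls strictly between the two arm means, either
assignment narrows the mean gap, and the larger reduction can come
from the arm the rule does not pick (adding a value `v` to an arm
with mean `m` and size `n` moves that mean by `(v - m)/(n + 1)`). In
randomized small-sample instances a percent or two of cast votes land
in this regime; the test suite deliberately asserts the strict
property and documents the misdirected residue as a known property of
the method rather than papering over it.

Optionally (`size_balance = TRUE`, the default) the arm sizes
themselves vote, via an exact two-sided binomial test of the arm-0
count at rate 1/2, on equal footing with covariates under the name
`"sample_size"`.

If a **strict majority** of votes favors one arm, that arm receives
the allocation with probability `biased_probability` (> 0.5); a tie or
an empty tally leaves the coin fair. This is the "minimal" in minimal
sufficient balance: unless pre-specified criteria actually trigger,
the allocation is plain 1:1 randomization, preserving unpredictability.

Imbalance is reported throughout as the **standardized difference**:
for continuous covariates the difference in means over the pooled
standard deviation, for proportions
$(p_0 - p_1)\big/\sqrt{(p_0(1-p_0) + p_1(1-p_1))/2}$,
alongside the plain **risk difference** $p_0 - p_1$. The conventional
validity thresholds d = 0.1 and a 10% risk difference are used as
reference lines in reports and as simulation acceptance bounds.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `p_threshold` | 0.3 | per-covariate test significance below which a vote is cast. Deliberately liberal: the test is a trigger, not an inference. |
| `biased_probability` | 0.7 | probability given to the favored arm when criteria trigger. A common biased-coin choice; large enough to pull imbalance back quickly, small enough to keep allocations unpredictable. |
| `burn_in` | 20 units | initial simple 1:1 allocations. Imbalance tests on a handful of units are noise; 20 gives every test a workable sample without leaving much room for early drift. |
| `size_balance` | `TRUE` | whether arm-size imbalance votes. |
| `active_from` (per covariate) | 0 | enrollment index from which a covariate participates — an *index, not a date*, so simulation and replay need no clock. A covariate added mid-trial (e.g. a baseline test introduced after launch) is modeled as `active_from = k`. |

All four algorithm parameters are declared, configurable choices: the
methodology constrains only that the favored arm receive *more than
50%*, and published deployments rarely print their exact settings.

## Units, dyads, and missing values

The unit of randomization may be an individual or a partnered dyad
randomized together; a unit carries one covariate vector regardless.
How a dyad's two members combine into that vector (index partner,
worst case, mean, ...) is the caller's decision — the algorithm is
deliberately agnostic, since no general rule exists.

A missing value for an optional covariate excludes the unit from that
covariate's test and silences that covariate's vote for the incoming
unit; a missing *required* covariate blocks randomization with a
validation rejection. This matches sequential-trial reality, where a
unit may be randomized before every optional assessment is complete.

## The trigger workflow

The automation loop mirrors how data-entry-trigger (DET) style
deployments behave: the capture system POSTs a URL-encoded query
string (`project_id`, `record`, `instrument`) whenever a form is
saved. `handle_trigger()` then:

1. parses the payload (`parse_trigger()`);
2. checks that a randomization is actually required
   (`should_randomize()`): right project, right form
   (case-insensitively), known record, readiness indicator set, no
   existing allocation;
3. validates the unit's covariates;
4. runs the MSB engine;
5. writes the allocation back to the record store with optimistic
   concurrency (a version counter checked at write time — a
   conflicting writer loses cleanly rather than corrupting the store);
6. appends exactly one JSON-lines audit entry, whatever the outcome.

Re-delivery of a trigger after success is idempotent. The store write
precedes the log append; a crash between the two is surfaced by
`check_consistency()` at startup rather than hidden by transactional
machinery the deployment reality does not provide. The trial state is
rebuilt from the store on every trigger and the allocation draw is
seeded from the configured seed plus the count of already-randomized
units, so any given store state replays to the same allocation.

For outages there is a pre-generated static back-up list
(`generate_backup_list()`); consuming an entry
(`apply_backup_allocation()`) marks the unit `backup_list` at
probability 0.5 and — the reconciliation contract — makes it
indistinguishable from an algorithmic allocation of the same arm for
every future balance computation.

## The simulator, and what it does not show

`generate_stream()` draws ready-to-randomize units from configured
marginals. The shipped default roster mirrors the balancing covariates
of a two-arm HIV-prevention trial in 16–34-year-olds: participation
status (3 levels), limited participation, race/ethnicity (4 levels),
gender-nonconforming/trans identity, PrEP use, baseline STI
positivity, and age uniform on [16, 34]. The prevalences
(0.5/0.2/0.3, 0.2, 0.4/0.25/0.2/0.15, 0.15, 0.35, 0.1) and a dyad
fraction of 0.3 are deliberate mid-range placeholders, chosen once:
they are *not* estimates of any trial population, because the
published marginals of real enrollments are generally unavailable.
Claims from this simulator are claims about the algorithm, not about
any population.

Covariates are generated independently — no correlation structure —
and every unit arrives complete and ready. Real enrollment has
correlated covariates, missingness, and data-entry churn; passing
simulation bounds here therefore demonstrates the engine's balancing
behavior under clean conditions, not operational performance of a
deployment.

`compare_schemes()` runs paired replicates (same enrollment stream,
MSB vs simple 1:1) and summarizes the distribution of the
end-of-trial *maximum* |standardized difference| across covariates and
maximum |risk difference| across non-continuous covariates — worst
case, not average, because one badly imbalanced prognostic covariate
is what threatens validity. The package's acceptance checks run 100
replicates of 2,086-unit trials (a realistic trial-scale n that keeps
the whole suite within desk-scale runtimes) and require the MSB 95th
percentiles to sit within d = 0.1 and 10%.

## Numerical choices

* The Welch t and chi-square p-values are computed in closed form from
  sufficient statistics (the engine evaluates one test per active
  covariate at every allocation — hundreds of thousands of tests in a
  simulation study); the test suite asserts equivalence with
  `stats::t.test()` and `stats::chisq.test(correct = FALSE)` to 1e-8
  on random instances. Fisher's exact test delegates to
  `stats::fisher.test()`.
* The exact binomial size test uses the closed form valid at rate 1/2
  (`2 * pbinom(min(n0, n1), n, 1/2)`, capped at 1; 1 when the arms are
  exactly equal), checked against `stats::binom.test()`.
* Degenerate inputs are defined, not accidental: identical arm
  multisets give p = 1 and d = 0; an arm with no data gives p = 1 and
  no vote; zero pooled spread with unequal means returns a signed
  infinity sentinel rather than NaN.
* Each trial owns a private Mersenne-Twister stream consumed in
  enrollment order, with every uniform draw recorded in the allocation
  record, so a full allocation sequence replays bit-for-bit under its
  seed and the session's RNG is never disturbed.
* Ties (a new value exactly at the pooled mean; equal proportions;
  an even vote split) always resolve to "no bias": with no direction
  that strictly reduces imbalance, MSB's default is the fair coin.

## Known limitations

* Two arms only, equal target allocation; no stratified or
  minimization schemes (the covariate interface leaves room, the
  engine is MSB-only).
* No multiplicity adjustment across per-covariate tests — votes are
  intentionally per-covariate.
* The record store is a file, not a database: optimistic versioning
  handles the realistic single-site concurrency it emulates, nothing
  stronger.
* The simulator makes no power or outcome claims.
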