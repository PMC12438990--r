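---
title: "Diagnostic trajectories: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnostic trajectories: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diagtraj)
```

## The problem

Children and adolescents who receive a first psychiatric diagnosis (the
*D1*, a first-time main ICD-10 F-chapter discharge diagnosis before age
18.0) often receive different diagnoses later: depression becomes bipolar
disorder, an adjustment disorder precedes a personality disorder, autism is
joined by ADHD. `diagtraj` turns dated registry-style event records into
annual diagnostic *state sequences* and quantifies this instability three
ways: per-sequence normalized entropy, the prevalence of diagnostic shifts,
and time-to-subsequent-diagnosis hazard contrasts.

Registry extracts of this kind are not publicly deposited, so the package
pairs every analysis stage with a discrete-time Markov cohort simulator
with known ground truth. Everything downstream of ingest is exercised, and
its statistical behavior verified, on simulated cohorts.

## The taxonomy

Diagnoses enter at the two-cipher level (F00–F99) and are grouped into 19
analysis categories (SUD, SZ, BD, SRD, OMD, AND, OCD, SAD, SOM, ED, PD, ID,
ODD, ASD, ADHD, CD, AD, TD, OTHER). The grouping ships as an editable rule
file (`inst/extdata/diagnostic_categories.csv`) of include/exclude prefixes
resolved by longest-prefix match, so subcode carve-outs (F84.2–F84.4 belong
to OTHER, not ASD; F94.0 is excluded from AD) take precedence over their
parent blocks.

The rule list is closed: codes claimed by no rule — the organic block
F00–F09, F49, F85–F87, F96–F97, the bare F98 block, F94.0 and F98.7 — map
to `UNMAPPED` rather than being folded into OTHER. Silently inventing
taxonomy would be worse than excluding; unmapped records are dropped from
sequences but counted in the ingest report and in the `n_unmapped`
attribute. For the hazard contrasts, outcomes are defined at the one-cipher
chapter level (F0–F9), which *does* cover every code, so chapters with no
19-category home (F0, parts of F9) still appear there.

## Sequence construction

Each person's follow-up is cut into ten 12-month windows anchored at the D1
date; "12 months" means the same day-of-month one year later, clamping at
month ends (a Feb-29 anchor advances to Feb-28). The state of a window is
the category of the **last** diagnosis dated inside it — the most recent
diagnosis in a period is taken to carry the most clinical validity — and
windows without a diagnosis inherit the prevailing state
(prevailing-diagnosis projection). Death and emigration are absorbing: an
absorbing event inside a window claims that window and all later ones, and
death wins a same-window tie with a diagnosis or an emigration. Period
length is a parameter (`n_periods` together with month arithmetic), so 3-
or 6-month sensitivity runs are possible, but 12 months is the primary
design.

Two consequences worth knowing:

* A shift that is reversed within a single window is invisible to the
  sequence. `record_shift_summary()` therefore reports the record-level
  prevalence alongside the sequence-level `shift_summary()`.
* A death in window 1 would, under the stated rules, make the first state
  `DEAD`; in indexed cohorts this cannot happen in practice (the person was
  alive and diagnosed at entry), and the simulator draws absorbing events
  only from period 2 on.

The windowed builder is verified against an independent brute-force oracle
that assigns every calendar day its prevailing state and reads off each
window's final day — the two agree exactly on 1,000 random simulated
persons (see `tests/testthat/test-acceptance.R`).

## Normalized entropy

For a sequence of length $L$ over an alphabet of $a$ states with occupancy
fractions $p_i$,

$$h \;=\; \frac{-\sum_i p_i \ln p_i}{\ln a} \in [0, 1],$$

zero for a constant sequence, one when every alphabet state is occupied
equally (attainable when $L$ is a multiple of $a$). The measure is
permutation-invariant: it quantifies the *diversity* of states, not their
ordering. The alphabet size defaults to $a = 21$ (19 categories plus DEAD
and EMIGRATED) and is configurable to 19; with $L = 10 < a$ the attainable
maximum is $\ln 10 / \ln a$, and observed cohort means are far below it, so
the choice mainly rescales. Both modes are exposed because either reading
of "all the states that can occur" is defensible; 21 is the default since
sequences do carry the absorbing states. The natural logarithm is used;
normalization makes the base irrelevant.

Group contrasts (`compare_entropy_groups()`) use a Welch two-sample t-test
for two groups — the unequal-variance form is the robust default when
nothing is known about variance homogeneity — and one-way ANOVA for three
or more (age bands 0–10 vs 11–17 at D1, parental education SHORT / MEDIUM
/ LONG, entry-year bands). Groups with fewer than two observations yield an
explicit `insufficient_data` result. Entropy values are bounded, skewed and
have an atom at zero, so the t-test is a large-sample approximation; its
type-I calibration at the sizes used here is checked by simulation in the
acceptance suite (rejection rate within [3%, 7%] of nominal 5% over 1,000
two-group resamples from a shared generator).

## Diagnostic shifts and suppression

A *shift* is any period state that is a diagnostic category different from
the D1 category. Re-diagnoses of the same category are not shifts (a second
depression diagnosis does not count; a bipolar diagnosis after depression
does), and within-category code changes (F32 to F33) are invisible at the
19-category resolution by design. Absorbing states never count as shifts;
by default a person who dies without shifting counts as stable, and
`drop_absorbed = TRUE` instead excludes such persons — the choice between
the two readings is genuinely open, so both are exposed.

All rendered tables respect small-cell suppression: any displayed sequence
or cell supported by fewer than five individuals (configurable) is withheld
and pooled into an aggregate residual, so displayed plus residual always
equals the stratum total. Plots are *metadata-first*: every figure carries
a machine-readable description of exactly what was drawn, which is how the
test suite proves that suppressed cells never reach a rendering.

## Hazard contrasts

For each D1 category and each chapter outcome F0–F9, persons are followed
from the D1 date to the first post-D1 diagnosis in that chapter whose
two-cipher block differs from the D1's own block (a repeat of the D1
diagnosis never qualifies; a *different* block within the D1's own chapter
does — `exclude_same_chapter = TRUE` drops same-chapter D1s as a
sensitivity), censored at death, emigration, or 3,652 days (10 years). The
D1-vs-all-other-D1s contrast is fit per sex with a single binary exposure
term by Cox partial likelihood with Efron tie handling (the data are
day-resolution, so ties are rare; Efron is the accurate default). Death is
treated as censoring, not as a competing risk — a documented limitation;
Fine–Gray modeling is out of scope.

Multiplicity is handled by Bonferroni: `bonferroni_plan(n)` computes
$\alpha = 0.05/n$ and the matching confidence level. The number of tests is
derived from the contrast grid actually attempted at runtime rather than
fixed a priori. For reference, 180 tests give $\alpha = 0.05/180 \approx
0.0278\%$ — note that a significance level of "0.026%" sometimes quoted for
this design is not exactly $0.05/180$; the package computes the division
from first principles. With $\alpha$ near $0.0003$ the Wald intervals are
conventionally rendered as 99.9% CIs.

Degenerate inputs — an empty arm, or zero events in an arm, where the
partial-likelihood maximum is unbounded — return a flagged row with
undefined estimate rather than an error. Estimator behavior is verified by
simulation: with exponential event times and a true hazard ratio of 2 at
5,000 persons per arm, the mean estimate over 200 replicates is within 3%
of 2 and the 99.9% interval covers the truth at its nominal rate.

## The synthetic cohort generator

`generate_cohort()` draws, per person: sex (female share 0.4226), parental
education (SHORT/MEDIUM/LONG at 0.25/0.45/0.30), a D1 category from the
per-sex mixture, a truncated-normal onset age, and a D1 date uniform over
the 1996–2011 entry window; then, for periods 2–10, death and emigration
Bernoulli draws (death first, and first wins) followed by one draw from the
transition row, emitting a dated record only on change, placed uniformly
strictly inside the period so it exercises the last-diagnosis-per-window
logic. Identical configs and seeds give byte-identical record files.

The shipped calibration (`inst/extdata/d1_calibration.csv`) pins its per-sex
mixture and onset ages to published nationwide anchor values where they are
available — stress/adjustment disorders 23.0%, eating disorders 11.9% and
ADHD 9.7% of girls' D1s; ADHD 24.7%, autism 19.3% and other developmental
disorders 6.2% of boys'; bipolar disorder rarest in both sexes; attachment
disorder and autism earliest-onset (8.1–8.9 years), substance use and
bipolar disorder latest (15.6–16.2 years), boys diagnosed earlier than
girls in most categories — and fills the remaining cells with
field-plausible values normalized to 100%. The transition matrix has no
published counterpart at all, so the default is a uniform-off-diagonal
matrix with stay probability 0.93; **neither it nor the filled mixture
cells are estimates of any real cohort.** Per-period absorbing
probabilities default to 0.0005 (death) and 0.002 (emigration), reflecting
how rare both are at these ages.

What the simulator deliberately does not emulate: calendar-period
diagnostic drift, within-family clustering, secular trends in service use,
within-window reversals (at most one transition per period), and
covariate-dependent transition dynamics. Passing recovery tests on
simulated cohorts therefore demonstrates that the *pipeline* is correct and
calibrated, not that any particular real-world percentage is reproduced.

## Numerical and degenerate-input choices

* Decimal age is days since birth / 365.25; D1 eligibility is strict
  (`age < 18.0`). Age bands at D1 are 0–10 and 11–17 (cohort entry itself
  requires age below 18.0, so "11–18" and "11–17" describe the same set).
* Same-day diagnosis ties, both at D1 identification and within windows,
  keep the last record in file order, consistent with
  last-diagnosis-per-window.
* Probability vectors must sum to 1 within 1e-9; transition matrices must
  be row-stochastic to the same tolerance.
* 10 years of administrative censoring is fixed at 3,652 days.
* A two-group entropy contrast where both groups have zero variance returns
  t = 0 (equal means) rather than NaN.
* Problem sizes in the test suite — 20,000 persons for shift-prevalence
  recovery, 50,000 for calibration recovery, 1,000 for the windowing
  oracle, 200 replicates of 10,000 for estimator coverage, 1,000 resamples
  for t-test calibration — were chosen to make three-binomial-SE bounds
  tight enough to detect real defects while keeping a full run in tens of
  seconds.

## Known limitations

The record format carries main diagnoses only and has no main/secondary
flag; callers must pre-filter mixed extracts. Sequences aggregate to
12-month resolution, so short-lived diagnostic excursions are invisible (by
design; the record-level shift summary is the check). Death is a competing
risk that the hazard contrasts treat as censoring. And the simulator's
transition dynamics are a testability device: analyses of real registry
extracts should treat shipped defaults as documentation of structure, not
of rates.
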