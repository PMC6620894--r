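---
title: "hoverbayes: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hoverbayes: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hoverbayes)
```

## The scientific setting

Decades of work on Bayesian reasoning show that people asked for the
positive predictive value (PPV) of a binary test — the probability of the
hypothesis given positive evidence — perform poorly when the problem is
stated in conditional probabilities and much better when it is stated in
natural frequencies (nested counts from sequential sampling). A second
strand of work shows that performance also depends on whether the numbers
match the reasoner's lived experience of the event. `hoverbayes`
implements the analysis machinery for experiments that cross these two
factors (information format × data-generating mode) and that additionally
record *how* participants explore the problem: the task data are hidden
behind buttons on a tree diagram and revealed only while hovered, so the
hover log is a direct trace of information acquisition.

## Task model

A task instance is a triple (base rate $b$, true-positive rate $t$,
false-alarm rate $f$) rendered as a two-level tree (`problem_tree`). The
frequency rendering scales the triple onto an integer population
(default 1000): the first child of each split is rounded half-up and the
complement receives the residual, so children always sum exactly to their
parent. (Rounding half *up* rather than banker's rounding keeps node
values independent of parity; the residual rule is our choice — any
convention that conserves counts would do, and it only matters at the
last displayed digit.) The percentage rendering renormalises to 100 at
every branch. The true posterior is

$$P(H\mid E) = \frac{t\,b}{t\,b + f\,(1-b)}.$$

A task with $t\,b + f\,(1-b) = 0$ has no positive-evidence mass and is
rejected as degenerate. Note a consequence of integer display: the
posterior recomputed from displayed leaf counts, $FA/(FA+nFA)$, differs
from the triple posterior by up to about $2/(FA+nFA)$ — the *positive
evidence* count, not the population, sets the display accuracy. The test
suite asserts exactly this bound.

## Performance metrics

* **Correctness** uses the strict rounding criterion: an answer expressed
  in percent is correct iff it lies in $[\lfloor 100 P_t\rfloor,
  \lceil 100 P_t\rceil]$, inclusive. Both roundings of the true value must
  be accepted, which is why the band is two-sided even when $100 P_t$ is
  nearly integral.
* **Log-relative-error** is $\log_{10}(P_e/P_t)$ for the participant's
  estimate $P_e$; **log-experience-deviation** is $\log_{10}(P_s/P_t)$
  where $P_s$ is the posterior implied by the participant's *reported*
  triple. In experience-matched cohorts the reported triple *is* the task
  triple, so the deviation is identically zero — a useful pipeline
  self-check. A zero estimate would make the log undefined; we floor it
  at $1/(10\cdot\text{population})$ (a tenth of a displayable event) and
  flag the record (`lre_floored`) rather than dropping it.
* **Strategy classification** is a fixed priority cascade: strict-rounding
  correct → `correct_ppv`; else within `tol` of the true-positive rate →
  `sensitivity_confusion` (the canonical $P(E|H)$-for-$P(H|E)$ confusion);
  else, under the frequency format, stated denominator equal to the
  population → `total_denominator`; else `other`. The default
  `tol = 0.005` is half a percentage point, the granularity of the
  correctness criterion. The cascade means an answer that is *both*
  correct and equal to the sensitivity counts as correct — deliberate,
  since such tasks cannot distinguish the two readings.

## Interaction analysis

Hover logs (participant, AOI, enter/exit ms; half-open intervals) are
sorted and collapsed: consecutive hovers on the same AOI merge into one
visit whose dwell is the summed duration. The collapse rule is our
documented choice — with it, bigrams live exactly on the $8\times7=56$
ordered-pair space, and every sequence of $n$ collapsed visits contributes
$n-1$ transitions. No debouncing is applied by default (`min_duration_ms =
0`): the paradigm's explicit reveal gesture already filters incidental
cursor crossings, and a threshold is available for logs where it does not.

Validity rules: participants are excluded if an active ad-blocker was
detected, if the question was never viewed, or if fewer than two distinct
information AOIs were viewed. Dwell-time tables are computed per
participant (percentages of the participant's own total hover time, which
sum to 100) and then summarised as mean/SD across participants, so
long-session participants do not dominate the group summary.

## Group inference

**Hellinger permutation test.** Group transition distributions are the
participant count vectors pooled and renormalised; the observed statistic
is the Hellinger distance between the two groups' pooled distributions.
Two null constructions are provided, because the literature describes the
test both as a permutation test and as resampling "with replacement":

* `with_replacement` (default): both pseudo-groups are drawn with
  replacement from the combined participants. This matches the published
  description and is *conservative* here — bootstrap duplication inflates
  null distances (measured type-I error 0.018 at $\alpha=0.05$, 40/group).
* `label_permutation`: the classical relabelling of the observed
  partition, exact under participant exchangeability (measured type-I
  0.040, inside the nominal band).

Both modes use the add-one estimator $p = (1 + \#\{d_{null} \ge
d_{obs}\})/(B+1)$, take an explicit seed, and redraw (and count)
replicates in which a pseudo-group has zero transitions. The acceptance
suite asserts nominal calibration for the permutation mode and
non-anti-conservatism for the bootstrap mode; power against a planted
between-condition effect of Hellinger magnitude 0.12 at 75/group exceeds
0.8 in either mode. Which construction the original analysis used is not
fully determined by its description; we default to the with-replacement
reading and document both.

**Odds-ratio screening.** Each transition's odds ratio between conditions
is computed on the 2×2 table {count, total − count} with a 95% Wald CI on
the log scale (the CI method is our choice; Haldane–Anscombe +0.5 applied
to all cells when any is zero). A transition is *discriminative* when its
CI excludes 1 and its maximum frequency $F = \max(x_i, y_i)$ reaches
`min_frequency` (default 30 — the conventional "large enough to be
representative" threshold; the source analysis states no number). Two
caveats are deliberate and documented rather than patched: (i) across 56
transitions, 95% CIs on *sampled* null data are expected to flag ~2.8
transitions by chance, so "no flags" is guaranteed only for a group
compared with itself; (ii) pooled counts are clustered within
participants, making the binomial-flavoured Wald CI anti-conservative.
The screen is therefore a *screening* device, ranked by $|\log OR|$, not
a family-wise-controlled test — matching its published use.

**Association and regression reporting.** Format × correctness tables use
Pearson chi-squared without continuity correction (matching the magnitude
of published values; documented assumption) with optional Bonferroni
adjustment and Cramér's V. The correctness model is a maximum-likelihood
logistic fit `correct ~ format + dgm + numeracy` reported as odds ratios
with 95% Wald CIs (reference classes: frequency format,
experience-matched mode); perfect separation is flagged and CIs withheld.
The error model is least-squares `log_relative_error ~ format +
log_experience_deviation` on the model scale. One known reporting quirk
of the source analysis: its text converts the format coefficient
$\beta = 0.26$ (log10 response scale) into "a 1.30 increase", a
back-transformation that does not follow from the stated scale
($10^{0.26} \approx 1.82$); we report coefficients on the model scale
only.

## The synthetic-cohort generator

The generator is the package's stated world, not a tuning knob. Defaults:

* **Sample sizes**: 150 per format cell, matching the recruited cohorts.
* **Reported triples**: Beta draws with means near the believed values
  observed in this paradigm — base $\sim$ Beta(2, 18) (mean 0.10),
  true-positive $\sim$ Beta(5, 5) (0.50), false-alarm $\sim$
  Beta(2.7, 7.3) (0.27) — quantized the way participants state them
  (per-1000 counts or tenths of a percent) and clamped away from 0 and 1.
  The fixed-values task triple is (0.1, 0.5, 0.27), the cohort medians.
* **Strategy mixtures** per study/format reproduce the reported answer
  shares (e.g. experience-matched: 39% correct under frequencies with the
  total-denominator error dominating the remainder; 14% correct under
  percentages with 60% sensitivity confusion). `other` answers are
  uniform on [0, 1] and quoted out of 100, so they cannot collide with
  the total-denominator signature.
* **Hover chains**: first-order Markov chains over the 8 AOIs, zero
  diagonal. The baseline row is uniform over the other seven AOIs with
  the question twice as attractive; the frequency chain up-weights the
  "reversion to total" transitions (`F-T`, `nF-T`, `FnA-F`, `nFA-nF`),
  the percentage chain the question-checking ones (`Q-T`, `FnA-nF`,
  `nF-Q`), with a common tilt solved numerically so the two chains'
  theoretical bigram distributions sit at a chosen Hellinger distance
  (default 0.12, the magnitude of the published between-format effect).
  Sequence length is geometric (stop 0.05, mean ~21 visits, minimum 2);
  dwell is log-normal per AOI with the question's typical dwell ~4× a
  data node's, which reproduces ~40–50% of hover time on the question.
* **Q forced**: a question visit is prepended when the chain never
  reaches it, so synthetic participants pass the validity filter unless
  exclusion behaviour is being exercised via `force_question_visit =
  FALSE`.

What the generator does **not** emulate: individual differences in
chains (all participants in a condition share one chain, so real-data
between-participant heterogeneity is understated); any dependence of the
answer on the hover path; response times; and the real cohorts' exact
marginal distributions. A green test therefore establishes that the
*pipeline* recovers planted structure at realistic sizes — not that the
generator reproduces the deposited cohorts.

## Numerical and reproducibility choices

* Sequential posteriors are computed in log-odds; ties in the permutation
  null are counted in favour of the null (`>=`).
* All stochastic entry points take an explicit integer seed; with one
  seed the full pipeline is byte-reproducible on a given platform. R's
  default Mersenne-Twister is used (no counter-based generator exists in
  base R or the supported dependency set); per-participant substreams are
  derived from the master seed and kept below $2^{31}$.
* The permutation test is vectorised (participant-selection count
  matrices against the 56 × n count matrix, chunked at 2000 resamples) so
  the stated calibration experiments (500 × 1000 resamples) run in about
  a minute.
* Exit codes of the CLI: 0 success, 2 validation error, 3 degenerate
  analysis (e.g. every participant excluded).

## Known limitations

* The bags-and-chips sequential task is validated against its exact
  closed form (49/58 ≈ 0.8448); the commonly quoted 0.85 is that value
  loosely rounded.
* Whether percentage-format answers below 1% were entered as decimals or
  percentages in the original web task is unknowable from the logs; we
  treat all percentage answers as values on [0, 100].
* The OR screen applies no multiplicity control beyond the CI rule, by
  design (see above); treat its output as candidates for inspection.

```{r example}
# a compact end-to-end run
cfg <- cohort_config(n_per_cell = 30, seed = 7)
co <- generate_cohort(cfg)
m <- compute_metrics(co$participants)
tapply(m$correct, m$format, mean)

tabs <- lapply(parse_event_log(co$events), bigram_transitions)
fmt <- split(tabs, co$participants$format)
permutation_test(fmt$frequency, fmt$probability, n_perm = 999, seed = 1)
```
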