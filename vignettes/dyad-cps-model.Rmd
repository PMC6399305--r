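---
title: "Scoring and modeling dyadic collaborative problem solving from process stream data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and modeling dyadic collaborative problem solving from process stream data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpsdyad)
```

## The measurement problem

In human-to-human collaborative problem solving (CPS) assessment, two
students (roles A and B) work through computer-based tasks designed with
an *asymmetric* mechanism: each member sees different information and
controls, so neither can finish alone. The testing platform records every
action — chat messages, slider moves, apply clicks, task brackets — as a
time-stamped row tagged with the group, task, actor role and content.
This *process stream* is rich but cannot be fed to a measurement model
directly. Two problems must be solved:

1. **Evidence extraction.** Observable indicators must be defined by rule
   and extracted from the stream, in the spirit of evidence-centered
   design. Because of the asymmetry, each member produces a unique
   stream, so indicators come at three levels: individual indicators for
   A, individual indicators for B, and *group* indicators (joint
   conversation patterns, task outcomes) that neither member produces
   alone.
2. **Dyad dependence.** Partners are not independent: treating their
   scores as two unrelated respondents violates local independence.
   `cpsdyad` instead treats the two members as two *correlated latent
   dimensions* of a single case (the dyad).

## Indicator extraction

An indicator specification names the indicator (`T1A01` = task 1,
individual indicator for A, index 01; `G` marks group indicators), maps
it to a CPS-framework element, and gives the extraction rule. The rule
vocabulary covers the indicator families used in this style of
assessment:

* `rule_count_events()` — activeness: count every event a role generated;
* `rule_presence()` — direct indicators: a single action (optionally with
  a content pattern) occurs;
* `rule_sequence()` — inferred indicators: an ordered subsequence of
  actions occurs;
* `rule_chat_blocks()` — interaction: maximal runs of consecutive chats
  uninterrupted by actions are found, consecutive same-speaker chats are
  collapsed into speaker blocks, and adjacent block pairs are counted
  (`floor(blocks / 2)` per run). Speaker orders A,B,A,B and A,A,B,A,B
  both give 2. We count pairs irrespective of which role opens the run —
  the alternative reading (requiring A to speak first) satisfies the same
  worked examples but would penalize B-initiated exchanges for no
  substantive reason.
* `rule_outcome()` — the group-level task success, read from a complete
  (start/end-bracketed) stream only.

Frequency indicators are discretized before modeling. The empirical rule
sets the cut-off at `ceiling(mean - SD)` of the sample distribution
(sample SD, n − 1): a distribution with mean 37.18 and SD 15.74 gives
21.44, rounded up to 22, so a count of 21 scores 0 and a count of 22
scores 1. *Ceiling* (not round-half-up) is fixed as the meaning of
"rounded up"; the convention matters even though population-vs-sample SD
would not change this example. Meaning-based thresholds are supplied as
`fixed` rules. Missing cells (a dyad lacking a task) stay missing and
are handled by the likelihood, never imputed or zero-filled.

```{r cutoffs}
empirical_cutoff(c(2, 4, 6, 8))   # ceiling(5 - 2.582)
apply_cutoff(21:23, threshold_rule("fixed", cutoff = 22))
```

Out-of-order log rows are reported as violations rather than silently
re-sorted (a `sort_events` switch re-sorts stably, preserving file order
for ties), because silent reordering could manufacture or destroy
behavioral patterns such as action-interrupted chat runs.

## The within-item two-dimensional Rasch model

Let \(\theta = (\theta_A, \theta_B)\) be the dyad's latent abilities.
Indicator \(i\) with categories \(k = 0, \dots, K_i - 1\) follows the
multidimensional random coefficients multinomial logit model (MRCMLM):

\[
P(X_{ik} = 1 \mid \theta) =
\frac{\exp(\mathbf{b}_{ik}'\theta + \mathbf{a}_{ik}'\xi)}
     {\sum_{k'} \exp(\mathbf{b}_{ik'}'\theta + \mathbf{a}_{ik'}'\xi)}.
\]

The scoring matrix **B** attaches categories to dimensions: category
\(k\) of an A-indicator scores \((k, 0)\), of a B-indicator \((0, k)\),
and of a group indicator \((k, k)\) — *within-item* multidimensionality.
The design matrix **A** uses the partial-credit reduction: category
\(k\) of indicator \(i\) carries coefficient −1 on each of its first
\(k\) step parameters, so a dichotomous indicator has one difficulty and
a \(K\)-category indicator \(K - 1\) steps; larger \(\xi\) means harder.
A dichotomous indicator reduces to
\(P(1) = \mathrm{logistic}(\theta_d - \delta_i)\) (individual) or
\(\mathrm{logistic}(\theta_A + \theta_B - \delta_i)\) (group).

For identification the population mean is fixed at \((0, 0)\) with all
item parameters free (the convention of standard MML calibration programs;
sum-to-zero difficulties would be the alternative). The
population covariance \(\Sigma\) is free, and its correlation \(\rho\)
quantifies the dyad dependence.

### Estimation

`fit_mml_em()` maximizes the marginal likelihood, integrating
\(\theta\) over the bivariate normal on a tensor Gauss–Hermite grid
(default 31 nodes per dimension) rotated by the Cholesky factor of the
current \(\Sigma\):

* **E-step** — posterior weights for every dyad on the grid; missing
  cells drop out of the conditional product (ignorable missingness).
* **M-step** — per-indicator Newton updates (with step halving on the
  expected complete-data objective, so the marginal likelihood is
  monotone non-decreasing) and a posterior-second-moment update of
  \(\Sigma\) with means held at zero. \(\Sigma\) can be held fixed for
  controlled comparisons.
* Convergence when the largest absolute change in any step parameter or
  \(\Sigma\) entry falls below `tol` (default 1e-4; cap 500 iterations).
  Standard errors come from the empirical cross-product of per-dyad
  score contributions.

Category probabilities are computed with max-subtraction, so extreme
parameters cannot overflow. The quadrature is guarded in the test suite
by an independent dense-grid trapezoid oracle (marginal likelihood to
1e-6; EM maximizer against direct `optim` maximization of the oracle
likelihood to 1e-3 on small toys).

`estimate_abilities_eap()` returns posterior means and SDs per dyad;
a dyad with no observed indicators falls back to the prior, mean
\((0, 0)\) (exact by the symmetry of the Gauss–Hermite grid) with prior
SDs.

## Diagnostics and the two-stage workflow

`calibrate()` orchestrates the standard two-stage flow: fit all
indicators; compute quality statistics; exclude indicators failing the
retention rule; refit survivors and estimate abilities from them.

* **CTT discrimination** — corrected point-biserial: the indicator
  against the rest-score total of indicators sharing its dimension
  (group indicators share both dimensions, so A/B rest-scores include
  group indicators; a group indicator correlates against the dyad total
  minus itself).
* **Infit MNSQ** — \(\sum_n (x_{ni} - E_{ni})^2 / \sum_n W_{ni}\) with
  conditional moments at each dyad's EAP estimate. The fit variance
  \(q\) uses the conditional fourth moment
  (\(q = \sum (C_{ni} - W_{ni}^2) / (\sum W_{ni})^2\)), giving the null
  95% interval \(1 \pm 1.96\sqrt{q}\) and the Wilson–Hilferty
  standardized \(T = (M^{1/3} - 1)\,3/\sqrt{q} + \sqrt{q}/3\). The
  interval is for the *null* MNSQ of 1, which is why printed intervals
  bracket 1. Evaluating moments at EAP points (rather than integrating
  the posterior) is an approximation: under the correct model it
  shrinks residuals slightly, so mean MNSQ sits a little below 1
  (≈ 0.93 in the packaged null-simulation check at n = 2000) — within
  the 1 ± 0.1 calibration band asserted in the tests.
* **Retention rule** — drop iff MNSQ ∉ [0.77, 1.33], discrimination
  < 0, or correlation with the task's outcome indicator < 0 (outcome
  indicators exempt; Pearson/phi on the categorical scores).
* **Reliabilities** — item separation reliability
  \((\mathrm{var}(\hat\delta) - \overline{SE^2}) / \mathrm{var}(\hat\delta)\),
  truncated to [0, 1]; EAP reliability per dimension
  \(\mathrm{var}(\mathrm{EAP}) / (\mathrm{var}(\mathrm{EAP}) +
  \overline{\mathrm{SD}^2_{post}})\).
* **Dimension correlation** — Pearson correlation of the EAP pairs.
  Note that with a correlated prior, EAP shrinkage *inflates* this
  estimate relative to the generating \(\rho\) unless the test is very
  informative; the model's own \(\hat\rho\) (from \(\Sigma\)) is the
  cleaner estimate of the latent dependence.
* **Cohen's kappa** — chance-corrected agreement between the scoring
  program and a human rater for dichotomous indicators, labeled
  excellent (> 0.75), fair to good (0.4–0.75), poor otherwise. Kappa is
  reported missing when chance agreement is 1 (both raters constant).
* **Wright map** — abilities histogrammed per dimension on the logit
  scale with indicators at their difficulties (polytomous indicators at
  the mean of their steps), flagging indicators below the lowest
  ability.

## The synthetic-data generator

No interaction logs from the original assessments are publicly
deposited, so the package ships a seeded simulator that is itself
first-class, tested code:

* `simulate_population()` — bivariate-normal abilities, default
  \(\rho = 0.56\) (a realistic dependence level for asymmetric dyad
  tasks), unit variances.
* `simulate_scores()` — model-consistent categorical responses from the
  MRCMLM at the drawn abilities.
* `simulate_event_logs()` — the inverse of extraction: builds complete
  per-(dyad, task) streams (task brackets, an uninterrupted alternating
  chat run realizing the planted chat-block count, control/apply
  actions realizing presence and sequence plants, padding actions
  realizing the planted activeness counts, a task-result event) with
  strictly increasing 1-second timestamps. Unachievable plants (e.g. an
  activeness count smaller than the events its other plants require)
  raise an error naming the indicator.
* `simulate_study()` — the full pipeline: ability-linked plants (binary
  indicators from the Rasch model; activeness and chat counts from
  ability-linked negative binomials with mean ≈ 37 and SD ≈ 16,
  matching the frequency regime observed in operational assessments), logs, and a truth sidecar.
  Extraction reproduces the sidecar cell-for-cell; everything is
  bit-reproducible under a fixed seed.

The default event-log roster is 8 indicators per task (one per rule
family and role) over 4 tasks. This keeps one representative of every
extraction code path rather than mimicking a full operational test's 50-odd indicator
roster; the model-side simulations keep the operational *scale*
(11 A + 11 B + 8 group in the recovery studies). What the simulator does
*not* emulate: real chat semantics (content is placeholder text — the
operational indicators are content-blind), within-task learning or
pacing dynamics, and rater error. Passing round-trip tests therefore
demonstrate correctness of extraction and estimation, not behavioral
realism of the logs.

## Numerical and design choices

* Quadrature 31 nodes/dimension by default (tests compare 21- and
  31-node results against dense oracles); Cholesky rotation follows
  \(\Sigma\) each iteration.
* Timestamp ties keep file order (stable sort).
* In the recovery and calibration studies the individual indicators are
  trichotomous and group indicators dichotomous, difficulties spread
  over [−2, 2], n = 2000 dyads: a realistic, informative design in the
  reliability regime expected of a well-constructed test (EAP reliabilities above 0.8; a
  30-indicator dichotomous-only roster measures each member with only
  ~19 binary observations and lands near 0.79). Problem sizes in the
  test suite (n = 150–2000, 15–31 nodes) were chosen so each check runs
  at the smallest scale that still measures its property stably.
* Degenerate indicators (one observed category) abort `fit_mml_em()`
  with a named error and are auto-dropped with a warning by
  `calibrate()`.
* The deviance is reported as −2 log marginal likelihood; deviance
  bookkeeping differs across programs, so it is comparable within this
  package only.

## Limitations

* No semantic scoring of chat content; indicators are operational.
* Strictly Rasch (no 2PL/3PL discriminations — CTT discrimination is a
  diagnostic, not a model parameter); exactly two dimensions; no
  group-composition effects or multilevel random effects.
* Infit moments at EAP points (see above); numerical agreement with any
  specific commercial calibration program is approximate by
  construction.
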