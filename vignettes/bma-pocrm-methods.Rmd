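---
title: "Dose finding under partial orderings: model selection versus model averaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose finding under partial orderings: model selection versus model averaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmapocrm)
```

## The problem

Phase I combination trials escalate two drugs at once.  Within either drug,
more is safely assumed to be more toxic; across diagonal moves (one drug up,
the other down) the toxicity ordering is unknown.  The admissible total
orderings of the dose grid form a *partial ordering*: a set of $M$ candidate
simple orderings, each a permutation of the $K$ combinations consistent with
single-agent monotonicity.

Under ordering $m$ the risk of a dose-limiting toxicity (DLT) at combination
$d_k$ is modelled by a one-parameter power curve through a fixed skeleton
$0 < \alpha_1 < \dots < \alpha_K < 1$ permuted by the ordering:

$$\psi_m(d_k, a) = \alpha_{m,k}^{\exp(a)}, \qquad a \sim N(0,\ 1.34),$$

where $\alpha_{m,k}$ is the skeleton value at the toxicity rank of $d_k$
under ordering $m$.  Given the binomial likelihood of the accumulated
per-dose counts $(n_k, y_k)$, each ordering has a marginal likelihood and a
posterior probability $p(m \mid \Omega_j)$; every design here allocates the
next cohort at $\arg\min_k |\hat R(d_k) - \theta|$ for a pre-set target
toxicity rate (TTR) $\theta$, and they differ only in how $\hat R$ is
formed:

* **Selection (POCRM)** picks $m^* = \arg\max_m p(m \mid \Omega_j)$,
  computes the posterior mean $\hat a_{m^*}$, and uses the plug-in curve
  $\psi_{m^*}(d_k, \hat a_{m^*})$.
* **Model averaging (BMA-POCRM)** pushes each ordering's posterior of $a$
  through $\psi_m$ to a posterior density of $R(d_k)$, mixes the densities
  with weights $p(m \mid \Omega_j)$, and uses the mixture mean.  By a
  change-of-order-of-integration identity this equals the
  posterior-weighted average of the per-ordering posterior means, which is
  how `bma_point_estimates()` computes it; `bma_zhang` keeps the re-ordered
  computation as a deliberately independent code path, and the test suite
  also verifies the mixture-density route by direct integration.
* **Recommendation averaging (`bma_wages`)** averages the per-ordering
  *recommended doses* instead: $\pi(d_k) = \sum_m p(m\mid\Omega_j)\,
  \mathbf{1}\{d_k \text{ recommended under } m\}$, allocating at
  $\arg\max_k \pi(d_k)$.  It produces no averaged toxicity curve, so the
  estimation diagnostics below do not apply to it.

## Estimation coherency

A new non-DLT at dose $d_i$ carries no evidence that any dose comparable to
$d_i$ became *more* toxic.  Writing $\nu_i$ ($\xi_i$) for the doses ranked
below (above) $d_i$ under **every** candidate ordering, an update is
*two-sided estimation coherent* when, after a non-DLT at $d_i$, no estimate
in $\nu_i \cup \xi_i$ rises, and after a DLT none falls; the one-sided
variant restricts to $\nu_i$ (non-DLT) or $\xi_i$ (DLT).
`detect_incoherencies()` audits single updates and `audit_trial()` whole
trials, flagging only moves beyond a threshold (default $0.001$) so that
quadrature noise is never reported as incoherency.

Selection designs violate this routinely: when the identity of the
maximum-posterior ordering flips, every estimate jumps between two
different plug-in curves at once.  Under an unchanged selected ordering the
single-model update is coherent, so every selection incoherency coincides
with an ordering switch — a mechanism the test suite verifies empirically
on thousands of randomized update paths.  Averaging smooths those
transitions; its incoherencies are rare and small.

## The worked example

`worked_example()` ships a 3×2 grid mid-trial: after 11 patients
(`n = (1,0,1,6,2,1)`, `y = (0,0,0,3,1,1)`, TTR 0.4) the selection design
recommends $d_2$; patient 12 is treated there without a DLT.  Because
$\nu_2 \cup \xi_2 = \{d_1, d_4, d_6\}$, none of those estimates should
rise — yet the selection design's $d_4$ estimate climbs from 0.486 to
0.556 (+0.07), because the selected ordering switches (from the 6th listed
ordering to the 5th).  The averaged estimates all move coherently, with
largest changes $-0.039$ ($d_2$) and $-0.016$ ($d_5$).

Two configuration details of this example deserve explanation:

* **Skeleton.**  The example uses `indifference_interval_skeleton(6,
  target = 0.4, halfwidth = 0.08, prior_mtd = 3)`, giving
  $(0.110, 0.241, 0.400, 0.554, 0.684, 0.783)$.  The halfwidth controls the
  skeleton's spread and hence how sharply the data can discriminate between
  orderings: a very tight skeleton (halfwidth 0.02 at this target gives
  steps of ~0.04) leaves the candidate orderings nearly
  likelihood-equivalent, ordering posteriors barely move, and neither the
  selection switch nor the diagnostic behaviour above is visible.  A
  halfwidth of 0.08 with the prior MTD mid-grid produces the informative
  setting in which these designs are genuinely stressed.
* **Tie-break.**  At the cohort-12 update the data at $d_2$ and $d_3$ are
  identical (one patient, no DLT each), so orderings that differ only by
  swapping those two doses have *mathematically equal* marginal
  likelihoods: the 3rd and 5th listed orderings tie exactly at the top of
  the posterior.  Ties are therefore resolved deterministically;
  the default keeps the **largest** ordering index (here the 5th), which is
  the resolution under which this example's estimate trajectory — in
  particular the $d_2$ drop of $-0.215$ — arises.  `tie_break = "first"`
  is available; the tie flag is returned so callers can log it.

The six candidate orderings for a 3×2 grid (by rows, by columns, and four
antidiagonal traversals) contain one duplicate; it is retained, so the
duplicated ordering carries double prior weight under uniform priors.
`partial_order_spec(..., dedup = TRUE)` collapses duplicates for
sensitivity analyses.

## Numerics

All posterior integrals run against the Normal prior, so the package uses
fixed-order Gauss–Hermite quadrature (151 nodes by default).  This is
deterministic, vectorises across orderings and doses (one likelihood
evaluation per node serves the marginal likelihood, the posterior mean of
$a$, and every per-dose posterior-mean toxicity), and agrees with adaptive
quadrature and a 10,001-point trapezoid oracle to ~$10^{-9}$ on trial-sized
data; the dual-route averaging checks pass at $10^{-8}$.  Marginal
likelihoods accumulate in log space with a max-shift, and probabilities are
clipped to $[10^{-12}, 1 - 10^{-12}]$ inside logarithms.  Partial-range
integrals (the mixture CDF behind credible intervals and overdose
probabilities) use adaptive quadrature instead, since a fixed full-axis
rule cannot honour a moving truncation point.

The skeleton recursion is solved in closed form (each step is one log
ratio); extreme configurations whose recursion saturates at 0 or 1 in
double precision are rejected with an error rather than returned.  The
`power_plain` parametrization ($\psi = \alpha^a$) is retained for the 2×2
theory checkers, whose algebra is written in that form; when it is used for
inference the prior mean should sit at 1 (the package does not silently
re-centre it).

## 2×2 coherency conditions

For the 2×2 grid with its two admissible orderings at equal prior weight,
closed-form sufficient conditions for path-wise estimation coherency are
implemented mechanically from their published statements
(`pocrm_2x2_condition()`, `bma_2x2_condition()`), returning all intermediate
quantities.  Two findings from exercising them numerically:

* The selection-design condition compares extrema of the candidate
  parameter sets $\mathcal A_1, \mathcal A_2$, which share two elements;
  the shared elements force $\min \mathcal A_2 \le \max \mathcal A_1$,
  while the inequality $\alpha_3^{\hat a_2^{\min}} \le
  \alpha_2^{\hat a_1^{\max}}$ requires the reverse whenever
  $\alpha_2 < \alpha_3$ strictly.  The condition is therefore unattainable
  for strictly increasing skeletons — consistent with how easily the
  selection design is driven incoherent — and the checker is exercised in
  tests as a mechanical implication (no satisfying configuration was found
  in $2\times10^4$ random draws, matching the argument above).
* The averaging-design condition is attainable (roughly 15% of random
  skeleton/truth draws).  For configurations satisfying it, exhaustive
  enumeration of **all** $2^6$ outcome paths of a six-patient trial finds
  zero averaged-design incoherencies, as the theory demands.
* One intermediate term of the averaging condition references a parameter
  maximum whose printed index falls outside the two-ordering setting; by
  the pattern of the neighbouring terms the package reads it as the
  ordering-1 maximum (`u4_hat = "a1max"`), with the alternative reading
  available as an explicit switch rather than a silent correction.

When both designs are incoherent at the same update, the averaged
magnitude is bounded by the selection magnitude times
$1 / (1 - \log \alpha_K)$; `magnitude_bound_check()` verifies this on
paired events and the simulation tests confirm zero violations.

## Simulation engine and scenario generator

`run_trial()` pre-draws a Bernoulli outcome stream per dose, so the $j$-th
patient ever assigned a dose receives that stream's $j$-th entry.  Running
several designs on the same streams (as `compare_designs()` does) exposes
them to identical patient responses — common random numbers — which makes
design contrasts fair and reduces Monte Carlo variance.  Everything is
reproducible from a single integer seed.

Operating characteristics follow the field's conventions: PCS counts
recommendations whose true toxicity **equals** the TTR exactly (scenarios
are built to contain exactly one such dose, and equality is tested at
$10^{-9}$); PAS uses the deliberately asymmetric window
$[\theta - 0.1,\ \theta]$ (a dose slightly above target is not
"acceptable"); a dose is overly toxic when its true rate exceeds
$1.1\,\theta$, feeding POTS and NPTOT; incoherency statistics use the
0.001 threshold above.

`generate_scenarios()` draws monotone toxicity surfaces by cumulative
positive increments along both margins, then rejection-samples for the
requested structure: families with exactly 0, 1 or 2 candidate orderings
that rank-sort the truth (duplicates counted separately), an all-toxic
family (minimum above $1.1\theta$) and an all-safe family (maximum below
$\theta$, hence PCS must be 0).  On the 3×2 grid the recommended candidate
set spans *every* admissible ordering, so the zero-correct family cannot
exist there and the generator refuses it; it is available on larger grids
(for example 3×3).  The generator emulates smooth monotone dose-toxicity
surfaces only; it does not model patient heterogeneity, late-onset
toxicity, or misclassified outcomes, so passing tests speak to design
behaviour under the assumed Bernoulli model, not to robustness against
those features of real data.

The shipped tests run at reduced scale, chosen to exercise the claims
without needless repetition: the directional comparison (averaging
incoherent less often than selection on every scenario) uses four 3×2
scenarios (one-correct, two-correct, all-toxic, all-safe) at 500
replicates of 18 single-patient cohorts with a TTR of 0.3 and a
`halfwidth = 0.07, prior_mtd = 2` skeleton; the update-path properties use
1,000 seeded 2×2 trials of 10 patients under the plain parametrization
(prior mean 1) with a `target = 0.35, halfwidth = 0.12` skeleton — a
spread at which ordering switches actually occur, since very tight 2×2
skeletons produce almost no detectable jumps.  Trials start at $d_1$ and
apply the pure allocation criterion; a no-skipping clamp (at most one
untried level per drug margin) is available via
`design_config(allow_skipping = FALSE)` but is off by default, and no
stopping rule beyond the fixed cohort count is applied — safety stopping
belongs to the protocol layer, not the estimator.

## Replaying a completed trial

`build_response_streams()` turns a per-dose summary $(n_j, y_j)$ of a
finished study into fixed response streams: the first $n_j$ entries are a
seeded permutation of the outcomes actually observed, the remainder
Beta–Bernoulli imputations from $\mathrm{Beta}(1 + y_j,\ 1 + n_j - y_j)$
(never-assigned doses use the symmetric $\mathrm{Beta}(3,3)$).  The
published description of the imputation is ambiguous between drawing one
rate per dose and one per synthetic patient; the package defaults to a
fresh draw per patient (`beta_draw = "per_patient"`), which propagates the
posterior uncertainty of the dose's rate into every imputed outcome, and
exposes `"per_dose"` as the alternative.  `replay_trial()` then enters any
fixed run-in cohorts before the first model update and proceeds
model-guided, so different designs replayed on the same streams face
identical patients.  No real trial data ship with the package; users supply
their own summary table (`read_trial_summary()`).

## Known limitations

* Single-agent and two-agent partial orders only; no dose–schedule or
  three-agent orderings, and no posterior-threshold pruning of orderings.
* One-parameter working models only; with a single parameter,
  deterministic quadrature dominates MCMC in both speed and
  reproducibility, so no sampler is provided.
* The closed-form coherency conditions are specific to the 2×2 grid.
* Operating characteristics at full publication scale (tens of thousands
  of replicates over large scenario batteries) are a matter of compute
  budget, not code: the same functions scale by raising `n_reps`.
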