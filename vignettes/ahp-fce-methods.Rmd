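---
title: "Hierarchical AHP–FCE evaluation: model, conventions and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical AHP-FCE evaluation: model, conventions and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ahpfce)
```

## The evaluation model

`ahpfce` scores a multi-level indicator system rated by an expert panel.
The ingredients are:

* a **factor set** `U`: a rooted indicator hierarchy with a goal node,
  criterion nodes and leaf indicators (`indicator_hierarchy()`);
* an **evaluation set** `V`: ordered grades with numeric values, by
  default five grades scored 1–5 (`rating_scale()`);
* an **expert panel**: one Likert rating per expert per leaf, missing
  cells allowed (`expert_panel()`);
* **weights** `W` over every sibling group, from the entropy weight
  method, from AHP pairwise comparison, or a convex combination of the
  two (`fit_weights()`).

The fuzzy comprehensive evaluation chain is then

1. **Membership estimation** — for each leaf, the membership degree of a
   grade is the fraction of responding experts who chose it:
   `r[leaf, g] = n(leaf, g) / n(leaf)`. This is the purely
   frequency-based membership matrix `R`; no parametric membership
   functions are involved.
2. **Synthesis** — a group's evaluation vector is `A = W·R`, the
   weighted average of its members' grade distributions. We use the
   weighted-average operator because the scoring rule `P = W·R·V` is an
   ordinary matrix product; the max–min composition of classical fuzzy
   synthesis is available behind `synthesize(..., operator = "maxmin")`
   for comparison but is not the default, since it discards most of the
   panel's information and does not reproduce weighted-mean scores.
3. **Defuzzification** — `P = A·V`, the expectation of the grade values
   under `A`, a score on the 1–5 scale.
4. **Aggregation** — the chain is applied recursively: leaf vectors are
   membership rows, internal vectors are syntheses of child vectors
   under the group's normalized weights, up to the root
   (`aggregate_hierarchy()`). A fixed-score variant
   (`aggregate_fixed_scores()`) takes published scalar sub-scores for a
   sibling group and returns their weighted sum; it exists because
   evaluation reports often print dimension scores without the
   underlying membership rows, and the two routes are *not* forced to
   agree (coarsened dimension scores generally differ from full
   bottom-up aggregation — in the bundled case study the published
   dimension route gives 3.63 while the one branch that can be
   re-aggregated from printed rows gives 3.57).

Grade reporting follows two conventions at once: the raw score is
bracketed by its adjacent scale labels (a 3.63 lies between "average"
and "important"), and the min–max normalized score is bucketed into five
performance bands on [0, 1] — poor, average, medium, good, excellent —
each lower-inclusive, the top band closed at 1. The bands live on the
normalized axis because band boundaries are conventionally quoted on
0–1 while scores live on 1–5.

## Weighting methods

**Entropy weights** (`entropy_weights()`) measure how much an indicator
discriminates between observed items. Columns are min–max normalized
(`minmax_normalize()`, mirrored for negative-direction indicators),
proportions `P_ij = Y_ij / Σ_i Y_ij` are formed, the information entropy
is `E_j = -(1/ln n) Σ_i p_ij ln p_ij`, and weights are
`W_j = (1 - E_j) / (k - Σ E)`. Numerical conventions:

* `0·ln 0 := 0`, the standard continuity convention;
* a constant column is normalized to all 0.5 and assigned `E_j = 1`
  (weight exactly 0) with a warning — an indicator with no variation
  carries no information, and this avoids a 0/0;
* entropies are clamped to [0, 1] against roundoff;
* if every column is constant the method has no information at all and
  errors rather than returning arbitrary weights.

**AHP weights** (`principal_weights()`) are the normalized principal
right eigenvector of a positive reciprocal judgment matrix, computed by
power iteration (tolerance 1e-10 on the weight vector, capped at 10,000
iterations; non-convergence is an error, not a silent fallback). The
consistency test is the standard one: `CI = (λ_max − n)/(n − 1)`,
`CR = CI / RI(n)` with Saaty's random-index table (0, 0, 0.58, 0.90,
1.12, 1.24, 1.32, 1.41, 1.45 for n = 1…9), accepting `CR < 0.1`. For
n ≤ 2 a reciprocal matrix is always consistent and `CR` is defined as 0.
The geometric-mean row estimator is offered as
`method = "geometric"`; the eigenvector is the default because it is the
estimator the CR test presumes. In tests the implementation is
cross-checked against a dense eigensolver, which is never used as the
implementation itself.

When individual judgment matrices are unavailable and only Likert means
are, `likert_to_pairwise()` builds a judgment matrix from mean-rating
differences: `d = round(mean_i − mean_j)` clipped to [−4, 4], mapped
through |d| → 1, 3, 5, 7, 9 with reciprocals for negative `d`. This map
is a documented convention, not a community standard — surveys rarely
state how a Likert instrument became a pairwise matrix — so the map is a
parameter. It is monotone, reciprocal by construction, and spans the
full Saaty scale at the maximal 4-point spread.

`combine_weights()` mixes two weightings of the same group as
`α·w_a + (1−α)·w_b`, renormalized; `α` has no privileged default beyond
0.5 and is a modelling choice for the user.

## Robustness suite

**Sensitivity** (`sensitivity_perturb()`, `sensitivity_sweep()`)
multiplies one weight by `(1 ± δ)` and renormalizes the whole vector
before recomputing the composite. Renormalization is part of the
semantics: weights are shares of a unit budget, and perturbing a share
by ±10% without renormalizing would conflate a weight change with a
change of the total — for the bundled case study it would inflate the
apparent effect by an order of magnitude.

**Resampling stability** (`bootstrap_stability()`) draws groups of
experts without replacement (default 10 groups at fraction 0.8),
rebuilds `R` and the composite per group, and reports
`max |group − full| / full`. The fraction is a convention exposed as a
parameter; a draw that silences an indicator entirely is redrawn within
a bounded retry budget. All draws flow through one seeded generator, so
results are bit-reproducible given the seed.

**Reliability** (`cronbach_alpha()`) is the classical
`α = k/(k−1) · (1 − Σ s²_item / s²_total)` with n−1 variances over
complete rows.

## The synthetic-data generators

`generate_panel()` draws each expert × leaf rating independently from a
per-leaf **consensus distribution** over the grades, thins cells to a
per-leaf response rate, and attaches profiles drawn from a workplace
stratum mix. The consensus vectors are exactly the object the
membership stage estimates, so parameter recovery is a direct test: at
5,000 experts the seed-averaged empirical membership matrix recovers the
consensus to within 0.02 in every cell, and composite scores converge to
the analytic `W·(consensus)·V` value.

The default `jilin_panel_spec()` mirrors the bundled case study's
conditions: 33 experts over 18 leaves; the five government-regulation
leaves use the published membership rows as consensus with response
rate 17/33 (the published rows are consistent with 17 respondents per
indicator, while the panel had 33 — the package therefore treats
missing cells as first-class rather than guessing who answered what);
the remaining blocks use smooth unimodal profiles centred on their
published dimension scores (mean 3.0 for the corporate-responsibility
block, 3.5 for testing and participation). Strata default to the
15/8/6/4 composition stated in the study's sample description; note the
published expert roster itself tabulates to 12/7/6/8, an internal
inconsistency of the source we preserve as-is on the fixture side.

What the generator deliberately does **not** model: correlation between
an expert's ratings across indicators (no expert-level trait), covariate
effects of education or experience, and within-panel rating dependence.
Consequently Cronbach's α on a synthetic panel is near zero by
construction — passing pipeline tests say nothing about the internal
consistency of any real questionnaire, and the published α = 0.875 is
not a reproducible quantity from printed data.

`generate_raw_matrix()` draws indicator columns log-normally with
`sdlog` equal to a per-indicator dispersion parameter, so dispersion
controls the inequality of the column — the feature entropy weighting
rewards; dispersion 0 produces the constant column that exercises the
degenerate-input policy.

## Numerical conventions and degenerate inputs

* Weight vectors are normalized at construction and checked to sum to 1
  within 1e-9; membership rows within 1e-5 (accommodating values
  transcribed at 6 printed decimals, whose sums can be off by 1e-6);
  evaluation vectors are closed to exactly 1 at the synthesis boundary.
* Published tables are stored verbatim in the fixture; normalization
  happens at use, never at storage, so the fixture reproduces printed
  values to their printed precision.
* Hierarchies must have all leaves at one uniform depth. This admits
  both two-level (goal + indicators) and three-level trees while
  rejecting ragged ones, where "the leaves of level 2" and "the nodes
  with no children" would diverge and group weights become ambiguous.
* Grade bands are lower-inclusive with the top band closed at 1, so
  every normalized score belongs to exactly one band.
* Membership reports are written at 6 decimal places, matching the
  precision evaluation studies typically print.

## Problem sizes used in the test suite

Unit and property tests run on small randomized instances (matrices up
to 6×6, panels of 12–40 experts, 10 bootstrap groups); the parameter-
recovery checks use panels of 2,000–5,000 experts averaged over three
seeds, which bounds the Monte-Carlo error of a membership cell well
below the 0.02 acceptance band. These sizes were chosen so the full
suite exercises every convergence claim while remaining quick enough to
run on every change.

## Known limitations

* The Likert→pairwise map loses information relative to eliciting full
  individual judgment matrices; group AHP by geometric mean of expert
  matrices is out of scope.
* The fixed-score aggregation route and full bottom-up aggregation are
  both provided but cannot be reconciled without the full membership
  matrix, which published reports rarely print; the bundled case study's
  exact total (3.6363) is therefore not a derivable target from its
  printed tables.
* Membership estimation is purely frequency-based; with very few
  respondents per indicator the rows are coarse (multiples of 1/n), and
  no smoothing is applied.
* The resampling procedure's published form ("average deviation rate of
  10 groups", ±3.5%) under-specifies the resample fraction and the
  deviation statistic; the package documents its own convention (max
  relative deviation, fraction 0.8 without replacement) and treats the
  published band as context, not as a target.
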