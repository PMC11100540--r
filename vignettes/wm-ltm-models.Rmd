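---
title: "Models of working memory and episodic long-term memory interplay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models of working memory and episodic long-term memory interplay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmltm)
```

## The scientific problem

Working memory (WM) holds a handful of bindings — word–word pairs, or
colour–object conjunctions — for immediate use. Episodic long-term
memory (LTM) stores such bindings durably. When people are first
familiarised with some pairs and then perform a WM task that mixes
pre-learned and novel pairs, performance can reveal *when* WM draws on
the LTM traces: pre-learned pairs whose current pairing matches the
stored one can help (proactive facilitation, PF), and pairs whose
current pairing contradicts the stored one can hurt (proactive
interference, PI). If WM is shielded from LTM at low memory load, PF
and PI should appear only once the load exceeds WM capacity.

`wmltm` implements the full inferential pipeline for this question:
generative simulators of four experimental designs, the two Bayesian
hierarchical models used to analyse them, Bayes-factor machinery for
the focal hypotheses, and an end-to-end parameter-recovery harness.
Because trial-level human data are not packaged, every claim the
package makes is validated by *parameter recovery on synthetic
cohorts*: simulate data with known parameters, fit the matching model,
and check that the truth is recovered.

## The simulated designs

Four designs are built by `build_design()`:

* **E1** crosses WM load (new pairs: 0, 2, 4, 6) with LTM load
  (pre-learned pairs: 0 or 2) in six conditions (2+0, 4+0, 6+0, 0+2,
  2+2, 4+2), 15 trials per condition spread one-per-block over 15
  blocks (90 WM trials). Each of the two learning phases presents 90
  word pairs. Retrieval is a four-alternative forced choice (4AFC)
  among target, within-trial intrusion, LTM lure, and new item; every
  pair of every trial is tested.
* **E2** removes the 2+2 condition so that all set-size-4 trials are
  unambiguously "pure WM" (75 trials). The design text specifies only
  the dropped condition; we keep 15 trials per remaining cell as the
  minimal change from E1.
* **E3** crosses set size (2, 3, 4) with pair type (new–new,
  old–match, old–mismatch). The admissible per-trial compositions are
  the seven rows returned by `trial_compositions()`; each block of 9
  trials contains one trial per set-size-2 row, three of the single
  set-size-3 row and one per set-size-4 row — 3 trials per set size
  per block, 27 trials over 3 blocks. 54 pairs are pre-learned.
* **E4** uses the same set-size/pair-type structure with colour–object
  conjunctions: 120 conjunctions pre-learned in groups of 10, then 9
  blocks of 9 trials (81 trials). Colours live on a 360-point wheel on
  a circle in CIELAB space (centre L = 70, a = 20, b = 38, radius 60;
  `build_color_wheel()`), and retrieval is continuous reproduction:
  the response is an angle, scored as the signed circular deviation
  from the studied colour.

The simulators emulate the *category and angular structure* of the
data: response categories driven by per-condition propensities
(`simulate_choice_responses()`) and response angles driven by an
explicit mixture process (`simulate_repro_responses()`). They do not
emulate response times, lexical or image content (stimuli are opaque
identifiers), learning dynamics within the familiarisation phase, or
presentation timing (carried only as design constants). Passing tests
therefore show that the *inferential machinery* is correct and well
calibrated at the study's design sizes — not that any particular
psychological claim holds in real data.

A hierarchical generative layer (`simulate_population()`) draws
participant-level parameters as normal deviations around group means
on the unconstrained scale (logits for probabilities, log for the von
Mises precision), mirroring the hierarchy the fitting modules assume,
and returns the ground truth alongside the data.

### Generator defaults

`default_group_params()` fixes the reference cohorts used in the
recovery studies. Accuracy falls with total load (e.g. 95% at 2+0 to
62% at 6+0 in E1-style cohorts); in E3-style cohorts PF/PI are absent
at set size 2 and grow with set size; in E4 cohorts the LTM-intrusion
mixture weight is at its floor everywhere except old-mismatch pairs at
set size 4, and precision falls with set size (kappa 16/13/10).
Between-participant dispersion is 0.5 on the accuracy logit and 0.4 /
0.2 on the mixture logit / log-kappa scales — typical magnitudes for
individual differences in such tasks. These values were chosen once,
to mirror the qualitative result structure the designs were built to
detect, and are not tuned thereafter.

## The aggregated binomial logistic model (E1–E3)

Accuracy is analysed at the level of participant × design cell counts:
`k` correct responses out of `n` retrievals (`aggregate_cells()`),
modelled as Binomial with a logit link — an aggregated logistic mixed
model. The logit link both constrains predicted probabilities to (0,1)
and improves sensitivity near ceiling or floor.

Fixed effects are the full factorial of the design factors under
sum-to-zero contrasts, so a coefficient of zero means "no effect" and
the Savage-Dickey density ratio applies directly. Coefficients get
Normal(0, 1) priors; the intercept, which encodes overall performance
rather than an effect, gets Normal(0, 1.5). Every participant receives
correlated random deviations on all fixed-effect columns (the maximal
random-effects structure), with a Wishart prior (identity scale,
q + 1 degrees of freedom) on the random-effect precision matrix — the
standard parameterization for the Gibbs sampler used.

Two design wrinkles deserve note:

* The E1/E2 layouts observe only 6 of the 8 WM-load × LTM-load
  factorial cells, so the interaction is not fully estimable. The
  cell-level design matrix is reduced to a full-rank column set by
  pivoted QR, and all focal hypotheses are expressed as *cell-mean
  contrasts* (`contrast()`, `pf_pi_contrasts()`), which are invariant
  to the coding. The same route sidesteps the question of how to
  parameterize the 0+2 cell (WM load 0).
* WM load is treated as categorical throughout: the designs test
  level-specific comparisons (e.g. LTM load 0 vs 2 at WM load 2), not
  a linear trend.

Sampling runs through JAGS (4 chains × 2000 warmup + 3000 retained by
default). Convergence is assessed by split-chain R-hat < 1.01 on all
fixed effects; failure raises a warning and is recorded in the
returned `convergence_report`, never silently accepted.

Because a cell-mean contrast is linear in the coefficients, its
induced prior is normal with an analytically known SD; `bf_contrast()`
uses that for exact Savage-Dickey priors rather than simulating them.

## The hierarchical von Mises mixture model (E4)

A continuous reproduction response can come from four sources: the
target's colour, another colour from the same trial (swap), the
pre-learned LTM colour (intrusion), or guessing. The per-degree
density of a response `y` is

```
P_M  · vM(y; target, kappa)
+ P_Swap · mean over other items of vM(y; item, kappa)
+ P_LTM  · vM(y; ltm_colour, kappa)
+ P_G / 360
```

with a single von Mises precision `kappa` per set size shared by all
three memory components (the minimal parameterization; nothing in the
design identifies separate precisions). Angles are kept in degrees on
[-180, 180) — the wheel's native scale, under which the guessing
density is exactly 1/360 — and converted to radians only inside the
von Mises mathematics. `kappa = 0` is permitted and reproduces the
uniform density, so the guessing component shares the same code path.

Old-mismatch pairs carry their true pre-learned colour as
`ltm_colour`. New–new and old–match pairs receive *imaginary* LTM
colours drawn uniformly on the wheel
(`assign_imaginary_ltm_colors()`): participants never saw these, so
the fitted P_LTM in those cells is a floor/baseline, and the
LTM-intrusion test (`ltm_intrusion_test()`) is the contrast
P_LTM(old-mismatch) − P_LTM(new–new) at each set size.

Component probabilities are parameterized by SoftMax with the guessing
logit pinned at 0 for identifiability (any reference choice gives the
same probabilities); three free logits per set-size × pair-type cell.
Participants deviate from the group by additive normal effects on each
of the three component logits and on log-kappa — one deviation per
parameter *type*, shared across cells. This is the package's reading
of "participant-level deviations on all parameters": it covers every
parameter type while keeping the participant model identified at 81
trials per person. Priors: Normal(0, 1) on group logits,
Normal(log 10, 1) on group log-kappa, half-Normal(0.5) on the four
deviation SDs; all overridable via `mixture_priors()`.

### Sampling

The mixture is marginalised over components (no latent assignment
variables) and sampled by an adaptive Metropolis-within-Gibbs scheme
written in C++: component-wise random-walk updates with Robbins-Monro
scale adaptation towards 44% acceptance during warmup, frozen
afterwards. Two extra move types fix the geometry that plain
component-wise updates handle poorly:

* a joint rescaling of each deviation SD together with all its
  deviations (a funnel-traversing move whose Metropolis ratio carries
  the transformation Jacobian), and
* a likelihood-invariant translation that shifts all deviations of one
  type by δ while subtracting δ from the matching group parameters,
  accepted on the prior ratio alone — decorrelating group levels from
  the deviation mean.

Bessel functions are evaluated in exponentially scaled form so the
density is stable for large kappa; the mixture density is floored at
1e-300 before taking logs. Convergence is assessed by split-chain
R-hat < 1.01 over all group- and participant-level parameters, again
reported and never silently accepted.

## Evidence

All inferential claims reduce to Bayes factors computed from posterior
draws:

* `savage_dickey_bf()` — point-null BF10 as prior/posterior density at
  0. The posterior density at 0 is estimated by a normal approximation
  from the draws' mean and SD (the default; accurate for the
  near-Gaussian logit-scale marginals this package produces) or by a
  Gaussian kernel-density estimate. Both estimators are gated by a
  conjugate normal oracle test. A nonpositive density estimate raises
  an error rather than returning an infinite BF.
* `directed_bf()` — directed hypotheses as the ratio of posterior
  *mass* in the expected direction to the mass against, by draw
  counting; an empty minority is reported as a bound (BF ≥ number of
  draws), not a point value.
* `classify_bf()` — the BF > 3 convention: substantial evidence for
  the effect above 3, for the null below 1/3, inconclusive between.

## Screening and description

`screen_participants()` implements three deterministic exclusion
rules: delayed-test accuracy strictly below the task's chance level
(25% for 4AFC, 1/3 for 3AFC — both exposed because the verbal designs
use both test formats); overall accuracy strictly more than 2 SDs
below the cohort mean, iterated to a fixed point so screening is
idempotent; and learning-phase mean recall error within ±5° of the
90° chance level ("did not learn"), the band being configurable since
the criterion is stated only as "approximately 90°".

`within_subject_ci()` computes condition-mean intervals after
participant-centring with the Morey bias correction
`sqrt(C / (C − 1))`: between-participant level differences are removed
(adding a constant to one participant's means changes nothing), and a
cohort whose participants share one condition profile yields
zero-width intervals. `describe_dataset()` reports per-condition
accuracy or mean absolute recall error with these intervals.

## Numerical conventions

* Angles: half-open degrees [-180, 180); `wrap_angle(180)` is -180.
* Expected absolute circular error of uniform responding is exactly
  90°, the chance anchor for continuous reproduction; 4AFC chance is
  25%.
* HDIs are the narrowest contiguous window over the sorted draws;
  posterior summaries require at least 100 draws, Bayes factors at
  least 1000.
* Von Mises sampling uses the Best–Fisher rejection method, validated
  against the density by a mean-resultant-length check.
* Every exported stochastic function takes an explicit seed, derives
  internal stream seeds by hashing (seed, stream-label) pairs, and
  restores the caller's RNG state, so runs are reproducible end to
  end and nearby seeds give unrelated streams.

## Problem sizes

The packaged recovery studies use the designs' own trial counts with
cohorts of the order the studies used: 25–30 participants for the
choice models and 30 participants × 81 trials for the mixture model,
with 2 chains and several hundred to ~1600 retained draws per fit —
sizes at which the reference parameters are recovered within ±0.07
(probabilities) and ±25% (kappa) and null effects produce median
BF10 < 1. The paper-scale sampler settings (4 × 2000 + 3000) remain
the defaults for real analyses.

## Known limitations

* **The guessing corner is not identified.** Data generated by
  (almost) pure guessing can be explained either by a large P_G or by
  near-zero precision with arbitrary mixture weights; both predict
  uniform responding. Under the package's priors the low-precision
  explanation is cheaper (driving P_G toward 1 costs three logits
  several prior SDs each), so the fitted *decomposition* at this
  corner follows the priors even though the fitted *predictive*
  correctly sits at the 90° chance level. The tests therefore check
  the predictive implication at that corner. Away from the corner —
  e.g. at the reference point P_M = 0.7 — the decomposition is well
  identified and recovery is clean.
* Swap and guessing trade off at moderate precision when trials have
  few items, which inflates the posterior spread of P_Swap and P_G
  relative to P_M.
* Normal(0, 1) logit priors mildly shrink extreme probabilities
  toward the centre at small cohorts; this is visible as a downward
  bias of a percentage point or two for probabilities near 0.9.
* The E3 learning test is described as three-alternative in one place
  and referenced against 4AFC chance in another; both chance levels
  are implemented and the choice is explicit in `chance_level()`.
* The mixture hierarchy places deviations per parameter type, not per
  cell; cohorts with strong participant × condition interactions
  would violate this assumption.
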