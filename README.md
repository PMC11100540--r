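# wmltm

Hierarchical Bayesian models of the interplay between working memory
(WM) and episodic long-term memory (LTM) in paired-associate tasks —
with generative simulators that make the whole pipeline testable by
parameter recovery, no human data required.

## The problem

When people first memorise a set of pairs (word–word, or
colour–object) and later hold a mixture of pre-learned and novel pairs
in a WM task, pre-learned material can help or hurt: *proactive
facilitation* (PF) when the current pairing matches the stored trace,
*proactive interference* (PI) when it mismatches. Whether those
effects appear at low memory load tells us whether WM is shielded from
LTM until its capacity is exceeded. `wmltm` is for researchers who
want to simulate such designs, fit the standard models, and check —
before touching real data — that the inference chain recovers known
truths at realistic design sizes.

## What is in the package

**Simulators** for four designs: crossed WM load × LTM load 4AFC
word-pair tasks (E1: 90 trials in 15 blocks, 6 conditions; E2 drops
the 2+2 condition), and set-size × pair-type designs (new–new /
old–match / old–mismatch) for word pairs (E3: 27 trials, 3 blocks) and
colour–object conjunctions on a 360-colour CIELAB wheel (E4: 81
trials, 9 blocks, 120 pre-learned conjunctions). A hierarchical
population layer returns data plus ground-truth parameters.

**Choice model.** Accuracy in E1–E3 is modelled as an aggregated
logistic mixed model: for participant *s* in design cell *c*,

    k_sc ~ Binomial(n_sc, p_sc),   logit(p_sc) = x_c' (beta + b_s)

with sum-to-zero factorial fixed effects, Normal(0, 1) coefficient
priors (Normal(0, 1.5) intercept) and maximal correlated
by-participant random effects; sampled via JAGS.

**Mixture model.** Continuous reproduction in E4 is modelled by a
hierarchical four-component von Mises mixture: each response comes
from the target (probability P_M), another item from the trial
(P_Swap), the pre-learned or imaginary LTM colour (P_LTM), or uniform
guessing (P_G), with one precision kappa per set size:

    f(y) = P_M vM(y; target, kappa) + P_Swap mean_j vM(y; item_j, kappa)
         + P_LTM vM(y; ltm, kappa) + P_G / 360

Probabilities are SoftMax-linked (guess logit pinned at 0) and vary by
set size × pair type; participants deviate normally on each component
logit and on log-kappa. The sampler is a purpose-built adaptive
Metropolis-within-Gibbs scheme in C++ with funnel-rescaling and
translation moves.

**Evidence.** Savage-Dickey density-ratio Bayes factors (analytic
induced priors for cell-mean contrasts), directed Bayes factors by
draw counting, and the BF > 3 classification rule. Convergence is
assessed by split-chain R-hat < 1.01 and always reported.

**Screening and description.** The designs' exclusion rules
(below-chance delayed test, > 2 SD below the cohort mean, at-chance
learning), and Cousineau–Morey within-subject confidence intervals.

## Worked example

Simulate an E3-style cohort of 120 participants whose generating
parameters contain no PF/PI at set size 2 and real effects at set size
4, fit the choice model, and test the focal contrasts:

```r
library(wmltm)
cfg <- recovery_config(experiment = "E3", n_participants = 120, seed = 42,
                       chains = 4, warmup = 2000, samples = 3000)
report <- run_recovery_study(cfg)
print(report)
#> Recovery study: E3, 120 participants, seed 42
#>   max R-hat: 1.0342 | mean |bias|: 0.0112 | coverage: 100%
#> # A tibble: 6 × 4
#>   contrast                           type                bf10 classification
#>   <chr>                              <chr>              <dbl> <chr>
#> 1 PF (old_match - new_new) at SS2    savage_dickey     0.0952 substantial_for_null
#> 2 PI (old_mismatch - new_new) at SS2 savage_dickey     0.0772 substantial_for_null
#> 3 PF (old_match - new_new) at SS3    savage_dickey     1.43   inconclusive
#> 4 PI (old_mismatch - new_new) at SS3 savage_dickey     1.26   inconclusive
#> 5 PF (old_match - new_new) at SS4    savage_dickey 43022.     substantial_for_effect
#> 6 PI (old_mismatch - new_new) at SS4 savage_dickey 97571.     substantial_for_effect
```

Read this as the pipeline reproducing the structure it was given: at
set size 2 the Bayes factors favour the *null* (BF01 ≈ 11 and 13 — no
facilitation, no interference), at set size 3 — where the generating
effects are small — the evidence is inconclusive, and at set size 4
both effects are decisively detected (BF10 in the tens of thousands).
Cell accuracies are recovered with mean absolute bias 0.011 and every
95% interval covers its generating value; `report$recovery` holds the
cell-by-cell table. One fixed-effect coefficient retains a split
R-hat of 1.03 at these settings; the fit warns about it, and the
contrasts are stable across independent reruns.

The same harness runs the E4 mixture model (`experiment = "E4"`),
reporting recovery of P_M, P_Swap, P_LTM, P_G and kappa per design
cell plus the LTM-intrusion contrasts.

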