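---
title: "Modelling gene-family gain, loss, and size evolution on a time-calibrated species tree"
author: "GeneFamEvo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling gene-family gain, loss, and size evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GeneFamEvo)
```

## What the package models

GeneFamEvo analyses the evolution of gene families (orthogroups) across a
rooted, time-calibrated species phylogeny, with branch durations in
millions of years (My). It takes the two standard products of an
orthology inference run — a species tree and an orthogroup-by-species
gene-count table — and answers three families of questions:

1. **Where did each gene family originate, and where was it lost?**
   (Dollo parsimony reconstruction with per-node accounting.)
2. **How fast do family sizes evolve, and do designated branches — for
   example branches leading to giant-bodied lineages — evolve faster?**
   (A birth–death model of family size with per-branch-class rates, a
   parametric-bootstrap likelihood-ratio test, exact per-branch shift
   tests, and branch-wise rates.)
3. **Are families that shifted on a focal branch set enriched for a gene
   label of interest (e.g. cancer-gene orthology), beyond what random
   branch sets produce, and does the label interact with the branch set
   in the per-branch rates?** (Exact 2×2 tests, a branch-set permutation
   null, and a random-intercept interaction model.)

Every stage can be exercised on data from the bundled synthetic
generator, which shares its generative law with the fitted model so that
parameter-recovery tests isolate the estimator.

## Dollo reconstruction

Each family is assumed to originate exactly once and to be lost any
number of times. Presence in a species means a count of at least one; no
abundance weighting is applied. Under this cost regime (a second gain is
never allowed), the minimum-loss placement of the origin is the MRCA of
the species possessing the family: placing the origin any deeper can only
add losses, and no shallower node covers all possessing tips. A node is
then present iff it lies in the origin's subtree and at least one tip
below it retains the family, and the loss events are exactly the maximal
absent subtrees. The suite verifies this against exhaustive enumeration
of all single-gain histories on every rooted topology of up to six tips.

Two caveats are worth stating plainly:

* **Origins cannot be seen beyond the root.** A family present in the
  root's two oldest subclades is assigned to the root even if it is in
  fact older; with no outgroup there is no signal for a deeper origin.
* **The MRCA placement is biased downward under heavy loss.** If a whole
  flank of the true origin's subtree loses the family, the MRCA of the
  survivors is a strictly lower node. The probability of exact origin
  recovery is therefore roughly `1 - 2p` per origin for per-branch loss
  probability `p`, not `1`. The recovery test consequently demands ≥ 99%
  exact recovery only at sparse loss (`p = 0.002`) and, at `p = 0.15`,
  checks the weaker (always true) property that the inferred origin lies
  inside the true origin's subtree.

Per-node accounting reports, for every branch: families present at the
child node, families that originated on the branch (*novel*), families
lost on the branch (total and stratified by the origin node of the lost
family), losses unique to that branch tree-wide (*unique lost*), families
conserved in every descendant tip (*core*), and novel-and-core families.
The flow identity `total(child) = total(parent) − lost + novel` holds on
every branch and is asserted on every synthetic run. Because a published
figure may count either families or (family, branch) loss events per
cell, both the per-branch totals and the per-origin stratification are
emitted.

Polytomies are rejected at load by default; if allowed, each child of a
polytomy is treated independently, which preserves the flow identity but
makes "sister branch" notions ambiguous — use with care.

## Representative annotation and enrichment

A family inherits an annotation term iff at least 75% of its proteins
carry the term **and** at least 75% of its taxa have at least one
annotated protein (both thresholds inclusive and configurable; singleton
proteins can be promoted to single-protein families). Terms are opaque
strings: no ontology graph propagation is attempted, so GO parents and
children are distinct labels.

The 2×2 exact test reports the two-sided p-value under the
probability-ordering rule (the sum of hypergeometric point probabilities
not exceeding that of the observed table, the convention of the standard
R implementation) — mid-p or doubling conventions can differ in the third
decimal. The reported odds ratio is the *sample* odds ratio `ad/bc`, with
a 0.5 continuity correction on all cells when any cell is zero; it is
reproducible without iterative estimation, but note that published odds
ratios computed as conditional maximum-likelihood estimates can differ
slightly. Benjamini–Hochberg adjustment is applied within each
comparison (one branch × one annotation type), never across comparisons.
The enrichment universe is whatever the caller supplies — all families,
or only annotated families — because either choice is defensible and
published analyses rarely state which was used.

## The birth–death model of family size

Family size evolves along each branch by a linear birth–death process
with equal per-gene birth and death rate λ (gains/losses per gene per
My). With `α = λt/(1 + λt)` for a branch of duration `t`, the transition
probability from parent size `s ≥ 1` to child size `c` is

$$P(c \mid s) = \sum_{j=0}^{\min(s,c)} \binom{s}{j}\binom{s+c-j-1}{s-1}
\alpha^{s+c-2j}(1-2\alpha)^{j},$$

and size 0 is absorbing. A single rate governs both gains and losses;
separate birth and death rates, among-family rate variation, and an
annotation-error component are out of scope. Terms are evaluated in log
space; when `λt > 1` (so `1 − 2α < 0`) the terms alternate in sign and a
signed summation is used. The kernel is truncated to sizes `0..sMax`
(default 100, matching the input filter that drops families exceeding
100 copies in any species) and rows are renormalised, with the
pre-renormalisation deficit retained for monitoring; the suite checks
that the untruncated rows are stochastic and satisfy the martingale
property `E[c | s] = s` to 1e−8.

The per-family likelihood is computed by Felsenstein pruning over sizes,
summing the root size over a prior, and is **conditioned on the family
being observed in at least two species** — the same ascertainment as the
input filter ("present in at least two species"), computed as
`1 − P(no tip) − Σ_j P(only tip j)` with the same pruning machinery. The
root prior is geometric (p = 0.5) truncated to `1..sMax` by default, with
a point-mass option; the exact root treatment of the reference C++
implementation is not published, so the choice is documented rather than
claimed. The pruning likelihood is verified against brute-force
enumeration over all node-size combinations on trees of up to four tips
(tolerance 1e−9 log-units).

Rates are fitted by bounded derivative-free optimisation of the summed
log-likelihood on the log-λ scale: Brent search for one class, cyclic
coordinate descent with seeded multi-start for several classes. The
two-class model (background vs a designated "giant" branch set) is
compared to the one-class model by a parametric bootstrap: replicate
datasets of equal family count are simulated from the fitted null (with
the same ascertainment), both models are refitted, and the p-value is the
proportion of replicate statistics **at least as large as** the observed
`2ΔlnL` — the convention that makes extreme observations significant; an
observed statistic beyond every replicate is reported as `p = 0` with the
bound `1/n_reps` attached.

Ancestral sizes are *marginal* posterior modes per internal node (ties
broken toward the smaller size), computed by the up–down algorithm under
the same prior; marginal modes are well defined per node and testable by
exhaustive enumeration, unlike a joint max-product path. Tip
"reconstructions" are the observed counts. The per-branch shift test
scores the reconstructed parent→child transition against its kernel row
by the same probability-ordering rule (small p ⇔ improbable transition;
`p = 1` for a point-mass row), flagging `p < 0.05`. Branch rates are
`|parent − child| / t` in copies per My — absolute differences, because
mean rates are compared as magnitudes downstream. A five-class model (one
rate per independent giant lineage) is deliberately not offered: with
desk-scale data it is weakly identified, and the corresponding published
fit is reported not to have converged.

## Giant-branch × label analyses

From the per-branch shift flags the package builds: all shifted families,
families shifted on at least one branch of a focal set, and families
shifted on focal branches only. Enrichment of a label (e.g. cancer
orthology) among focal-shifted families is tested by the exact 2×2 test
on either universe — all families, or all shifted families. A sister
branch set provides a specificity control with the identical contract.

The permutation null redraws `k` branches (default 6) uniformly **from
all branches of the tree** — tips and internals alike, the root having no
branch — rebuilds the shifted set, and recomputes the odds ratio on the
same universe; `p` is the proportion of null odds ratios at least as
large as the observed one (rank-based, hence invariant to monotone
transforms of the statistic). Draws overlapping the focal set enter the
null by design. Degenerate permuted tables contribute OR = 1 and are
counted.

The interaction model fits `rate ~ giant * cancer + (1 | family)` by
maximum likelihood (lme4), over per-(family, branch) rate observations of
shifted families on **all** branches (observations with zero size change
are informative zeros, not missing data). Wald tests use a
standard-normal reference: with thousands of observations the difference
from a Satterthwaite-corrected t reference is negligible, and the normal
reference keeps the fit free of extra dependencies. Rates enter
untransformed by default (`log1p` optionally), and when the fitted
random-intercept variance is zero the coefficients coincide exactly with
ordinary least squares — a property the suite asserts. Rate ratios
(mean giant-branch rate over mean other-branch rate, per label stratum)
are pooled over (family, branch) observations.

## The synthetic generator: what it does and does not emulate

`simulatePresence()` draws family origins as a Poisson process along
branches (rate in origins per My), then loses each family independently
on each strictly descendant branch with a fixed probability (a per-My
alternative exists). Families surviving nowhere are unobservable and are
redrawn, exactly as real orthogroup tables never show all-extinct
families. A family originating on a terminal branch has no descendant
branch on which to be lost, so even loss probability 1 leaves tip-origin
singletons observable — the generator's model, and the reconstruction's,
not an edge-case bug.

`simulateCounts()` draws root sizes from the configured prior and child
sizes by inverse-CDF sampling from the **same truncated kernel rows the
likelihood uses**. This is a deliberate design decision: simulator and
estimator share one kernel, so recovery tests measure estimation error
alone, not model mismatch. A configurable fraction of families is
"shifted": their giant-branch rate is multiplied; `simulateLabels()`
then tilts a Bernoulli cancer label toward shifted families by a
configurable odds multiplier while holding the overall labelled fraction
fixed (the baseline probability is solved numerically), and emits
per-protein annotation terms at configurable frequency.

Default parameters describe a desk-scale vertebrate-like study: a global
rate of 0.0006092 gains/losses per gene per My, a twofold giant
multiplier, per-branch loss probability 0.1, a geometric(0.5) root prior,
a 5% cancer fraction (a few hundred cancer-census genes among ~18k
families), and a 450 My root depth for simulated trees.

What the generator does **not** emulate — and therefore what passing
tests do not establish about real data: orthogroup inference errors
(over-split or merged families, the dominant real-world artifact),
annotation noise and ontology structure, among-family rate variation,
gene-tree/species-tree discordance, correlated loss across related
families, and assembly/annotation-driven absence. Conclusions about
estimator correctness transfer to real data; conclusions about
robustness do not.

## Numerical choices and problem sizes

* Kernel matrices are built from precomputed log-binomial index tables
  and cached per (λ, t, sMax); pruning rescales partial likelihoods by
  column sums to avoid underflow, accumulating the log scale.
* Optimiser tolerances are on the log-λ scale: 1e−6 for headline fits,
  relaxed (1e−3–3e−3) inside bootstrap replicates where the statistic's
  Monte-Carlo noise dominates; replicate and observed fits always use the
  same generative and ascertainment settings.
* Ties in posterior modes break toward the smaller size; ties in exact
  tests share their probability mass within a 1e−7 relative tolerance.
* The test suite sizes its simulations to run on one CPU: rate recovery
  uses 20 datasets of 2,000 families on 10 tips (`sMax = 40`, with a
  truncation-stability check separately asserting that `sMax` does not
  bind); resampling calibration uses 50 null seeds with 100 bootstrap
  replicates each on 5-tip, 60-family data (`sMax = 15`); mixed-model
  coverage uses 200 seeds of 150 families × 12 branches. These sizes are
  the package's validation choices; the functions themselves accept
  arbitrary problem sizes.

## Known limitations

* Equal birth and death rates; no gamma rate variation across families;
  no measurement-error (annotation error) component.
* The Dollo origin is the MRCA of possessing tips: origins deeper than
  the root are invisible, and heavy loss biases origins downward (see
  above).
* Exact branch shift tests are conditional on the *point* reconstruction
  of parent and child sizes; reconstruction uncertainty is not
  propagated into the shift p-values.
* The permutation null treats branches as exchangeable units; it does
  not condition on branch length or depth, so focal sets of atypically
  long branches inherit whatever advantage length confers.
* Wald-normal inference in the mixed model is asymptotic; with few
  families or branches, intervals can undercover slightly (the observed
  200-seed coverage in the suite is 0.93–0.96 at nominal 0.95).
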