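# GeneFamEvo

Comparative analysis of gene-family evolution on a time-calibrated
species tree, in R.

Orthology inference pipelines (e.g. OrthoFinder) reduce a set of
proteomes to two objects: a rooted species tree with branch durations in
millions of years, and an orthogroup-by-species gene-count table.
GeneFamEvo takes those two objects and answers the questions a
comparative genomicist asks of them:

* **Gain and loss.** Where did each gene family originate, and on which
  branches was it lost? (Dollo parsimony: a single origin at the MRCA of
  possessing species, losses as maximal absent subtrees, with per-node
  totals of present / novel / lost / uniquely-lost / core / novel-core
  families.)
* **Size evolution.** How fast do family sizes evolve, and do designated
  branches — say, branches leading to giant-bodied lineages — carry a
  different rate? (A birth–death model of family size with rate λ in
  gains/losses per gene per My and transition kernel
  `P(c|s) = Σ_j C(s,j) C(s+c−j−1, s−1) α^{s+c−2j} (1−2α)^j`,
  `α = λt/(1+λt)`; maximum-likelihood fitting of one rate per branch
  class; a parametric-bootstrap likelihood-ratio test between nested
  rate models; marginal ancestral sizes; exact per-branch shift tests;
  branch rates `|Δsize|/t`.)
* **Label enrichment on branch sets.** Are families that shifted on the
  focal branches enriched for a label such as cancer-gene orthology —
  beyond what random branch sets produce — and does the label interact
  with the branch set in the per-branch rates? (Fisher exact tests with
  BH correction, a sister-branch control, a random-branch permutation
  null, and a random-intercept model
  `rate ~ giant * cancer + (1 | family)`.)

A fully seeded synthetic generator (trees, presence/absence, counts,
labels, annotations) shares its generative law with the fitted model, so
every stage ships with parameter-recovery and calibration tests that
need no external data. It also includes an ohnolog-splitting audit
(`splitReport`) for checking a family partition against an independent
reference partition.

## Worked example

```r
library(GeneFamEvo)

tree <- simulateTimeTree(12, seed = 42, depth = 450)
tid  <- tipIds(tree)
giant <- branchSet(tree, tid[order(tree@brlen[tid],
                                   decreasing = TRUE)][1:3], "giant")
cfg <- simConfig(seed = 42, nFamilies = 2000, lambdaBackground = 0.002,
                 giantMultiplier = 5, fractionShifted = 0.3,
                 fractionCancer = 0.12, effectOdds = 6, sMax = 40,
                 giantBranches = giant)
sim    <- simulateCounts(tree, cfg)
labels <- simulateLabels(sim$counts, sim$truth, cfg)

dolloReconstruct(sim$counts, tree)
#> DolloReconstruction: 2000 families on 12-tip tree
#>   598 total loss events; 491 families with >= 1 loss

cls <- setNames(rep("background", length(branchIds(tree))), branchIds(tree))
cls[as.character(setBranches(giant))] <- "giant"
fit <- fitLambda(sim$counts, tree, classes = cls, sMax = 40,
                 nStarts = 2, tol = 1e-3)
fit
#> BDFit: logLik = -21747.8272 over 2000 families
#>   lambda[giant] = 0.00418066
#>   lambda[background] = 0.00193494

anc    <- ancestralStates(sim$counts, tree, fit@model)
shifts <- branchShiftPvalues(anc, tree, fit@model)
shifts
#> BranchShiftTable: 2000 families x 22 branches; 729 flags at p < 0.05

branchSetEnrichment(shifts, giant, labels$cancer, "all_shifted")
#> ... OR = 1.75, p = 0.0449
permutationNull(shifts, giant, labels$cancer, tree, k = 3,
                nPerm = 100, seed = 42)
#> ... observed OR more extreme than 96% of random draws (p = 0.04)
```

Reading the numbers: the two-class fit recovers the background rate
(truth 0.002) and attributes an elevated rate to the giant branches
(truth 0.002 × 5 applied to 30% of families, so the class-level estimate
lands between the two); 729 branch transitions are individually
improbable under the fitted kernel at p < 0.05; families shifted on the
giant branches are 1.75× enriched in odds for the (planted) cancer
label relative to families shifted elsewhere; and only 4 of 100 random
three-branch sets produce as extreme an odds ratio.

Real data enter through `readNewick()`, `readGeneCounts()` (OrthoFinder
`Orthogroups.GeneCount.tsv` dialect), `readAnnotationMap()`,
`readGeneSet()` and `readBranchSet()`; `runPipeline(runConfig(...))`
drives all stages and writes TSVs plus a run manifest.

See the methods vignette (`vignettes/gene-family-evolution.Rmd`) for the
model, its assumptions, parameter defaults, numerical choices, and what
the synthetic generator does and does not emulate.

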