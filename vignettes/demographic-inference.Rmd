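---
title: "Demographic inference for ancient North Eurasian cohorts: models, estimators and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demographic inference for ancient North Eurasian cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`adnapop` re-implements, as one coherent and fully tested stack, the
population-genetic inference tools routinely applied to low-coverage
ancient-DNA cohorts: f-statistics, qpAdm admixture modeling, pairwise
mismatch-rate kinship, admixture-LD dating, projection PCA, and
composite-likelihood demographic fitting on the joint site frequency
spectrum (SFS). Because real ancient-DNA studies hinge on reference panels
and sequence archives far beyond desk scale, the package is validated the
opposite way round: a published multi-population demographic model of the
Bronze Age Kola Peninsula population from Bolshoy Oleni Ostrov (BOO) and
its North Eurasian context is packaged as the generative truth, synthetic
data are simulated under it, and every estimator must recover the
parameters it was given. This vignette records the models, the estimator
conventions, the numerical choices, and what the validation does and does
not establish.

## The packaged demographic model

`boo_final_model()` encodes a six-branch history: an African branch (YRI)
at the root, a Western Eurasian branch (represented by the Loschbour
hunter-gatherer), an Eastern Eurasian branch (CHB), Eastern European
hunter-gatherers (EEHG), the Eastern Siberia Late Neolithic/Bronze Age
lineage, and BOO itself. Its fitted quantities are: YRI–Eurasian split
87,790 ya; Western–Eastern Eurasian split 53,010 ya; Eastern Siberia
LNBA–CHB divergence 21,580 ya; gene flow CHB→EEHG at fraction 0.094 and
EEHG→Eastern Siberia LNBA at 0.125; a recent pulse Eastern Siberia
LNBA→BOO of 0.398 at 4,086 ya; and diploid effective sizes 1690 (Eastern
Siberia LNBA), 2470 (EEHG) and 235 (BOO).

A fitted model as printed is not a complete simulable object, so the
config adds conventional values for everything else, each flagged
`assumed: true` and overridable via `set_parameter()`:

* Ne = 10,000 for YRI, CHB, Loschbour and all ancestral segments.
* Sampling ages: Loschbour 8,000 ya, EEHG 11,000 ya, Eastern Siberia LNBA
  4,500 ya, BOO 3,565 ya, moderns at 0.
* Ancient pulse times: 25,000 ya (CHB→EEHG) and 19,000 ya
  (EEHG→Eastern Siberia LNBA), consistent with the two gene flows
  predating the LNBA populations' sampling by tens of millennia.
* Branch origins that the fit does not constrain: EEHG splits from the
  Western Eurasian lineage 30,000 ya; BOO branches from EEHG 5,000 ya.

The BOO sampling age deserves a note. The admixture pulse sits at 4,086 ya
and the dating analysis places it 17.98 generations — 521 years at 29
years/generation — before the cohort's mean age, which pins sampling at
about 3,565 ya. We use that value so the model is arithmetically
self-consistent: the mosaic-dating validation then has the printed 17.98
generations as its exact truth rather than a value a few percent off.

Population sizes are constant per branch. The model grammar therefore has
exactly four event types — splits, pulses, dated samples, and nothing
else — which covers this history completely; per-branch size changes or
continuous migration are out of scope. Time is stored in years and
converted to generations on entry to the simulator (`years / 29` exactly,
no rounding).

## The coalescent engine and the two SFS estimands

All site-level simulation runs through a single compiled routine: an
event-driven Hudson coalescent for one non-recombining site, with dated
sample entry, pulse admixture as backward lineage reassignment (each
lineage in the destination moves to the source with probability alpha),
and splits as forced mergers. Unlinked sites are independent genealogies.
This is deliberately *not* a recombining-sequence simulator: every
statistic the package fits (SFS, f-statistics, qpAdm) needs only unlinked
sites, and linkage enters solely through the mosaic generator described
below, which models ancestry segments directly.

Two quantities come out of the engine, and keeping their estimands aligned
matters more than it may look:

* `expected_sfs()` averages, over genealogies, the branch length
  subtending each joint derived-allele configuration, then normalizes:
  the infinite-sites expectation E[L_k] / E[L_total] of a segregating
  site's configuration.
* `simulate_coalescent()` draws observed segregating sites. A site is
  *not* one mutation per genealogy: genealogies with more total branch
  length host more segregating sites. The sampler therefore pools all
  branches across genealogies and draws sites length-weighted with
  replacement, which reproduces the ratio-of-expectations estimand
  exactly. (The one-mutation-per-tree shortcut estimates
  E[L_k / L_total] instead and is measurably biased — in early testing it
  shifted a recovered admixture fraction by about 0.08.)

The composite likelihood is the multinomial
`sum(n_k * log p_k)` over segregating cells, with expected probabilities
floored at 1e-12; the two monomorphic corner cells are structurally
excluded.

### Monte-Carlo noise and common random numbers

Profile likelihoods compare expected SFS across a parameter grid, and
with a 5^6-cell joint spectrum the Monte-Carlo error of each cell enters
the likelihood multiplied by observed counts. Two design choices keep the
profiles smooth:

* every genealogy has its own cheaply reseeded RNG stream
  (xoshiro256++), so replicate r is coupled across grid values — a
  parameter change only decorrelates the replicates whose draws it
  actually touches;
* profile experiments use 1,000,000 genealogies per grid point, and
  4,000,000 for the two weakly identified ancient pulse fractions, where
  measured profile noise at fixed data still rivaled the data's own
  sampling noise at 10^6. The function default (20,000) is fine for
  low-dimensional spectra but far too noisy for the six-population joint
  SFS; at these budgets the between-grid-point jitter is small against
  curvature signals of tens to hundreds of log-likelihood units.

Grid maxima are refined by a quadratic through the argmax and its
neighbors, on the log scale for geometric (Ne) grids. Grid values that
violate the model's event ordering — e.g. profiling a divergence time
past a fixed pulse that feeds the lineage — have zero likelihood and are
assigned `-Inf` rather than treated as errors, so profiles whose stated
range includes structurally impossible values remain well defined.

Bootstrap confidence intervals resample the site-level SFS cell indices
with replacement and re-maximize; the expected-SFS grid depends only on
the model and is computed once per profile, which is what makes 100
nonparametric bootstrap replicates affordable.

## f-statistics and qpAdm conventions

f2, f3 and f4 are allele-frequency products averaged per SNP
((pA−pB)(pC−pD) for f4, and so on), aggregated as SNP-count-weighted
block means over blocks of nominally 5 cM (the conventional span;
`make_blocks()` cuts greedily and never crosses a chromosome), with
Busing-style weighted delete-one-block jackknife standard errors. Each
statistic uses every SNP defined in *all* of its populations — per-
statistic masks, not a global intersection — and the usable counts are
reported so masks stay auditable. The optional bias correction subtracts
the finite-sample heterozygosity term p(1−p)/(n−1) using observed allele
counts, which is what makes single-individual pseudohaploid test units
legal with the correction off (outgroup-f3 ranking convention) and
required for admixture-f3 negativity tests.

qpAdm is implemented in the f4-matrix generalized-least-squares
formulation rather than the original coancestry-graph machinery: with
lefts {target, sources} and rights r1..rR, the vector
f4(x, r1; rj, r1), j = 2..R is linear in x's allele frequencies, so a
target that is a mixture satisfies the same linear relation with weights
summing to one. Weights solve the sum-constrained GLS problem under the
block-jackknife covariance of the residual vector (two GLS iterations
from an OLS start); the model p-value is the tail of the residual
chi-square with (rights − sources) degrees of freedom; a fit is
"feasible" exactly when every weight lies in [0, 1], and infeasible
models are flagged, not suppressed. The covariance is ridge-regularized
(epsilon 1e-9 on the diagonal scale) only when its condition number
exceeds 1e12, with a warning. The basis choice (first right as the
reference in both f4 slots) is fixed and documented; weights are
invariant to source ordering, which the tests verify.

## Relatedness

The pairwise mismatch rate (PMR) is the fraction of doubly-called SNPs at
which two pseudohaploid genomes disagree; diploid input is
pseudohaploidized first. Degree classification normalizes by an
unrelated-pair baseline — the median pair rate under the assumption that
most pairs are unrelated, or an external value — and applies the READ
cutoffs verbatim: below 0.625 identical/twin, then first degree to
0.8125, second degree to 0.90625, unrelated above. Instead of READ's
sliding-window variance, pair rates can carry a block-jackknife standard
error over the same block partition the f-statistics use; it plays the
identical role with one fewer tuning knob. Pairs with fewer than 5,000
overlapping SNPs are reported but flagged unusable.

The pedigree generator drops genes through the minimal pedigree for each
relationship at unlinked sites and tracks founder-allele identity, so
realized IBD sharing is available alongside the genotypes (half-sibs
average 25% of the genome sharing one allele IBD, first cousins 12.5%).

## Admixture-LD dating

The dating statistic weights each SNP by the source frequency contrast
w = p1 − p2 and, within chromosomes, averages w_i w_j r_i r_j over SNP
pairs in genetic-distance bins, where r is the individual's normalized
genotype residual against its expectation under the genome-wide mixture
fraction (estimated by least squares of target frequencies on the two
source frequencies). After a single pulse t generations ago the curve
decays as exp(−t d) in Morgans; `fit_exponential()` fits
A·exp(−λd) + c by Levenberg–Marquardt least squares, the affine c
absorbing any residual baseline. Bins run 0.5–20 cM in 0.1 cM steps;
sub-0.5 cM pairs are excluded as contaminated by background LD. The
standard error is a delete-one-chromosome jackknife of the whole
binning-and-fitting pipeline. Swapping the source labels flips w's sign
and leaves every product unchanged, a symmetry the tests assert exactly.

The mosaic generator is the matching forward model: Poisson(t·L)
breakpoints per chromosome copy, i.i.d. source-1 ancestry with
probability alpha per segment, Balding–Nichols source frequencies at
divergence scale 0.05 (an Fst-like quantity; the default matches
moderately diverged Eurasian source pairs), genotypes drawn per segment.
Emitted mosaics merge same-ancestry neighbors, so interior source-1
segment lengths are exponential with rate t(1−alpha) — the thinned
switch process — while the raw crossover counts are reported separately
for Poisson checks.

## Projection PCA

PCA follows smartpca conventions: SNPs with any missing modern call are
dropped, genotypes centered and scaled by sqrt(p(1−p)), components from
the SVD of the normalized matrix, loading signs fixed so each
component's largest-magnitude loading is positive. Ancient individuals
are placed by least-squares regression of their normalized non-missing
calls on the loadings (the `lsqproject` treatment); individuals under
1,000 usable SNPs are flagged low-confidence. No shrinkage correction is
applied: projected ancients sit slightly inside the modern clusters,
which affects absolute, not relative, placement — the property the
between-cluster tests rely on.

## Validation design, problem sizes and limitations

The acceptance experiments treat the packaged model's printed parameters
as simulation truth: 50,000 unlinked segregating sites (100,000 for the
three deep split times) across 4 haploids per population, an 11-point
profile per parameter with all others held at truth, and 10^6 genealogies
per expected-SFS evaluation; the mosaic dating run uses 100 diploids on
20 chromosomes of 1 Morgan with 50,000 SNPs. Each recovered value is
required to fall inside that parameter's published 95% CI. These sizes
were chosen as the smallest at which profile curvature clearly dominates
both sampling and Monte-Carlo noise for every parameter.

What passing does and does not show: the synthetic data realize the
estimators' own modeling assumptions — a known ancestral allele, no
sequencing error or reference bias, missingness independent of genotype,
Balding–Nichols rather than coalescent source divergence in the mosaic
world, and free recombination between all SNPs used by the SFS and
f-statistics. Recovery under these conditions establishes correctness of
the estimators and their uncertainty calibration, not robustness to
ascertainment, damage, or contamination, which real-data workflows must
address upstream. The single-parameter profile design matches the
stepwise way such models are built and keeps every experiment bounded; it
does not explore parameter correlations, which the original study's joint
optimization and its bootstrap distributions do.
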