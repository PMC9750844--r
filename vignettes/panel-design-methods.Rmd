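---
title: "Methods: GTSeq panel design and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GTSeq panel design and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gtpanel)
```

This vignette is the package's account of the statistical machinery it
implements, the assumptions behind it, and the design choices made where
the underlying methods literature leaves room.

## The data model

A genotype baseline is a set of individuals genotyped at a shared marker
panel, with each call an *unordered* allele pair or missing. Markers are
biallelic SNPs or microhaplotypes — short amplicons carrying several SNPs
whose phased combination acts as one multiallelic marker; allele identity
is by case-folded string match, since microhaplotype alleles are sequence
strings. Samples are nested functionally: individual → collection
(spawning-site sample) → reporting unit (management grouping) → lake.
Half-calls are coerced to missing with a warning: no analysis here uses
single gene copies, and permitting them would silently distort allele
counts.

Marker definitions may be declared up front or inferred from observed
calls. Inference is permissive — monomorphic columns and multiallelic
single-position variants are accepted as data — whereas declared marker
sets are validated strictly (a declared SNP must have exactly two alleles;
in strict mode a call outside the declared allele set is an error rather
than an appended allele).

## Diversity and differentiation

Per (group, marker): observed heterozygosity `Ho`; Nei's unbiased gene
diversity `Hs = (2n/(2n−1))(1 − Σ p̂²)` with `n` genotyped individuals;
effective allele count `Ae = 1/Σ p̂²`; and `Gis = 1 − Ho/Hs`. Monomorphic
cells report `Ho = Hs = 0`, `Ae = 1`, and an undefined (`NA`) `Gis`.

Hardy–Weinberg departure is tested by permutation: gene copies are
shuffled among individuals within the group and `Gis` recomputed. Because
shuffling preserves allele frequencies, `Hs` is invariant and the deficit
tail `Gis_perm ≥ Gis_obs` is equivalent to `Ho_perm ≤ Ho_obs`; the
observed configuration is included in the null set, so
`p = (1 + #{perm ≥ obs})/(n_perm + 1)` and the smallest attainable p-value
is `1/(n_perm + 1)`. A literal one-sided *t*-test on genotype data is not
a reproducible recipe, and the permutation test is what the standard
population-genetics software computes; the default direction is
heterozygote deficit, configurable.

Differentiation uses the Weir–Cockerham (1984) θ estimator: per allele and
locus, variance components `a` (among groups), `b` (among individuals
within groups), `c` (within individuals) are computed from group sizes,
allele frequencies, and heterozygote-carriage frequencies, summed over
alleles, and ratioed as `θ = Σa / Σ(a+b+c)` per locus or over loci.
Negative per-locus components are retained before summation — truncation
would bias the multi-locus ratio. Markers monomorphic overall contribute
zero components and drop out. Confidence intervals bootstrap over loci.
Loci where the average group sample size is ≤ 1 individual are skipped
(the `b` component is undefined there).

Linkage disequilibrium is the composite (phase-free) squared Pearson
correlation of 0/1/2 dosages, with each microhaplotype expanded into its
constituent SNPs by character position of the allele strings. Pairs with
fewer than 10 co-genotyped individuals are `NA`. The headline summaries
are the mean inter-marker r² and the fraction of SNPs whose maximum
inter-marker r² exceeds 0.3 — the latter because kinship power
calculations assume independent loci and become optimistic when that
fails.

## Marker screening

Candidates pass four sequential rules with the inequalities exactly as
conventionally stated: missing fraction strictly above 0.20 fails (0.20
exactly passes); pooled Fis must lie strictly inside (−0.2, 0.2); every
constituent SNP position must lie strictly inside (17, 140) on the forward
read (no position metadata fails the rule, with an explicit reason); and
the allele count must be < 11. Sequential application makes the per-rule
removal counts sum with survivors to the input count, and screening is
idempotent. Two decisions the rule statement leaves open: Fis is computed
on the pooled sample (the ±0.2 band exists precisely to tolerate
structure-driven heterozygote deficit at the screening stage; a
per-collection variant is available), and a marker whose Fis is undefined
(monomorphic) passes the Fis rule, since the rule cannot measure it.

Microhaplotypes genotype at lower rates than single SNPs. To keep one
entry per locus, a microhaplotype above the missingness cap is replaced by
its constituent SNP with the highest pooled minor allele frequency —
constituent SNPs are matched by the `<mhap>_<position>` naming convention,
and MAF ties break toward the smaller forward-read position (a
deterministic rule is required; the choice is otherwise arbitrary).

## Panel composition

Panels mix two ranked criteria: per-locus θ across collections (stock
separation) and pooled observed heterozygosity of microhaplotypes
(kinship information). `rank_and_compose(n_fst, n_he)` takes the top
`n_fst` by θ, then the top `n_he` microhaplotypes by `Ho` among the
remainder; ties break by the secondary criterion and then marker id, so
selection is deterministic and order-invariant. Heterozygosity picks are
restricted to microhaplotypes because multiallelic markers are what drive
pairwise-kinship likelihoods; observed (not expected) heterozygosity is
ranked, with the alternative available. The five canonical compositions
sweep (1, 0.75, 0.5, 0.25, 0) of the panel size from all-FST to
all-heterozygosity, and `evaluate_scenarios()` reports each panel's mean
leave-one-out GSI accuracy and full-sibling false-positive rate at
FNR = 0.01 — the two ends of the trade-off.

## Genetic stock identification

Baseline allele frequencies are Dirichlet posterior means under the
unit-information prior: `p = (x + 1/A)/(n + 1)` per (collection, marker,
allele), so every defined allele has positive mass in every collection and
log-likelihoods are always finite; an empty collection yields the uniform
`1/A`. Individual log-likelihoods are Hardy–Weinberg: `log(2 p_a p_b)` for
heterozygotes, `log(p_a²)` for homozygotes, missing loci contributing 0.

Mixture analysis is EM: E-step `pofZ_ib ∝ π_b exp(ℓ_ib)` stabilized by
log-sum-exp, M-step `π_b = mean_i pofZ_ib`, uniform initialization,
iterated until `max|Δπ| < 10⁻⁸` (cap 1000 iterations, flagged if hit).
The log-likelihood trace is non-decreasing, pofZ rows sum to 1 within
10⁻⁹, and memberships aggregate over the collections of each reporting
unit; an individual is assigned to the top unit when its aggregated
membership strictly exceeds the pofZ threshold (default 0.7), else left
unassigned. Full Bayesian sampling over mixture proportions is
deliberately out of scope — EM point estimation with pofZ is the contract.

Expected assignment accuracy comes from 100% leave-one-out simulations:
every simulated individual originates in the focal reporting unit, with
its source collection drawn proportional to baseline sample size and its
genotype built per locus by drawing two gene copies *without replacement*
from that collection's observed copies. When the individual is scored
against its own source collection, those two copies are subtracted from
the counts (posterior mean over `n − 2` copies). This gene-copy
cross-validation realizes "leave-one-out" concretely: an individual's own
alleles never inflate its self-assignment likelihood, which is the
optimistic bias that naive resampling suffers (removing the subtraction
raises the own-collection log-likelihood by about +10 over 500 loci in
the package's panmictic checks). A collection with fewer than two copies
at a locus skips that locus for the draw. Accuracy is reported among
assigned individuals (the total-denominator variant is a flag away), and
threshold sweeps recompute accuracy and unassigned rates from the retained
membership matrices without re-simulating.

One behavior worth knowing: with truly exchangeable units (differentiation
zero), the *expected* accuracy at threshold 0 is chance, but any single
realized baseline tilts all of its replicates' assignments the same way —
the tilt is a property of the drawn baseline, not of the simulation noise.
Validation therefore averages chance-level checks over independent
baseline draws. The unassigned rate is provably non-decreasing in the
threshold; accuracy among assigned is not a mathematical monotone (a
high-confidence wrong call can survive a raised threshold), though it
increases in practice on structured data.

## Kinship power

Pairwise relationships are the κ models U = (1,0,0), PO = (0,1,0),
FS = (¼,½,¼), HS = (½,½,0) over 0/1/2 alleles shared identical by
descent. The joint probability of an unordered genotype pair at one locus
is `κ₀P(G₁)P(G₂) + κ₁P(G₁)T(G₂|G₁) + κ₂P(G₁)1[G₁=G₂]`, with
`T(G₂|G₁)` the probability that G₂ is one allele drawn uniformly from G₁
plus one population draw. Genotyping error is whole-genotype replacement
by a Hardy–Weinberg draw at rate μ, independently per member, which gives
the closed-form observed-pair mixture
`(1−μ)² P_true + (1−(1−μ)²) P(G₁)P(G₂)` — the simplest model that breaks
the "PO pairs always share an allele" exclusion, which power analyses must
tolerate. The default μ for power runs is 0.005; μ = 0 supports exact
exclusion checks. These probabilities are verified in the test suite
against a pedigree-enumeration oracle (exhaustive sums over parental
allele configurations and Mendelian transmissions) and by the
sum-to-one audit over all genotype pairs.

Power is expressed as log-likelihood-ratio ensembles
`Λ = Σ_loci ln P(G₁,G₂|K)/P(G₁,G₂|U)` over simulated pairs, with loci
independent and missing loci skipped pairwise. The decision threshold at a
false-negative rate `f` is the empirical `f`-quantile λ* of Λ under K;
the false-positive rate is estimated either directly (fraction of U-pairs
with Λ ≥ λ*) or by importance sampling with the numerator hypothesis as
proposal: because Λ is exactly the log density ratio,
`FPR = E_K[e^{−Λ} 1(Λ ≥ λ*)]`. Self-normalization is unnecessary — the
weights are exact density ratios — and this is what makes full-sibling
rates of order 10⁻²⁰ and below estimable from 10⁴ draws. The two
estimators are cross-checked against each other wherever the direct method
has resolution, and `E_U[e^Λ] = 1` (the fundamental likelihood-ratio
identity) is tested within Monte-Carlo error. A direct estimate with zero
exceedances reports the upper bound `3/n_sim` with a flag. Linked loci
inflate power claims; the LD summary above is the diagnostic, and thinning
by r² before power runs is the recommended remedy.

## Panel QC

Shannon equitability of a primer pool is `H = −Σ pᵢ ln pᵢ / ln S` over
the `S` retained markers' primer-read shares; `H = 1` iff perfectly even,
and zero-read markers stay in `S` (richness matters, not just evenness).
Pool optimization mirrors the iterative bench procedure: each round
removes markers whose share exceeds `k×` the mean share (default
`k = 10`) or whose probe/primer on-target fraction falls below 0.2, until
`H ≥ 0.8`, nothing violates, or a floor pool size is reached. The removal
thresholds are package defaults — the bench procedure is judgment-driven
and publishes only the target `H` — and both are arguments.

The primer:probe proportion is defined here as probe/primer, the
on-target fraction in [0, 1] (the phrase is directionally ambiguous in
common use; an inverted variant is a flag). Consistency across runs is
Pearson correlation of the proportion aggregated per marker and per
individual over shared keys, with zero-variance cases reported `NA` with a
reason, and per-individual coverage as summed probe reads over panel size
(an X-fold depth). Genotype congruence between runs is the percentage of
co-called loci with identical unordered calls, computed after removing
individuals below a 50% genotyping rate in any run; loci missing in one
run are excluded rather than counted incongruent, matching the "identical
genotype calls" reading. Summaries follow the median / mean (SD) /
min–max layout split by marker kind, and a one-way fixed-effects ANOVA
tests whether mean congruence differs among run pairs (plus an optional
regression on mean read depth when read counts are supplied).

## The synthetic-data generators

`simulate_baseline()` draws a two-level Balding–Nichols hierarchy:
ancestral SNP minor allele frequencies uniform on (0.05, 0.5) (mirroring
upstream MAF screening of candidate SNPs; the exact historical cutoff is
unpublished, so the floor is a parameter), microhaplotype frequencies
symmetric Dirichlet(1) over 2–10 alleles, lake frequencies
`Dirichlet(p·(1−F_lake)/F_lake)`, collection frequencies likewise around
their lake, genotypes HWE within collection, and independent missingness.
`F = 0` is the exact limit (child equals parent). The defaults — 5 lakes ×
6 collections, `F_lake = 0.08`, `F_coll = 0.02`, ~500 loci (300 SNPs,
200 mhaps), ~10% missing — emulate a Great-Lakes-scale spawning-stock
survey; the acceptance script additionally draws per-collection sizes
uniformly from 13–73. Under this model the expected θ at each level equals
the configured `F`, which is what the recovery tests check (±0.02 at
L = 500, n = 50).

Kin pairs are built by explicit Mendelian descent from HWE parents (PO
pairs an offspring with one parent; FS share both parents; HS exactly
one), so their single-locus joint distribution is exactly the κ model —
the identity the likelihood-ratio machinery relies on. Read-count tables
use log-normal marker amplification factors, log-normal individual
depths, Poisson primer reads, binomial probe reads, and Poisson
off-target reads.

What the generators deliberately do **not** emulate: physical linkage and
recombination (loci are independent, mirroring the analysis assumption),
sequence-level artifacts (no FASTQ, no allele-specific amplification
bias), non-equilibrium demography (bottlenecks, admixture clines), and
family structure inside baselines. Passing tests therefore demonstrate
correctness of the estimators under their own assumptions — not robustness
to linked loci, related baseline individuals, or batch effects in real
amplicon data.

## Numerical choices and problem sizes

Log-sum-exp throughout the EM; Dirichlet priors guarantee finite
log-likelihoods; categorical draws use vectorized inverse-CDF sampling
with the final cumulative bin clamped to 1 against rounding; EM tolerance
10⁻⁸ on mixture proportions; importance weights are exact ratios, so no
normalization step exists to fail. All generators and simulations are
bit-reproducible from their seed.

The validation suite runs at deliberately chosen scales: differentiation
recovery at 20 groups × 50 individuals × 500 loci over 5 seeds; mixture
recovery at L = 300, mixture 200; chance-level assignment averaged over 12
independent panmictic baselines (100 individuals per collection); the
composition trade-off at eight low-divergence units (`F = 0.004`,
1600-locus candidate pool, 600-marker panels, 5 seeds) where assignment
accuracy is far from saturation so the accuracy/power trade-off is visible
and strictly ordered; congruence detection at 95 individuals × 300 loci
with 1%/1%/3% run errors over 5 seeds. The acceptance script reproduces
the full chain at study scale (30 collections, ~1300 individuals,
500 markers) in a few minutes on one CPU.

## Known limitations

* Accuracy among assigned individuals is not guaranteed monotone in the
  pofZ threshold (see above); only the unassigned rate is.
* The κ-model machinery covers U/PO/FS/HS; it does not discriminate
  between related hypotheses (e.g., HS vs FS), reconstruct pedigrees, or
  model physical linkage.
* The congruence ANOVA is ordinary one-way fixed-effects on per-individual
  percentages; run-pair observations share individuals, so its p-values
  are heuristics for flagging a discordant run, not exact inference.
* VCF ingestion is intentionally excluded; genotype tables and read-count
  summaries are the package's inputs. A long-format reader covers
  deposited-data layouts.
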