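---
title: "Models and methods behind tetradqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tetradqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tetradqtl)
```

tetradqtl maps a binary ploidy phenotype — whether a population founded by a
haploid F1 yeast segregant autodiploidizes during laboratory evolution — onto
a biallelic marker map, starting from sparse per-marker parental read counts.
This vignette records the models, the tunable parameters and their defaults,
the numerical choices, and the places where the design was genuinely open.

## The generative model

A cross of two haploid parents (alleles labelled B and W) is simulated in
three layers.

**Meiosis.** A gamete is a two-state Markov chain along each chromosome:
the state at the first marker is Bernoulli(1/2) and the chain switches
between adjacent markers `d` cM apart with the Haldane probability
`r = (1 - e^(-2d/100)) / 2`. Chromosomes are independent. A tetrad is built
as {s1, complement(s1), s2, complement(s2)} from two independent gametes.
This construction guarantees exact 2:2 segregation of every marker within a
tetrad and gives each single spore the correct marginal recombination
process. It deliberately ignores chromatid and crossover interference and
gene conversion, so tetrad-level two-strand/four-strand crossover
correlations are not reproduced — acceptable here because the analysis
treats spores individually. Bulk-isolated ("selected") spores are simulated
as independent gametes with no tetrad structure.

**Phenotype.** A single causal marker acts through allele-specific
penetrances: carriers of B diploidize with probability `penetrance_B`
(default 0.69) and carriers of W with `penetrance_W` (default 0.18),
independently across segregants. These defaults are the allele effects
estimated in the mapping experiment the simulator emulates; with 2:2
segregation the expected population-level diploidization rate is their
average, 43.5%, matching the observed 44% (113/260 spores). Whether
diploidization of distinct populations is strictly independent is not
established experimentally; the simulator assumes independence, which makes
the tetrad spectrum (0–4 diploid spores per tetrad) slightly more binomial
than real data might be.

**Sequencing.** Per segregant and marker, total depth is
Poisson(`mean_depth`, default 5 — low-coverage whole-genome sequencing) and
reads matching the true allele are Binomial(depth, 1 − ε) with symmetric
per-read error ε (default 0.005); misreads are attributed to the other
parental allele. Pooled samples draw `depth` reads per marker with B
probability `f(1−ε) + (1−f)ε`, where `f` is the B frequency among pooled
segregants. No FASTQ-level artifacts (mapping bias, duplicated fragments,
index hopping) are modeled, so passing tests demonstrate statistical
correctness of the inference given this count model, not robustness to
alignment pathologies in real data.

When a map lacks genetic positions they are derived from physical positions
at 0.4 cM/kb (1 cM per 2.5 kb, the yeast genome-wide average), configurable
in `genetic_map()`.

## Genotype inference

`infer_genotypes()` runs a two-state forward–backward pass per chromosome:
uniform (1/2, 1/2) start, Haldane transitions from the map, and binomial
emissions `P(n_B | state B) = dbinom(n_B, n_B + n_W, 1 − ε)`. The emission
error defaults to ε = 0.005 and is configurable; no emission model is
prescribed by the experiment itself, and a symmetric binomial is the
standard choice for parental-allele counts. Decoding is posterior
(marginal), not Viterbi: the per-locus QTL scan consumes per-locus
genotype probabilities, so marginal posteriors are the natural product.
A call is made when the posterior exceeds `call_threshold` (default 0.95,
controlling the missingness/error trade-off); zero-coverage markers carry
no information and fall to the prior smoothed by their neighbours.

Numerically the recursion is scaled: per-site emission log-likelihoods are
shifted by their column maximum before exponentiation and the forward and
backward vectors are renormalized at every step, so depths into the
hundreds of reads are safe. With ε = 0 a marker observing both alleles has
zero likelihood under both states; this is reported as an error rather than
silently renormalized.

The implementation is validated against exhaustive path enumeration (all
2^L state paths for L ≤ 12) at 1e−9 tolerance, and posteriors are exactly
antisymmetric under a B↔W label swap.

## Quality control

Three diagnostics precede mapping, each exposed via `qc_thresholds()`:

* *Segregation distortion*: per-marker χ² goodness-of-fit of called B:W
  against 1:1 (1 df), Bonferroni-corrected at family-wise α = 0.05.
* *Genotype similarity*: pairwise identity at co-called markers; pairs above
  0.90 are treated as duplicates and the member with more missing calls is
  dropped (ties broken lexicographically, so QC is deterministic).
  Unrelated segregants sit near 0.5; tetrad complements near 0.
* *Crossover counts*: switches between consecutive non-missing calls,
  summed over chromosomes. A segregant is an outlier when its count exceeds
  the larger of `median + 5·MAD` and twice the map length in Morgans. The
  "larger of" choice matters only on short maps, where either heuristic
  alone is noisy; at genome scale (~45 crossovers per spore) the two cutoffs
  nearly coincide.

All statistics are computed on the input before anything is removed, so
`apply_qc()` is idempotent and every removal is logged with its reason. QC
only removes; it never edits genotypes.

## The single-QTL scan

`genotype_probs()` imputes `P(B)` for every segregant on a grid of marker
positions plus pseudomarkers every `step_cM` (default 1 cM), reusing the
forward–backward machinery with genotype *calls* as observations (a call is
correct with probability 1 − ε; missing calls and pseudomarkers are
uninformative).

Two scan statistics are provided because the field uses both and their
agreement is itself a useful check:

* **EM interval mapping** maximizes the binomial mixture likelihood over the
  two penetrances at each position. EM starts at the phenotype mean ± 0.1
  (clamped inside (0,1)) and stops when the log-likelihood improves by less
  than 1e−8 or at 1,000 iterations; the EM objective is monotone, which the
  test suite asserts per position. LOD is the log10 ratio against the
  phenotype-only binomial null.
* **Haley–Knott regression** regresses the 0/1 phenotype on `P(B)`;
  `LOD = (n/2) log10(RSS0/RSS1)`. It is an approximation but is orders of
  magnitude faster, which matters for permutations, and on fully
  informative markers both methods match their closed forms to 1e−9.

Genome-wide significance uses permutation of phenotype labels against whole
genotype rows (unstratified), with the threshold at the 1 − α quantile of
the permuted genome-wide maxima and the genome-wide p-value reported with
the add-one rule (k+1)/(n_perm+1) — a bounded value, never an exact zero.
Under the full generative chain (5X counts → HMM → grid probabilities) the
realized genome-wide type-I error at α = 0.05 is ~0.04 over 1,000 null
crosses: slightly conservative, because the finite permutation sample and
the strict-exceedance rule both shave a little level. With idealized
error-free hard calls the conservativeness is stronger (~0.02): on a
2:2-balanced marker panel the max-LOD statistic is then supported on few
discrete values and ties with its own permutation null.

`scan_regressout()` rescans with `P(B)` at a chosen position as an additive
covariate — an extra regressor for Haley–Knott; for EM, segregants are
stratified by the covariate posterior and stratum-specific penetrances are
fitted in both null and alternative. The LOD at the covariate's own
position collapses to ~0. One calibration fact worth stating plainly: after
regressing out a true QTL, the residual genome-wide maximum still exceeds a
correctly calibrated 5% threshold in ~5% of datasets *by construction*, so
"no residual QTL anywhere" is expected in only ~95% of replicate crosses,
not all of them.

## Multi-QTL search and held-out fitting

`stepwise_search()` maximizes the penalized LOD
`pLOD = LOD − T_main·#loci − T_int·#interactions`, forward-adding loci (up
to `max_qtl`, default 4) or interactions among included loci and
backward-deleting after each acceptance; the best model visited is
returned, and the result is a local optimum certified against all
single-deletion neighbours. `T_main` defaults to the genome-wide
permutation threshold on the training data; no two-dimensional permutation
scheme is defined for interactions, so `T_int` defaults to `T_main` —
conservative and simple, and both are configurable. The search can be
restricted to a chromosome subset, as when prior single-QTL scans justify
searching only two chromosomes.

`split_data()` makes the seeded train/test partition (default 150 training
segregants, leaving 105 of 255). `fit_model()` evaluates the selected model
on held-out segregants: the model LOD on the binomial likelihood-ratio
scale (deviance drop / 2 ln 10 from the logistic fit — chosen so that a
perfectly associated locus on balanced data gives exactly n·log10 2),
variance explained as 1 − RSS_full/RSS_null on the 0/1 scale with a
deviance-scale alternative reported alongside (the scale of a published
"% variance explained" is often ambiguous, so both are kept), a χ²
likelihood-ratio test and an F test. `refine_positions()` re-profiles each
locus with the others fixed until no position moves; the model LOD is
non-decreasing. `estimate_effects()` returns posterior-weighted phenotype
means per allele — for a binary trait these are the estimated penetrances —
with binomial standard errors on the effective (weight-sum) sample size.

## Pool enrichment

For phenotype-sorted pools, `pool_allele_fraction()` reports per-pool
B-read fractions with exact Clopper–Pearson intervals (preferred over the
Wilson score interval so that small pools never get interval endpoints
outside the achievable support). `compare_pools()` aggregates counts within
the haploid and diploid groups and applies a two-proportion χ² test, by
default without continuity correction since pooled read counts are large;
a `by =` argument stratifies the contrast by covariate tags (e.g.
auxotrophy classes) while the headline contrast pools all strata. Under the
penetrance defaults, Bayes' rule puts the causal-locus B fraction at
0.69/0.87 ≈ 0.79 in diploid pools and 0.31/1.13 ≈ 0.27 in haploid pools,
which simulated pools reproduce.

## Reproducibility and problem sizes

Every stochastic function takes an explicit seed and is bit-identical under
it. `run_pipeline()` expands one global seed into fixed per-stage offsets,
so any stage can be re-run independently, and writes a manifest (package
version, seed, full configuration) sufficient to reproduce every artifact.

The validation suite runs on reduced synthetic maps — hundreds of markers
over five or six chromosomes for replicate-heavy checks, a 16-chromosome
genome-scale map where chance near-clone similarity must be realistically
rare — rather than the full 8,505-marker panel; the statistical properties
being asserted (2:2 segregation, posterior exactness, scan calibration,
recovery rates) do not depend on marker count beyond map resolution, and
the chosen sizes keep the whole suite to a couple of minutes. Parameter
recovery uses 50 replicate 255-segregant crosses at 5X and ε = 0.005:
the scan localizes the causal locus within 10 cM in 50/50, the stepwise
search returns a one-locus model in 47/50, and both allele penetrances fall
within 2 standard errors of truth in 45/50.

## Known limitations

* No aneuploidy, gene conversion, crossover interference, or segregation
  distortion is generated; QC calibration on simulated data therefore
  checks the false-positive side only.
* The emission model assumes symmetric, position-independent read error;
  reference-bias asymmetries in real alignments are not represented.
* Haley–Knott permutation thresholds are used for the stepwise penalties;
  EM-based permutations are available but slow.
* The multi-QTL search is greedy; it certifies a local, not global,
  penalized-LOD optimum.
* Only biallelic SNP markers are supported; multi-allelic records in a VCF
  are skipped with a warning.
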