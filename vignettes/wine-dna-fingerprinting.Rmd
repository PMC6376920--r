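---
title: "Wine DNA fingerprinting: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wine DNA fingerprinting: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(winefp)
```

## The problem

Wine retains traces of grapevine (*Vitis vinifera*) DNA. Amplifying a panel
of 7–10 microsatellite (SSR) markers from that residue yields a *wine DNA
fingerprint*: per locus, the set of allele fragment sizes that survived
fermentation and ageing. Compared against reference genotypes of candidate
varieties, the fingerprint supports two inferences:

* **identification** — which variety is the main component of the wine;
* **admixture** — whether a given variety is present in a blend at all.

The difficulty is that wine DNA is scarce and degraded. A single PCR is
unreliable: true alleles *drop out* (the more so the older the wine and the
smaller the contributing blend fraction) and spurious alleles *drop in*.
Every design choice in this package follows from taking that error structure
seriously rather than treating wine like a clean diploid sample.

## From peaks to validated profiles

Raw evidence is a peak table per technical replica (independent PCR of the
same extract): fractional fragment sizes with fluorescence heights.
Three steps produce a validated profile:

1. **Calibration.** Plant references with known genotypes run in the same
   experiment act as internal calibrators. Per locus, the additive offset is
   the *median* of (true − observed) over calibrator peaks — the median
   resists a single aberrant peak, and offsets are per locus because
   capillary mobility varies with fragment size. When a calibrator locus
   shows exactly as many peaks as it has distinct true alleles, peaks are
   paired to alleles by rank; this measures even a drift larger than one
   repeat unit, which is then flagged `unreliable` (|offset| ≥ repeat_unit/2)
   rather than silently snapping peaks to the wrong grid point. Otherwise
   each peak matches its nearest true allele within one repeat unit, and
   unmatched peaks are ignored (calibrators can carry artefacts too).
2. **Binning.** `round(size + offset)` to the nearest integer bp, halves
   away from zero. Peaks landing outside a locus's plausibility bounds are
   discarded and counted.
3. **Consensus.** An allele enters the profile only if it recurs in at least
   `min_count` distinct replicas — by default the majority, `ceiling(n/2)`,
   i.e. 2 of 3. Majority vote is the standard forensic consensus: a drop-in
   with per-replica probability $p$ survives 2-of-3 validation with
   probability of order $3p^2$, so at $p = 0.01$ a spurious allele survives
   about once per 30,000 locus calls. Loci where no allele reaches
   `min_count` stay untyped — absence of evidence is recorded, not imputed.

Wines are typed in at least three replicas (up to six for complex blends);
plant references in two. Two replicas are accepted with a warning, since
`min_count = 2` then demands perfect recurrence.

## Discrimination power of the panel

With per-locus allele frequencies $p_i$ estimated by gene counting from the
diploid references (a homozygote contributes two copies), the probability
of identity is

$$PI = \sum_i p_i^4 + \sum_{i<j} (2 p_i p_j)^2,$$

the probability that two random Hardy–Weinberg individuals share an
unordered genotype; the panel value is the product over loci. The plain
estimator is the default; the small-sample corrected variant is available
(`locus_pi(..., unbiased = TRUE)`). Wines are *mixtures*, not diploid
draws, so they are excluded from frequency estimation by default;
`include_wines = TRUE` adds each wine allele once as a pseudo-count for
sensitivity analysis. The random match probability of a specific profile is
the product over typed loci of $p_i^2$ or $2 p_i p_j$.

## Distances, trees and cluster confidence

**Distance.** No single canonical metric exists for comparing a multi-allele
wine set against a diploid genotype. We use the Dice coefficient on allele
multisets, $s = 2|a \cap b| / (|a| + |b|)$, with diploid calls keeping both
gene copies. On two diploid genotypes this reduces exactly to the classical
allele-sharing similarity (shared copies)/2, and it degrades gracefully for
multi-allelic wine sets; Jaccard on distinct alleles is available behind
`metric = "jaccard"`. The profile distance is one minus the mean similarity
over co-typed loci.

**Comparability threshold.** Pairs sharing fewer than `min_cotyped = 4` typed
loci are declared incomparable and pinned at the maximal distance 1, keeping
the matrix complete for tree building while the flag travels into reports.
Four is the smallest count at which a panel retains discriminating power
worth interpreting; monovarietal comparisons can tolerate slightly fewer
markers than blends, which is why the threshold is a parameter.

**Trees.** Neighbor-Joining (Saitou–Nei, exact on additive matrices) and
average-linkage (UPGMA) dendrograms are implemented in-package so that tie
breaking is deterministic (lexicographically smallest label pair) and
negative NJ branch lengths are clamped to zero with a count kept. Newick
output carries six-decimal branch lengths and quotes labels containing
spaces.

**Cluster confidence.** The bootstrap resamples *loci* — the exchangeable
units of evidence in an SSR panel — with replacement, at ten scales
$r \in \{0.5, \dots, 1.4\}$ of the panel size, default 1000 replicates per
scale. The frequency of a cluster at scale 1 is its bootstrap probability
BP. The approximately unbiased p-value comes from the multiscale model
$z_r = v\sqrt{r} + c/\sqrt{r}$, $z_r = \Phi^{-1}(1 - \mathrm{bp}_r)$,
fitted by weighted least squares with binomial delta-method weights
$n\,\phi(z_r)^2 / (\mathrm{bp}_r(1-\mathrm{bp}_r))$, giving
$\mathrm{au} = 1 - \Phi(v - c)$. WLS (rather than maximum likelihood) is
accurate at 1000 replicates per scale and keeps the fit a two-parameter
linear problem. Scales with bp exactly 0 or 1 carry no usable quantile and
are dropped; curves that are 0 (or 1) everywhere fall back to au = 0 (or 1).

## The admixture call

The headline inference is deliberately a *score*, not a probability: a
calibrated presence probability would need a full dropout likelihood, which
is out of scope. For a candidate variety, the inclusion score is the
fraction of its allele copies found in the wine over co-typed loci
(homozygotes weigh their single allele twice). The score ignores extra wine
alleles — those belong to other blend components and affect the distance,
not inclusion. Calls:

* `compatible` if score ≥ θ (default **0.75**: tolerates roughly one
  dropped allele copy per two loci on a seven-locus comparison — the working
  margin for degraded DNA);
* `excluded` below θ;
* `inconclusive` when fewer than `min_cotyped` loci are co-typed.

The main varietal component is the comparable candidate at smallest
distance, with an ambiguity margin ε = **0.02**: when the runner-up is
within ε the call is reported ambiguous, because some variety pairs
(classically Cabernet Sauvignon/Merlot) are near-indistinguishable on a
small SSR panel and a hair's-breadth ranking should not be sold as a call.

PCA ordination uses presence/absence encoding of (locus, allele) incidence:
wine profiles are sets, so allele copy numbers are unobservable in a
mixture.

## The synthetic-data generator

The generator exists so that every downstream stage is testable without
wet-lab genotyping, and its defaults *are* the study conditions of the
package's acceptance checks:

* per-locus spectra of 8 alleles on the 2 bp repeat grid, frequencies from
  a symmetric Dirichlet(1) — the uneven spectra typical of grapevine SSR
  panels;
* reference genotypes drawn under Hardy–Weinberg equilibrium;
* wines as proportion-weighted blends, three technical replicas;
* detection probability
  $p = p_{base}\cdot \pi^{\gamma}\cdot e^{-\lambda\, a}$ for a component of
  blend proportion $\pi$ in a wine of age $a$, with defaults
  $p_{base} = 0.98$, $\gamma = 0.15$, $\lambda = 0.05$/year. Only
  qualitative anchors exist for these rates — a ~1.2% minor component is
  borderline-detectable in a young wine and fades over several years, and a
  varietal signal degrades noticeably past five years — so the defaults were
  fixed once to reproduce that regime ($p \approx 0.48$ per allele for a
  1.2% component at one year, so 2-of-3 consensus retains some but not all
  of its alleles) and are not tuned further;
* drop-in probability 0.01 per locus per replica, drawn from the spectrum
  excluding true alleles (a drop-in can never masquerade as a true allele);
* sizing jitter uniform on ±0.4 bp — small enough that binning at a 2 bp
  repeat unit stays unambiguous; peak heights are lognormal around the
  contributing proportion and cosmetic (nothing downstream reads them).

What it does **not** emulate: PCR stutter, heterozygote peak imbalance,
microbial/yeast background DNA, null alleles, between-run chemistry
differences. Passing tests therefore show the *statistical* machinery is
sound under the modelled error structure, not that any particular wet-lab
protocol achieves these error rates.

All randomness flows from one integer seed per generator call; derived
seeds stay below $2^{31}$.

## The multiplex integration model

Heterogeneous evidence layers over the same wines (DNA similarity, chemical
similarity, ...) form a multiplex network. The supra-adjacency matrix $M$
has the layer adjacencies $A_1, \dots, A_h$ on the block diagonal and
$\omega_{ij} I$ off-diagonal, with interlayer strengths
$\omega_{ij} = \omega_{ji} \in [0, 1]$ (0 = independent layers, 1 = total
dependence). Entries of $M^k$ count weighted walks of length $k$; the
communicability between two node copies is the corresponding entry of
$e^M$ (all walks, weighted $1/k!$, including the $k = 0$ identity term).
Layers aggregate by summing communicability over all $h^2$ layer-copy pairs
and dividing by $h$ — the normalization under which one layer reduces to
$e^{A_1}$ and decoupled layers ($\omega \equiv 0$) reduce to the plain mean
of per-layer communicabilities. The strengths are fitted by grid search
(default step 0.1, shared scalar $\omega$) minimizing the squared
edge-weight difference between the aggregate and a response network; the
full-matrix search is gated to $h \le 4$ because its cost grows as
$(1/\mathrm{step}+1)^{h(h-1)/2}$. Ties go to the smallest $\omega$. When no
external chemistry is available, layers can be built from this pipeline's
own similarity output ($1 -$ distance); the model itself is
evidence-agnostic.

## Numerical choices and degenerate inputs

* Rounding is half-away-from-zero, so `x.5` always moves outward; binning
  errors (out-of-bounds after offset) discard the peak and increment a
  logged counter instead of failing the run.
* NJ/UPGMA ties are resolved by the lexicographically smallest label pair;
  equidistant inputs therefore give one deterministic resolution.
* Incomparable pairs enter trees at distance 1.0 rather than as missing
  values; the comparability mask is preserved in `wdf_dist` and reports.
* Duplicate samples in a dataset merge only when their calls agree exactly;
  conflicts are an error naming the loci, never a silent overwrite.
* A blank `alleles` field in a genotype CSV marks the locus untyped and is
  skipped on read.
* Bootstrap replicates whose tree construction fails (degenerate resampled
  matrices) count as "cluster absent".

## Problem sizes used in the checks

The shipped test-suite and acceptance script use: 100 simulations for the
monovarietal-recovery and 85/15-blend checks, 200 per age point (with
paired per-index seeds across ages, so the age effect is measured against
common random numbers) for the minor-component fade-out, 100–200 random
additive matrices (4–12 taxa) for NJ exactness, 100 random spectra for the
PI oracle, and exhaustive enumeration over all undirected graphs on up to 5
nodes for the walk-count oracle. These sizes make the stochastic checks
reproducible and sharp while keeping a full run in the low minutes on one
CPU.

## Known limitations

* The inclusion score is not a calibrated probability; likelihood-ratio
  mixture statistics and mixture-proportion estimation are out of scope.
* Allele frequencies from a handful of reference varieties are noisy; PI
  values from small reference sets should be read as panel diagnostics, not
  population parameters.
* The dropout law is a two-parameter phenomenological model anchored to
  qualitative observations; absolute rates in real cellars will differ.
* Trees are distance-based; no maximum-likelihood or Bayesian phylogenetics.
* The multiplex model is a data-integration scaffold: with only DNA-derived
  layers available it has no empirical target, and its checks are
  property-based (oracles and self-consistent recovery).
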