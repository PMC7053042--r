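---
title: "Methods: pooled-sequencing diversity analysis in poolDiversity"
author: "poolDiversity authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled-sequencing diversity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolDiversity)
```

# The analysis model

Pool-seq replaces individual genotypes with read counts: each accession is
one sequencing library made from pooled DNA of many individuals, and at a
biallelic site the fraction of reads carrying the alternate allele
estimates the population alternate-allele frequency `q` in that accession.
Every statistic in this package is a single-locus function of these
frequencies:

- **Allele frequency.** `q = altReads / depth`, with `p = 1 - q` anchored
  to the reference-genome allele so polarity is identical across pools.
  Cells below a depth threshold are missing, never imputed.
- **Gene diversity.** Expected heterozygosity `2pq` per site, averaged per
  pool over non-missing sites, then summarized per lineage as mean ± sample
  sd over member pools. `2pq` is the plug-in estimator; no finite-pool-size
  bias correction is applied (the quantity compared across accessions is
  the same plug-in everywhere, so the shared downward bias of order
  `1/(2N)` cancels in comparisons).
- **Lineage-specific variation (LSV).** After discretizing frequencies into
  allele states (ABSENT / SEGREGATING / FIXED / MISSING), a site is LSV for
  lineage L when every pool inside L is FIXED and every pool outside L is
  ABSENT — homozygous private variation. At the species level the outside
  set is empty, so the condition degenerates to fixation in all pools; we
  report that level for completeness but flag the degeneracy here.
- **Relationships.** Variant presence (alternate reads ≥ a small threshold)
  gives shared-variant counts `N_ij`; Dice `2N_ij/(N_ii+N_jj)` or cosine
  `N_ij/sqrt(N_ii N_jj)` coefficients give an identity-by-state similarity.
  A KING-robust kinship route is also provided: pool frequencies are
  discretized to pseudo-genotypes (0/1/2) and the robust estimator
  `(N_het,het - 2 N_opposite-hom)/(N_het(i)+N_het(j))` is applied.
  Distances (`1 - r`, or `max(0.5 - phi, 0)` for kinship) feed Saitou–Nei
  neighbor joining with site-bootstrap support.
- **Structure.** PCA by SVD of the per-locus mean-centered pool × site
  frequency matrix; AMOVA on pool frequency vectors under the squared
  Euclidean metric with among-crop-type, among-accession-within-crop-type
  and within-accession strata.

# Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| `minDepth` | 15 reads, required in **every** pool | Below ~15 reads the binomial noise on `q` overwhelms the signal; requiring it in all pools keeps the site set identical across pools, which every cross-pool comparison here assumes. The threshold is configurable; we apply it as ≥ 15. |
| `epsilon` (state tolerance) | 0 for noise-free simulated counts, 0.05 for real read counts | At 80X, a truly fixed allele still yields an occasional opposite read; `epsilon = 0.05` absorbs roughly the error rate plus binomial jitter without admitting genuinely segregating sites (which sit far from 0/1). A genotype-call mode (`poolStateFromGenotypes`) is available when the VCF carries GT calls, mapping homozygous-alt to FIXED and homozygous-ref to ABSENT. |
| `minAltReads` (presence) | 2 | One read can be a sequencing error; two concordant reads almost never are at error rates ~1e-3. |
| Pseudo-genotype thresholds | 0.25 / 0.75 | Mid-point split of the frequency range into ref-like / het-like / alt-like; only the KING route uses them. |
| `missingPolicy` (LSV) | `strict` | A missing pool inside L cannot be shown fixed, and a missing pool outside cannot be shown absent; `strict` refuses both, avoiding false privates from dropout. `lenient` treats missingness outside L as absence, which raises recall at the cost of precision. |
| Bootstrap replicates | 100 | Standard resolution for branch support; supports are multiples of 0.01. |
| AMOVA permutations | 199 default in examples | Resolution 0.005 at modest cost; the test is optional (`nPerm = 0`). |

# The synthetic-data generator

`simulateFrequencies` draws a two-level hierarchy under the Balding–Nichols
parameterization: ancestral frequency `pi ~ Beta(0.8, 0.8)` (U-shaped,
mimicking the excess of extreme frequencies in an empirical site-frequency
spectrum), crop-type frequency
`~ Beta(pi (1-F)/F, (1-pi)(1-F)/F)` with `F = fCropType`, and accession
frequencies drifted from their crop type with `F = fAccession`. `F = 0` is
the documented no-drift limit (child = parent), and frequencies already at
0 or 1 are absorbing. `samplePoolCounts` then layers the three observation
processes: binomial pool composition (`2N` gametes, default `N = 25`
individuals), Poisson read depth (default mean 80), and symmetric per-read
miscall error (default 1e-3) on the alternate-read binomial.

Defaults mirror the sequencing design the package targets: 23 pools in four
crop types of 10/7/2/4 accessions, 25 individuals per pool, ~80X, nine
chromosomes, and an indel label fraction of 0.1 (roughly the indel share of
a typical per-accession variant tally in such data). The nested drift
parameters are free knobs — no published estimate of the within-crop-type
variance structure exists for this design — and default to `fCropType =
0.1`, `fAccession = 0.02`, i.e. modest crop-type differentiation with
accessions tightly clustered inside their type. `injectLSV` appends loci
fixed in one lineage and absent everywhere else, with bookkeeping, to give
the LSV scan a known answer.

What the generator deliberately does **not** emulate: linkage (loci are
independent — every statistic here is single-locus, but bootstrap supports
on real, linked data would be anti-conservative), indel length
distributions (the label only feeds the class split in tallies), reference
bias, mapping artifacts, multiallelic error products, and any demographic
history beyond the two-level drift. Passing tests on simulations therefore
validate the estimators under the stated statistical model, not the
upstream variant-calling pipeline.

Simulation sizes used throughout the tests and the acceptance script —
1,000–10,000 loci and 12–23 pools — were chosen as the scale at which every
Monte-Carlo tolerance in the suite is comfortably met while the whole suite
runs in well under a minute per file; the statistics themselves are
dimension-free.

# Numerical and design choices

- **Depth filter semantics.** "Depth ≥ 15" is enforced in every pool
  (site dropped otherwise), so all pools share one site set. The filter is
  idempotent.
- **Biallelic across all accessions** means exactly one ALT allele in the
  merged record; multiallelic records are read (alternate counts summed)
  but excluded by the default filter.
- **q, not p, is stored.** `p` is always derived, so the polarity
  convention (reference allele = p) cannot drift between modules.
- **Missing cells** are excluded, never imputed: per-pool means skip them,
  PCA and AMOVA are complete-case by site.
- **LSV tallies.** Per-chromosome mean = lineage total / number of
  chromosomes. Published tables of this kind do not always satisfy such
  identities exactly (rounding, post-hoc edits); the package's
  `consistencyCheck` enforces them on everything it produces.
- **Lineage diversity aggregation** exposes an exclusion set because
  published crop-type means for collections containing near-homozygous
  inbred or self-fertile accessions are typically computed after dropping
  them; which pools were dropped is a reporting choice, so the package
  makes it explicit rather than guessing.
- **NJ determinism.** Neighbor joining is delegated to `ape::nj`
  (deterministic for a given matrix; ties resolved by first index). Dice
  and cosine coefficients lie in [0, 1] so `d = 1 - r` is a proper
  dissimilarity; KING-robust kinship may be negative, so `d = max(0.5 -
  phi, 0)` anchors self-kinship at distance zero and clips the scale at
  zero.
- **Bootstrap unit = sites (loci)**, the standard phylogenetic bootstrap;
  supports are fractions of replicate trees containing each original
  bipartition, computed on the unrooted topology.
- **AMOVA.** Whole-matrix (multilocus Euclidean) decomposition rather than
  per-locus-then-average: the two give identical sums of squares (the SS
  are additive over loci), and the whole-matrix route keeps the df
  bookkeeping unambiguous. Unequal group sizes use the standard weighted-n
  coefficients. Negative variance components are truncated to zero before
  percentages. With one pool per accession — the design this package
  targets — the within-accession stratum has zero df; its component is
  reported as 0 with an explicit note, and the residual variation appears
  in the among-accession stratum. Stratum labels are written out in full
  (`among_crop_types`, `among_accessions_within_crop_types`,
  `within_accessions`) precisely because abbreviated labels in published
  AMOVA tables of this kind are easy to transpose.
- **Permutation test.** Accession-to-crop-type labels are permuted (pools
  move with their accession); `p = (1 + #{sigma_perm >= sigma_obs}) /
  (nPerm + 1)`. The identity assignment can recur among sampled
  permutations, so the attainable minimum `1/(nPerm+1)` is reached only
  when no sampled permutation ties the observed grouping.
- **PCA.** Per-locus mean-centering, no variance scaling: centering is what
  makes `d_k^2 / sum d^2` a variance-explained; scaling would equalize
  locus contributions and change the geometry. Scores are reported up to
  sign (an SVD ambiguity).

# Known limitations

- All estimators are plug-in; no unbiased pool-seq corrections
  (finite pool size, unequal individual contributions to the pool).
- The LSV definition is sharp (fixed inside, absent outside); borderline
  frequencies move sites in and out of the set as `epsilon` changes, and
  both the ABSENT and FIXED regions widen with `epsilon`, so the LSV set is
  not monotone in `epsilon`.
- Species-level "LSV" without an outgroup is simply fixation everywhere.
- KING-robust was designed for diploid genotypes; on pseudo-genotypes from
  pools it is a heuristic similarity, offered alongside Dice/cosine, not a
  kinship estimate in the formal sense.
- AMOVA percentages depend on the stratum structure available: with one
  pool per accession the within-accession variance is not estimable and
  the reported percentages cover the remaining strata.
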