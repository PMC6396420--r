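---
title: "Bayesian noninvasive fetal genotyping from cfDNA: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian noninvasive fetal genotyping from cfDNA: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nipgeno)
```

## The inference problem

Cell-free DNA in maternal plasma is a mixture: a fraction *f* (the fetal
fraction, typically 5–25%) of the fragments derive from the placenta and
carry the fetal genotype, the rest are maternal. Given both parents'
germline genotypes at a biallelic site and the alleles observed on the
cfDNA fragments covering it, we want the fetal genotype. Sites fall into
categories fixed by the parental genotypes:

* **maternal-only heterozygous** (mother 0/1, father homozygous): the hard
  case — both alleles circulate in the mother's own plasma, and the fetal
  genotype shifts the allele balance only by ~*f*/2;
* **paternal-only heterozygous**: the informative paternal allele makes the
  call comparatively easy;
* **double-heterozygous**: all three fetal genotypes are possible (chance
  accuracy 1/3, vs 1/2 for the single-parent categories);
* **fetal-informative** (parents homozygous for *different* alleles): the
  fetus is an obligate heterozygote — no call needed, but these sites
  identify fetal fragments and anchor the fetal-fraction estimates;
* **uninformative** (parents share the same homozygous genotype): skipped.

## Posterior, prior, likelihood

For fetal genotype $G$ with Mendelian prior $P(G)$ (allele-transmission
probabilities from the parental genotypes; genotypes requiring a de novo
mutation get prior 0 and are never resurrected by data):

$$P(G\mid\text{data}) = \frac{P(\text{data}\mid G)\,P(G)}
  {\sum_i P(\text{data}\mid G_i)\,P(G_i)},\qquad
P(\text{data}\mid G)=\prod_{j=1}^m\bigl[P(r_j\mid\text{fet})\,f_j +
  P(r_j\mid\text{mat})\,(1-f_j)\bigr].$$

Each fragment $r_j$ is a two-component mixture: fetal with probability
$f_j$, maternal otherwise. The emission probability of the observed allele
is 0.5 under a heterozygous source and $1-\varepsilon$ / $\varepsilon$
under a matching/mismatching homozygote. With $\varepsilon = 0$ this is the
idealized model in which, e.g., a fragment showing allele A under fetus
$aa$ and mother $Aa$ has likelihood $0\cdot f + 0.5\,(1-f)$; the package
default is $\varepsilon = 10^{-3}$, because under exact-zero emissions a
single sequencing error annihilates a genotype's likelihood. The model
degenerates continuously to the idealized form as $\varepsilon\to 0$, and
$\varepsilon = 0$ remains available. Base and mapping qualities are *not*
folded into $\varepsilon$: quality is handled by lenient pre-filters
(defaults mapQ ≥ 20, baseQ ≥ 13) before modelling, and again post hoc by
recalibration — never inside the likelihood.

All likelihood arithmetic is in natural-log space with max-shift
normalization: at hundreds of fragments per site the linear-space product
underflows. With zero observations the posterior equals the prior exactly.
Exact posterior ties (possible at symmetric priors with no data) break
toward the earlier genotype in (0/0, 0/1, 1/1) and set a `tie` flag, so
calls are deterministic. In the measure-zero degenerate case where
$\varepsilon=0$ data annihilate every admissible genotype, the posterior
falls back to the prior rather than returning NaN.

## The fragment-length-dependent fetal fraction

Fetal fragments are shorter than maternal ones — length modes near 140 bp
vs 166 bp, with heavily overlapping distributions. Instead of enriching by
a hard size cutoff (which discards information), each fragment's mixture
weight is the fetal fraction *of its own length bin*. At fetal-informative
sites, fragments carrying the paternal-specific allele are certainly fetal
(count $b$), fragments carrying the maternal allele form the background
(count $a$); since the fetus is an obligate heterozygote, only half of its
fragments show the paternal allele, giving the total-fraction estimator

$$\hat f = \frac{2b}{a+b},$$

clamped to $[10^{-6}, 1]$. The same estimator within each 1-bp length bin
gives $\hat f_L$; bins with fewer than `min_count` (default 50) informative
fragments fall back to $\hat f$, as do fragments that are not properly
paired or longer than `max_tlen` = 500 bp. Two documented approximations
are accepted rather than corrected: the "shared" length histogram is
contaminated by the minority of fetal fragments carrying the maternal
allele, and no smoothing is applied across adjacent bins by default (an
odd-width moving average is available). An alternative `method =
"rescaled"` derives $\hat f_L$ by mixture inversion from the two labelled
length distributions and $\hat f$ — useful when per-bin counts are thin —
but the direct per-bin estimator is the default.

## Evidence extraction

The caller's only read-level input is the evidence store: one row per
(fragment, site) with the supported allele, absolute template length,
pairing flag, qualities and a fragment identifier. Extraction rules: at
most one observation per physical fragment per site; if both mates cover
the site and disagree, the fragment is discarded; duplicate-flagged,
secondary and supplementary alignments are skipped; a template length of 0
marks "unavailable" and forces the not-properly-paired fallback. SNP
support is the base at the site after a CIGAR walk. Indel support requires
the read's local haplotype — the query bases aligned within the REF-allele
interval, insertions anchored inside it included — to match exactly one of
the two allele sequences, with the alignment spanning one base past the
interval so a truncated insertion cannot masquerade as reference; anything
ambiguous is discarded. This is deterministic and caller-independent, at
the price of discarding reads a realigning caller might rescue. Indels are
taken left-normalized as provided; no re-normalization is attempted, and
multi-allelic records are excluded by design.

## The synthetic trio generator

Since real cfDNA trios with fetal ground truth are controlled-access, the
generator is a first-class module emulating their statistical structure:
parental genotypes drawn to hit requested per-category site counts, the
fetal genotype drawn from the Mendelian prior, depth per site Poisson
(negative binomial optional), each fragment fetal with probability
`true_ff`, lengths from discretized skew-normal laws re-anchored so the
discrete modes sit exactly at 140 bp (fetal, scale 22) and 166 bp
(maternal, scale 18, right-skewed; ≈90% of mass in 100–220 bp — only the
modes are anchored in published fragmentomics, the family is a
pragmatic choice), ~1% improperly paired. Defaults — 2,000 sites per
category, fetal fraction 0.15 (first-trimester-typical), depth 100 (the
lower edge of the conventional 100–1000 filtering band) — are fixed study
conditions, not tuning knobs.

Allele errors default to a quality-linked law: each observation draws a
phred base quality from N(33, 6) and flips with its phred-implied
probability (mean error ≈ 10⁻³); a constant `error_rate` is available.
Optionally a fraction `p_noisy_sites` of loci are simulated as error-prone
(mismapping-like) artifacts: flip rate `noisy_error_rate` (default 0.1)
and depressed mapping qualities. This is off by default and switched on
(at 5%) for the recalibration experiments, whose premise is that call
errors carry feature-detectable structure — as systematic artifacts do in
real data. What the generator does *not* emulate: alignment and capture
biases, GC effects, strand information, multi-allelic sites, linked errors
along a fragment. Passing tests therefore demonstrate correctness of the
inference machinery under the stated generative law, not performance on
real sequencing data.

## Fetal-fraction and depth reduction

To emulate harder sequencing settings from one deep family, the store is
subsampled. Writing $f$ for the site-level observed fraction (twice the
paternal-specific allele share where identifiable, else the store-wide
total, which also substitutes when $d \ge f$) and $d$ for the target:

* **identifiable sites** (mother homozygous, father carrying the other
  allele): discard $N = (1-d/f)\,b$ of the fetal-allele reads — $N$
  rounded down or up at random with probability equal to its fractional
  part, an unbiased realization — then sample $N$ shared-allele reads with
  probability proportional to their length's frequency in the fetal length
  distribution and redraw their lengths from the maternal distribution,
  and finally generate $N$ new shared-allele reads with maternal-law
  lengths (qualities copied from a random template read at the site).
  Per-site totals are conserved; the expected paternal-allele share lands
  exactly at $d$;
* **maternal-heterozygous sites**: no fetal-specific allele exists, so only
  the length signal can be adjusted: a share of reads is sampled by
  fetal-length frequency and given maternal-law lengths. The package
  converts the *excess fetal mass*, a $(1-d/f)f$ share — the same quantity
  the identifiable branch converts. The superficially simpler alternative
  of converting a $d/f$ share (available as `maternal_het_rule =
  "literal"`) converts *more* lengths the *smaller* the requested
  reduction is, erasing the length signal most when it should be least
  disturbed; on synthetic grids it inverts the expected dependence of
  accuracy on fetal fraction, so it is not the default.

Depth reduction is simpler: every observation is kept independently with
probability target-median / measured-median. `grid_experiment()` composes
reduce → downsample → re-estimate profile → genotype → evaluate per grid
cell and returns a tidy table; on the package's synthetic families the
accuracy surface is non-decreasing in both depth and fetal fraction for
every category, with paternal-only ≥ maternal-only ≥ double-het — the grid
used in the tests is 3×3 (fractions 0.05/0.10/0.20 × median depths
50/100/150) from a base family of 1,500 sites per category at fraction
0.25 and depth 200.

## Recalibration

A seeded probability random forest (500 trees, single-threaded for
determinism, inverse-class-frequency case weights) is trained per category
to predict whether a call is correct, from a fixed, versioned feature
schema: site features (variant type, category, one-hot parental genotypes,
depth, allele counts and balance, per-allele length/quality means and SDs
with zero-imputation plus presence flags, improper-pair fraction) and
caller features (the three posteriors and log-likelihoods, the call,
prior/posterior entropies, the total fetal fraction and the mode used).
Strand balance is deliberately absent — the evidence store keeps no strand.
Training pools follow the category structure: maternal-only and double-het
SNP models train within category; the paternal-only model pools all three
categories (its own error rate is too low to learn from); indel models
pool SNPs and indels of the same category. A 25% held-out split is scored
and stored with the model. Scores in [0, 1] filter calls at a conventional
0.7 operating point. In the cross-family experiments (train two synthetic
families, test five others drawn from the same law), the recalibrated AUC
matches or exceeds the raw-posterior AUC in every category and filtering
raises retained-subset accuracy; the gain is largest where the raw
posterior is blind (systematically corrupted loci called with high
confidence).

## Numerical and interface choices

* Coordinates are 1-based VCF externally; the store serializes as gzip TSV
  plus a JSON sidecar carrying the schema version (mismatches are hard
  errors naming both versions); profiles serialize as TSV + JSON with the
  total fraction duplicated in C99 hex float notation so the round trip is
  bit-exact; calls are written as VCF 4.2 (sample `FETUS`, posteriors to 6
  decimals, category/depth/mode in FORMAT fields, `NOOBS` flagging
  zero-observation sites).
* Every stochastic operation takes an explicit seed and restores global RNG
  state (`withr::with_seed`); identical seeds give bit-identical stores,
  reductions and forests.
* Depth/posterior filtering (e.g. depth 100–1000, posterior > 0.99) is
  post hoc, in `filter_calls()`, never inside the caller.
* Test and acceptance problem sizes (≈2,000–5,000 sites per arm, depths
  50–200, 2–5 replicates) were chosen as the smallest at which the checked
  contrasts are statistically stable.

## Limitations

Multi-allelic sites, de novo mutations and structural variants are out of
scope; parental genotypes are taken as hard calls (their uncertainty does
not enter the prior); haplotype-based approaches are intentionally
avoided; the evidence extractor's strict exact-match indel rule discards
ambiguous reads rather than realigning; and all performance statements in
this package are statements about its synthetic generative law.
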