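---
title: "Methods: windowed divergence scans and genomic islands with divscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed divergence scans and genomic islands with divscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divscan)
```

## What the package computes

divscan scans a two-population whole-genome SNP panel for *genomic islands
of differentiation*: contiguous regions whose divergence stands out
against the genome-wide background. The workflow is the one population
genomicists assemble from VCFtools, pixy, PLINK, bedtools and
clusterProfiler, reimplemented as one tested package:

1. ingest a (preferably all-sites) VCF, a sample-to-population map and a
   GFF3 annotation;
2. hard-filter sites and LD-prune;
3. compute per-individual heterozygosity and sliding-window nucleotide
   diversity ($\pi$), absolute divergence ($D_{xy}$) and Weir–Cockerham
   $F_{st}$;
4. flag the empirical top 1% of windows for each statistic, merge nearby
   outliers into regions, and intersect the $F_{st}$ and $D_{xy}$ flag
   sets into conservative *core islands*;
5. extract overlapping genes and test functional-term over-representation
   with one-sided hypergeometric tests;
6. estimate pairwise IBD relatedness (PI\_HAT) and LD decay as cohort
   quality checks.

A Balding–Nichols simulator generates two-population panels with known
ground truth, which is how every statistical claim in the test suite is
validated.

## Estimators

**Per-site diversity and divergence.** With $c$ copies of the alternate
allele among $n$ called alleles, per-site diversity is the mean pairwise
difference $\pi_s = c(n-c)/\binom{n}{2}$. Between populations with counts
$(c_1, n_1)$ and $(c_2, n_2)$, absolute divergence is
$d_s = \big(c_1(n_2-c_2) + c_2(n_1-c_1)\big)/(n_1 n_2)$.

**Missing-data-aware windows.** A window's $\pi$ is
$\sum_s \text{numerator}_s / \sum_s \text{pairs}_s$ over all callable
sites: invariant sites contribute zero numerator but a full denominator,
and sites where a population has no called allele are skipped from both.
This ratio-of-sums construction (the pixy approach) keeps $\pi$ and
$D_{xy}$ unbiased under genotypes missing completely at random, which the
test suite checks by masking 10% of calls and bounding the shift by 3
standard errors of the unmasked estimate. Without all-sites input the
absolute values are meaningless, so a `window_length` denominator mode
exists for variant-only VCFs and is labelled as such in the output.

**Weir–Cockerham $F_{st}$.** Each biallelic site yields the three
variance components of the two-level diploid analysis — $a$ (among
populations), $b$ (among individuals within populations), $c$ (within
individuals) — from the per-population sample sizes, allele frequencies
and observed heterozygote frequencies. Windowed $F_{st}$ is the ratio of
sums $\sum a / \sum (a+b+c)$ (the "weighted" estimate of the reference
tools), which is far more stable across windows than averaging site
ratios. Negative values are retained: clamping at zero would distort the
empirical percentile used for outlier calling. Components are
cross-checked against an independent implementation that goes through the
ANOVA mean squares instead of the closed-form expressions; both routes
agree to $10^{-10}$ over a thousand random genotype configurations.

**Outliers, merging, core islands.** The top fraction (default 1%) is
rank-based: the $\lceil 0.01\,W \rceil$ highest defined window values are
flagged, ties at the realized threshold included, with no interpolated
quantile involved. Flagged windows are merged when their gap is at most
10 kb — the rule is inclusive at exactly 10,000 bp, and the boundary is
tested explicitly. Core islands intersect the $F_{st}$ and $D_{xy}$ flag
sets *at the window level* before merging; merging first and intersecting
regions would let a long merged region claim windows that were never
jointly extreme. The containment of the core cover inside both
single-statistic covers is asserted on every run. Both the pre-merge core
window count and the merged island count are reported, since either can
be the quantity of interest.

**Relatedness.** PI\_HAT comes from the PLINK-style method of moments:
identity-by-state counts (IBS 0/1/2) over informative sites are equated
to their expectations under IBD states 0/1/2 and solved sequentially for
$P(\text{IBD}=k)$. The solution is constrained sequentially: observing
*more* opposite homozygotes than the panmictic expectation ($P_0 > 1$)
means no detectable sharing and yields $(1,0,0)$; remaining negative
components are clamped and the triple renormalized. PI\_HAT
$= P_2 + P_1/2$ and dissimilarity $= 1 - $ PI\_HAT. Expectations use
plug-in allele frequencies, pooled across the whole panel by default
because that is how a single relatedness run over a mixed cohort behaves;
pooling strongly diverged populations is exactly what drives
cross-population pairs to the $P_0 > 1$ regime and PI\_HAT 0, while
*inflating* within-population values — a caveat the output documentation
repeats, and a per-population frequency mode is provided. No finite-panel
bias correction of the expectations is applied; with very small panels
(the study scale of 7 + 2) absolute PI\_HAT values should be read
qualitatively.

**LD.** $r^2$ is the squared Pearson correlation of genotype dosages on
pairwise-complete samples, restricted to sites with MAF $\ge$ 0.10 and
same-chromosome pairs within 1 Mb, and averaged in right-closed 10-kb
bins. Dense panels are thinned to 2,000 evenly spaced sites per
chromosome before pairing — binned means are insensitive to this, and it
bounds the pair count. Profiles are refused for populations under 4
samples unless forced: with $n = 2$ nearly every polymorphic pair sits at
$r^2 \approx 1$ regardless of true LD. Pruning follows the
50-SNP-window / 10-SNP-step / $r^2 > 0.2$ greedy scan, removing the
later-positioned member of an offending pair — a deterministic
tie-break, where the reference tool's choice varies by version.

**Enrichment.** Over-representation uses the hypergeometric upper tail
$P(X \ge k)$, identical to the one-sided Fisher exact test on the 2×2
table (the test suite asserts both this identity and agreement with
exhaustive enumeration for every parameter combination with $N \le 12$).
Terms with fewer than 5 universe genes are excluded before testing, the
universe defaults to the per-namespace annotated genes, and no
multiple-testing correction is applied to the ranking — a
Benjamini–Hochberg column is emitted for reference but never filters. The
$p < 0.10$ display threshold marks rows for reporting only.

## The synthetic-data generator

`simulate_two_pop()` draws, per variant site, an ancestral frequency $p$
uniform on [0.05, 0.95] and population frequencies from the
Balding–Nichols distribution
$\mathrm{Beta}\!\big(p\tfrac{1-F}{F},\,(1-p)\tfrac{1-F}{F}\big)$, then
genotypes as Binomial(2, $p_{pop}$) within each population. Because
$E[F_{st}] \approx F$ under this model, the generator is a quantitative
oracle: the test suite demands genome-wide ratio-of-sums $F_{st}$ within
±0.02 of $F$ over $F \in \{0.05, 0.2, 0.5\}$ at 5,000 sites and 20+20
samples.

The default scenario mirrors the targeted study design: 7 + 2 diploid
samples; a 2 × 40 Mb genome (a deliberately scaled-down stand-in for a
gigabase genome, sized so the top-1% scan still flags enough distinct
window clusters to probe all islands); five planted 800-kb islands
(5% of the genome) at $F = 0.6$ over an $F = 0.05$ background; one
variant site per kb plus four invariant all-sites records per variant
(callable-site denominators); constant QUAL/DP above the filter defaults;
5% MCAR missingness. An optional split-depth knob adds
$2\mu T L$ private post-split mutations per population (derived frequency
uniform in the owner population), giving the infinite-sites expectation
of $2\mu T$ added $D_{xy}$ per bp — this is where the configured
$\mu = 6\times10^{-9}$ and 3-year generation time act, and it is what
makes $D_{xy}$ grow monotonically with split depth in the tests.
`simulate_relatives()` builds MZ/PO/FS/UN pairs by Mendelian transmission
from founder frequencies; `simulate_ld_haplotypes()` builds mosaic
haplotypes from a small founder pool with distance-dependent switching,
the one generator that produces genuine LD decay.

What the generator does *not* emulate: linkage in the main two-population
panel (sites are independent given frequencies, so LD-decay profiles of
the default fixture are flat at the $\sim 1/n$ sampling floor);
realistic site-frequency spectra (ancestral frequencies are uniform, so
per-site $\pi$ is orders of magnitude above the $10^{-4}$–$10^{-3}$ of
real vertebrate data — absolute $\pi$ values from fixtures are per
emitted callable site, not per genome bp); sequencing-error or
depth-correlated artifacts; selection within islands beyond elevated
drift. Passing tests therefore demonstrate estimator correctness and
pipeline recovery under drift and missingness, not robustness to
caller-specific artifacts.

With the unbalanced 7 + 2 design, window $D_{xy}$ is dominated by the
4-allele sampling noise of the small population: under the drift-only
model the top-1% $D_{xy}$ windows are mostly background noise rather than
island windows, so the $F_{st} \cap D_{xy}$ core-island count is small
and volatile (typically 0–5 on the default fixture). That mirrors the
intent of the dual threshold — it is an extremely stringent filter — and
is why recovery guarantees are asserted for the $F_{st}$ regions, not the
core set.

## Numerical and design choices

- **Coordinates.** Everything interval-shaped (windows, regions, genes,
  BED) is 0-based half-open; VCF positions stay 1-based on the site
  table, with the boundary rule $s \le pos - 1 < e$ tested at both edges.
- **Hard-filter defaults** (QUAL ≥ 30, depth within 1/3×–2× of the mean
  site depth, missingness ≤ 0.10, MAF ≥ 0.05) are package choices, not
  reported values: the source protocol names the filter axes without
  printing thresholds, and the MAF/missingness values match its pruning
  stage. Every rule is configurable and can be disabled; drops are
  attributed to the first failing rule in a fixed order
  (chromosome → QUAL → depth → missingness → MAF). The depth rule is
  mean-relative rather than absolute — with per-dataset coverage varying
  7–11×, fixed bounds would not transfer.
- **Half-missing genotypes** (`./1`) are coded missing; phase separators
  are ignored.
- **Fst windows** with fewer than `min_variant_sites` (default 1) variant
  sites are flagged undefined (`NA`) and excluded from ranking rather
  than set to 0.
- **Degenerate inputs**: empty flag sets merge to empty region sets; an
  all-equal value vector flags everything with a warning; windows shorter
  than the window size are truncated at chromosome ends.
- **Problem sizes in the test suite** (5,000-site recovery panels, 10
  replicates of the 80 Mb island scenario, 1,000-draw null calibrations)
  were chosen so each statistical tolerance is a 3-standard-error bound
  with comfortable margin while the whole suite stays in the minutes
  range on a laptop core.

## Known limitations

- Two populations only; no haploid or mixed-ploidy support.
- The sequential moment solution for IBD is the classic PLINK one; for
  panels of a few samples a KING-robust estimator would be preferable,
  and is out of scope.
- Enrichment assumes a flat annotation (gene → term); term topology
  (GO graph propagation) is the caller's responsibility.
- The empirical top-1% rule is purely rank-based, as in the emulated
  analysis; no significance is attached to outlier status.
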