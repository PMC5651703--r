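---
title: "Calling regulatory elements and regulatory variants from pooled reporter screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling regulatory elements and regulatory variants from pooled reporter screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(starrvar)
library(dplyr)
```

## The screen and its two questions

A pooled-capture STARR-seq screen clones ~465-bp genomic fragments, captured
around a designed panel of candidate SNPs from the genomic DNA of several
diploid individuals, downstream of a reporter ORF. Because the element
transcribes itself, the abundance of each fragment in the reporter mRNA
(*output* library) relative to the plasmid pool (*input* library) measures
its transcription-regulatory activity. Capturing a pool of individuals puts
both alleles of common variants into the library, so the same data answer
two questions:

1. **Which SNP-containing regions regulate transcription?** Regions with
   significantly more output than input are positive regulatory elements
   (PREs); significantly less, negative regulatory elements (NREs).
2. **Which variants are themselves regulatory?** A variant whose alleles
   differ in activity shifts the ref:alt allele ratio between input and
   output.

`starrvar` implements both analyses and their supporting stages. This
vignette records the model, the defaults and their rationale, the numerical
choices, and what the synthetic validation does and does not demonstrate.

## Fragment processing

Fragments are the outer spans of properly paired alignments. We keep a
fragment when its length is within 400–600 bp (the size selection of the
library) and it covers at least one panel SNP. The observed base at each
covered SNP is taken from whichever mate covers it; if both mates cover the
SNP and disagree, the call is masked to unknown, as it is when base quality
is below 20 (configurable). Unknown and non-ref/non-alt ("other") calls
stay in region counts — the fragment is still evidence of coverage — but are
excluded from allele tables.

A fragment covering *k* panel SNPs contributes one count to each of the *k*
regions. The alternative (fractional counts) would couple neighbouring
regions' statistics; counting once per region preserves each region's
coverage and matches the per-SNP independence of the downstream tests.
Coordinates are 0-based half-open internally (fragments, peaks) and 1-based
in variant tables; the converters in `pos_to_zero()` / `zero_to_pos()` are
the only place this mapping lives. PCR-duplicate collapsing is off by
default — at several hundred fragments per 500-bp region, true fragment
multiplicity is expected and indistinguishable from duplication without
UMIs.

## Element activity: the negative-binomial Wald test

Counts are normalized with median-of-ratios size factors: the factor for
library $j$ is the median over regions $r$ of $K_{rj} / (\prod_j K_{rj})^{1/n}$,
using regions with all-positive counts. Per region we fit

$$\mu_{ij} = s_j \, q_i \, 2^{x_j \beta_i}, \qquad K_{ij} \sim \mathrm{NB}(\mu_{ij}, \alpha_i),$$

with $x_j = 1$ for output libraries, by iteratively reweighted least
squares, and test $\beta_i = 0$ with the Wald statistic
$\hat\beta_i / \mathrm{SE}(\hat\beta_i)$ against the standard normal. The
reported `log2FC` is the unshrunken maximum-likelihood $\hat\beta_i$: effect
sizes feed the allelic stage and truth comparisons, where shrinkage would
bias recovery checks.

**Dispersion.** With two replicates per condition the per-region
method-of-moments dispersion,
$\hat\alpha_r = (v_r - \xi \bar\mu_r)/\bar\mu_r^2$ with
$\xi = \mathrm{mean}(1/s_j)$, has only two residual degrees of freedom, so
it is stabilized in two steps:

* a mean–dispersion trend $\alpha(\mu) = a_0 + a_1/\mu$ fitted by weighted
  least squares of the excess variance on $(\mu^2, \mu)$ across all regions
  (weights $\propto 1/\mathrm{E}[v]^2$, iterated three times) — pooling
  across regions makes the trend accurate even though each region is noisy;
* empirical-Bayes shrinkage of $\log\hat\alpha_r$ toward
  $\log\alpha(\bar\mu_r)$ with prior variance 0.25 and sampling variance
  $\psi_1(\mathrm{df}/2)$ (trigamma), the asymptotic variance of a
  log-dispersion estimate.

Two guards matter for calibration. A region whose moment estimate is
non-positive (about half of all regions at these degrees of freedom) carries
no usable individual information; it takes the trend value rather than a
floored value — log-averaging a floored near-zero estimate would silently
collapse that region's dispersion several-fold and inflate the far tail of
the Wald statistic, exactly where FDR control at $10^{-5}$-scale p values is
decided. Positive estimates are bounded to trend$\times[1/64, 64]$ before
log averaging for the same reason. With these choices, Wald p values on
2000-region null screens are uniform (Kolmogorov–Smirnov distance < 0.05)
and Benjamini–Hochberg keeps the realized false discovery proportion at the
nominal 0.01.

**Classification.** Regions with mean normalized count below 10 are labelled
`filtered` and excluded from the BH burden (a fixed, transparent independent
filter; threshold optimization would make the tested set depend on the data
in ways that are hard to audit). Remaining regions are `PRE` if
`padj < 0.01` and `log2FC > 0`, `NRE` if negative, else `inactive`. The NB
stage is implemented in-package — the screen specifies a method class, not a
particular external implementation — but tests cross-check the size factors
against DESeq2 (agreement to 1e-10; both implement the same estimator) and
the fold changes against both DESeq2 (correlation > 0.98) and an exact
Poisson GLM in the vanishing-dispersion limit.

## Regulatory variants: allelic imbalance

Per SNP and library we tally ref and alt fragment counts. "Normalized by
coverage" is implemented as per-library depth rescaling — each library's
counts are scaled by (mean library depth / library depth) — because the
tested quantity is the within-SNP allele ratio, which depth rescaling
preserves while making the pooled-count filter comparable across libraries.
A per-SNP coverage rescaling is available (`normalize = "snp"`) for
sensitivity analysis. Replicates are pooled within condition; SNPs with any
pooled normalized count below 10 (ref or alt, input or output) are excluded
and reported.

The effect size is the ratio of ratios
$(\mathrm{out}_{alt}/\mathrm{out}_{ref}) / (\mathrm{in}_{alt}/\mathrm{in}_{ref})$
(the reciprocal is also reported). Significance comes from the two-sided
Fisher exact test on the pooled table arranged alleles × condition. Exact
tests need integers, so pooled normalized counts are rounded half-to-even
(R's `round()`), a deterministic rule that does not drift sums upward. BH
adjustment runs across all tested SNPs and `padj < 0.1` flags a SNP
regulatory; each flagged SNP is annotated with its host region's class. The
binomial sampling model behind the exact test is appropriate here because,
conditional on a region's total, fragment alleles are draws from the pool's
chromosomes (see the generator below); a beta-binomial extension for
overdispersed allele ratios is deliberately out of scope.

`fisher_exact_cmle()` reports the conditional maximum-likelihood odds ratio
(the estimate that maximizes the noncentral hypergeometric likelihood given
the margins) with a 95% CI by likelihood inversion, delegating to
`stats::fisher.test()` — the canonical implementation of exactly this
estimator. The test suite verifies its two-sided p against exhaustive
hypergeometric enumeration on every 2×2 table with total at most 40. Tables
with a zero margin carry no information: p = 1, odds ratio missing.

## Enrichment and motif disruption

Peak overlap is point-in-interval on the SNP position (not fragment
overlap): a 500-bp fragment would overlap peaks its variant has nothing to
do with. Enrichment of one SNP class against another is the conditional-MLE
odds ratio on the in-peak × class table. The production overlap path uses
GenomicRanges; tests check it against a naive $O(nm)$ membership scan.

PWM scoring uses log2 likelihood ratios against a background (uniform by
default, configurable), with pseudocount 0.01 added per cell before
normalization. Each allele's score is the maximum over all motif windows
covering the SNP, on both strands by default; the delta score is alt minus
ref, and max |delta| ≥ 3 over motifs marks a SNP motif-disrupting (an 8-fold
likelihood change — large enough that sub-threshold jitter from pseudocount
choices does not flip calls). ChIP-seq peak support is an optional extra
filter so the stage runs without external tracks.

## Coverage simulation and eQTL stage

`coverage_curve()` answers the design question "how many pooled individuals
make both alleles of the panel visible?": sample $i$ individuals without
replacement, count SNPs whose sampled genotypes contain both alleles, divide
by the designed panel size (not the polymorphic count — the designer cares
about the whole panel), and repeat (5 by default) for a standard deviation.
The closed form $1-(1-f)^{2i}-f^{2i}$ holds for with-replacement HWE
sampling, so the analytic check is run only on pools much larger than $i$.

The eQTL stage residualizes expression on somatic copy number and promoter
methylation (OLS with intercept — residualization without an intercept is
almost surely never intended even when model equations omit it), then
regresses residuals on genotype dosage (0/1/2 additive by default; a
carrier-vs-noncarrier group mode and one-sided tails are options).
Covariates are not standardized, so coefficients stay in the data's units.
When genotype is orthogonal to the covariates in sample, the two-step
estimate equals the joint-OLS genotype coefficient; the tests verify this to
1e-8 and exact recovery on noiseless data.

## The synthetic-data generator

`simulate_dataset()` emulates the screen end to end: a panel of tag + linked
SNPs (positions spaced 5 kb on a synthetic chromosome so regions are
disjoint), a diploid pool drawn under Hardy–Weinberg with independent SNPs
(LD structure is irrelevant to every statistic under test), and counts at
region × allele × replicate resolution — the resolution the statistics
consume. Library noise is one gamma factor per region per library (mean 1,
variance = `nb_dispersion`) shared by both alleles, with Poisson counts
around it: each allele count is marginally NB(mean, dispersion), while the
allele split given the region total stays binomial — the distribution
implied by sampling each fragment's allele from a pool chromosome.
Independent NB draws per allele would inflate allele-ratio noise beyond what
any chromosome-sampling process can produce and would misrepresent the
screen the exact test is calibrated for.

Output means are input means × the region's activity fold change, times the
allelic effect on alt-allele fragments — multiplicative, matching the
ratio-of-ratios effect definition. Defaults: MAF uniform on [0.05, 0.5], ten
pooled individuals, 200 fragments per region per library, two replicates,
dispersion 0.02 (deep, well-correlated replicate libraries; the real
libraries' dispersion is not published, so this is configurable and echoed
in output metadata), fragment lengths N(465, 30) truncated to [400, 600].
Planted activities live inside a 0.5–16-fold range: PRE folds log-uniform on
[1.25, 16], NRE on [0.5, 0.8] — asymmetric because the fold scale itself is
asymmetric below 1, and sub-1.25-fold effects are biologically
indistinguishable from inactive at screen depth. Exact effects (for
recovery studies) are planted via degenerate ranges such as
`pre_log2fc_range = c(1, 1)`. Allelic effects are planted only at SNPs whose
sampled pool carries both alleles; an effect at a monomorphic SNP would be
unobservable ground truth and would corrupt recovery denominators.

Per-fragment records (lengths, positions covering the SNP, alleles) are
derived from the counts, so all outputs stay cross-consistent; generation is
toggleable because the million-fragment tables are irrelevant to count-level
studies. A minimal SAM writer emits proper pairs from those fragments to
exercise the SAM reader round trip.

**What passing tests show — and don't.** Recovery and FDR results on this
generator validate the statistics under the generator's assumptions:
disjoint regions, haplotype-free pools, no capture-efficiency or GC bias, no
sequencing error, no PCR duplication structure. Real screens violate all of
these to some degree; in particular, systematic reference-mapping bias and
capture bias can shift allele ratios coherently across libraries in ways no
within-screen test detects. The validation demonstrates correctness of the
implementation, not robustness to artefacts the generator deliberately
omits.

## Validation problem sizes

The shipped suite uses sizes chosen to make the Monte-Carlo error of each
check small relative to its margin: 20 null screens of 2000 regions for FDR
calibration (bounds set at nominal level + 3 binomial standard errors of a
20-screen mean, fixed a priori); three 500-region screens at depth 500,
dispersion 0.01 for activity recovery and two 1000-SNP screens at depth 1000
for allelic recovery (the depths at which the planted effects are
comfortably identifiable — recovery at threshold depth is power-limited, not
implementation-limited); 50 round-trip simulations for enrichment CI
coverage; exhaustive enumeration of all 135,751 2×2 tables with total ≤ 40
for the exact test.

## Known limitations

* Two-condition design only (input vs output); no covariates, no
  multi-factor designs, no outlier-count replacement.
* The Wald normal reference with two replicates per condition is
  approximate; p values near machine precision should not be
  over-interpreted.
* Allelic tests assume binomial allele sampling within regions;
  overdispersed allelic noise (e.g. from capture bias) is not modelled.
* The SAM reader supports the minimal mandatory fields and proper pairs
  only — BAM/CRAM, supplementary alignments and indels at SNP sites are out
  of scope (align and name-sort upstream).
* eQTL fitting is per-variant; genome-wide scans and latent-factor
  correction belong upstream or downstream of this package.
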