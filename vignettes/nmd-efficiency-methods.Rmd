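---
title: "Quantifying individual NMD efficiency: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying individual NMD efficiency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NMDeff)
```

## The problem

Nonsense-mediated mRNA decay (NMD) degrades transcripts that terminate
translation prematurely — those carrying premature termination codons (PTCs)
from nonsense or frameshift variants — and a class of endogenous transcripts
whose architecture mimics premature termination (upstream open reading
frames, splice junctions in the 3'UTR). The pathway's efficiency is not a
constant of the transcriptome: it differs between tissues and between
individuals. This package estimates that efficiency per sample (iNMDeff) from
standard bulk RNA-seq count data and provides the statistics needed to test
whether the variation is structured rather than noise.

## The two estimators

Both estimators are maximum-likelihood negative-binomial (NB) regressions
with a log link, fitted by `MASS::glm.nb` (iteratively reweighted least
squares with alternating profile estimation of the dispersion `theta`).

**ETG.** Within one sample, raw counts of NMD-target transcripts and their
same-gene control transcripts are pooled and modeled as

$$\log \mu = \beta_0 + \beta_1\,\mathrm{NMDtarget} + \mathrm{geneID} +
\beta_{len}\,\mathrm{transcriptLength},$$

with the gene identifier as a fixed effect. Pairing target and control within
the same gene is the crucial internal control: a copy-number change or a
trans-acting factor scales both transcripts and is absorbed by the gene
effect, leaving $\beta_1$ to measure only the target-specific attenuation.
Transcript length (total exon length, nt) absorbs the length bias of read
counting; it enters untransformed by default with a log-length switch.

**ASE.** At heterozygous germline PTC loci, the two allele counts of each
variant form one internally controlled contrast:
$\log \mu = \beta_0 + \beta_1\,\mathrm{NMDtarget} + \mathrm{geneID}$, one row
per allele. The gene (not the variant) is the blocking factor, exactly as the
model is written; when several variants share a gene they share one baseline,
a documented consequence rather than a bug.

In both cases `iNMDeff = -beta1`, so `exp(-iNMDeff)` is the modeled
target/control (or MUT/WT) expression ratio: values above 1 mean the target
is *more* abundant than its control — lower NMD efficiency.

An equivalent formulation fits the same models as Bayesian NB regressions
with diffuse priors; with such priors the posterior mode coincides with the
MLE to within sampling noise, so this package uses the ML fit with Wald
standard errors — its one deliberate methodological simplification. A parametric-bootstrap interval (`bootstrapInmdeffCi`) is
available where Wald intervals are doubtful (tiny unit counts, near-zero
arms). A `theta` that runs to the iteration limit signals the Poisson-like
regime where the dispersion is unidentifiable but $\beta_1$ is stable; it is
recorded in the diagnostics and deliberately not treated as non-convergence.

## Feature annotation and the PTC rules

A transcript is annotated with three NMD-relevant features:

* **uORFs** — AUG-initiated ORFs that start and terminate strictly inside the
  5'UTR ("does not overlap the CDS" is read as requiring the stop codon
  before the CDS start) with a minimum length of 30 nt counted from the A of
  the AUG through the stop codon. Overlapping uORFs are counted individually.
* **3'UTR EJC** — an exon-exon junction strictly more than 50 nt downstream
  of the first nt after the stop codon. A junction at exactly 50 nt does not
  count; the inequality is deliberately strict.
* **3'UTR GC fraction** — recorded and used only to break ties when several
  transcripts qualify as a gene's NMD target (highest GC wins, remaining ties
  broken by lexicographic transcript id so selection is deterministic).

Target/control pair selection uses median `log(TPM)` thresholds of 1 (target)
and 3 (control) — natural log by default, with the base configurable — and
requires the target/control expression ratio to be at most 0.9, optionally
also in wild-type cell-line data when such a table is supplied.

PTC classification applies the positional rules to the first nt of the stop
codon in spliced transcript coordinates:

* evading if in the last exon, within the last 55 nt of the penultimate exon,
  or within the first ~200 nt of the transcript (200 nt for the ASE rule set;
  measured on the spliced transcript, a deliberate resolution of an ambiguity
  between transcript and CDS coordinates);
* a 3'UTR EJC flips last-exon/55nt evading calls to triggering (the
  start-proximal call is not overridden);
* the dN/dS-style rule set tightens the start-proximal threshold to 250 nt
  and adds the long-exon rule: exons of 1000 nt or more evade, exons between
  500 and 1000 nt fall in a buffer zone and are excluded, and triggering
  requires an exon of at most 500 nt.

Two phrasings of the 55nt rule circulate — "within 55 nt downstream of the
last base of the penultimate exon" and "within the last 55 nt of the
penultimate exon"; this package implements the latter, the canonical reading
consistent with how the long-exon rule set states it.

Indel PTC prediction applies the edit in spliced coordinates, translates the
mutated CDS from the affected codon onward (continuing into the 3'UTR for
frameshifts), and maps the first stop of the shifted frame back through the
exon structure; positions inside an inserted block map to the nearest
original base. In-frame edits report a PTC only when the new stop precedes
the original stop codon.

## Filtering cascades

Filters run per individual and per gene/variant set. ETG: a pair survives
only if at least one member has `log2(raw count) >= 1` in at least half of
the individual's tissue cohort (whole cohort when no tissue labels exist —
restricting prevalence to the individual's own tissue keeps the filter
comparable across cohorts of unequal composition; the global fallback is
flagged); non-coding transcripts and transcripts overlapping the individual's
truncating-variant/CNA exclusion intervals are dropped; at least 2 pairs are
required and at most 50 are kept (seeded subsampling; the consensus gene set
is exempt). ASE: PASS heterozygous variants, total coverage of at least 5
(SNVs) or 2 (indels), population MAF at most 20% (exactly 20% is
kept; exclusion is strictly greater), no single-exon or
non-coding transcripts, no positively selected genes, no genes in the most
constrained LOEUF bin (conventions differ between the lowest percentile and
the lowest decile, so the bin is a configuration parameter defaulting to the
most constrained 10%), set-specific class rules, at least 3 and at most 100 variants.
Subsampling seeds derive from a global seed plus a hash of the individual id,
and are recorded in the output, so adding individuals never reshuffles
existing ones.

## Randomization statistics

**ITNVD** measures whether tissues differ: the SD over tissues of the
tissue-median iNMDeff, against a null built by permuting the sample-to-tissue
assignment with sizes preserved. The deviation is observed minus the null
median; the p-value is `(#{null > observed} + 1) / nIter` with strict
inequality, so the smallest attainable p at the default 2000 iterations is
5e-4. **TND** asks the same question for one tissue's median; its p-value is
taken in the tail matching the sign of the deviation, the minimal reading
under which both significantly high and significantly low tissues are
reportable with the one-tailed counting formula. Permutation is at the sample
level; donor-blocked permutation is available for donor-nested multi-tissue
cohorts but is off by default. The empirical FDR contrasts hit rates under randomized and
observed phenotypes — `(rand hits / rand tests) / (obs hits / obs tests)`;
the convention is fixed by the worked case (3 randomized vs 10 observed hits
at equal test totals = 30%), and the inverse ratio is attached for audit. The per-PTC
variability tests (`variabilityTest`) compare within-individual or
within-PTC structure of `pNMDeff = -log2(MUT/WT)` against a baseline that
permutes values over the whole table (a single exchangeable null);
`+Inf` scores (complete mutant degradation) are excluded from both Spearman
and variance flavors so the two metrics see the same records, and the
excess-variance p-value is a permutation tail rather than an F-test, chosen
because the permutation tail makes no distributional assumption.

## CNA signatures

Gene-level GISTIC scores are split into an amplification and a deletion block
(`amp + del` reconstructs the input exactly), and sparse principal components
are extracted by a deflation-based soft-thresholding power iteration written
for this package: loadings are thresholded at `alpha` times the largest
absolute loading of the leading component, a single global penalty scale
under which trailing noise components collapse to all-zero loadings — the
"effective PC" count falls out naturally, and the algorithm is deterministic
(SVD warm start, no RNG), so loadings reproduce bit-identically. Components
are sign-oriented so their loading sum is positive. The `(alpha, k)` grid is
scored by the median genomic lag-1 autocorrelation of the leading 1% (at
least one) of effective PCs — arm-scale events produce blocks of similar
loadings and autocorrelation near 1. The leading (highest-variance) components are
scored by default because those are the arm-scale signatures whose
autocorrelation should approach 1; a `subset = "trailing"` switch scores the
smallest effective components instead. The grid point with the maximal score subject to
a closeness threshold (default 0.9) wins; if none reaches it, the best
available is returned with a warning (the global maximizer is preferred over
the largest qualifying alpha; both are defensible and the threshold is
exposed).

Signature-phenotype association runs ASE as discovery and ETG as validation
(FDR 10% in both, Benjamini-Hochberg, validation corrected only over the
discovery hits), and calls a signature replicated only when the effect signs
agree. Focal amplifications are contiguous altered runs spanning less than
25% of a chromosome arm's genes (a configurable default — focal and
arm-level events form a continuum and any cutoff is a convention), and candidate prioritization requires expression negatively
correlated with iNMDeff and positively with the gene's own dosage, with both
correlation thresholds configurable (defaults -0.2 and +0.2, chosen as mild
effect-size floors rather than significance cutoffs).

## The synthetic cohort generator

The generator inverts the estimators' own models: control transcripts draw
from `NB(baseline * depth, theta)` with log-normal gene baselines, targets
from the same mean attenuated by `exp(-eta)`; ASE wild-type alleles from
`NB(depth * locusFactor, theta)` with mutant alleles attenuated for
triggering PTCs and at ratio 1 for evading/synonymous variants; per-sample
efficiencies are `base + tissue shift + N(0, sd)`. Defaults — depth 100
(ETG) and 30 (ASE) reads, `theta = 10`, 50 pairs, 10 variants — are the
conditions under which the recovery analyses are run. The toy genome plants uORFs and
3'UTR junctions at controlled distances (always including the 40/50/60 nt
boundary trio) with an A-free alphabet outside planted elements so the
ground-truth feature counts are exact. Library-size variation is a per-sample
log-normal factor to exercise the internal-control invariants. One global
seed fans out through `childSeed(seed, component, counter)` so adding a
component never perturbs existing streams, and every simulator returns a
manifest sufficient to compute its expected estimates analytically.

What the generator does *not* emulate: mapping bias and read-level noise,
splice-isoform mixtures, correlated gene baselines, batch structure, or
somatic subclonality. Passing recovery tests therefore demonstrate that the
estimators invert their own generative model at realistic depths and
dispersions — not that real cohorts are free of those confounders; on real
data the filtering cascades carry that burden.

## Numerical choices and degenerate inputs

* Interval arithmetic is 0-based half-open internally; GTF input is 1-based
  closed and converted at the boundary. Coordinate conversion round-trips
  exactly on both strands.
* A PTC position is reported as the 1-based CDS coordinate of the stop
  codon's first nt.
* `pNMDeff` is `+Inf` when the mutant count is zero and undefined (an error)
  when the wild-type count is zero; callers exclude such loci.
* An all-zero arm in the NB regression is flagged in the diagnostics and the
  fit attempted; non-convergence propagates as `converged = FALSE` rather
  than an error.
* Constant loading vectors have no defined lag-1 correlation and score 0 with
  a `constant` flag.
* Collinear covariates in the variance decomposition raise an error naming
  the offending pair rather than silently aliasing.

## Problem sizes used by the test suite

The suite validates parameter recovery at 200 individuals x 50 pairs (ETG,
mean absolute error below 0.1) and 200 individuals x 10 variants at 30x (ASE,
below 0.2); ITNVD unbiasedness at 20 tissues x 100 samples over 10 seeds; and
type-I error over 1500 null cohorts of 6 tissues x 15 samples at 400
permutations, sizes chosen once as the smallest at which the binomial Monte
Carlo error is comfortably inside the 4-7% acceptance band. The planted
CNA analysis uses 1000 genes x 120 samples with a 200-gene segment at 30%
carrier frequency and a 0.3 efficiency decrement. No empirical claim is made
in this vignette that the suite or `scripts/acceptance.R` does not itself
compute.

## Known limitations

The ETG method inherits any residual confounding that survives its filters
(isoform switching between conditions will masquerade as NMD variation); the
ASE method is noisy at low coverage and limited to individuals carrying
enough usable PTCs; the gene-level blocking of the ASE model pools variants
within a gene; sparse-PCA signatures are identified only up to the penalty
scale and orientation convention; and the focality cutoff, score binning and
candidate-correlation thresholds are field conventions, not estimated
quantities.
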