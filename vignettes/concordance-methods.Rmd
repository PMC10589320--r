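---
title: "Methods: measuring multi-institution WES concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring multi-institution WES concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wesconcord)
```

`wesconcord` compares somatic variant call sets, copy-number
segmentations, and complex biomarker scores produced by several
laboratories or pipelines for the same tumor cases. This vignette
documents the statistical procedures, the parameters that matter, the
numerical conventions, and what the synthetic-cohort generator does and
does not emulate.

## Variant matching and normalization

Two centers "agree" on a somatic variant when the normalized
(chromosome, position, ref, alt) keys match exactly. Because the same
indel can be written in several equivalent ways, `normalize_variant()`
first trims the shared allele suffix, then the shared prefix (always
retaining one anchor base, advancing the position), and — when a
reference context is supplied — left-aligns indels by repeatedly
shifting them toward lower coordinates while the flanking sequence
permits. The invariant, property-tested against an oracle that applies
each encoding to a context string and compares the edited haplotypes,
is that every equivalent encoding maps to one key and that
normalization is idempotent.

Literal exact matching without normalization is available
(`normalize = FALSE` in `read_variant_calls()`) because production
pipelines that compare on raw representations systematically disagree
on indels; running both modes quantifies how much of the observed
indel discordance is representational.

Variants use 1-based coordinates (VCF convention); copy-number
segments are stored 0-based half-open (BED convention), with a
`onebased` input dialect converted on read. Unknown FILTER strings map
to `other_filtered`, strings that look like quality filters (`q20`,
`LowQual`, anything containing "qual") to `quality_filtered`.

## Consensus references and agreement scoring

Without ground truth in clinical tissue, the reference for case $c$ at
support $k$ is the consensus set $R_k(c)$ of variants called by at
least $k$ distinct institutions; $R_{k+1} \subseteq R_k$ by
construction. Against a reference, TP/FP/FN counts give

$$\mathrm{PPA} = \frac{TP}{TP+FN}, \qquad
  \mathrm{PPV} = \frac{TP}{TP+FP}.$$

A case with an empty reference (no institution detected anything, or
nothing reached consensus) leaves PPA undefined; undefined ratios are
reported as missing and excluded from aggregates, never coerced to
zero. Two aggregations are emitted: pooled counts summed over cases
(primary — it weights cases by their variant burden) and the mean of
defined per-case ratios (secondary). Proportions carry exact
Clopper–Pearson 95% intervals computed from Beta quantiles
($\mathrm{Beta}(k, n-k+1)$ and $\mathrm{Beta}(k+1, n-k)$), with the
boundary cases 0 and 1 at $k=0$ and $k=n$.

### Discordance causes

Each discordant detection — a variant missed by an institution that at
least two others called, or called by a single institution only — is
assigned exactly one cause using the discordant institution's evidence
record (its pre-filter call, VAF, coverage, supporting reads, and
flags). Causes are tested in a fixed precedence order because a record
can satisfy several criteria at once:

1. low VAF or coverage (VAF < 0.10 or depth < 100; thresholds
   configurable),
2. removal by a quality/other filter,
3. merging into another alteration's annotation,
4. germline mislabeling (direction-dependent),
5. reporting as a structural variant,
6. intron/polymorphism filtering,
7. no supporting reads or off-target position,
8. flag-driven special cases (splice reclassification, promoter
   region, somatic LOH, homologous region), indel representation for
   singletons,
9. `unexplained` when no evidence exists.

One deliberate refinement: a record removed by a filter *because* it
was labeled intronic or polymorphic is classified as
intron/polymorphism filtering, not generic filter removal — otherwise
the generic filter cause (tested earlier) would absorb that category
entirely. Low VAF/coverage precedes the filter causes so that a
borderline variant that was both weakly supported and filtered is
attributed to its evidence, which is how the two-regime detection
model of the generator labels it.

## Base-level copy-number comparison

Profiles are completed to a full tiling of the comparable genome
(autosomes + chrX by default; chrY excluded because sex-chromosome
handling differs between centers), with unreported regions set to the
neutral CN 2 and adjacent equal-CN segments merged. The predominant
ploidy is the CN covering the largest base fraction, ties broken
toward the lower CN (a 50/50 diploid/tetraploid profile is called
diploid — the conservative reading).

Every base of two profiles is then exact-matched, duplication-
explained, or mismatched. Duplication correction addresses the
dominant gross discrepancy: one center calls a whole-genome
duplication (WGD) the other does not, so its entire profile is scaled
by two. The default rule declares a base explained when
$cn_a/\pi_a = cn_b/\pi_b$ (with $\pi$ the predominant ploidies). We
chose the ratio form over the additive form
$cn_a-\pi_a = cn_b-\pi_b$ (available via `rule = "delta"`) because
only the ratio rule makes a profile fully explained against its exact
doubling: an amplified segment at CN 3 in a diploid genome appears at
CN 6 after doubling, and $3-2 \neq 6-4$ while $3/2 = 6/4$. The
additive rule would charge every altered segment of a WGD-discordant
pair as a mismatch, which contradicts the scenario the correction is
meant to capture.

The comparison is implemented over interval intersections (the merged
breakpoint set of both profiles) and is exactly equal to a per-base
loop — asserted on randomized profiles against a brute-force oracle.
Mismatched bases accumulate a $|\Delta CN|$ histogram, pooled across
pairs and normalized to fractions.

### Gene-level events

The representative CN over a gene interval is the minimum across
overlapping segments for deletion calling and the maximum for
amplification calling. Classification: deep deletion at CN 0,
monoallelic deletion at CN 1 (absolute thresholds, independent of
ploidy), high-level amplification at CN ≥ ploidy + 5, low-level
amplification above ploidy. The deletion/amplification asymmetry is
deliberate: a CN of 1 is one remaining allele regardless of how many
copies the rest of the genome carries, whereas "amplified" is only
meaningful relative to the background ploidy. Per-gene agreement
across institutions is `all_agree`, `threshold_disagreement` (high-
vs low-level amplification only), or `presence_disagreement` (any
other mixture, including deep vs monoallelic deletion).

## Biomarker concordance

Scores are compared pairwise between institutions on
pairwise-complete observations (a center that cannot determine, say,
tumor purity for one case drops only that pair's case). Three
statistics per pair:

- Pearson correlation, with zero-variance vectors flagged as
  undefined rather than propagating NaN;
- the zero-intercept regression slope $b = \sum x_i y_i / \sum x_i^2$
  and the systematic deviation $(b-1)\cdot 100\%$ — the intercept is
  fixed at zero because a biomarker score of zero must map to zero
  under any calibration difference, making $b$ a pure scale bias;
- a paired Wilcoxon signed-rank test, one-sided by design (the
  direction is an explicit argument, not inferred from the data),
  exact for up to 25 non-zero differences and a continuity-corrected
  normal approximation above; exactness at cohort scale (n = 30)
  keeps small-sample p-values honest while staying deterministic.
  Zero differences are dropped; an all-zero comparison returns p = 1
  with a warning.

Cutoff status uses score ≥ cutoff as positive — the boundary counts
positive, consistent with a TMB of exactly 10 mut/MB being reported
as TMB-high while 9.95 is not. Defaults are 42 for HRDsum and
10 mut/MB for TMB; MSI cutoffs are per-institution (10% default, 40%
for a center using a different MSI tool). Per-case agreement
(`all_positive` / `all_negative` / `discordant`) is listwise: a case
with any missing score is excluded from the agreement summary. No
multiple-testing correction is applied to the pairwise p-values; they
are descriptive.

## Wet-lab versus bioinformatic variability

The replicate design measures the same samples twice over: once per
bioinformatic pipeline on a single lab's raw data, and once per
sequencing lab through a single pipeline. Before computing spreads,
each replicate column is divided by its zero-intercept slope against a
designated reference replicate — division, because the observation
model is a pure scale bias $y = b\,x$, and dividing by $\hat b$ is its
natural inverse; the operation is idempotent. Per-sample standard
deviations use the unbiased $n-1$ form (not specified by convention in
this setting; $n-1$ keeps 2-replicate SDs unbiased in scale across
axes with different replicate counts), samples with fewer than two
non-missing replicates are skipped rather than imputed, and the two
axes are compared on shared samples by a one-sided paired Wilcoxon
test (wet-lab > bioinformatic by default). Outliers beyond the
1.5×IQR whiskers of either SD distribution are flagged by sample id.
A full mixed-effects variance-component model is out of scope: the
two-matrix SD design answers the operational question (which knob
moves results more) without distributional commitments.

## The synthetic cohort generator

Every analysis stage is validated on simulated cohorts whose
discordance mechanisms are known. The generator's defaults describe a
30-case, five-institution comparison:

| parameter | default | rationale |
|---|---|---|
| cases | 30 | cohort scale of a realistic multi-center pilot |
| true variants/case | Poisson(32) | tens of somatic calls per exome in a restricted gene panel |
| VAF mixture | 80% clonal Beta(7,13), 20% subclonal Beta(2,30) | clonal peak near 0.35, subclonal mass below 0.1 |
| purity | Uniform(0.46, 0.90) | histology-style purity range of banked specimens |
| detection | 0.97 confident / 0.40 below VAF 0.10 or depth 100 | two-regime model matching the binary VAF/coverage taxonomy used in discordance review |
| filter miss / merge | 0.02 / 0.01 per confident detection | small post-detection loss channels |
| false positives | Poisson(1.5)/case, VAF ~ Beta(1.2, 25) | low-VAF spectrum of singleton artifacts |
| coverage | NegBin, means 150–320×, size 12 | wide spread of per-center exome depth |
| CN truth | ~12 altered segments (~550 kb), WGD prob 0.15 | gross aneuploidy plus occasional genome duplication |
| CN noise | ±1 kernel, p = 0.13·(0.7/purity), WGD miscall 0.05, 5 kb breakpoint jitter | purity-dependent segmentation error |
| HRD biases | 1.00, 0.95, 1.04, 0.89, 0.97 | pairwise deviations spanning roughly −15% to +9% |
| MSI cutoffs | 40% for one center, 10% otherwise | tool-driven cutoff heterogeneity |

These values were fixed once, at design time, to reproduce the
qualitative structure reported for real multi-center comparisons
(roughly half of unique variants detected by all centers, about a
quarter by a single center, consensus PPA near or above 90%, and
about three quarters of the genome CN-concordant), and the analysis
code was then held to them. The detection model is two-regime rather
than a logistic curve in VAF×depth because the discordance taxonomy
itself is binary at those thresholds; a continuous model would blur
the generative labels the classifier is validated against. Filter and
merge channels act only on confidently detected variants so that each
miss has exactly one unambiguous mechanism label under the
classifier's precedence.

Determinism: a mandatory master seed spawns per-(case, institution,
channel) sub-seeds through a counter-based hash of the institution id
and channel name, so regenerating one institution's data never
perturbs another's, and two runs with the same configuration are
byte-identical on disk. The manifest records the seed and a hash of
the full configuration.

What the generator does **not** emulate — and therefore what passing
tests cannot show about real data: FFPE artifacts (fresh-frozen
assumption), read-level errors and mapping ambiguity (no FASTQ/BAM),
panel/capture-kit differences beyond mean coverage, correlated
biomarker truths (HRD, TMB and MSI are drawn independently), germline
leakage dynamics, and real VAF spectra shaped by subclonal
architecture. Agreement metrics on simulated cohorts validate the
*arithmetic and inference machinery*, not the clinical performance of
any pipeline.

## Numerical conventions and degenerate inputs

- Predominant-ploidy ties break toward the lower CN; status boundary
  equals positive; undefined ratios are NA, never 0.
- `fill_profile` is idempotent; re-extracting non-neutral segments
  after filling round-trips the input (after merging).
- Observed biomarker scores are clipped at 0 (MSI also at 100);
  purity estimates are clipped to (0, 1].
- Empty cases are legal everywhere: an empty reference yields
  undefined PPA, a variant-free cohort renders a "no variants"
  summary, zero mismatched bases yield an empty |ΔCN| distribution.
- All randomized tests run under fixed seeds. Test problem sizes are
  chosen so the full suite runs in about two minutes: 100 kb toy
  genomes for the per-base comparison oracle, 10,000+ simulated
  variants for detection-probability recovery, 500 replicates for
  bias recovery, 200 replicates × 3 ratios for the variance
  decomposition, and a 30-case default cohort for end-to-end
  determinism.

## Known limitations

- Matching is position-exact after normalization; complex clustered
  substitutions that centers decompose differently can still fail to
  match (the annotation-merge flag captures the reviewed cases).
- The duplication correction uses whole-profile predominant ploidies;
  chromosome-arm-level duplications are charged as mismatches.
- Gene-level calls reduce a gene to min/max CN; intragenic breakpoint
  disagreements are not distinguished from whole-gene disagreements.
- The Wilcoxon direction must be chosen a priori per comparison; the
  package does not infer it.
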