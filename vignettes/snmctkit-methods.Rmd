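---
title: "snmctkit: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{snmctkit: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snmctkit)
library(data.table)
```

This vignette is the package's own account of the statistics it
implements: the assumptions behind each procedure, the tunable parameters
with their defaults and why, what the synthetic-data generator does and
does not emulate, and the places where the design was genuinely open and
a choice had to be made.

## The data model

A nucleus contributes two records. Its **methylome** is a per-cytosine
call table — chromosome, 0-based position, strand, context class
(CG/CHG/CHH), methylated read count `mc`, total read count `cov` — with
`mc <= cov` enforced at construction. Haploidy is the central structural
assumption: after PCR deduplication a true single pollen nucleus has
`cov` of exactly 1 wherever it has coverage at all, which is what makes
coverage-based doublet detection possible. Its **transcriptome** is a
column of a genes x nuclei integer count matrix with chloroplast and
mitochondrial genes flagged.

Coordinates are 0-based half-open (BED convention) everywhere internally.
Per-site call files in the wild are usually 1-based, so
`read_meth_calls()` takes `position_base` (default 1) and converts on
read; the writer mirrors it. An explicit flag was preferred over guessing
because both dialects exist and a silent off-by-one would corrupt every
region statistic downstream. Context is carried as a 3-class label in the
file rather than recomputed from a reference genome: this removes any
FASTA dependency, and the analysis operates on extractor-labelled
contexts anyway. Organelle sequences are identified by a configurable
chromosome-name set (default `ChrC`; `ChrM` can be added).

## Nucleus QC

Four filters are pure functions of a nucleus's own data; one (the doublet
censor) is a function of the cohort.

**Depth filters.** A nucleus passes RNA QC with at least 1000 reads over
at least 200 genes, and WGBS QC with at least 10% of 1-kb genome bins
covered by one or more reads. Both boundaries are inclusive ("at least"),
and the bin grid tiles each chromosome from zero in fixed 1-kb steps with
the last partial bin included. Total counts assigned to genes stand in
for "RNA-seq reads" since the count matrix is what this stage receives.

**Organelle filter.** Fails when the organelle fraction of RNA reads is
strictly greater than 10%. A nucleus with zero reads has an undefined
fraction; the RNA depth filter governs that case and the organelle flag
stays unset.

**Coverage doublet statistic and censor.** For each nucleus we count
sites covered exactly once (`n_cov1`) and more than once (`n_covmulti`)
and form `multi_fraction = n_covmulti / (n_cov1 + n_covmulti)`. Even for
true singletons this fraction grows mechanically with total coverage
(residual duplicate reads, mapping artefacts), so the censor conditions
on depth: nuclei are placed into quantile bins of total covered sites
(at most 10 bins, and never more than one bin per 20 nuclei, since a
median over fewer points is not robust and a too-fine grid can make a
clump of high-coverage doublets its own median), and within each bin a nucleus is flagged when its
multi-fraction exceeds the bin median plus `k_mad = 5` scaled MADs
(1.4826 x MAD). When a bin's MAD is zero — common, because singleton
multi-fractions are frequently exactly zero — the rule falls back to
flagging values strictly above median + 1e-6, which can never mass-flag a
bin of identical values. No quantitative censoring rule is standard for
this statistic; a robust location/scale outlier rule conditioned on
coverage was chosen because it is deterministic, order-invariant and has
no tuned constants beyond `k_mad`. Cohorts below 20 nuclei are not
censored (a warning is emitted): quantile bins of a handful of nuclei
make median/MAD meaningless.

**Conversion QC.** The chloroplast genome is taken as truly unmethylated,
so the pooled chloroplast methylation fraction estimates the
non-conversion rate and `conversion_estimate = 1 - fraction`. The flag
threshold is 0.03 apparent methylation — genuine conversion failures
show far more than 3% — guarded by a minimum chloroplast coverage of 100
reads so that a handful of stray calls cannot condemn a nucleus; below
the guard the estimate is reported but the flag withheld. Both numbers
are configurable. Note a structural knife edge: a nucleus whose true
conversion rate is exactly 0.97 sits exactly at the 0.03 threshold, and
its binomial estimate falls above it with probability one half at any
coverage; flags are only meaningful for conversion rates clearly away
from the threshold.

## Cluster assignment

The package assigns nuclei to trajectory clusters with supervised marker
scoring rather than graph clustering: normalized expression (counts per
10k nuclear reads, log1p; organelle genes excluded before scaling) is
z-scored per gene, each cluster is scored as the mean z of its marker
genes, and the argmax wins, with ties broken by trajectory order. The
choice is deliberate: cluster identities in this system are defined and
validated by known marker genes, marker scoring is deterministic and
directly testable against ground truth, and the 25-kb methylome feature
matrix and the normalized expression matrix are both exported for
whatever embedding or community-detection tool a user prefers.
Projection of a new experiment onto an existing cohort is realized by
freezing the per-gene mean/SD from the reference cohort (`reference`
argument) and scoring new nuclei against them.

The mature-VN/SN doublet rule relabels nuclei currently in VN4, VN5 or SN
whose ratio `r = log2((mean SN-marker expr + eps) / (mean VN4,5-marker
expr + eps))` lies in the inclusive window [-0.2, 0.2]; `eps = 1e-9`
guards empty panels. Window endpoints are inclusive because the rule is
stated as "within" the interval. Only those three labels are candidates;
every other label is a fixed point of the operation.

## Methylome statistics

**Region means.** The per-nucleus methylation level over a region set is
the weighted mean: summed methylated calls over summed total calls across
every covered in-region cytosine of the requested context. Single-nucleus
analyses use `min_cov = 1` (haploid nuclei rarely exceed 1x); bulk-style
analyses use the `min_cov = 5` rule. A `min_sites` guard (default 1) is
exposed because it is genuinely unclear whether per-nucleus distributions
should additionally require a minimum number of informative sites; the
default imposes nothing beyond non-missingness.

**Pseudobulk.** Pooling sums `mc` and `cov` per site across member nuclei
within cluster x genotype. The invariant pool-then-divide =
coverage-weighted mean of per-nucleus fractions holds exactly (it is
algebra, not approximation) and is enforced by test.

**Profiles and densities.** Metaplots bin sites either by strand-aware
offset from a 5' anchor (reference-point mode) or by relative position in
a linearly scaled region body; each bin reports the coverage-weighted
mean. The mC density of a 400-bp bin is the *sum* of per-cytosine percent
methylation over qualifying sites (cov >= 5 by default) — units are
summed percent, a density of methylated cytosines, not a fraction — with
empty bins reporting 0, and peak-centred mode placing one window of
width 400 on each interval midpoint. Chromosome-scale views use a rolling
mean over 100-kb windows stepped every 10 kb; the smoothing method for
such plots is not standardized, and a windowed weighted mean is the
simplest order-invariant choice.

**Effect sizes.** Cohen's d uses the pooled-SD formula with n-1 sample
variances. Star categories partition |d| as n.e. < 0.2 <= \* < 0.5 <=
\*\* < 0.9 <= \*\*\* < 1.5 <= \*\*\*\*; the legends that define these
bins use strict inequalities that leave exact equality unassigned, so the
package closes each interval on the left to make the mapping total and
deterministic. Degenerate cells (pooled SD zero) give d = 0 when means
agree and signed infinity (categorized \*\*\*\*) when they differ.
P-values use Welch's two-sided t-test: the grid compares groups of
different sizes and variances, and "two-sided t-test" without a variance
assumption is best served by the unequal-variance form. Cells with fewer
than 2 nuclei per group are marked insufficient rather than dropped.
A caution that matters when reading grids: at 100 nuclei per group the
null sampling SD of d-hat is about 0.14, so roughly one unaffected cell
in six will drift past the 0.2 "n.e." boundary by chance; single-star
cells at this depth are not evidence.

## Expression statistics

TPM follows the standard rate normalization. The differential-expression
stand-in is exactly what its name says — a Welch t-test on log2(CPM+1)
with Benjamini-Hochberg correction and the padj < 0.05, |log2FC| > 1
significance rule — and tags its output with
`method = "welch_t_log2cpm_bh"` so results are never mistaken for a
count-model fit. It inherits CPM's known weakness: strong asymmetric
composition shifts bias fold changes, so it is suitable for the
moderate planted effects it is tested on, not for transcriptome-scale
inference.

The rescue classifier averages replicates within genotype, z-scores each
transcript's genotype-mean TPM profile, clusters with average-linkage
hierarchical clustering on Euclidean distance, and cuts at `k = 12`.
Each cluster is labelled independently from its centroid via
`r = (log2(mutAB+1) - log2(WT+1)) / (log2(mutA+1) - log2(WT+1))`:
r <= 0.25 rescued, r <= 0.75 partially rescued, otherwise not rescued;
clusters with weak derepression (denominator < 0.5), strong inversion
(r < -1) or overshoot beyond the mutant (r > 1.5) are "other". Two
choices deserve explanation. First, `k` is deliberately much larger than
the number of labels: labels attach to clusters through the centroid
rule, so several clusters sharing a label is well-defined, and a fine cut
keeps each cluster pattern-homogeneous — at k equal to the category
count, average linkage reliably produces mixed clusters (it merged
rescued with partially-rescued profiles while splitting not-rescued in
two on planted data). Second, the lower guard sits at r < -1, not just
below the rescued threshold: a transcript whose mutAB level lands mildly
*below* wild type is monotone over-rescue and belongs with "rescued";
only a strong inversion is a non-monotone pattern.

Activation timing takes per-cluster mean expression for wild type and
mutant and reports the earliest VN cluster where log2((mut+1)/(wt+1))
exceeds 1 with mutant mean above `min_expr`; activation in VN1-VN3
(including the VN1to2 intermediate) is immature, in VN4-VN5 mature.

## Overlap analysis

Two intervals overlap reciprocally when either has strictly more than
`frac` (default 50%) of its bases covered by the other. When several B
intervals hit one A interval, the A-side test uses A's total bases shared
with the union of B (the merged set), while the single-partner clause is
evaluated per B interval; sets are merged within themselves first, with a
warning, and only truly overlapping intervals are merged — book-ended
intervals stay separate. ">50%" is read literally: exactly half does not
qualify. The shuffle null preserves interval lengths and per-chromosome
counts (chromosomal composition matters when region sets are
pericentromeric), places intervals uniformly over valid starts with
rejection sampling against self-overlap, and is deterministic under a
seed. Enrichment is summarized as an empirical z and a one-sided
empirical p with the +1 correction.

## Homology classification

Per locus, the best gene bitscore and the best TE bitscore (TE and TE
gene annotations pooled) are reduced by max; absent hits score 0.
Significance (bitscore > 100) is evaluated before the ratio rule: one
significant class wins outright; two significant classes resolve by the
3x ratio, or to "ambiguous" when neither dominates; no significant class
gives "neither". The single >100 cutoff is applied to both classes —
the source rule names a numeric cutoff only for the TE side, and one
consistent threshold is preferable to an undefined second one. The
"ambiguous" label exists because a both-significant, sub-3x locus has no
defined label otherwise; real loci mostly resolve, but the mapping must
be total.

## The synthetic-data generator

The generator emulates the statistical structure the analyses rely on,
with full ground truth: a genome of a few short nuclear chromosomes plus
an unmethylated chloroplast; cytosine sites placed at realistic per-kb
densities per context; region sets (CG-hypo-DMR-like, with progressive
per-cluster CG demethylation along the VN trajectory; pericentromeric
CHH-gain regions) whose true methylation per cluster x genotype is fully
recorded; haploid per-site Bernoulli capture (coverage 0 or 1) with a
per-nucleus lognormal depth factor; doublets as exact read-set unions of
two independently drawn nuclei (preferentially mature-VN + SN, the
physical association characteristic of mature pollen); conversion
failures that convert unmethylated cytosines to apparent methylation at
rate 1 - conversion on all chromosomes including the chloroplast; and
negative-binomial RNA with per-cluster marker panels, organelle-gene
read fractions, and planted QC failures in known counts.

Two generator features exist specifically so the paper-style rules can
behave as they do on real data. First, per-nucleus coverage varies
(lognormal factor, sd 0.25 by default): without it, conditioning the
doublet censor on total coverage is meaningless and every doublet ends up
alone in the top quantile bin, where it becomes its own median. Second,
marker expression bleeds to developmentally adjacent clusters
(fold^0.75, and fold^0.85 between VN4 and VN5), with branch topology
MN -> VN path and MN -> GN -> SN: trajectory stages are continuous, the
mature VN stages share most of their markers, and a VN+SN doublet only
carries one of the two mature-VN panels — with disjoint panels the
SN/VN4,5 log-ratio of a true doublet is biased upward out of the
[-0.2, 0.2] window, which is not how the rule behaves on real pollen.

Methylation is sampled independently per site per nucleus: the analyses
aggregate over regions, so within-region spatial autocorrelation would
cost realism in variance terms but change nothing the tests measure.
What the generator does *not* emulate: read-level errors and alignment
artefacts, sequence content, residual PCR duplicates (singleton coverage
is exactly <= 1, so the censor's zero-MAD fallback path is the one
usually exercised), batch and plate effects, ambient RNA, and diploid GN
after S-phase (a flag exists but defaults off to keep the haploid
invariant clean). Passing tests therefore demonstrate that the
implementations recover the structure they claim to recover at realistic
effect sizes and depths — not that they are robust to every artefact of
real sequencing data.

All randomness flows from one master seed through per-nucleus substreams
keyed by hashed nucleus ids (a 31-bit polynomial string hash), so
generation is reproducible and independent of iteration order; fixture
directories written by `make_fixture()` are byte-identical across runs at
the same seed.

## Problem sizes and numerical tolerances

The test suite exercises: conservation identities at float tolerance
1e-12; a 315-nucleus doublet cohort (~20k sites, 30% capture) for the
censor; conversion cohorts of 10 nuclei at ~2000x chloroplast coverage
(binomial SE ~0.002 on the group mean, well inside the +/-0.005 check);
the 10-cluster trajectory fixture at 100 nuclei per cluster with fold-8
markers for assignment accuracy and reassignment sensitivity; a
2000-nucleus two-genotype fixture with a -0.30 CG shift confined to one
cluster for effect-grid recovery and specificity; 200-per-side random
interval sets against a per-base brute-force oracle; and planted
rescue-class proportions mirroring a 50/17/26/7% split at 4-fold effects.
These sizes were chosen so each check is decisively powered (planted
effects sit many null SDs from zero) while the whole suite runs in about
two minutes.

## Known limitations

The marker-score assignment presumes curated panels and will not discover
unexpected cell states; the DE stand-in is composition-sensitive; the
doublet censor's binned median/MAD needs cohorts of tens of nuclei per
coverage stratum; conversion flags are uninformative for true rates near
1 - threshold; and the rescue classifier's labels depend on centroid
ratios, so very small clusters inherit noisy labels (they are still
reported, with cluster sizes, in the centroid table).
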