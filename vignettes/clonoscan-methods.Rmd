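---
title: "Methods: single-cell B cell transcriptome, repertoire and binding analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell B cell transcriptome, repertoire and binding analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`clonoscan` implements the analysis stack of a single-cell B cell study
that combines scRNA-seq, CITE-seq surface phenotyping and single-cell BCR
sequencing of peripheral-blood CD19+ cells from two disease groups
(here labelled `stage1` and `healthy`), followed by recombinant expression
of clonally expanded BCRs and an insulin-binding ELISA screen. Every stage
is driven by a synthetic-cohort generator with known ground truth, so the
whole pipeline is verifiable at desk scale. Upstream read processing
(alignment, contig assembly, demultiplexing), variance-stabilising
transforms, graph clustering, embedding and pathway enrichment are out of
scope: the pipeline consumes a count matrix with cluster labels and an
AIRR rearrangement table, which is where those tools hand over.

# Cell QC and normalization

A cell is removed iff it has fewer than 200 detected RNA features or more
than 10% of its counts in mitochondrial genes (identified by the
configurable name prefix `MT-`). Both bounds are strict, so a cell at
exactly 200 features and exactly 10% mitochondrial content is retained.
QC is idempotent and flags rather than deletes, so every downstream
operation filters on `qc_pass`.

RNA counts are library-size scaled to 10,000 per cell and `log1p`
transformed. This deliberately replaces regression-based
variance-stabilising transforms: the downstream statistics consumed here
(rank tests, percent-expressed fractions, de-logged fold changes) are
either rank-based or computed on the de-logged scale, where the choice of
transform has little leverage, and cluster labels are taken as input
rather than recomputed. For the same reason immunoglobulin V/J/C and
Y-chromosome genes are excluded from any feature set via a blocklist
instead of being regressed out of the embedding.

ADT counts use the centered log-ratio: per cell,
$x_i \mapsto \ln\!\big((x_i+1)/\mathrm{gm}(x+1)\big)$, whose output rows
sum to zero exactly — a property the tests assert.

# Group comparisons: the rank-sum backbone

All group comparisons (per-donor cluster frequencies, per-gene expression,
per-cell SHM) use a two-sided Wilcoxon rank-sum test implemented in the
package. The implementation enumerates all
$\binom{n_1+n_2}{n_1}$ assignments of the pooled mid-ranks whenever that
count is at most $10^5$ — which covers every comparison with groups of
eight or fewer, and the 9-vs-8 donor design — and otherwise uses the
normal approximation with tie correction and continuity correction. The
in-package implementation exists because exact enumeration must keep
working under ties (frequency vectors and sparse expression data are full
of ties), where `stats::wilcox.test` silently switches to the
approximation. `stats::wilcox.test` remains the cross-check in tie-free
cases, and an independently coded bitmask enumerator is the oracle under
ties.

# Differential expression and the filter stack

Within a stratum (cluster or collapsed subset), each gene is tested
between groups on normalized values. A gene is reported as significant
iff all of:

* fold change > 1.2, computed as the ratio of group means on the
  `expm1` scale with $\varepsilon = 10^{-9}$ — the convention of the
  standard single-cell marker test;
* Bonferroni-adjusted p < 0.05, with the adjustment factor equal to the
  number of genes in the object (configurable);
* expressed (raw count > 0) in more than 30% of cells in at least one
  group;
* not on the blocklist (IGHV/IGKV/IGLV, IGHJ/IGKJ/IGLJ, IGKC/IGLC
  patterns plus a supplied Y-chromosome gene list; heavy-chain constant
  genes are *not* blocked, since isotype information is biology, not
  clonal artefact).

Strata with fewer than 3 cells in either group are skipped with a
warning — at realistic cohort sizes this routinely happens to
plasmablasts. Gene sets that survive the stack in several strata are
partitioned by exact membership pattern (a Venn partition).

The binder-cell contrast (`ibc_contrast`) is intentionally different: at
a dozen-or-so antigen-binding cells no test survives multiple-testing
correction, so genes are *ranked by fold change* among genes expressed in
at least half (inclusive) of the binding cells with fold change at least
1.2 (inclusive), the top 40 are reported, and adjusted p values are
carried along as annotation only. A background cluster can be
down-sampled to 100 cells under a caller-provided seed for display.

# Repertoire analytics

**Chain resolution.** Cells keep one productive heavy and one productive
light chain; among multiple candidates the highest UMI count wins, ties
break to the longest sequence, then the lexicographically smallest CDR3.
Cells still holding two or more heavies *and* two or more lights are
putative doublets and are excluded. Gene calls are stripped of allele
suffixes at parse time; all matching is gene-level.

**Clonotypes.** Within a donor, cells partition by exact
(VH gene, VL gene); inside a partition two cells are linked when both the
heavy and the light CDR3 amino-acid identities reach 0.85 (inclusive),
and clonotypes are connected components under single linkage
(union-find). Equal-length CDR3s use positional identity; unequal lengths
use $1 - \mathrm{Levenshtein}/\max(\mathrm{len})$. Identity on amino
acids is the default (nucleotide mode is a flag) — the common convention
for 85%-identity clonal grouping, and the scale on which the tested
antibodies are described. Single linkage means A–C can share a clonotype
through B without being 85% identical themselves; the tests document this
deliberately. Clonotypes never merge across donors. Expansion is
size ≥ 2 within a donor.

**SHM.** Percent somatic hypermutation of a chain is computed from a
global end-free (overlap) alignment of the observed sequence to its
germline V gene (match +1, mismatch −1, gap −2, terminal gaps free):
SHM% = 100 × mismatches / aligned non-gap columns. Free end gaps make the
junction and J-segment tail hang off the alignment, approximating
V-REGION mutation accounting without IMGT numbering. Alignments run
through `Biostrings::pairwiseAlignment`, batched per V gene; mutations
placed at the very last germline positions can be trimmed by the end-free
optimum, a known sub-percent edge effect that the recovery tests bound.

**Statistics.** Per-stratum SHM is compared between groups with the
rank-sum test. The distribution of expanded cells across clusters is
tested with Pearson's chi-squared (no continuity correction) on the
clusters × groups table of expanded-cell counts; clusters with no
expanded cells are dropped and a caveat flag reports expected counts
below 5.

# ELISA analytics

Dilution series are 1:2 from 10 µg/ml with 4 replicate wells and an
instrument ceiling of OD 3.0. Per well, a median/MAD screen flags the
most deviant replicate when its deviation exceeds $k \cdot \mathrm{MAD}$,
removing at most one replicate; wells with fewer than 3 replicates are
untouched. $k = 16.1$ was calibrated by simulation as the empirical 99th
percentile of $\max_i |x_i - \mathrm{med}|/\mathrm{MAD}$ over $4\times10^5$
clean Gaussian quadruplicates, so the per-well false-flag rate is the
nominal 1%. This is a transparent stand-in for proprietary
robust-regression outlier tests in plate software; the MAD of four
replicates is extremely variable, which is why the calibrated multiplier
is far larger than large-sample intuition suggests.

AUC is the trapezoid of mean OD against log2(concentration), so 1:2
steps have unit width. With truncation enabled, integration is restricted
to concentrations at or below the lowest concentration achieving the
series maximum (or the first mean OD ≥ 3), excluding the saturated
shoulder. The binding screen uses full curves; percent inhibition uses
truncated curves, with the un-inhibited series' truncation point applied
to both conditions.

A test mAb's score is AUC(test)/AUC(isotype negative); the positivity
cutoff is half the positive control's ratio, applied inclusively, and
both the exact cutoff and its integer rounding (half away from zero) are
reported — the call uses the exact value. Percent inhibition is
$100\,(1 - \mathrm{AUC}_{\text{inhibited}}/\mathrm{AUC}_{\text{plain}})$.

# The synthetic cohort: what it emulates

The generator reproduces the statistical structure the pipeline is meant
to analyze — not transcriptome biology. Defaults: 9 + 8 donors in two
groups; 2,000–5,000 cells per donor (the per-donor recovery range is a
knob because real per-donor variance is study-specific); 12 clusters
collapsing to 5 subsets, with memory clusters 1, 3 (atypical-like,
CD21-low in the ADT panel) and 7; per-donor cluster frequencies drawn
from a Dirichlet around group-shifted baselines (naive cluster 6 up,
memory cluster 3 and plasmablast cluster 11 down in `stage1`).

RNA counts are negative binomial with gene-level dispersion, cluster
marker blocks, and planted group×stratum effects multiplying the mean by
$2^{\log_2 FC}$. Planted DE genes have their baseline mean floored at
0.8 counts: an effect planted on a gene below the >30%-detected filter
floor would be unrecoverable through the pipeline's own filter stack by
construction, so planted genes are placed where the stack can see them.
QC failures are planted explicitly (cells restricted to 120 genes;
mitochondrial fractions drawn from U(0.12, 0.30)); healthy cells draw
mitochondrial fractions from Beta(2, 46) (mean ≈ 4%), whose tail above
10% produces a realistic few-percent background removal rate.

The repertoire gives every cell one heavy and one light chain. Lineages
are drawn per donor with sizes 1–12 from a configurable distribution
(singleton-dominated geometric tail by default) and land in clusters
tilted by per-group expansion weights (atypical-like cluster 3 for
`stage1`, memory cluster 1 for `healthy`). Lineage members share the
founder's V genes; member CDR3s mutate from the founder at the amino-acid
level with matched codon edits, capped at 15% of CDR3 length so members
stay within the clonotype threshold of the founder (descendant pairs may
fall below it — exactly the single-linkage case). V regions mutate
uniformly at the cluster's (optionally group-specific) SHM rate; the
default rates put memory at 3.9–4.3%, the atypical-like cluster at a
2.42% vs 3.52% group contrast, activated at 0.62% vs 1.11%, and
naive/transitional near germline. Isotypes draw from per-cluster mixes
(the atypical-like cluster mostly unswitched). Chains are emitted as an
AIRR-C rearrangement TSV (with `*01` alleles, exercising the parser) and
germlines as FASTA.

Plates are sampled from saturating binding curves whose amplitude is
solved from the noise-free trapezoid integral so that a mAb's *true AUC
ratio* is exact in the unit the classifier measures; the paired
competitor series scales the whole mean curve by (1 − inhibition
fraction), making the planted inhibition exact over any truncation grid.
Gaussian replicate noise (sd 0.05 OD) and gross outliers (a replicate
replaced by U(0, 3)) are added, with at most one outlier per
4-replicate well — matching the one-removal design of the outlier screen
so the planted truth stays unambiguous — at an unchanged marginal rate
(2% of replicates by default).

What passing tests do **not** show about real data: no batch effects, no
pathway co-expression, no ambient RNA or doublet transcriptomes, no
allele-level V gene variation, no indels in V regions (the SHM model is
substitution-only, though the aligner tolerates indels), and clustering
is taken from ground truth rather than recomputed.

# Numerical choices and degenerate inputs

* Rank-sum enumeration uses a $10^{-9}$ slack when comparing deviations,
  avoiding float ties; all-tied samples return p = 1 in both modes.
* Fold changes use $\varepsilon = 10^{-9}$; thresholds are applied as
  stated (fold change strictly > 1.2 in the filter stack; ≥ 1.2 in the
  binder contrast, which the source convention states as "minimum").
* Identity thresholds compare with a $10^{-12}$ slack so 11/13 vs 0.846…
  behaves as the arithmetic says.
* Clonotype ids are assigned after canonically sorting cells, so the
  partition and its labels are invariant to input order.
* Percentages in cohort summaries round half away from zero (62.5 → 63),
  the convention of demographic tables.
* Degenerate inputs error with classed conditions
  (`clonoscan_config_error`, `clonoscan_input_error`): empty matrices,
  all-zero cells post-QC, unmapped clusters, non-positive EC50, a
  zero-AUC negative control, empty CDR3 strings.
* `run_all` writes a canonical JSON report (no HTML); determinism is
  checked by hashing the file across reruns with the same seed.

# Problem sizes

The shipped analysis scripts simulate 17 donors at 300–400 cells each
with 1,200 genes — enough for every stratum except plasmablasts to clear
the minimum-cell rules, and small enough to run the whole workflow in a
few minutes. The validation suite uses 3+3 donors at 250–300 cells for
cohort-level checks (≈200+ cells per group in the memory stratum, the
regime in which the DE recovery property is stated), 900 single-donor
cells for SHM recovery, 200 Monte-Carlo replicates for the expansion
power check, 500 simulated mAbs for the classification check, and
10,000 clean wells for the outlier false-flag rate. Percent-inhibition
recovery is reported as the mean over six independent plate simulations
per planted fraction, which measures the estimator rather than
single-plate replicate noise.

# Known limitations

* The group-shift mechanism in the generator keys on the literal group
  label `stage1`; other designs need explicit shift vectors.
* SHM near the V-region 3' end can be trimmed by the end-free alignment
  (sub-percent, bounded by tests).
* The chi-squared power property holds for concentrated expansion
  contrasts (the two-memory-cluster design used here); diffuse
  enrichment across many clusters needs more than 100 expanded cells per
  group at the same effect size.
* The outlier screen's calibration constant is specific to quadruplicate
  wells; other replicate counts reuse it scaled, which is approximate.
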