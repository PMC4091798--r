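---
title: "Methods: cross-species germline transcriptomics without replicates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species germline transcriptomics without replicates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossgerm)
```

## The problem this package addresses

Comparing germline cell-type transcriptomes between an apomictic species
and a sexual relative runs into three compounding constraints.  First, the
apomict typically has no sequenced genome, so its RNA is hybridized to the
relative's microarray (a *heterologous* hybridization) and its reads are
mapped to a de-novo assembled transcriptome.  Second, laser-microdissected
cell-type samples (a few hundred cells per sample) admit no biological
replicates.  Third, the two platforms and two species must be reconciled
onto a common gene space before any comparison is meaningful.  `crossgerm`
implements the complete analysis chain for this setting, and a
synthetic-data module that generates every input type with known ground
truth, so each stage is validated against an independent oracle rather
than against unavailable raw data.

## Presence/absence calls from negative probesets

On a heterologous hybridization, a probeset's signal depends on how well
its 25-mer probes match the sample species' transcripts, so the usual
within-species detection calls are biased.  The PANP idea inverts the
problem: probes that demonstrably *cannot* hybridize measure pure optical
and cross-hybridization background.  `align_probes` searches every probe
against both strands of the assembled transcriptome, full-length and
ungapped, allowing up to 3 mismatches (the search is seed-and-filter: a
hit with at most k mismatches must contain one of k+1 disjoint probe
segments exactly; exact segment hits come from `Biostrings::matchPDict`
and are then Hamming-verified).  A probeset with no aligned probe at all
is *negative* (`classify_negative`); a relaxation to "at least a fraction
f unaligned" is available but not the default, because the strictest rule
gives the purest background sample.

Expression is summarized RMA-style but without background convolution:
log2, quantile normalization (`quantile_normalize`, ties receive the mean
of their rank-assigned values), then per-probeset two-way median polish
(`median_polish`: rows first, at most 10 sweeps, stopping when the total
absolute adjustment of a sweep drops below 0.01).  The presence p-value of
a probeset on an array is the empirical survivor function of the negative
probesets' expression on that array, evaluated at the probeset's
expression, with linear interpolation between the unique sorted background
values; tied background values share the conservative (larger) p, values
at or below the background minimum give p = 1, values above the maximum
give p = 0.  The published algorithm this reconstructs is described only
conceptually, so the interpolation rule (rather than a step function) is a
documented package decision; it makes p-values continuous and keeps the
null distribution close to uniform, which the test suite checks by
Kolmogorov-Smirnov at n = 5000.  Calls use p <= 0.02 for Present (the
threshold of the study design this mirrors) and a configurable marginal
band up to 0.04.

## Closest homologues from PSL alignments

Cross-species gene identity comes from BLAT-style alignments of one
species' transcripts to the other's cDNA, consumed as 21-column PSL
(`read_psl`, with psLayout header auto-detection and per-record invariant
checks).  PSL has no bit score, so the per-record score is the standard
BLAT score derivable from its fields:
`matches + repMatches - misMatches - qNumInsert - tNumInsert`
(`psl_score`).  Transcript variants (`comp<i>_c<j>_seq<k>`) collapse to
gene models by stripping the `_seq` suffix (`variant_gene`).  For each
query gene, scores and aligned lengths are summed per candidate target
gene; the homologue is the argmax of the score sum among pairs whose total
aligned length reaches 100 bp, otherwise none (`assign_homologues`).  Two
points were genuinely open and are fixed as follows: aligned length is
summed on the query side (`qEnd - qStart`), because coverage of the query
is what makes a homologue claim about that query credible (target-side
summing is available by argument); score-sum ties break to the
lexicographically smallest target id, for determinism.

## Counts, expression calls and normalization

Gene expression is the sum of its transcript variants' counts
(`gene_counts`; per-sample totals are conserved exactly).  A gene counts
as expressed in a sample with at least 5 mapped reads, applied to raw
counts — the rule predates normalization.  Two normalizations serve two
paths: TMM factors (`tmm_factors`: doubly-trimmed weighted mean of
log-ratios against the upper-quartile-nearest reference column, factors
rescaled to geometric mean 1) feed the differential-expression path, and
median-of-ratios size factors (`size_factors_median_ratio`: per sample,
the median over all-nonzero genes of count over gene-wise geometric mean)
feed the display path (`row_scale_log2`, `hcluster`).  TMM is computed
once across all samples rather than per pair; per-pair recomputation would
make the three pairwise contrasts of one focal cell type inconsistent
with each other.  Note that TMM is only approximately invariant to
rescaling one library: the inverse-variance weights depend on raw counts,
so a pure depth change perturbs factors at the percent level; the test
suite checks exact agreement with the reference implementation instead.

## Differential expression without replicates

Two methods with different stringency:

**Simulated-replicate noise clouds** (`noiseq_sim`).  For each of the two
samples, `nss = 5` technical replicates are simulated by multinomial
subsampling of the sample's gene proportions at `pnr = 0.2` of its library
size (jittered by `v = 0.02`); all within-sample replicate pairs
contribute per-gene (|M|, D) points — M the log2 ratio, D the absolute
difference of normalized expression, zero counts replaced by `k = 0.5` —
to a pooled noise cloud.  A gene's DE probability is the fraction of noise
points it dominates on both axes (non-strict, so ties resolve toward
higher probability), and a gene is *enriched* in the focal cell type when
its probability exceeds `q = 0.9` with the focal sample up in **all three**
pairwise contrasts.  The four internal parameters are the published
defaults of the method this follows; they are exposed as arguments.
Because replicates are drawn at a fifth of the library depth, the noise
cloud overstates full-depth technical noise, making the procedure
conservative — on synthetic 4-fold changes at 10% prevalence it recovers
roughly a third to a half of planted genes with high precision, and the
suite prints the observed recall rather than asserting a level.

**Exact negative-binomial test at fixed dispersion** (`exact_nb_test`).
With no replicates the dispersion cannot be estimated, so it is fixed at
phi = bcv^2 = 0.64 (bcv 0.8, a deliberately generous value for biological
variation between cell types).  Libraries are equalized to their geometric
mean by rounded pseudo-counts; conditional on the pseudo-count total s,
each split has probability proportional to the product of two NB densities
with mean s/2 and dispersion phi, and the two-sided p-value sums all
splits no more likely than the observed one (relative tie tolerance
1e-10).  This simplifies the reference implementation's quantile-adjusted
pseudo-counts to geometric-mean scaling, keeping the test fully
enumerable: the suite checks equality with an independent full-support
enumeration to 1e-12 and the phi = 0 reduction to the conditional binomial
test, and verifies the empirical size at nominal 0.05 under a null NB
simulation (the analytic size is 0.046; discreteness makes the test
slightly conservative).  Enrichment uses FDR < 0.05
(Benjamini-Hochberg, `bh_adjust`) in all focal contrasts; one designated
pair — canonically the two most similar cell types, egg and central cell
— is tested at raw p < 0.001 instead, since at phi = 0.64 the FDR rule is
hopeless for near-identical transcriptomes.

## Evidence harmonization and set algebra

Cross-platform evidence is a per-(gene, cell type) record: how many of the
cell type's arrays call it Present, and its read support
(`build_evidence`; RNA-seq ids are anchored to the partner species' gene
space through the homologue map, genes without a homologue keep their
species-local id and so can only appear in species-exclusive sets —
the genome-based second criterion of the original design needs the real
genome and is out of scope).  Expression rules are data, not code
(`evidence_rule`): flat AND/OR combinations of `array_P` and `reads`
clauses, with shipped presets — `aic` ("P on both arrays OR >= 5 reads"),
`gamete` ("P on the single array OR >= 5 reads"), and the stricter
`aic_exclusive` conjunction (">= 5 reads AND P on at least one array")
used when claiming a gene is expressed in the apomictic founder cell but
not its sexual counterpart.  `exclusive_sets` partitions the union of the
two species' expressed genes into A-only/B-only/shared, `overlap_counts`
produces Venn region counts, and `multi_sample_expressed` implements the
"expressed in at least 2 samples" tally (each Present array and each
RNA-seq sample with >= 5 reads counts as one supporting sample).

## Overrepresentation analysis

GO annotations are propagated by the true-path rule
(`propagate_annotations`, validated against a repeated-parent-lookup
oracle) over a single-rooted acyclic `is_a` DAG.  `fisher_classic` is the
one-sided hypergeometric upper tail with `expected = annotated * |study| /
|universe|`.  To decorrelate nested terms the package ships the *elim*
algorithm (`go_elim`): terms are tested leaves-to-root and a term
significant at the 0.01 cutoff has its study genes removed from all
ancestors before they are tested.  The original analysis used the related
*weight* algorithm; elim is the documented stand-in because it has an
exact, oracle-checkable specification, and results are labelled as elim.
Families and protein domains use the two-sided Fisher test
(`fisher_two_sided`, minimum-likelihood convention) so depletion is
detectable.  The GO universe is the set of genes with at least one
propagated annotation; a full-array universe is the appropriate choice
when the study set itself was defined on the array.  P-values are reported
unadjusted with a p < 0.01 reporting convention, as is standard for these
tables.

## What the synthetic data does and does not emulate

The generators (`sim_config`, `gen_transcriptome`, `gen_probesets`,
`gen_array_intensities`, `gen_counts`, `gen_annotations`,
`gen_homolog_psl`) reproduce the *statistical structure* each stage
depends on: per-base probe/target divergence (binomial mismatch counts),
a log-normal background/signal intensity mixture with additive per-probe
affinity effects (mean 0, SD 0.5) so median polish has structure to
remove, NB counts with variance mu + phi mu^2 and configurable planted
fold changes, homologous pairs with decoy alignments at half score, and
rooted is_a DAGs.  Defaults place the signal 3 background SDs above
background (9 vs 6 on the log2 scale, SD 1), use 25-mer probes in sets of
11, phi = 0.64, and a 10% DE fraction at 4-fold — values chosen once as
representative of ATH1-class arrays and between-cell-type contrasts.  The
generators do not emulate genome evolution (sequences are iid uniform
ACGT, so negative probesets are cleanly separable), positional coverage
bias, GC effects, or colorspace read error; passing tests therefore
demonstrate correctness of the algorithms under their stated models, not
robustness to every artefact of real arrays or SOLiD sequencing.  One
master seed drives everything; each generator derives a per-stage sub-seed
(seed x 97 + stage x 7919, reduced mod 2^31) so stages are individually
reproducible and byte-identical under rerun.

## Problem sizes and numerical choices

The bundled fixture (`inst/extdata/fixture-config.yaml`) uses 300 genes,
150 probesets x 11 probes, two arrays, four samples of 100k reads — sizes
at which the full pipeline, including the exact search and all four
noiseq contrasts, completes in seconds while every rate of interest
(calibration, recall, type-I error) is measurable.  Calibration checks use
50k negatives / 5k nulls; the NB size check uses 2000 null genes.  Other
numerical decisions collected in one place: median polish 10 sweeps /
0.01 tolerance; quantile-normalization ties averaged within tie groups;
survivor-function interpolation linear with conservative ties; probe
search rejects non-ACGT probes with a warning (they count as unaligned)
and never matches N in targets; homologue ties lexicographic; noiseq
dominance non-strict; NB tie tolerance 1e-10 relative; Fisher two-sided
tie tolerance 1e-7 relative (the convention of common software); display
pseudocount 1.

## Known limitations

Single-replicate inference is the design constraint, not a removable one:
the NB dispersion is assumed, not estimated, and the noiseq noise cloud
reflects subsampled technical noise only.  The evidence module compares
species on the homologue-anchored space, so assembly fragmentation
(several gene models mapping to one homologue) collapses by union of
evidence.  The elim decorrelation is not the weight algorithm and gives
systematically different (more conservative) parent p-values.  CEL
parsing, background convolution, read alignment and assembly are out of
scope; the package consumes the standard text formats those tools emit.
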