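---
title: "Quantitative iCLIP analysis of RBP competition: models and methods"
author: "CLIPcompete"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative iCLIP analysis of RBP competition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CLIPcompete)
```

# Scope

CLIPcompete implements a quantitative analysis of individual-nucleotide
resolution UV crosslinking and immunoprecipitation (iCLIP) data, built around
one biological question: how does an abundant, U-tract-specific
heterogeneous nuclear ribonucleoprotein (hnRNP C) compete with the core 3'
splice-site factor U2AF65 for binding to pre-mRNA, and what happens to
splicing — in particular to the exonization of intronic antisense Alu-like
elements — when the competitor is depleted?

The package covers the full chain: demultiplexing and PCR-duplicate removal
into single-nucleotide crosslink-event tracks; binding-site calling by
within-gene randomization FDR; gene-normalized occupancy, size factors and
differential binding between knockdown and control; de novo exon filtering,
Alu-exon classification, disruption prediction and a conditional-threshold
combiner across two knockdowns; RNA maps, pentamer enrichment and RBP
co-binding profiles; consensus-coordinate mapping of repeat elements and a
cumulative-frequency U-tract selection statistic. A synthetic-data module
generates toy datasets with planted competition so that every statistic can
be validated against known ground truth.

# Crosslink events and binding sites

## From reads to events

An iCLIP read carries a 4-nt experimental barcode and 5 nt of random
barcode; `demultiplexReads()` splits samples on the former and carries the
latter in the read name. Because reverse transcription truncates at the
crosslinked nucleotide, the crosslink site of an aligned read is the
position immediately 5' of the read start in transcript orientation
(`assignCrosslink()`). Reads identical in (contig, strand, crosslink
position, random barcode) are PCR duplicates and collapse to one *crosslink
event* (`collapseDuplicates()`). The printed barcode composition does not
fix the within-read order of barcode nucleotides; the default layout
`NNNXXXXNN` is an explicit assumption and any layout over {N, X} can be
supplied.

The duplicate key deliberately uses the crosslink position rather than the
full alignment span, so differences in 3' trimming cannot split true
duplicates.

## Peak calling by within-gene randomization

A binding site is a cluster of crosslink positions whose *height* — the
event count in a window of `flank` nt to either side — is unlikely under a
uniform redistribution of the gene's events. For each gene, the observed
`n` events are placed uniformly at random (with replacement) over the gene
`iterations` times; the empirical FDR at height `h` is the mean number of
randomized crosslinked positions reaching height `>= h`, divided by the
observed number. Values are capped at 1 and forced monotone non-increasing
in `h`, so a taller height is never reported as less reliable. Significant
positions within `flank` nt of each other merge into one site spanning
their outermost positions; the summit is the position with most events,
ties resolved toward the transcript 5' end. Defaults follow the two binder
archetypes: `flank = 10` for the broad binder (hnRNP C), `flank = 5` for
the focused binder (U2AF65), both at FDR < 5%.

Numerical contract: after `set.seed(seed)` the randomization consumes
exactly `iterations` draws of `sample.int(gene_length, n, replace = TRUE)`,
and each gene's seed is `seed + gene index`. This makes the caller exactly
reproducible by an independent implementation — the test suite holds the
caller to bit-identical agreement with a naive brute-force oracle on
hundreds of random genes. The FDR estimator uses the plain mean over
iterations (not mean plus a spread term); this is the simplest unbiased
choice and is stated here because published descriptions of this family of
peak callers do not always print it.

# Occupancy and differential binding

Measured crosslinking reflects both affinity and transcript abundance. The
*normalized occupancy* of a site divides its event count by the gene total
(the summed events over that gene's binding sites) times the gene length.
For broad binders the numerator is restricted to an 11-nt window centered
on the summit. Sites overlapping more than one annotated gene are excluded;
gene totals may alternatively be computed over all gene positions
(`gene_total = "gene"`), a documented switch because either reading of
"total count of the respective gene" is defensible.

Between conditions, libraries differ in depth; `medianRatioSizeFactors()`
computes the standard median-of-ratios constants over sites positive in all
samples, and `differentialBinding()` reports
`log2((occ_kd/f_kd + eps) / (occ_ctrl/f_ctrl + eps))` with categories: at
least four-fold up (`log2FC >= 2`, inclusive), four-fold down, unchanged
(`|log2FC| < 0.1`), or other. The pseudocount defaults to half the smallest
positive corrected occupancy, so sites with zero counts in one condition
remain finite; the four-fold boundaries tolerate ~1e-9 of float noise so an
exact four-fold change lands in the inclusive category.

# The synthetic-data generator

The generator is first-class, tested code: it defines the study conditions
under which the pipeline's statistical behaviour is assessed.

**Genome.** One chromosome carrying `n_genes` (default 300) non-overlapping
genes of 2-4 kb, alternating strands, each with three genuine exons. A
pyrimidine tract (18 nt of C/U, 60% U) with a terminal AG is planted
upstream of each internal acceptor. Each gene hosts `n_alu_per_gene`
(default 2) Alu-like elements inside its introns, antisense to the gene.
The element consensus is a synthetic ~300-nt sequence with the canonical
anatomy — two arms separated by a poly(A) linker and followed by a poly(A)
tail — not a repeat-database sequence: for every statistic computed here
only the anatomy matters. Antisense insertion turns the tail and linker
blocks into the upstream and linker U-tracts of the transcript.

**Tract lengths.** Planted tract lengths are `utract_min + Poisson(mean -
utract_min)` with `mean = 8` for control elements and `10` for the exonized
set — the +2 nt shift that the selection statistic must recover. Point
substitutions at `mutation_rate` (default 5%) are applied to the arms only;
tract-length variation is modelled by the length distribution itself, which
keeps the planted lengths exact for parameter-recovery tests. Exonized
labels are balanced within genes (half of each gene's elements), a matched
within-gene design: this makes labels exchangeable under within-gene
permutation, which the calibration tests rely on (see below).

**Crosslink emission.** Counts are Poisson per nucleotide — the simplest
count model whose variance scales with the mean; no overdispersion is
simulated. The competitor's rate is `base_rate_c` plus, over each tract,
the affinity `lambda_C = alpha * max(0, length - 3)` spread across tract
positions: three uridines are the minimal element, and each additional
uridine adds `alpha` (default 0.5) expected events. The U2AF65 rate is
`base_rate_u + beta * pyr(p)`, where `pyr(p)` counts pyrimidines in the
centered 11-nt window in excess of 6 — zero over most background sequence,
up to 5 inside pyrimidine tracts and U-tracts.

**Competition.** In the control condition the U2AF65 rate inside a tract is
multiplied by `1 - s * P_occ`, with suppression `s` in [0,1] (default 0.8)
and a saturating occupancy `P_occ = 1 - exp(-lambda_C / occ_scale)`
(default scale 4). The knockdown drops the suppression term entirely. The
saturating occupancy is a deliberate design choice: a binary bound/unbound
indicator makes the expected knockdown/control ratio identical for all
bound tracts, whereas competitive binding should — and in these data must —
strengthen with the competitor's affinity. `occ_scale = 0` recovers the
binary indicator exactly, and the suppression-limit tests use that setting.

**Inclusion.** Each exonized element contributes a cryptic exon whose true
inclusion is `psi = plogis(gamma * (occ_U - psi_threshold))`, where `occ_U`
is the mean per-nucleotide U2AF65 rate over the exon's upstream tract in
that condition (defaults `gamma = 2`, threshold 1.5 give control inclusion
around 0.2 and knockdown inclusion 0.4-0.8 depending on tract length). A
bounded, monotone, single-slope link is all the downstream tests require.
Junction totals per gene, condition (`ctrl`, `kd1`, `kd2`) and replicate
are Poisson(`depth`); inclusion counts are Binomial(total, psi), so
inclusion + exclusion reproduces the drawn totals exactly.

**Reproducibility.** One global seed is split deterministically into
sub-seeds for the genome, the tracks and the count tables, so each
sub-generator is independently reproducible and identical configurations
produce byte-identical files.

**What the generator does not emulate.** Read-level artifacts (sequencing
errors, quality variation, mappability), overdispersion between biological
replicates, transcript-level isoform structure, nonsense-mediated decay,
and the indel processes (polymerase slippage) that complicate tract-length
evolution in real repeats. Passing tests on these data therefore
demonstrate the correctness and calibration of the *computations*, not
performance on real libraries.

# Exon pipeline

`filterExons()` applies the three de novo quality filters in order — exons
must (a) come from multi-exon transcripts, (b) have at least one
junction-spanning read at a splice site, (c) measure 25 bp to 10 kb — then
merges overlapping exons whose starts and ends each differ by less than 25
bp, taking outer boundaries (single linkage; the result is independent of
input order). Gene assignment is direct when an exon overlaps exactly one
annotated gene, inherited through the predicted gene model when that model
overlaps exactly one gene, and exons spanning several genes are discarded.
An *Alu exon* has at least one splice site — the boundary exonic
nucleotide, our containment convention — inside an element antisense to the
exon, with that site supported by a junction read.

Disruption prediction flags a frameshift when the exon length is not a
multiple of 3 and scans the exon's three internal reading frames for stop
codons; the default combination rule (frameshift OR stops in all three
frames) is announced with a message whenever it is used implicitly, because
the alternative any-frame rule is equally defensible and selectable.
Frame anchoring uses the exon-internal frames rather than the upstream
coding frame, which de novo predictions do not reliably provide.

The per-exon usage test is an explicit stand-in for a negative-binomial
exon-usage model: a 2x2 contingency test (exon counts versus remaining gene
counts, knockdown versus control; chi-square with continuity correction,
Fisher's exact test when any expected cell is below 5). Any external
p-value column can replace it; everything downstream consumes only p-values
and fold changes. The combiner then requires p < 0.01 in at least one
knockdown, p < 0.05 in the other, and concordant direction. Established
exons — already included and no longer regulated — require at least 50
reads across samples and fold changes inside (1/1.5, 1.5) in both
knockdowns; the two-sided reading of "fold change < 1.5" is ours, since an
exon halving its inclusion is regulated, not established.

# Positional summaries and motifs

RNA maps (`rnaMap()`) anchor offsets at a splice site in transcript
orientation, offset 0 being the boundary exonic nucleotide, and report
either the percentage of exons with at least one event per offset or summed
event counts (size-factor corrected when comparing libraries). Heatmap
matrices (`spliceSiteHeatmap()`) use the window [-50, +10] around the 3'
splice site and keep exons with at least five events in the filter track,
ordering rows identically across tracks.

Pentamer enrichment weights every 5-mer covering any position within
`flank` nt (default 10) of a crosslink nucleotide by the event count, and
divides by the same computation on positions randomized uniformly within
the same genes — the same null model as the peak caller, chosen for
consistency. Expected counts are floored at one occurrence so unobserved
pentamers stay finite. The figure-level statistic names the comparison but
not the window; 10 nt is an exposed default.

The RBP co-binding profile counts, per offset in [-100, +100] around the
query summits, the fraction of summits covered by another protein's site,
normalized to the mean over the background offsets [-99, -90] and
[+90, +99] — "two 10-nt windows 90 nt up- and downstream" admits off-by-one
readings, and these indices are the documented one. A zero background
leaves the profile flagged undefined rather than divided by zero.

# Repeat-element evolution

Elements are classified sense/antisense/ambiguous/intergenic by
gene-overlap strand. `alignToConsensus()` performs a global affine-gap
pairwise alignment (match +1, mismatch -1, gap open 5, extend 1) between
each element (in consensus orientation) and the consensus, restricted to
elements within ±15% of the consensus length, yielding a monotone mapping
from element positions to consensus coordinates. Pairwise alignment
replaces grouped multiple alignment here: it is deterministic,
dependency-light, and coordinate mapping — not phylogeny — is the goal.

Splice sites of Alu exons with junction support on both sides are projected
through the mapping into consensus-coordinate histograms, with arm
assignment by position relative to the linker block. Tract lengths are the
longest A-run within the consensus regions designated as tail (upstream
tract) and linker; when the alignment gaps out a region, the run is
measured on the element span between the flanking mapped coordinates.

The selection statistic compares, at each length L, the fraction of tracts
of at least L uridines in the exonized set against the matched control set
(non-exonized antisense elements of the same genes): ratio plus Pearson's
chi-square (Fisher when any cell is below five). "Longer than a given
length" is implemented inclusively (>= L) to match the axis wording of the
cumulative display. The consensus-coordinate windows for the upstream and
linker regions are configuration, discovered from the consensus poly(A)
blocks for the synthetic consensus.

**Calibration of the permutation check.** Shuffling exonized labels within
genes is a valid null only when labels are exchangeable within genes. Two
details matter. First, per-gene label counts are preserved by within-gene
permutation; if label counts correlate by chance with a gene's tract
lengths, every permutation inherits a fixed offset. The generator's
balanced matched design (equal exonized/control counts per gene) removes
this. Second, type-I rate must be measured on data generated under the
null (equal tract-length distributions); on data with the planted +2 nt
shift, permuted datasets are mixtures, not null samples. The calibration
test therefore uses a dedicated null-configured genome and observes
rejection rates of 3.4-5.6% across genome seeds.

# Problem sizes and runtimes

The shipped tests and the acceptance script use the study conditions at
desk scale, chosen once: 300 genes (~1 Mb genome, roughly 2-5 x 10^5
U2AF65 events per condition) for the competition and null analyses with 100
randomization iterations; 1,000 elements (500 per set) for the selection
statistic with 500 label permutations; 1,000 null and 500 planted exons at
depth 500 for usage-test calibration; and 110-120 random mini-genes for
brute-force oracle equivalence. The full suite completes in a few minutes
on one CPU.

# Known limitations

* The FDR randomization assumes within-gene uniformity; structured
  background (coverage gradients, mappability) is neither simulated nor
  corrected for.
* Occupancies are computed from summed replicates; replicate-level
  dispersion of occupancies is out of scope.
* The usage test ignores biological replicate variance beyond pooling
  (binomial sampling only); its calibration statement applies to data of
  that structure.
* Pairwise consensus alignment can misplace coordinates inside long
  homopolymers; tract-length extraction therefore works on designated
  consensus regions with a gap fallback rather than on per-base identity.
* The annotation hierarchy resolves positions near both splice sites by
  distance with ties to the 3' splice site; positions equidistant to
  multiple genes' features follow the category priority only.
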