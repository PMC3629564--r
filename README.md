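# CLIPcompete

Quantitative iCLIP analysis of competition between RNA-binding proteins,
with an application built in: how a U-tract-specific nuclear protein
(hnRNP C) blocks the 3' splice-site factor U2AF65 from cryptic
polypyrimidine tracts, and how losing that protection exonizes intronic
antisense Alu elements.

The package is for computational biologists analyzing
nucleotide-resolution CLIP data who need the *quantitative* layer on top of
peak calling: per-site occupancies comparable across conditions,
differential-binding categories, the positional and motif summaries that
diagnose competition, and the evolutionary statistic that asks whether
exonized repeat elements preserve longer U-tracts than their matched
intronic neighbours.

## The core quantities

* **Crosslink event** — one deduplicated read; its crosslink nucleotide is
  the position 5' of the read start (cDNA truncation). Events are stored as
  a `CrosslinkTrack` (a width-1, stranded `GRanges` with counts).
* **Binding site** — a cluster of positions whose windowed event count
  ("height", window ±f nt) has empirical FDR < 5% against `R` uniform
  redistributions of the gene's `n` events:
  `FDR(h) = mean_r #{randomized positions with height >= h} / #{observed positions with height >= h}`.
* **Normalized occupancy** — site events / (gene total x gene length), the
  gene total being summed events over the gene's sites; an 11-nt summit
  window is used for broad binders.
* **Differential binding** —
  `log2((occ_KD/f_KD + eps) / (occ_Ctrl/f_Ctrl + eps))` with
  median-of-ratios size factors `f`; categories: >= 4-fold up / down,
  unchanged (`|log2FC| < 0.1`), other.
* **Conditional thresholding** — a change is reproducible across two
  knockdowns when p < 0.01 in one, p < 0.05 in the other, same direction.
* **U-tract selection ratio** — at each length L, the fraction of tracts
  >= L uridines in exonized elements over the same fraction in non-exonized
  antisense elements of the same genes, with chi-square/Fisher p-values.

A synthetic-data module (`simConfig()`, `simulateDataset()`) generates a
toy genome whose introns carry antisense Alu-like elements with planted
U-tracts, Poisson crosslink tracks with a tunable suppression of U2AF65 at
competitor-occupied tracts, and junction count tables with logistic
inclusion — plus the ground truth needed to verify that every statistic
above recovers what was planted.

## Worked example

```r
library(CLIPcompete)

cfg <- simConfig(n_genes = 60L, seed = 42L)   # suppression s = 0.8
sim <- simulateDataset(cfg)
res <- competitionAnalysis(sim$genome, sim$tracks, flank = 5L,
                           iterations = 100L, seed = 43L)
```

The run calls U2AF65 binding sites on the collapsed control + knockdown
track, computes per-condition occupancies, size factors and log2 ratios,
and stratifies sites by overlap with the planted competitor-bound tracts:

```
sites called: 2340
mean log2FC (KD/Ctrl) at planted tracts: 0.64
mean log2FC elsewhere:                   -0.02
one-sided t-test p: 4.53e-33
mean log2FC by planted-affinity decile:
   1    2    3    4    5    6    7    8    9   10
0.40 0.39 0.46 0.58 0.59 0.60 0.92 0.77 0.73 0.99
Spearman rho across deciles: 0.94
```

U2AF65 binding rises upon knockdown specifically where the competitor was
planted, and the shift grows with the planted affinity — the signature of
direct competition. The motif layer tells the same story from sequence:

```r
pe <- pentamerEnrichment(sim$tracks$hnRNPC$ctrl, sim$genome$genes,
                         sim$genome$gene_tseq, flank = 10L,
                         iterations = 10L, seed = 44L)
head(pe$pentamer, 3)
#> [1] "UUUUU" "UUUUG" "UUUGA"
```

See the vignette (`vignettes/quantitative-iclip-competition.Rmd`) for the
models, parameter meanings, defaults and numerical conventions.

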