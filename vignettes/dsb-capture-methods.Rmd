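---
title: "Methods: break-end mapping, feature annotation and coverage statistics"
author: "breakscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: break-end mapping, feature annotation and coverage statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breakscape)
library(dplyr)
```

# The measurement model

DSB-capture sequencing ligates a sequencing adaptor directly onto broken DNA
ends, so that after paired-end alignment the most 5' nucleotide of the
*first mate* of a proper pair marks the position of a double-strand break
(DSB) at single-nucleotide resolution. Everything downstream of the aligner
is this package's territory; everything upstream (chemistry, alignment) is
out of scope.

The unit of measurement is a **break call**: a `(chrom, pos)` pair on the
0-based, half-open internal coordinate convention used throughout the
package. All external 1-based formats (SAM `POS`) are converted exactly
once, at parse time.

## Read filtering

A read pair contributes one break call iff it survives, in order:

1. **Primary-alignment flags.** Unmapped (0x4), secondary (0x100), QC-fail
   (0x200) and supplementary (0x800) records are dropped — the flag union
   2820. "Low quality" is interpreted strictly as the QC-fail flag; an
   optional `min_mapq` cutoff exists but defaults to off, because a flag
   expression encodes flags, not mapping quality.
2. **Proper pairing.** Records without both the paired (0x1) and
   proper-pair (0x2) bits are dropped; a TLEN of 0 (mates on different
   chromosomes) is dropped under its own counter, since the fragment-length
   restriction cannot be evaluated for it.
3. **Fragment length.** `100 <= |TLEN| <= 2000`, both bounds inclusive —
   the aligner-style convention for an insert-size window (`-I 100 -X
   2000` is inclusive at both ends).
4. **Duplicate marking.** Pairs sharing both mates' 5' coordinates and the
   first mate's orientation form a duplicate class; one representative —
   the lexicographically smallest query name, a deterministic and
   input-order-independent choice — survives per class.
5. **First-mate selection.** Flag value 67 (paired + proper + first in
   pair), duplicate state unset.

The break position is then `start` for a forward read and `end - 1` for a
reverse read. Breaks are counted per read: two fragments breaking at the
same nucleotide yield two break calls, and aggregation happens downstream.
Every input record lands in exactly one counter of the extraction report,
so `total = retained + sum(dropped_*)` always holds.

# Feature annotation

Each gene model contributes four windows, defined in its transcriptional
orientation around the TSS and TTS boundary coordinates:

| category  | window (transcription coordinates)       | default size |
|-----------|------------------------------------------|--------------|
| TSS       | TSS − 250 to TSS + 250                   | 500 bp       |
| promoter  | TSS − 1000 to TSS − 250                  | 750 bp       |
| gene body | TSS + 250 to TTS − 250                   | length − 500 |
| TTS       | TTS − 250 to TTS + 250                   | 500 bp       |

Genomic territory is resolved by **sequential subtraction at the category
level**: the TSS territory is the union of all genes' TSS windows; the
promoter territory is the union of promoter windows minus the TSS
territory; then TTS, then gene body; whatever remains is intergenic. A bp
claimed by one gene's TSS window and another gene's body window is TSS.
The alternative — resolving priorities per gene — would give a different
partition; the category-level reading matches a sequential
intersect-then-subtract pipeline of the whole feature sets.

Two conventions are fixed where prose definitions are ambiguous at shared
endpoints:

* Windows are realized as half-open intervals, so "TSS − 250 to + 250" is
  `[t − 250, t + 250)` and the bp at the promoter/TSS junction belongs to
  the higher-priority TSS window. Half-open tiling leaves no gaps and
  double-counts nothing, which is what makes the territory identity
  `sum(territory) = genome size` exact.
* Windows are clipped at chromosome edges rather than discarded, and a
  gene shorter than 500 bp simply has an empty body window.

Per-category break counts are normalized to the megabase size of the
category's resolved territory (**breaks/Mb**), so a small territory with
concentrated breakage (the TSS category, in practice) can be compared
against the megabases of intergenic space. The tests verify the partition
against a per-bp brute-force classifier on random toy genomes, including
deliberately overlapping gene models.

# Expression- and length-stratified coverage

Genes with FPKM > 0 are ranked by FPKM (ties broken by gene id, so the cut
is reproducible) and split into 10 rank bins of near-equal size — "evenly
divided" read as equal gene counts per bin, which is what an equal-decile
analysis of ~25k genes implies. Zero-FPKM genes are excluded and counted.

Per-gene coverage is the number of breaks in a TSS-centered window (±500 bp
for decile boxplots, ±250 bp for enrichment calling), **without** priority
resolution: a break under two overlapping genes' windows counts for both,
since per-gene coverage answers a per-gene question. Counts are
depth-normalized to breaks per million library breaks; the library size is
the sample's total retained break count.

Boxplot summaries use linear-interpolation quantiles (R type 7) with
5%/95% whiskers. Metaprofiles map breaks to strand-oriented offsets
(downstream positive) in ±2 kb around the TSS, histogrammed at 100 bp, and
are normalized per gene and per million library breaks, so the profile sum
times `n_genes × library/10^6` returns the in-window break count exactly.

## The paired signed-rank test

Condition contrasts use a two-sided paired Wilcoxon signed-rank test over
per-gene coverage. Break counts are small integers, so ties and zero
differences are the norm rather than the exception; the implementation
therefore:

* drops zero differences (classic Wilcoxon; Pratt's variant, which ranks
  zeros and then drops them from the statistic, is available);
* assigns average ranks to tied absolute differences;
* computes an exact p-value for ≤ 25 informative pairs from the
  conditional null (each rank assigned a positive sign with probability
  1/2) by a rank-polynomial convolution — doubling the ranks makes tied
  half-ranks integral, so the convolution is exact;
* above 25 pairs uses a normal approximation with the tie-corrected
  variance `sum(r²)/4` and a 0.5 continuity correction.

`stats::wilcox.test` declines exact computation in the presence of ties or
zeros, which is exactly the regime break counts live in; the in-package
implementation is validated against exhaustive 2^n sign enumeration for
all n ≤ 12 and against `wilcox.test` on tie-free inputs.

The gene-length analysis bins genes into length deciles and computes
per-kb gene-body coverage — breaks in the oriented `[TSS + 250, TTS −
250)` window divided by body length in kb and depth — with the Spearman
rank correlation of gene length versus per-kb coverage as the trend
statistic. The statistic is deliberately per-kb: a per-kb rate *increase*
with length, not mere proportionality of totals to length, is the
replication-stress signature.

# Enrichment calling

For each expressed gene the case/control fold change is

$$\mathrm{FC} = \frac{(c_\text{case} + \varepsilon) / L_\text{case}}
                     {(c_\text{ctrl} + \varepsilon) / L_\text{ctrl}}$$

with raw window counts $c$, library sizes $L$ and pseudocount
$\varepsilon = 0.5$. Genes with `FC > 1.5` and at least 5 supporting raw
breaks across both samples are called, ranked by fold change. The
pseudocount sits on the raw-count scale so that near-zero counts cannot
produce unbounded ratios; as a consequence exact scale invariance holds
when counts and libraries are scaled together only at $\varepsilon = 0$,
and swap symmetry (`FC_swapped = 1/FC`) is exact at $\varepsilon = 0$.
Both the threshold and the support rule are configurable; raising the
threshold always yields a subset of the calls.

A companion check compares the FPKM distribution of called genes against
all expressed genes (rank-sum test plus quantile overlay) to ask whether a
call set is merely an expression-shifted sample.

# The simulator

The generator emulates the statistical structure the analysis assumes, on
a toy genome, so that every stage is testable without any external data.
Breaks are drawn from a three-component mixture:

* **background** — uniform over the genome, weight `background_rate` per Mb;
* **TSS** — a gene is chosen with weight `tss_beta × FPKM^tss_alpha`
  (times the condition's TSS multiplier), and the break lands
  `Normal(TSS, 150 bp)` truncated at ±2 kb. The sub-linear default
  `tss_alpha = 0.5` keeps the coupling monotone in expression while
  preventing the most-expressed genes from monopolizing the component;
* **gene body** — a gene is chosen with weight
  `body_rate_per_kb × (length in kb)^body_length_power` (times the
  condition's body multiplier) and the break lands uniformly in the body
  window. The default `body_length_power = 2` makes the *per-kb* fragility
  grow linearly with gene length — the long-gene/common-fragile-site
  signature of replication stress. Power 1 gives a uniform per-kb rate,
  which is the natural no-association null: under it, per-kb body coverage
  is flat in length by construction, which is why the length-trend null
  checks use power 1 (with the TSS component off, so TSS-proximal spill
  into short bodies cannot masquerade as a length trend).

Conditions are multipliers on components: the knockdown-like condition
doubles the TSS weight; the replication-stress-like condition triples the
body weight. Everything is driven by one master seed through per-component
sub-seeds, so toggling one component never perturbs another's stream and
identical configs give byte-identical output, including the rendered SAM.

## Default study conditions and their power rationale

Defaults (chosen once, from the following design analysis): 5000 genes on
one 200 Mb chromosome; gene lengths LogNormal(log 15000, 0.6); FPKM
LogNormal(1, 1) with 10% zero-inflation; mixture weights giving shares of
roughly **85% background / 10% TSS / 5% body** under the control
condition; library 2 × 10^6 breaks.

The TSS share matters for a subtle reason. With a fixed per-sample library
and per-million depth normalization, doubling the TSS component weight
moves its *share* from $w$ to $2w/(1+w)$ (writing $w$ for the TSS fraction),
so the measurable knockdown/control coverage ratio is capped at
$2/(1+w)$ — about 1.82 at a 10% share, and only 1.08 at an 84% share. No
depth-normalized analysis can recover a rate multiplier exactly; a small
TSS share keeps the distortion inside a 15% band, and is also the
realistic regime — in genome-wide break mapping the overwhelming majority
of captured ends are dispersed background, not promoter-proximal.

Experiment sizes are the package's own choices: the end-to-end recovery
runs at 10^4 breaks on a 2 Mb toy; the expression-association and
length-trend analyses at 5000 genes and 2 × 10^5 breaks; the type-I
calibration at 1000 genes, 2 × 10^4 breaks and 200 replicate pairs. The
planted-hotspot experiment (50 genes at 3× TSS rate, fold-change threshold
1.5) runs at a 10^7-break library because calling depends on per-gene
Poisson noise: the false-positive probability for a null gene with
expected count $\lambda$ is roughly
$\Phi(-\log 1.5 / \sqrt{2/\lambda})$, and holding precision at 0.8
against ~4500 null genes requires $\lambda \gtrsim 90$ across most of the
expression distribution, which a 2 × 10^6 library at a 10% TSS share does
not provide.

## What the simulator does not emulate

No sequence content (reads carry `*` placeholders), no sequencing error or
mappability structure, no chromatin context, no translocations, no
fragment-size biology beyond a uniform 100–2000 nt draw, and no
inter-replicate biological variance — each sample is one multinomial draw
from the mixture. Passing recovery tests therefore demonstrates that the
pipeline's bookkeeping and statistics are correct under the generative
assumptions, not that those assumptions exhaust real DSB-capture data.

# Numerical and degenerate-input choices

* Coordinates: 0-based half-open everywhere internally; conversion happens
  once per reader.
* Duplicate representative: smallest query name (deterministic,
  order-independent).
* Quantiles: type 7 (linear interpolation) so published summaries are
  reproducible.
* Degenerate inputs: an all-zero difference vector yields p = 1 with a
  `degenerate` flag; equal-length gene sets make the length trend
  undefined (flagged, not fabricated); empty windows, empty break sets and
  zero-gene genomes are legal and return empty/zero results; a library
  size of 0 is an error rather than an Inf.
* Expression bins are rank cuts; with fewer positive genes than bins the
  request is an error rather than a silent merge.
* Pipeline outputs are written temp-then-rename, so a crashed run never
  leaves a truncated TSV; the manifest records input checksums, resolved
  parameters and per-stage counts, and identical inputs reproduce
  byte-identical outputs.

# Known limitations

* The SAM reader handles the 11 mandatory columns of well-formed SAM text;
  it is not a general-purpose validator and does not read BAM/CRAM.
* Duplicate marking keys on coordinates and orientation only (no UMI or
  base-quality logic), matching the coordinate-based definition of PCR
  duplicates in this assay.
* Fold-change calling has no replicate-aware error model; with replicates
  one would pool per condition or move to a count regression, which is out
  of scope here.
* The per-gene windows assume one transcript per gene id (the reader
  collapses to the longest transcript by default); alternative promoters
  are invisible at this level of description.

# A worked micro-example

```{r example}
cfg <- sim_config(seed = 42, n_genes = 80, chrom_length = 4e6,
                  library_size = 20000, duplicate_rate = 0.05,
                  contaminant_rates = c(secondary = 0.03, supplementary = 0.01,
                                        unmapped = 0.02, qcfail = 0.01))
genome <- make_genome(cfg)
expr <- make_expression(genome$genes, cfg)
sim <- simulate_breaks(genome$genes, expr, "p53kd", cfg)
sam <- tempfile(fileext = ".sam")
breaks_to_sam(sim$breaks, cfg, path = sam)

extraction <- extract_breaks(sam, sample = "p53kd")
glance(extraction)

partition <- build_partition(genome$genes, genome$chrom_sizes)
annotate_breaks(tidy(extraction), partition)
```

The TSS category shows by far the highest breaks/Mb density, the recovered
break count equals the simulated library exactly, and the drop counters
equal the injected contaminant counts — the properties the test suite
checks at scale.
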