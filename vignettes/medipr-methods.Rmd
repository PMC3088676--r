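---
title: "medipr: models and design of the MeDIP-seq methylome pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{medipr: models and design of the MeDIP-seq methylome pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medipr)
```

## Scope

`medipr` re-implements, as a tested and reusable pipeline, the standard
MeDIP-seq methylome analysis used for vertebrate genomes: detection of CpG
islands (CGIs), calling of highly methylated regions (HMRs) from
immunoprecipitation tags, annotation of both against gene models and
repeats, metagene profiles around genes, correlation of promoter
methylation with expression deciles, resampled GO over-representation, and
validation of called regions against bisulfite clone sequencing. Because
the real inputs (a reference genome, tens of millions of aligned tags) are
too heavy for routine testing, the package ships a first-class synthetic
generator that plants a known methylation landscape in a toy genome; every
analysis stage is benchmarked against that planted truth.

All coordinates are carried as `GenomicRanges::GRanges` (1-based, closed
intervals), the standard container of the Bioconductor ecosystem; BED
files are converted at the boundary by `rtracklayer`. Using a single
internal convention eliminates off-by-one drift between stages.

## The synthetic study conditions

`sim_params()` fixes the benchmark: one 1 Mb chromosome carrying 40 genes
of 2–10 kb, packed with at least 5 kb between gene spans so that 2 kb
flanks never collide; half of the promoters carry a planted CpG island; 30
single-copy repeat elements (60% labelled CR1) sit in the intergenic
space, at least 2.5 kb from any gene. Methylation levels are assigned per
CpG by region, with precedence CGI > repeat > flank > body > intergenic:

| region | level | rationale |
|---|---|---|
| gene body | 0.70 | bodies are hypermethylated relative to flanks |
| repeat | 0.80 | repetitive elements are the most methylated class |
| 2 kb flank | 0.10 | TSS/TTS neighbourhoods are depleted |
| CpG island | 0.05 | most islands are essentially unmethylated |
| intergenic | 0.35 | intermediate background |

Regions at or above `m_high = 0.6` (gene bodies outside islands, plus
repeats) form the *methylated domains*, the ground truth that the peak
caller is scored against.

Two sequence-composition choices matter and are deliberate:

* **Background CpGs are placed by stratified sampling** — one CpG at a
  uniform position inside every 100 bp bin, after breaking all spontaneous
  CG dinucleotides. The overall density (0.01 CpG/bp) matches a
  CpG-depleted vertebrate background, but the *local* density is held
  nearly constant. Under the MeDIP sampling model the expected coverage of
  a locus is proportional to methylation level × CpG density; with
  Poisson-placed CpGs the density term fluctuates enough (40% CV per
  fragment) to make moderately methylated, locally CpG-rich intergenic
  spots indistinguishable from genuinely hypermethylated domains. The
  benchmark probes recovery of the methylation *level*, so the generator
  decouples the nuisance dimension. Real genomes do not have this
  property; on real data the caller will report additional peaks over
  CpG-dense, moderately methylated sequence, which is a property of the
  assay itself, not of the implementation.
* **Planted islands sit just above the detection thresholds**: G+C 0.60
  with one CpG per 16 bp (observed/expected ≈ 0.69), rather than a
  caricature of alternating CG. Each island spans from 500 bp upstream of
  the TSS to the end of the proximal promoter, so island promoters are
  hypomethylated across the whole TSS ± 2 kb window, as CpG-island
  promoters are in vivo. This also keeps an unmethylated island's total
  methyl-CpG mass (level 0.05 × dense CpGs) below the intergenic pulldown
  background, so unmethylated islands do not peak — the qualitative
  observation the analysis is built around. The island's level extends
  over 300 bp *shores* beyond the detectable island, so the transition to
  body-level methylation happens outside the island span; without shores,
  body peaks graze island tails by a few bases and the ≥ 1 bp overlap
  rule would mislabel unmethylated islands as methylated purely through
  boundary resolution. The default landscape keeps every island
  unmethylated; `cgi_meth_prob` can plant hypermethylated islands
  (`m_cgi_meth = 0.8`) to exercise the methylated-island classification,
  at the cost of heavy-tailed promoter scores — a methylated island
  combines high CpG density with a high level, making it an extreme MeDIP
  attractor whose `-log10(p)` dwarfs ordinary body peaks.

MeDIP tags are drawn by exact rejection sampling of sonicated fragments:
length uniform on 200–350 bp, sampling weight equal to the summed
methylation of the fragment's CpGs plus `epsilon·len/100` (the
unmethylated carry-over of the pulldown, `epsilon = 0.01`), and the
sequenced tag is the 5'-most 35 bp of a uniformly chosen fragment end.
200,000 tags give a mean coverage comparable, per unit genome, to the tens
of millions of tags of a real bird-genome library. The generator does
**not** model mappability or multi-mapping (repeats are single-copy by
construction), PCR duplicates, sequencing errors, or paired ends; passing
the benchmark therefore says nothing about robustness to those artefacts.

Randomness flows from one master seed through fixed substreams (genome,
medip, rna, bis, go), so each component is reproducible on its own and the
whole pipeline is byte-deterministic.

## CpG island detection

Islands are defined by the classic criteria: length > 200 bp, G+C
fraction > 0.5, and CpG observed/expected ratio
$\mathrm{O/E} = \frac{N_{CpG} \cdot L}{N_C \cdot N_G} > 0.6$.
The criteria say nothing about windowing, so `scan_cpg_islands()` takes
the most literal reading: slide the minimum-length window (200 bp) at
1 bp steps, qualify each window on the strict inequalities, and merge
overlapping or adjacent qualifying windows into maximal islands. Three
conventions are ours and are exposed as arguments:

* merged islands are *not* re-filtered on merged-span statistics (every
  constituent window already qualifies; re-filtering can delete a region
  all of whose windows qualify); merged-span G+C, O/E and CpG count are
  reported for information;
* the length criterion is applied to the merged span, so a single
  qualifying window (exactly 200 bp) is not an island;
* windows containing `N` are disqualified, since O/E is undefined over
  ambiguity codes.

Genome-wide island counts are sensitive to these conventions, which is why
absolute island totals from other implementations are not comparable
without aligning them. The implementation is verified
interval-by-interval against a brute-force enumeration of every window on
random sequences.

An island is *methylated* when it overlaps a called peak by at least 1 bp
(configurable); the methylated percentage is `100 × methylated / total`
rounded to one decimal.

## Peak calling

`call_peaks()` is a deliberately simplified Poisson window scan (the full
MACS machinery — tag-shift estimation, dynamic local background — is out
of scope; the published thresholds are not). Each chromosome is tiled
with 300 bp windows at 100 bp steps; a window's count is the number of
tags whose 275 bp fragment extension overlaps it (275 bp is the midpoint
of the 200–350 bp sonication range). The null is Poisson with

$$\lambda = \text{library size} \times \frac{w + e}{G}$$

where $w$ is the window length, $e$ the extension and $G$ the effective
genome length (default: the genome). The $w + e$ catchment term is
essential: a tag overlaps a window whenever its 5' end falls within
$w + e$ bases of it, so a uniform library produces $\lambda$ overlap
counts per window; using $w$ alone would understate the null by a factor
of ~2 and mark most of the genome significant. A window is significant
iff its count is strictly greater than 10 **and** its Poisson upper-tail
probability is strictly below $10^{-5}$ — both thresholds as printed,
raw, with no multiple-testing correction (the analysis applies a fixed
cut, not an FDR). Significant windows within 100 bp merge into peaks;
each peak reports the tag count over its full span and its minimum
constituent-window p-value. Windows truncated at chromosome ends keep the
nominal $\lambda$, which is slightly conservative there.

On the default benchmark (seed 1) every planted methylated domain
≥ 1 kb overlaps a called peak and ~95% of peak bases fall inside planted
domains; the residual lies within one window-plus-fragment of domain
edges, the intrinsic resolution of the method.

## Feature annotation

The summary categories are: 5' end (2 kb strand-aware upstream of the
TSS), 3' end (2 kb downstream of the TTS), exon, intron, and intergenic
(none of the above; by construction exclusive). The 2 kb convention
follows the flank and promoter definitions used throughout the analysis.
Counting is non-exclusive — a region straddling an exon/intron boundary
increments both — which is forced by the internal arithmetic of the
published summaries (category counts sum to more than the totals).
Repeat-associated tags are tags whose extension overlaps a repeat; a tag
overlapping several repeats is assigned to the longest overlap, ties
broken by coordinate, for deterministic per-family fractions.

## Metagene profile

For each gene: 20 windows of 100 bp tiling the 2 kb upstream flank, 20
equal-fraction windows tiling the body (window $i$ spans
$[\lfloor iL/20 \rfloor, \lfloor (i+1)L/20 \rfloor)$ — an exact tiling),
and 20 windows of 100 bp downstream, reversed for minus-strand genes so
index 1 is always 5'-most. Window values are mean depths scaled to tags
per ten million (the published analysis states only "normalized depth";
the scale factor is exposed and irrelevant to the profile's shape). The
profile is the unweighted mean over genes; genes shorter than 200 bp are
excluded. On the benchmark the profile reproduces the expected shape: a
dip in the flank next to the TSS (deepened by island promoters) followed
by a body plateau at several times the distal-flank level.

## Expression integration

Raw per-gene tag counts are scaled to tags per million. A gene's
promoter methylation score is $-\log_{10}$ of the smallest p-value among
peaks overlapping TSS ± 2 kb, and 0 when no peak overlaps — "no peak" is
evidence of low methylation, and dropping such genes would bias the
deciles. Genes are sorted by expression (ties broken by gene id), split
into 10 near-equal groups (lowest deciles absorb the remainder), and the
reported `r` is the Pearson correlation of the 10 (mean expression, mean
score) pairs, with its two-sided n = 10 p-value.

The expression benchmark uses the same generator at 2 Mb / 120 genes.
With the default 40 genes there are only 4 genes per decile, and the
binomial noise of decile composition alone (sd ≈ 0.25 on the
island-promoter fraction per decile) would swamp the planted coupling no
matter how accurate the implementation; 12 genes per decile brings the
composition noise (sd ≈ 0.14) safely below the planted trend. This is a
power calculation about the benchmark, fixed before use, not a tuning
knob. With coupling `beta = 2` the planted difference in promoter
methylation (≈ 0.05 vs ≈ 0.4 mean level) separates expression rates by
a factor of ~2, and the recovered decile correlation lands in the −0.6 to
−0.9 range across seeds, the magnitude class of strongly coupled tissues;
with `beta = 0` the mean correlation over 50 expression draws is near 0.

## GO enrichment

Over-representation uses the one-sided hypergeometric upper tail
(`fisher_over_representation()`, exhaustively verified against a
binomial-coefficient oracle). The resampling calibration draws `iters`
random same-size gene sets from the universe and reports
`empirical_p = (1 + #{fisher_p(sample) <= fisher_p(observed)}) / (iters + 1)`;
the +1 correction keeps empirical p-values off zero. Both p-values are
reported so that either the plain-Fisher or the calibrated reading can be
used; the significance threshold (default 0.05) is a user flag, and no
multiple-testing correction is applied. The pipeline's synthetic GO
annotation is random and carries no biology — it exercises the machinery,
nothing more.

## Bisulfite validation

Clones are simulated per region with the standard conversion model: a
CpG cytosine is retained as C with probability equal to its methylation
level; a non-CpG cytosine converts to T with probability
`conversion_rate` (0.99). Only the + strand CpG cytosine is
interrogated, avoiding strand bookkeeping the assay description leaves
unspecified. `call_methylation()` counts C versus T per reference CpG
across clones (other bases are ignored but logged) and estimates
conversion efficiency from non-CpG cytosines — reported, never used to
adjust calls, since the published patterns are raw. Ten clones per
region is our choice of default (the number sequenced per region is not
stated in the assay description). The concordance report labels regions
peak/non-peak by overlap with the called peak set and checks that peak
regions are more methylated; on the benchmark the 4 peak regions average
≈ 0.8 and the 4 non-peak regions ≈ 0.1, matching the planted body and
flank levels within binomial error.

## Numerical and degenerate-input conventions

* Strict inequalities everywhere thresholds are printed as strict
  (`> 200 bp`, `> 50%`, `> 0.6`, `> 10` tags, `< 1e-5`).
* `obs_exp_ratio()` returns `Inf` when a window has no C or no G; the
  scanner treats such windows as failing (they contain no CpG either).
* Degenerate inputs error loudly rather than return silent defaults: an
  all-zero landscape with `epsilon = 0` ("no sampleable fragments"), an
  all-zero expression library, constant decile scores ("undefined
  correlation"), tags on unknown chromosomes (silent drops would corrupt
  the library size), selected genes outside the GO universe.
* A peak's BED score is `-10·log10(p)` capped at 1000; zero-depth runs
  are omitted from bedGraph output.
* The benchmark problem sizes (1 Mb / 40 genes for peak, metagene,
  replicate and bisulfite checks; 2 Mb / 120 genes for expression;
  20 random 10 kb sequences for the scanner oracle; 50 draws for the
  null-coupling check) keep the full suite within a few minutes on one
  core while leaving each check's statistical margin wide.

## Known limitations

The peak caller uses a single global background rate: appropriate for the
synthetic genome's uniform background, conservative or anticonservative
on real genomes with large-scale coverage trends. Genome-wide island
*counts* are convention-sensitive (windowing and merging are not part of
the printed criteria). The MeDIP weight model is linear in methyl-CpG
content with no antibody saturation. The expression model couples
methylation to transcription through a single exponential factor. None
of these limit the package's purpose — a tested, deterministic
re-implementation of the analysis logic — but numbers obtained on real
data should be interpreted with them in mind.
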