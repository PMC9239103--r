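---
title: "Methods: motif occupancy, GC landscape, regulon mapping and developmental timing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif occupancy, GC landscape, regulon mapping and developmental timing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(napchip)
```

## Scope and model

napchip analyses genome-wide binding of a nucleoid-associated protein
(NAP) that recognizes a short degenerate motif with a GATC core — the
regime of streptomycete NAPs binding `GATCWT` (= `GATCAT` / `GATCTT`) on
a ~72% GC chromosome. The package starts **after** read processing: it
consumes a genome FASTA, a GFF3 annotation, MACS2-style narrowPeak calls,
a gene count matrix and, optionally, an external differential-expression
table and time-lapse plate images. Peak calling, alignment and the
negative-binomial differential-expression fit are deliberately out of
scope; their outputs are inputs here.

## Coordinate conventions

Internally every interval is 0-based half-open (`[start, end)`), the
native convention of BED and narrowPeak; GFF3's 1-based inclusive
coordinates are converted on read (`start - 1`) and restored on report
boundaries. A 1-based inclusive span `a..b` has width `b − a + 1`
(`inclusive_length()`), so a printed range like 5052200–5052548 is 349 bp.
Summit offsets relative to a gene are strand-aware with **no position 0**:
+1 is the first base of the annotated start codon (the TSS proxy — the
study system has no TSS map, so the annotated gene start stands in for
the transcription start site), −1 the base immediately upstream.

## Motif scanning and occupancy

`scan_motif()` tests every window of every contig. All overlapping
occurrences are reported — no greedy masking, because closely spaced
GATC-core sites are genuine distinct binding sites in this system. `N`
matches no motif letter. The headline convention for counts is **both
strands with deduplication**: a palindromic occurrence (same interval
matched on both strands, as for `GATC` itself) is counted once, while a
reverse-strand image at a different interval counts separately. The
protein binds double-stranded DNA, which motivates the both-strand
default; since the deposited genome and peak files are not shipped, the
convention cannot be calibrated against the published genome-wide motif
count here, so it is frozen at this default and both knobs
(`strands`, `dedup`) are exposed.

Occupancy is accounted in both directions (`motif_occupancy()`): the
fraction of motif hits overlapping a region by ≥ 1 bp (containment mode
available), and the fraction of regions containing ≥ 1 hit.

The scanner is backed by `Biostrings::vmatchPattern` with the subject
held fixed; its correctness is established in the test suite against a
naive per-window oracle over random sequences, and the synthetic-genome
generator re-derives its ground truth with an independent window-by-window
rescan rather than trusting the planted positions.

## GC landscape

`gc_track()` computes `100·(G+C)/(A+C+G+T)` per window; `N` is excluded
from the denominator (all-`N` windows are undefined and flagged). Two
window styles exist because the analyses need both: coarse left-anchored
windows (5,000 bp per 500 bp step) for plotting, and a per-base track
(300 bp window, step 1) for segmentation. Per-base windows are
**centered** (`[p − 150, p + 150)`): the per-base formulation reads as a
positional smoother, and left-anchoring would shift every segment
boundary 150 bp to the right; an `anchor` knob is provided since the
original convention is not stated. `low_gc_regions()` merges maximal runs
of positions with window GC ≤ 70% into disjoint sorted intervals; planted
AT-rich islands are recovered with boundary error at most half a window,
which is the resolution limit this definition allows.

## Peak classification and colocalization

Strength (`fold_enrichment > 10`) and width (`width < 400`) filters are
strict inequalities, matching the conventions "more than 10-fold" and
"narrow (< 400 bp)". `common_peaks()` pairs each peak of sample A with
the sample-B peak of maximal overlap (ties broken by lowest B start;
a summit-in-interval mode is also provided), one pair per A peak.
`colocalize_low_gc()` scores a peak by the fraction of its width covered
by the **union** of low-GC regions (never double-counting overlapping
regions) with an inclusive ≥ 0.8 bound.

The published fold-enrichment correlation between time points could have
been computed on matched-peak fold enrichments or on per-base coverage
tracks; `enrichment_correlation()` implements the matched-peak Pearson r,
and the per-base route would require the read-level tracks this package
does not consume. One further note: the source text reports common sites
"at 25 and 38 h" in one sentence while every other mention uses 48 h; the
package treats the time points as opaque labels, so nothing depends on
the resolution of that inconsistency.

## Promoter assignment

A promoter window is `[start − 350, start + 50)` on the plus strand and
the strand-mirrored equivalent on the minus strand, clipped at contig
edges and flagged when truncated. A summit window is `[summit − 150,
summit + 151)` — the summit base plus 150 bp each side. A gene is
**promoter-bound** iff any summit window overlaps its promoter window by
≥ 1 bp; **coding-only** iff it is not promoter-bound and a summit window
overlaps `[start + 50, end)` (strand-aware); unbound otherwise. Note a
consequence of the ≥ 1 bp rule: a summit up to ~200 bp into the gene body
still counts as promoter-bound, because its ±150 bp window reaches the
+50 boundary. When several peaks hit one promoter the record reports the
maximum-fold-enrichment peak (deterministic tie-break on peak start), and
divergent gene pairs sharing an upstream region are each assigned the
shared peak. Every record keeps its justifying gene-by-peak overlaps as a
provenance attribute for audit. The records are invariant under
reverse-complementing the genome and flipping all annotations and peaks,
which the test suite checks explicitly.

## Statistics

* **Mann-Whitney U** (`mann_whitney_u()`): `U = #{a_i > b_j} + ½#{ties}`,
  computed from ranks. For tie-free samples with `n₁ + n₂ ≤ 12` the
  p-value is exact (via the U distribution); otherwise the normal
  approximation with tie correction and continuity correction is used.
  The identity `U_a + U_b = n₁n₂` holds always; type-I error at α = 0.05
  is calibrated to [0.03, 0.07] over 10,000 null simulations in the
  acceptance tests.
* **Levene's test** (`levene_test()`): one-way ANOVA F on absolute
  deviations from the group **mean** by default (the classic test, as
  named in the study; the median-centred Brown-Forsythe variant is a
  knob). Degenerate inputs are flagged rather than failed: identical
  deviations in both groups give `W = 0, p = 1`; constant-within,
  different-between deviations give an infinite F ratio (`W = Inf,
  p = 0`), which is what the ANOVA formula implies at zero within-group
  variance.
* **TPM** (`tpm()`): per-sample length-normalized rates scaled to 10⁶;
  all-zero samples are undefined and flagged.
* **Binding bias** (`binding_bias_table()`): per condition, TPM is
  averaged across replicates **before** the bound-versus-other
  comparison, so each condition contributes one observation per gene (the
  published table reports one n per condition; pooling replicates would
  triple it). The "other" group is genes with no binding at all or
  binding only outside the promoter. Fold-change rows consume an external
  table and may use a different gene universe — the study's TPM and
  fold-change rows have visibly different n's and the underlying filter
  is unstated, so both universes are explicit arguments rather than
  assumptions. p-values are reported without multiple-testing correction,
  matching the source tables; none of the per-row tests are simultaneous
  inferences here.
* **Spore morphometry** (`spore_ratio_compare()`): per-spore
  length/width ratio, medians, sample variances (n − 1), Mann-Whitney
  against the reference and Levene for variance.

## Plate brightness

Frames are converted to grayscale with ITU-R 601 luma weights
(0.299, 0.587, 0.114 — the original weights are unspecified, so the
standard broadcast luma is the default and the weights are a knob). The
ROI is a disc whose diameter is 70% of the plate diameter (defaulting to
`min(width, height)`), centred at the image centre; a pixel belongs to
the ROI iff its centre is within the radius. Raw per-frame ROI means are
min-max normalized to [0, 1]; constant series are flagged. Transition
detection smooths with a centred 3-frame moving average and reports local
extrema with topographic prominence ≥ 0.1 (plateaus introduced by the
smoother are resolved toward the largest unsmoothed value). Times are
reported at frame resolution — hourly in the emulated acquisition; a
sub-frame interpolation knob is deliberately absent from the default path
because the synthetic stacks are hourly.

## Synthetic data: what it emulates and what it does not

Every generator is a pure function of (parameters, seed) and is
byte-reproducible; a master seed fans out to per-generator child seeds by
a fixed linear-congruential scheme (`child_seed()`).

* `synth_genome()` draws i.i.d. bases at the background GC (no
  dinucleotide or codon structure), overwrites AT-rich islands, and
  plants motif words on random strands. Accidental background motifs are
  expected and *kept*: ground truth comes from a naive rescan, not from
  the planting list.
* `synth_peaks()` covers an exactly known fraction of motif hits:
  hits are grouped into proximity clusters, clusters are selected until
  exactly `round(frac · n_hits)` hits are covered, and each peak is
  trimmed so it never touches an unselected hit; decoy peaks never
  overlap any hit. The planted fraction is therefore recovered exactly,
  up to the integer rounding `1/n_hits`, and the decoy count fixes the
  region-centric fraction by construction.
* `synth_promoter_peaks()` plants summits inside chosen promoter
  windows while rejecting placements whose summit window would touch any
  unchosen gene's promoter, so the bound set is exact; genes with no
  valid placement can be dropped and recorded rather than failing the
  whole simulation.
* `synth_counts()` draws negative-binomial counts with log-normal
  per-gene baselines and length-proportional means, shifting bound genes
  by `2^planted_log2fc`. It does not emulate library-size differences,
  batch effects, or the mean-dispersion trend of real RNA-Seq.
* `synth_plate_stack()` renders a radially uniform disc following a
  piecewise-linear brightness curve through the planted transitions plus
  Gaussian pixel noise — no illumination drift, colony texture or colour.
* `synth_spores()` draws log-normal ratios at a stated median and
  log-sd.

Because the backgrounds are i.i.d. and the effects are planted cleanly,
passing these tests demonstrates the correctness of the *computations*,
not the biological robustness of the thresholds on real data — real
chromosomes have compositional structure, real peak calls have
width/enrichment correlations, and real counts are overdispersed in more
structured ways.

## The paperlike preset and problem sizes

`simulate_study(preset = "paperlike")` builds a 100-kb chromosome at 72%
GC with three AT-rich islands and 200 planted motifs on the left arm, and
40 genes (min. 400 bp intergenic) on the right arm; peaks cover 60% of
all motif hits, 40 decoys are added, and promoter peaks are planted on a
12-gene target set. Keeping motifs and genes on separate arms keeps the
promoter-bound set sparse enough for a meaningful bound-versus-other
comparison (motif-centred peaks near genes would otherwise bind most
promoters, as they do on the real chromosome where the bound fraction of
genes is much larger); accidental motifs on the gene arm still occur and
enter the recorded truth. The second time point drops 5% of peaks and
jitters boundaries (±20 bp) and fold enrichments (10% log-normal noise),
emulating the near-identical replicate structure of vegetative versus
sporulation samples.

A 100-kb chromosome cannot host the study-scale expression design (500
bound genes with 400-bp promoters), so the expression-bias power analysis
runs the counts generator directly over a 4,000-gene universe with 500
bound genes and a planted 1.5× suppression — the sample sizes of the
published bound-versus-other comparison at study scale — while the
genome-scale preset checks exact bound-set recovery. Plate stacks are
64 × 64 px with 50 hourly frames; these sizes are the package's default
simulation scale and are stated here so results are interpretable, not
because the method depends on them.

## Numerical choices and degenerate inputs

* Strict inequalities for the strength (>) and width (<) filters; an
  inclusive ≥ for the 0.8 coverage bound and the ≤ 70% GC threshold,
  following the quoted conventions.
* narrowPeak summit offsets of −1 (summit not called) fall back to the
  interval midpoint (floor) and are flagged.
* Ties in peak pairing and max-FE selection break deterministically
  (lowest start, then name), so reports are byte-stable.
* Genes shorter than the +50 promoter downstream extent have an empty
  coding interval; they can only be promoter-bound or unbound and are
  flagged.
* An empty bound set, all-zero samples, zero-variance correlations and
  constant brightness series raise or flag rather than silently
  propagating NaN.

## Known limitations

* The annotated gene start is a TSS proxy; genes with long 5' UTRs will
  have systematically shifted promoter windows.
* `read_gene_gff3()` validates at the record level (duplicate IDs,
  missing strand) but reports record indices, not raw file line numbers.
* The fold-enrichment correlation is defined on matched peaks only;
  coverage-track correlation is not implemented.
* The plate module quantifies brightness only; colour-channel pigment
  dynamics and plate-detection (off-centre plates) are out of scope, with
  the plate centre defaulting to the image centre.
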