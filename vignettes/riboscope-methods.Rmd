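---
title: "Methods and design notes for riboscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for riboscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboscope)
```

riboscope analyses bacterial ribosome profiling (Ribo-seq) and
end-enriched RNA sequencing (Rend-seq) data. This vignette records the
models and procedures each stage implements, the parameters that matter,
what the synthetic-data generator does and does not emulate, and the
numerical choices made where the design was genuinely open. The
companion README shows the user-facing workflow.

## Coordinate conventions

All coordinates are 0-based, half-open, and strand-explicit everywhere
inside the package; "upstream" always means 5′ of a feature *on its own
strand*. GFF3 (1-based inclusive) and BED/bedGraph files are converted at
the I/O boundary and nowhere else. The chief risk in TSS work is an
off-by-one at the 5′ end, and a single conversion boundary keeps that
failure mode inspectable in one file. Early phage genes in the motivating
class of experiments sit on the minus strand, so the generator places a
large fraction (default 40%) of genes on the minus strand and the test
suite exercises strand flipping throughout.

## Read preprocessing

Raw reads follow the library layout: 2 nt UMI prefix + footprint + 5 nt
UMI suffix + 5 nt sample barcode at the 3′ end. The pipeline order is
fixed and deliberate:

1. **Demultiplex** by exact match of the terminal 5-mer (no mismatch
   tolerance: exactness is reproducible, and barcode sets are chosen to
   be well separated).
2. **Deduplicate** on the *full* sequence, UMI still attached. Identical
   full sequences are overwhelmingly PCR duplicates; reads sharing a
   footprint but differing in UMI survive, so true biological
   re-observations are kept.
3. **Strip the UMI** (first 2 nt, last 5 nt) and drop reads shorter than
   5 nt after stripping (reads under 7 nt cannot be stripped at all and
   are counted separately).

Deduplicating *before* UMI removal matters: the reverse order would
collapse distinct molecules that happen to share a footprint. A test
asserts this exact order. Alignments overlapping user-supplied rRNA/tRNA
intervals by ≥ 1 nt are then discarded, and strand-aware end tracks are
built: one count per read at its biological 5′ or 3′ end (the 3′ end of a
minus-strand read is its lower genomic coordinate). Quantitative stages
default to unambiguously mapped reads (read ids with a single reported
alignment); an `all` mode exists for comparison.

## Phasing and metagene profiles

Frame is defined directly from the annotated start codon — no P-site
offset is estimated or applied, so the phasing table reports raw 3′-end
periodicity per read length. Genes whose annotated length is not a
multiple of 3 are excluded with a warning.

Metagene profiles include coding genes that are (i) at least 50 nt from
any other annotated gene on both flanks — the isolation rule is applied
to both flanks since a close neighbour on either side bleeds coverage
into the window — and (ii) covered by strictly more than 10 reads. Each
gene's window vector is normalized by its own mean *over the plotted
window* (not the whole gene), then averaged with equal gene weight. This
makes the flat-coverage profile exactly 1 at every offset and makes the
profile invariant to any one gene's sequencing depth; both properties are
tested.

## The ribosome silhouette statistic

A silhouette is the vector of footprint-end counts along one gene body
(3′ ends by default, consistent with the end-track default). It captures
the shape of ribosome coverage; depth is deliberately discarded through
the use of a rank statistic.

* **Compression.** At modest depth many positions are empty in both
  profiles being compared, and those shared zeros inflate rank
  correlation. Positions empty in *both* profiles are removed; positions
  empty in exactly one are informative and retained.
* **Similarity** is Spearman's ρ with average ranks — count data is
  tie-heavy and the tie rule must be fixed for reproducibility. A
  comparison is undefined (NA, never silently 0) when fewer than two
  positions survive compression or either compressed vector is constant.
* **Eligibility**: ≥ 50 mapped reads across ≥ 10 distinct positions per
  profile, for every participating library.
* **Comparison.** The within-state replicate-pair medians are pooled
  across both states by default (`pool_within`): both states' replicate
  noise is informative about the null, and pooling doubles the pairs at
  no cost. Cross-state pairs of bitwise-identical profiles are excluded
  from the between median — identical profiles only arise from
  degenerate duplicated inputs, never from real libraries, and excluding
  them makes the copies-as-second-state null give exactly equal medians.

A gene is flagged when `median_within − median_between > margin`.
`compare_states()` uses margin 0 (the raw diagonal); the genome-wide
`silhouette_screen()` defaults to margin 0.1. The null distribution of
the difference is symmetric around 0, so margin 0 flags about half of
unchanged genes by construction; calibration on the generator at ~1,000
reads per gene put the null spread within a few hundredths of zero and
genuinely reshaped genes several tenths above it, so 0.1 clears the null
with a wide buffer while costing essentially no power. At very low
per-gene coverage the null tail widens and occasional false flags
survive; the margin is exposed for stricter screens.

## TSS identification

Two statistics are computed per position n of an end-density track, each
over a 201-position window (±100 nt):

$$\mathrm{peak}(n) = \frac{\mathrm{RNA}(n)}{\sum_{m=-100}^{100}\mathrm{RNA}(n+m)/200},\qquad
\mathrm{delta}(n) = \frac{\sum_{m=-100}^{0}\mathrm{RNA}(n+m)+0.001}{\sum_{m=1}^{100}\mathrm{RNA}(n+m)+0.001}$$

Note the conventions implemented exactly as defined: the peak denominator
divides a 201-term sum by 200 (a constant track scores 200/201, a lone
spike scores 200); the delta numerator includes m = 0, i.e. the peak
position itself; and the 0.001 pseudocount guards empty windows (an
all-zero track scores delta 1). On coverage data the upstream/downstream
*ratio* is **small** at a true start — the signal lies downstream — so low
delta is TSS-like. One could equally have defined delta inverted
("increase into the gene"); the package treats low values as TSS-like
and surfaces the orientation in the documentation because the two
readings are easy to confuse. On the minus strand both statistics are
evaluated on the flipped orientation.

Candidate positions must carry ≥ 5 reads and a mean window density
≥ 0.1 nt⁻¹ (positions whose window is truncated by a contig edge are
excluded and recorded), then pass `peak ≥ min_peak` (default 10) and
`delta ≤ max_delta` (default 0.5). Runs of passing positions closer than
5 nt collapse to the maximal-peak position (ties: 5′-most) — a
deterministic replacement for manual curation of ragged peak shoulders.
Each candidate is assigned to the nearest downstream gene start on its
strand within 500 nt; the distance is the 5′ leader length, classed
leaderless (< 5 nt), leadered (≥ 15 nt) or anomalous (5–14 nt — a range
that well-formed bacterial leaders avoid, so a populated anomalous class
is itself a QC signal). The calling thresholds were calibrated on the
generator (a 30-fold 5′-end enrichment yields peak densities ≈ 30–60 and
deltas ≈ 0.3 at realistic coverage) and are exposed as arguments.

## Pseudogene re-annotation and recoding

Three sequence anomalies mark a gene as pseudogene-like: non-ATG first
codon, missing terminal stop, or in-frame internal stop. Anomalous genes
are ranked by total footprint count (ties broken by coordinate) to give a
reviewable list in place of manual inspection.

`propose_orf()` scores every candidate ORF — the ancestral (annotated)
start, or any in-locus ATG, extended to the first in-frame stop — by the
fraction of locus footprints inside it, minus a length penalty
λ·len/locus_len (λ = 0.1). The penalty breaks the degeneracy between
nested ORFs that capture the same reads; ties prefer the ancestral start,
then the longest, then the 5′-most candidate, making the proposal
deterministic. Only ATG is considered as an alternative start;
near-cognate initiation is out of scope. The proposal requires ≥ 20
footprints — below that the profile cannot distinguish candidates.

Readthrough/frameshift efficiency is the ratio of mean per-nt end density
downstream of the shift site (to the downstream stop) over the mean
upstream (from the upstream start), each after excluding 9 nt at every
ORF boundary. The margin (three codons) removes initiation and
termination peaks, which would otherwise inflate either mean; it is
configurable. The estimator is scale-invariant and, under Poisson
placement, unbiased across the 0.05–0.5 efficiency range (tested).
`detect_slippery()` reports classical X_XXY_YYZ heptamers (two adjacent
homopolymeric triplets, X = Y allowed, which covers poly-A/poly-U
contexts), A/T homopolymer runs ≥ 8 nt, and 13-nt windows containing
≥ 12 A/T — the signature of slippage-prone A-T tracts.

## Quantification

A read is counted for the single same-strand gene containing its
assigned end position; reads in no gene, or at positions covered by two
overlapping same-strand genes, are tallied as uncounted so column sums
reconcile exactly. Size factors are the median-of-ratios estimator
computed over genes with nonzero counts in every library (an error,
advising a pseudocount, is raised when no such gene exists). Fold changes
are `log2((mean_B + 0.5)/(mean_A + 0.5))` on normalized counts — the
symmetric 0.5 pseudocount stabilises zeros without biasing the sign.
Dispersion estimation and significance testing are deliberately not
reimplemented; dedicated differential-expression packages do that, and
riboscope's size factors are cross-checked against one in the test
suite. A library-exclusion mechanism (dropping an anomalous
replicate/timepoint before fold-change estimation) is available simply by
subsetting the count-matrix columns.

## The synthetic-data generator

The generator is first-class, tested code: it defines the study
conditions every recovery test runs under.

* **Genome**: genes of 100–250 codons (ATG start, in-frame stop, no
  internal stops), ≥ 150 nt intergenic spacing, ≥ 30% minus-strand by
  default; a configurable fraction (default 10%) carries one
  pseudogene-like defect; a 2 kb interval is reserved as rRNA-like
  contaminant territory.
* **Leaders**: a bimodal mixture — 60% leaderless (0–3 nt) and 40%
  Normal(40, 8) truncated at ≥ 15 nt — with a hard forbidden range of
  4–14 nt that is never emitted, reproducing the empty gap between
  leaderless and leadered starts in well-behaved bacterial TSS maps.
* **Footprints**: lengths over 15–45 nt with 80% of mass on 16–26 nt
  (triangular mode at 21 nt, geometric tail), matching the short
  footprints of these libraries; 3′-end frames follow the periodicity
  vector (default 0.8/0.1/0.1); per-gene placement uses smooth per-codon
  weights held fixed across libraries, so replicates share a silhouette.
* **Expression**: log-normal with sdlog 0.5 — about a seven-fold range
  around the median for 95% of genes, representative of the
  expressed-gene range that coverage filters retain, and chosen jointly
  with the default depth (10⁵ reads per library, ~10³ per gene) to match
  the per-gene coverage at which these analyses are actually run.
* **Conditions**: condition "B" applies the fold-change map and, for
  genes in the perturbation map, multiplies positional weights by
  per-position log-normal factors (the listed value is the log-sd;
  1.5 is a strong reshaping) that are identical across B replicates —
  a reproducible shape change, which is exactly what the silhouette
  statistic targets.
* **Counts**: read placement is multinomial at fixed total depth
  (equivalently, Poisson conditioned on the total), so audit-log
  conservation is exact and recovery tolerances are computable.
* **Rend-seq**: uniform body 5′-end coverage plus excess reads whose 5′
  end is exactly the TSS, calibrated so the expected TSS-to-body count
  ratio equals `rendseq_end_enrichment` (default 30). **RNA-seq**:
  uniform transcript coverage, no frame structure — the phasing null.

Not emulated, by design: sequencing errors and quality scores, alignment
ambiguity beyond optional duplicate read-ids, realistic rRNA/tRNA
sequence content, operonic co-transcription, 3′-end (terminator) peaks
in Rend-seq, and overdispersion beyond Poisson. Consequently, passing
recovery tests demonstrates correctness of the estimators under clean
generative conditions; they do not certify performance on real libraries
with structured noise, and thresholds (TSS calling, silhouette margin)
should be re-examined on real data.

## Problem sizes and determinism

The shipped tests run the generator at 20–100 genes and 10³–2×10⁵ reads
per library, sizes at which every stochastic recovery bound holds with
wide margin while the whole suite stays quick; the acceptance script uses
10⁴ reads for each recoding locus, 10⁵ Rend-seq reads over 100 leaderless
genes for the enrichment recovery, a 200-gene two-condition Poisson
matrix with the focal gene at 10⁴ expected counts, and 10⁵ reads for the
length calibration. At these sizes the remaining estimator noise is a
few percent — e.g. the recovered fold of a 36-fold repressed gene at 10⁴
A-condition counts has ≈ 3% standard error from the Poisson counts of
its two repressed replicates alone. All randomness in the package flows
from a single integer seed through per-library derived streams, so any
run is reproducible byte for byte; per-gene profile weights are derived
from the seed and gene id, so they are stable no matter how many
libraries are simulated.

## Known limitations

* The silhouette statistic localises *that* a gene's coverage shape
  changed, not *where* along the gene, and does not separate initiation
  from elongation effects.
* TSS calling reports the single best position per ≤ 5 nt cluster;
  closely spaced alternative starts are merged.
* `propose_orf()` considers single-ORF explanations only; two-ORF loci
  are handled by the shift-efficiency estimator with a user-supplied
  shift position.
* The efficiency estimator's window choices (9-nt margins, whole-segment
  means) are one defensible reading of "density ratio"; other windowings
  shift estimates by a few percent at realistic depth.
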