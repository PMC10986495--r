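# riboscope

Analysis of bacterial ribosome profiling (Ribo-seq) and end-enriched RNA
sequencing (Rend-seq), built for the kind of experiment in which a
fast-growing bacterium such as *Lactococcus cremoris* is sampled under two
conditions (e.g. mock- versus phage-infected) and translation is read out
at nucleotide resolution. It is aimed at people who have aligned footprint
libraries and a genome annotation and want, without writing bespoke
scripts: preprocessing and QC of the raw reads, triplet-periodicity and
metagene profiles, detection of genes whose ribosome *distribution* (not
level) changes between conditions, transcription start site (TSS) maps
with 5′ leader classification, evidence of translated pseudogenes and
frameshifting, and normalized fold changes.

Every stage is paired with a synthetic-data generator that produces
genomes, annotations, and Ribo-seq / RNA-seq / Rend-seq read sets with
known ground truth (TSS positions, fold changes, perturbed genes,
readthrough efficiencies), so each estimator has a recovery test.

## The statistics at the core

**Ribosome silhouette.** The per-position footprint-end count vector over
one gene body captures the *shape* of ribosome coverage. For two profiles
a, b over the same gene, positions with a=0 and b=0 are removed (shared
empty positions manufacture fake agreement at low depth), and similarity
is Spearman's rank correlation ρ(a, b) with average ranks. A gene with at
least 50 reads over at least 10 distinct positions in every library is
compared via

    median ρ within replicate pairs  vs  median ρ between condition pairs

and flagged as a differential silhouette when the within median exceeds
the between median by more than a margin (screen default 0.1).

**TSS calling.** On a per-position end-density track RNA(n), two window
statistics over ±100 nt drive the caller:

    peak_density(n)  = RNA(n) / ( Σ_{m=-100..100} RNA(n+m) / 200 )
    delta_density(n) = ( Σ_{m=-100..0} RNA(n+m) + 0.001 )
                     / ( Σ_{m=1..100}  RNA(n+m) + 0.001 )

A sharp 5′-end spike gives a large peak density; at a true start, signal
lies downstream, so delta density is small. Candidates need ≥ 5 reads at
the position, mean window density ≥ 0.1 nt⁻¹, peak ≥ 10 and delta ≤ 0.5
(all configurable); runs of passing positions within 5 nt collapse to the
maximal peak. Leader length is the distance to the nearest downstream
start codon on the same strand; leaders are classed leaderless (< 5 nt),
leadered (≥ 15 nt) or anomalous (5–14 nt).

**Readthrough / frameshift efficiency.** For a locus with two ORFs
joined by a shift site, efficiency = mean per-nt footprint density
downstream of the shift ÷ mean density upstream, excluding 9 nt at each
ORF boundary to avoid initiation/termination peaks.

**Quantification.** Unambiguous per-gene counts, median-of-ratios size
factors, and log2 fold changes with a symmetric 0.5 pseudocount
(repression negative).

## Worked example

```r
library(riboscope)

cfg <- sim_config(seed = 101, n_genes = 40, depth = 50000,
                  fold_changes = c(g005 = 1/36),
                  silhouette_perturbation = c(g007 = 1.5),
                  frameshift_loci = data.frame(gene = "g009",
                                               shift_pos = 300L,
                                               efficiency = 0.18))
bundle <- simulate_genome(cfg)
bundle
#> genome_bundle: 1 contig(s), 31485 bp, 40 genes ( 4 pseudogene-like, 24 minus-strand )
#>   ground truth attached

ribo  <- simulate_riboseq(bundle, cfg, condition = "A", replicate = 1)
track <- build_end_track(ribo$alignments, bundle$contig_lengths, "3p")
phase_decomposition(ribo$alignments, bundle)
#> phasing_table: 50000 CDS-assigned reads; frame fractions 0.799/0.101/0.099
```

The recovered frame fractions match the generative periodicity
(0.8/0.1/0.1): footprint 3′ ends step codon-wise through the reading
frame. TSS calling on a Rend-seq track recovers every gene's start:

```r
rend <- build_end_track(simulate_rendseq(bundle, cfg)$alignments,
                        bundle$contig_lengths, "5p")
tss <- call_tss(rend, bundle)
head(tss[, c("position", "strand", "peak_density", "gene", "leader_length")], 3)
#>   position strand peak_density gene leader_length
#> 1      223      +     41.32231 g001            47
#> 2      978      +     45.28833 g002             3
#> 3     2386      +     57.29730 g004            40
leader_summary(tss)$classes
#> leaderless   leadered  anomalous
#>         16         24          0
```

Leader lengths are bimodal (near-zero or ≈ 40 nt) with an empty 5–14 nt
gap, as the generator's leader mixture dictates. Finally, the
frameshift-locus estimator:

```r
shift_efficiency(bundle, "g009", track, shift_pos = 300)$efficiency
#> [1] 0.2262103
```

The generative readthrough efficiency was 0.18; at this modest per-locus
depth (~1,200 footprints) the density-ratio estimate carries a few
percentage points of Poisson error, which shrinks as depth grows (the
recovery tests use 10⁴ locus reads).

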