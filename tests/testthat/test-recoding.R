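test_that("anomaly scanning flags exactly the defective genes", {
  b <- tiny_bundle()
  tr <- track_with(b, list(gp = rep(2L, 30L), gm = rep(1L, 30L)))
  expect_identical(nrow(flag_pseudogenes(b, tr)), 0L)  # clean annotation
  # inject an internal stop into the plus gene
  g <- b
  s <- strsplit(g$genome$chr, "")[[1]]
  s[113:115] <- c("T", "A", "A")          # codon 5 of gp
  g$genome$chr <- paste(s, collapse = "")
  out <- flag_pseudogenes(g, tr)
  expect_identical(out$gene, "gp")
  expect_identical(out$anomalies, "internal_stop")
  expect_identical(out$total_footprints, 60L)
})

test_that("simulated pseudogene defects are recovered exactly and ranked", {
  cfg <- sim_config(n_genes = 30L, depth = 3e4, seed = 51L,
                    pseudogene_fraction = 0.2)
  b <- simulate_genome(cfg)
  tr <- build_end_track(simulate_riboseq(b, cfg, "A", 1)$alignments,
                        b$contig_lengths)
  out <- flag_pseudogenes(b, tr)
  truth <- b$truth$pseudogene_anomalies
  expect_identical(sort(out$gene), sort(names(truth)))
  expect_identical(stats::setNames(out$anomalies, out$gene)[names(truth)],
                   truth)
  expect_identical(out$total_footprints, sort(out$total_footprints,
                                              decreasing = TRUE))
})

test_that("ORF proposals maximize the coverage score by enumeration", {
  # locus: 60 codons, internal stop at codon 30, footprints over the
  # first half only -> the truncated ORF explains the profile best
  set.seed(6)
  sense <- riboscope:::sense_codons()
  cds <- paste0("ATG", paste(sample(sense, 28, replace = TRUE),
                             collapse = ""), "TAA",
                paste(sample(sense, 29, replace = TRUE), collapse = ""),
                "TGA")
  g <- strsplit(strrep("ACGT", 150), "")[[1]]
  g[101:280] <- strsplit(cds, "")[[1]]
  genes <- data.frame(gene_id = "px", contig = "chr", start = 100L,
                      end = 280L, strand = "+", class = "pseudogene",
                      tss = 100L, leader_length = 0L)
  b <- genome_bundle(c(chr = paste(g, collapse = "")), genes)
  counts <- c(rep(2L, 90L), rep(0L, 90L))
  tr <- track_with(b, list(px = counts))
  p <- propose_orf(b, "px", tr)
  expect_identical(p$start, 0L)
  expect_identical(p$end, 90L)
  expect_true(p$uses_ancestral_start)
  expect_equal(p$in_orf_fraction, 1)
  # independent oracle: enumerate every candidate and rescore
  cand <- riboscope:::candidate_orfs(cds)
  score <- vapply(seq_len(nrow(cand)), function(i)
    sum(counts[(cand$start[i] + 1):cand$end[i]]) / sum(counts) -
      0.1 * (cand$end[i] - cand$start[i]) / 180, numeric(1))
  best <- cand[which.max(score), ]
  expect_identical(c(p$start, p$end), c(best$start, best$end))
  # scaling invariance and the coverage floor
  p10 <- propose_orf(b, "px", track_with(b, list(px = 10L * counts)))
  expect_identical(c(p10$start, p10$end), c(p$start, p$end))
  expect_error(propose_orf(b, "px",
                           track_with(b, list(px = integer(180)))),
               "insufficient coverage")
})

test_that("shift efficiency is the boundary-excluded density ratio", {
  b <- tiny_bundle()
  genes <- data.frame(gene_id = "fs", contig = "chr", start = 50L,
                      end = 350L, strand = "+", class = "coding",
                      tss = 50L, leader_length = 0L)
  bf <- genome_bundle(b$genome, genes)
  same <- rep(4L, 300L)
  expect_equal(shift_efficiency(bf, "fs", track_with(bf, list(fs = same)),
                                150L)$efficiency, 1)
  down0 <- c(rep(4L, 150L), rep(0L, 150L))
  expect_equal(shift_efficiency(bf, "fs", track_with(bf, list(fs = down0)),
                                150L)$efficiency, 0)
  up0 <- rev(down0)
  expect_true(is.na(shift_efficiency(bf, "fs",
                                     track_with(bf, list(fs = up0)),
                                     150L)$efficiency))
  expect_error(shift_efficiency(bf, "fs", track_with(bf, list(fs = same)),
                                5L), "margins exhaust")
})

test_that("efficiency recovery is unbiased across the efficiency range", {
  b <- tiny_bundle()
  genes <- data.frame(gene_id = "fs", contig = "chr", start = 20L,
                      end = 380L, strand = "+", class = "coding",
                      tss = 20L, leader_length = 0L)
  bf <- genome_bundle(b$genome, genes)
  set.seed(7)
  for (e in c(0.05, 0.06, 0.18, 0.5)) {
    ests <- replicate(3, {
      counts <- c(rpois(180, 200), rpois(180, 200 * e))
      shift_efficiency(bf, "fs", track_with(bf, list(fs = counts)),
                       180L)$efficiency
    })
    expect_lt(abs(mean(ests) - e), 0.01)
  }
})

test_that("slippery motifs and A/T-rich tracts are detected", {
  # the -1 frameshift-prone AAT_TTT_TTT_TAA context
  r <- detect_slippery("GGCAATTTTTTTTAAGGC")
  expect_gt(nrow(r$slippery), 0)
  expect_true(any(grepl("^TTTTTT", r$slippery$heptamer)))
  expect_identical(r$at_runs$length, 8L)
  expect_identical(r$at_runs$base, "T")
  # 12 A-T pairs in a 13-nt window flags transcriptional slippage
  r2 <- detect_slippery("GGTAAAAAAAAACAAAATCGG", min_run = 8L)
  expect_gt(nrow(r2$at_rich_windows), 0)
  # GC-rich sequence with no run and no homopolymer triplets
  r3 <- detect_slippery("GACGTCAGCTAGCATGCATGAC")
  expect_identical(nrow(r3$at_runs), 0L)
  expect_identical(nrow(r3$at_rich_windows), 0L)
})
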