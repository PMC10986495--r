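test_that("demultiplexing partitions reads by exact 3' barcode", {
  batch <- data.frame(id = c("r1", "r2", "r3"),
                      seq = c("ACGTACGTAAAAA", "ACGTACGTAAAAT",
                              "GGGGCCCCTTTTT"))
  out <- demultiplex(batch, c(A = "AAAAA", B = "TTTTT"))
  expect_identical(out$A$seq, "ACGTACGT")       # barcode removed
  expect_identical(out$B$seq, "GGGGCCCC")
  expect_identical(out$unassigned$id, "r2")     # one mismatch -> unassigned
  expect_identical(sum(vapply(out, nrow, integer(1))), nrow(batch))
  expect_error(demultiplex(batch, c(A = "AAAAA", A = "CCCCC")), "distinct")
  expect_error(demultiplex(batch, c(A = "AAAAA", B = "AAAAA")), "distinct")
})

test_that("deduplication keeps first occurrence per sequence and is idempotent", {
  batch <- data.frame(id = sprintf("r%d", 1:5),
                      seq = c("AAATTT", "AAATTT", "AAATTT", "CCCGGG",
                              "AAATTA"))
  d <- deduplicate(batch)
  expect_identical(d$id, c("r1", "r4", "r5"))
  expect_identical(attr(d, "n_removed"), 2L)
  # distinct UMIs on the same footprint survive (dedup is pre-UMI-removal)
  umis <- data.frame(id = c("u1", "u2"),
                     seq = c("AAACGTACGTACGTCCC", "TTACGTACGTACGTGGG"))
  expect_identical(nrow(deduplicate(umis)), 2L)
  expect_identical(deduplicate(d)$id, d$id)
})

test_that("UMI stripping removes 2+5 nt and filters short reads", {
  batch <- data.frame(id = c("a", "b", "c"),
                      seq = c(strrep("A", 27), strrep("C", 11),
                              strrep("G", 6)))
  out <- strip_umi_and_filter(batch)
  expect_identical(nchar(out$seq), 20L)          # 27 -> 20
  expect_identical(out$id, "a")                  # 11 -> 4 nt, dropped
  rep <- attr(out, "report")
  expect_identical(unname(rep[c("dropped_short", "dropped_unstrippable")]),
                   c(1L, 1L))                     # 6 nt unstrippable
})

test_that("the preprocessing order is demultiplex, dedup, then strip", {
  # identical footprint+UMI under different barcodes must both survive
  # (dedup is per-bin); identical full sequences in one bin collapse even
  # though their UMIs would differ after stripping never applies.
  core <- "TTACGTACGTACGTCCCCC"
  batch <- data.frame(id = c("x1", "x2", "x3", "x4"),
                      seq = c(paste0(core, "AAAAA"), paste0(core, "AAAAA"),
                              paste0(core, "GGGGG"),
                              paste0("GG", "ACGTACGTACGT", "CCCCC",
                                     "AAAAA")))
  rep <- ingest_report(batch, c(A = "AAAAA", B = "GGGGG"))
  fates <- rep$fates
  expect_identical(fates$demultiplexed[fates$library == "A"], 3L)
  expect_identical(fates$deduplicated[fates$library == "A"], 2L)
  expect_identical(fates$demultiplexed[fates$library == "B"], 1L)
  expect_identical(fates$deduplicated[fates$library == "B"], 1L)
})

test_that("demultiplexed bin sizes match the simulator's audit depths", {
  cfg <- sim_config(n_genes = 6L, depth = 800, seed = 21L)
  b <- simulate_genome(cfg)
  l1 <- simulate_riboseq(b, cfg, "A", 1)
  l2 <- simulate_riboseq(b, cfg, "B", 1)
  pooled <- rbind(l1$reads, l2$reads)
  bins <- demultiplex(pooled, c(A1 = l1$meta$barcode, B1 = l2$meta$barcode))
  expect_identical(nrow(bins$A1), as.integer(sum(l1$audit)))
  expect_identical(nrow(bins$B1), as.integer(sum(l2$audit)))
  expect_identical(nrow(bins$unassigned), 0L)
})

test_that("contaminant filtering drops overlapping reads only", {
  ali <- data.frame(contig = "chr", start = c(100L, 195L, 210L),
                    end = c(120L, 205L, 230L),
                    read_id = c("in", "edge", "out"),
                    length = c(20L, 10L, 20L), strand = "+")
  iv <- data.frame(contig = "chr", start = 90L, end = 200L)
  out <- filter_contaminants(ali, iv)
  expect_identical(out$read_id, "out")
  expect_identical(attr(out, "n_removed"), 2L)
})

test_that("simulated contaminant load is removed at the expected rate", {
  cfg <- sim_config(n_genes = 8L, depth = 2e4, seed = 22L,
                    contaminant_fraction = 0.1)
  b <- simulate_genome(cfg)
  rs <- simulate_riboseq(b, cfg, "A", 1)
  out <- filter_contaminants(rs$alignments, b$contaminants)
  frac <- attr(out, "n_removed") / nrow(rs$alignments)
  expect_equal(frac, 0.1, tolerance = 0.1)
  expect_identical(attr(out, "n_removed"),
                   as.integer(unname(rs$audit["rRNA"])))
})

test_that("end tracks follow the strand-aware end conventions", {
  b <- tiny_bundle()
  ali <- data.frame(contig = "chr", start = c(100L, 100L),
                    end = c(120L, 120L), read_id = c("p", "m"),
                    length = 20L, strand = c("+", "-"))
  t3 <- build_end_track(ali, b$contig_lengths, "3p")
  expect_identical(t3$counts$chr$plus[119 + 1L], 1L)   # plus 3' = end-1
  expect_identical(t3$counts$chr$minus[100 + 1L], 1L)  # minus 3' = start
  t5 <- build_end_track(ali, b$contig_lengths, "5p")
  expect_identical(t5$counts$chr$plus[100 + 1L], 1L)
  expect_identical(t5$counts$chr$minus[119 + 1L], 1L)
  # conservation and multi-mapper handling
  expect_identical(sum(t3$counts$chr$plus) + sum(t3$counts$chr$minus),
                   nrow(ali))
  multi <- rbind(ali, data.frame(contig = "chr", start = 300L, end = 320L,
                                 read_id = "p", length = 20L,
                                 strand = "+"))
  tu <- build_end_track(multi, b$contig_lengths, "3p",
                        unambiguous_only = TRUE)
  expect_identical(tu$n_reads, 1L)                     # only "m" is unique
  expect_error(build_end_track(
    data.frame(contig = "chr", start = 390L, end = 420L, read_id = "x",
               length = 30L, strand = "+"), b$contig_lengths),
    "beyond contig")
})

test_that("the read-fate report reproduces the footprint-length fraction", {
  cfg <- sim_config(n_genes = 10L, depth = 5000, seed = 23L)
  b <- simulate_genome(cfg)
  rs <- simulate_riboseq(b, cfg, "A", 1)
  rep <- ingest_report(rs$reads, c(A1 = rs$meta$barcode))
  direct <- 100 * mean(rs$alignments$length >= 16 &
                         rs$alignments$length <= 26)
  expect_equal(unname(rep$pct_16_26["A1"]), direct, tolerance = 0.02)
})
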