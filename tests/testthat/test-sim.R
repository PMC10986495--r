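test_that("config validation rejects malformed parameter sets", {
  expect_error(sim_config(periodicity = c(0.5, 0.5, 0.1)), "periodicity")
  expect_error(sim_config(read_length_dist = c(`20` = 0.5)), "sum to 1")
  expect_error(sim_config(frameshift_loci = data.frame(
    gene = "g001", shift_pos = 10, efficiency = 1.2)), "efficiency")
  expect_error(sim_config(fold_changes = c(g001 = -2)), "fold changes")
  expect_error(sim_config(rendseq_end_enrichment = 0.5), "enrichment")
})

test_that("genome simulation is seed-deterministic down to the files", {
  cfg <- sim_config(n_genes = 10L, seed = 42L)
  b1 <- simulate_genome(cfg)
  b2 <- simulate_genome(cfg)
  expect_identical(b1$genome, b2$genome)
  expect_identical(b1$genes, b2$genes)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_fasta(b1$genome, f1); write_fasta(b2$genome, f2)
  expect_identical(readLines(f1), readLines(f2))
  g1 <- tempfile(fileext = ".gff3"); g2 <- tempfile(fileext = ".gff3")
  write_gff3(b1$genes, g1); write_gff3(b2$genes, g2)
  expect_identical(readLines(g1), readLines(g2))
})

test_that("gene models satisfy the generative contract", {
  cfg <- sim_config(n_genes = 40L, seed = 3L)
  b <- simulate_genome(cfg)
  genes <- b$genes
  # both strands populated, >= 30% minus
  expect_gte(mean(genes$strand == "-"), 0.3)
  expect_gt(sum(genes$strand == "+"), 0)
  # coding genes: ATG start, terminal stop, no internal stop
  for (gid in genes$gene_id[genes$class == "coding"]) {
    cod <- riboscope:::codons_of(riboscope:::gene_sequence(b, gid))
    expect_identical(cod[1], "ATG")
    expect_true(cod[length(cod)] %in% c("TAA", "TAG", "TGA"))
    expect_false(any(cod[2:(length(cod) - 1)] %in% c("TAA", "TAG", "TGA")))
  }
  # pseudogenes carry exactly the recorded defect
  expect_identical(sort(names(b$truth$pseudogene_anomalies)),
                   sort(genes$gene_id[genes$class == "pseudogene"]))
  # spacing
  o <- order(genes$start)
  expect_true(all(genes$start[o][-1] - genes$end[o][-nrow(genes)] >=
                    cfg$min_spacing))
  # no leader in the forbidden range, across many genes
  expect_false(any(genes$leader_length >= 4 & genes$leader_length <= 14))
})

test_that("degenerate leader mixture puts every TSS at the start codon", {
  cfg <- sim_config(n_genes = 15L, seed = 2L,
                    leader_model = list(fraction_leaderless = 1,
                                        leaderless_max = 0L,
                                        leadered_mean = 40, leadered_sd = 8,
                                        forbidden_range = c(4L, 14L)))
  b <- simulate_genome(cfg)
  expect_true(all(b$genes$leader_length == 0L))
  plus <- b$genes$strand == "+"
  expect_identical(b$genes$tss[plus], b$genes$start[plus])
  expect_identical(b$genes$tss[!plus], b$genes$end[!plus] - 1L)
})

test_that("an infeasible packing raises a capacity error", {
  expect_error(simulate_genome(sim_config(n_genes = 20L,
                                          genome_length = 1000L)),
               "cannot hold")
})

test_that("ribosome footprints conserve depth and obey the audit log", {
  cfg <- sim_config(n_genes = 10L, depth = 5000, seed = 9L)
  b <- simulate_genome(cfg)
  rs <- simulate_riboseq(b, cfg, "A", 1)
  expect_identical(sum(rs$audit), 5000L)
  expect_identical(nrow(rs$alignments), 5000L)
  from_id <- sub("^.*\\|", "", rs$alignments$read_id)
  expect_identical(as.integer(table(from_id)[names(rs$audit)]),
                   as.integer(rs$audit))
  expect_error(simulate_riboseq(b, cfg, "mock", 1), "unknown condition")
})

test_that("pure frame-0 periodicity places every 3' end in frame 0", {
  cfg <- sim_config(n_genes = 8L, depth = 3000, seed = 5L,
                    periodicity = c(1, 0, 0))
  b <- simulate_genome(cfg)
  rs <- simulate_riboseq(b, cfg, "A", 1)
  ph <- phase_decomposition(rs$alignments, b)
  expect_identical(unname(ph$fractions["f0"]), 1)
  expect_true(all(ph$table[, c("f1", "f2")] == 0))
})

test_that("a zero-efficiency frameshift locus emits nothing downstream", {
  fs <- data.frame(gene = "g001", shift_pos = 300L, efficiency = 0)
  cfg <- sim_config(n_genes = 5L, depth = 5000, seed = 6L,
                    frameshift_loci = fs)
  b <- simulate_genome(cfg)
  rs <- simulate_riboseq(b, cfg, "A", 1)
  g <- b$genes[b$genes$gene_id == "g001", ]
  pos <- riboscope:::end_positions(rs$alignments, "3p")
  sel <- sub("^.*\\|", "", rs$alignments$read_id) == "g001"
  local <- if (g$strand == "+") pos[sel] - g$start else g$end - 1L - pos[sel]
  expect_true(all(local < 300L))
})

test_that("Rend-seq end enrichment calibrates to the configured ratio", {
  cfg <- sim_config(n_genes = 20L, depth = 2e5, seed = 8L,
                    rendseq_end_enrichment = 30)
  b <- simulate_genome(cfg)
  rd <- simulate_rendseq(b, cfg)
  tr <- build_end_track(rd$alignments, b$contig_lengths, "5p")
  ratios <- vapply(seq_len(nrow(b$genes)), function(i) {
    g <- b$genes[i, ]
    iv <- riboscope:::transcript_interval(g)
    key <- if (g$strand == "+") "plus" else "minus"
    v <- tr$counts[[g$contig]][[key]][(iv[1] + 1L):iv[2]]
    if (g$strand == "-") v <- rev(v)
    v[1] / mean(v[-1])
  }, numeric(1))
  expect_equal(mean(ratios), 30, tolerance = 0.1)

  # enrichment 1: TSS indistinguishable from body
  cfg1 <- sim_config(n_genes = 20L, depth = 2e5, seed = 8L,
                     rendseq_end_enrichment = 1)
  rd1 <- simulate_rendseq(b, cfg1)
  tr1 <- build_end_track(rd1$alignments, b$contig_lengths, "5p")
  g <- b$genes[1, ]
  iv <- riboscope:::transcript_interval(g)
  key <- if (g$strand == "+") "plus" else "minus"
  v <- tr1$counts[[g$contig]][[key]][(iv[1] + 1L):iv[2]]
  if (g$strand == "-") v <- rev(v)
  expect_lt(abs(v[1] / mean(v[-1]) - 1), 0.5)
})

test_that("a zero-expression gene yields zero reads in every assay", {
  cfg <- sim_config(n_genes = 6L, depth = 2000, seed = 10L)
  b <- simulate_genome(cfg)
  b$truth$expression["g003"] <- 0
  for (ali in list(simulate_rendseq(b, cfg)$alignments,
                   simulate_rnaseq(b, cfg, "A", 1)$alignments,
                   simulate_riboseq(b, cfg, "A", 1)$alignments)) {
    expect_false(any(grepl("\\|g003$", ali$read_id)))
  }
})

test_that("RNA-seq output has no frame structure and recovers fold changes", {
  cfg <- sim_config(n_genes = 20L, depth = 2e5, seed = 12L,
                    fold_changes = c(g001 = 4, g002 = 0.25))
  b <- simulate_genome(cfg)
  ra <- simulate_rnaseq(b, cfg, "A", 1)
  ph <- phase_decomposition(ra$alignments, b, end_choice = "5p")
  expect_true(all(abs(ph$fractions - 1 / 3) < 0.02))
  rb <- simulate_rnaseq(b, cfg, "B", 1)
  ratio <- as.numeric(rb$audit[c("g001", "g002")] /
                        ra$audit[c("g001", "g002")])
  # library totals are equal, so ratios shrink toward the mean FC of the
  # two perturbed genes' share; compare against relative expectations
  expA <- b$truth$expression; expB <- expA
  expB[c("g001", "g002")] <- expB[c("g001", "g002")] * c(4, 0.25)
  expected <- (expB / sum(expB))[c("g001", "g002")] /
    (expA / sum(expA))[c("g001", "g002")]
  expect_equal(ratio, unname(expected), tolerance = 0.1)
})
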