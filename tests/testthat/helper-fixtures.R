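# Hand-built two-gene bundle (one gene per strand) for deterministic
# convention checks. CDS is ATG + 8 sense codons + TAA (30 nt).
tiny_cds <- function() paste0("ATG", "AAACCCGGGTTTAACACCAGGATT", "TAA")

tiny_bundle <- function() {
  g <- strsplit(strrep("ACGT", 100), "")[[1]]
  cds <- strsplit(tiny_cds(), "")[[1]]
  g[101:130] <- cds
  g[201:230] <- strsplit(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(tiny_cds()))),
    "")[[1]]
  genes <- data.frame(
    gene_id = c("gp", "gm"), contig = "chr",
    start = c(100L, 200L), end = c(130L, 230L),
    strand = c("+", "-"), class = "coding",
    tss = c(100L, 229L), leader_length = c(0L, 0L))
  genome_bundle(c(chr = paste(g, collapse = "")), genes)
}

# Empty end_track for a bundle; counts filled in by the caller.
empty_track <- function(bundle, end_choice = "3p") {
  counts <- lapply(bundle$contig_lengths, function(L)
    list(plus = integer(L), minus = integer(L)))
  structure(list(counts = counts, end_choice = end_choice,
                 contig_lengths = bundle$contig_lengths,
                 n_reads = 0L, meta = list()),
            class = "end_track")
}

# Place gene-local count vectors (5'->3') onto an empty track.
track_with <- function(bundle, local_counts, end_choice = "3p") {
  tr <- empty_track(bundle, end_choice)
  for (gid in names(local_counts)) {
    g <- bundle$genes[bundle$genes$gene_id == gid, ]
    v <- local_counts[[gid]]
    stopifnot(length(v) == g$end - g$start)
    key <- if (g$strand == "+") "plus" else "minus"
    if (g$strand == "-") v <- rev(v)
    tr$counts[[g$contig]][[key]][(g$start + 1L):g$end] <-
      tr$counts[[g$contig]][[key]][(g$start + 1L):g$end] + v
  }
  tr$n_reads <- sum(vapply(tr$counts, function(x)
    sum(x$plus) + sum(x$minus), numeric(1)))
  tr
}

# Independent Spearman oracle: explicit average ranks + explicit Pearson,
# applied after the same both-zero compression rule.
oracle_spearman <- function(a, b) {
  keep <- a != 0 | b != 0
  a <- a[keep]; b <- b[keep]
  if (length(a) < 2L || length(unique(a)) < 2L || length(unique(b)) < 2L)
    return(NA_real_)
  rk <- function(x) vapply(x, function(xi)
    sum(x < xi) + (sum(x == xi) + 1) / 2, numeric(1))
  ra <- rk(a); rb <- rk(b)
  num <- sum((ra - mean(ra)) * (rb - mean(rb)))
  den <- sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  num / den
}

# Brute-force density formulas (direct loops over the printed limits).
oracle_peak <- function(v, n1) {            # n1: 1-based position
  s <- 0
  for (m in -100:100) s <- s + v[n1 + m]
  if (s == 0) 0 else v[n1] / (s / 200)
}
oracle_delta <- function(v, n1) {
  up <- 0; down <- 0
  for (m in -100:0) up <- up + v[n1 + m]
  for (m in 1:100) down <- down + v[n1 + m]
  (up + 0.001) / (down + 0.001)
}

# Simulated default-condition data set shared by heavier tests.
default_sim <- function(n_genes = 40L, depth = 4e4, seed = 11L, ...) {
  cfg <- sim_config(n_genes = n_genes, depth = depth, seed = seed, ...)
  list(cfg = cfg, bundle = simulate_genome(cfg))
}
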