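# Synthetic Ribo-seq / RNA-seq / Rend-seq generator with known ground truth.
# Every downstream stage of the package has a recovery test against the
# truth objects produced here.

draw_leader <- function(lm, max_leader) {
  repeat {
    if (runif(1) < lm$fraction_leaderless) {
      l <- sample(0:lm$leaderless_max, 1L)
    } else {
      l <- round(rnorm(1, lm$leadered_mean, lm$leadered_sd))
      if (l < 15L || l > max_leader) next
    }
    fr <- lm$forbidden_range
    if (!is.null(fr) && l >= fr[1] && l <= fr[2]) next
    return(as.integer(l))
  }
}

#' Simulate a bacterial genome with annotated genes and ground truth
#'
#' Places protein-coding genes (ATG start, in-frame stop, no internal stops)
#' on both strands of a random genome with configurable intergenic spacing.
#' A subset of genes is made pseudogene-like by injecting one defect:
#' an internal stop codon, a non-ATG start, or a missing terminal stop.
#' Each gene receives a transcription start site drawn from the leader-length
#' mixture model; leaders inside the forbidden range are never emitted.
#' A designated rRNA-like interval is reserved for contaminant reads.
#'
#' @param config A [sim_config()].
#' @return A [genome_bundle()] whose `truth` element records per-gene TSS
#'   positions, leader lengths, expression rates, pseudogene defects, and
#'   the frameshift-locus table.
#' @export
simulate_genome <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_genes
  lm <- config$leader_model
  sense <- sense_codons()
  pad <- config$min_spacing + 120L
  max_leader <- config$min_spacing - 30L

  gene_id <- sprintf("g%03d", seq_len(n))
  n_pseudo <- floor(config$pseudogene_fraction * n)
  pseudo_idx <- if (n_pseudo > 0) sort(sample(n, n_pseudo)) else integer(0)
  fs <- config$frameshift_loci

  seqs <- character(n); strand <- character(n)
  start <- integer(n); end <- integer(n)
  leader <- integer(n); tss <- integer(n)
  anomaly <- rep(NA_character_, n)

  cursor <- pad
  for (i in seq_len(n)) {
    n_codons <- sample(100:250, 1L)
    body <- sample(sense, n_codons - 2L, replace = TRUE)
    s <- paste0("ATG", paste(body, collapse = ""),
                sample(STOP_CODONS, 1L))
    if (i %in% pseudo_idx) {
      cod <- codons_of(s)
      kind <- sample(c("internal_stop", "non_ATG_start", "missing_stop"), 1L)
      if (kind == "internal_stop") {
        j <- sample(seq(10L, n_codons - 10L), 1L)
        cod[j] <- sample(STOP_CODONS, 1L)
      } else if (kind == "non_ATG_start") {
        cod[1L] <- "GTG"
      } else {
        cod[n_codons] <- sample(sense, 1L)
      }
      s <- paste(cod, collapse = "")
      anomaly[i] <- kind
    }
    len <- nchar(s)
    strand[i] <- if (runif(1) < config$minus_fraction) "-" else "+"
    start[i] <- cursor
    end[i] <- cursor + len
    leader[i] <- draw_leader(lm, max_leader)
    tss[i] <- if (strand[i] == "+") start[i] - leader[i]
              else (end[i] - 1L) + leader[i]
    seqs[i] <- s
    cursor <- end[i] + config$min_spacing + sample(0:100, 1L)
  }

  rrna <- data.frame(contig = "chr", start = cursor, end = cursor + 2000L)
  cursor <- cursor + 2000L
  total <- cursor + pad
  if (!is.null(config$genome_length)) {
    if (config$genome_length < total)
      stop("genome_length ", config$genome_length, " cannot hold ", n,
           " genes plus spacing (needs >= ", total, " bp)")
    total <- as.integer(config$genome_length)
  }

  chars <- sample(c("A", "C", "G", "T"), total, replace = TRUE)
  for (i in seq_len(n)) {
    gs <- if (strand[i] == "+") seqs[i] else revcomp(seqs[i])
    chars[(start[i] + 1L):end[i]] <- strsplit(gs, "")[[1]]
  }
  genome <- c(chr = paste(chars, collapse = ""))

  genes <- data.frame(gene_id = gene_id, contig = "chr", start = start,
                      end = end, strand = strand,
                      class = ifelse(is.na(anomaly), "coding", "pseudogene"),
                      tss = tss, leader_length = leader,
                      stringsAsFactors = FALSE)
  expression <- setNames(rlnorm(n, config$expression_dist$meanlog,
                                config$expression_dist$sdlog), gene_id)
  truth <- list(
    tss = setNames(tss, gene_id),
    leader_length = setNames(leader, gene_id),
    expression = expression,
    pseudogene_anomalies = setNames(anomaly, gene_id)[!is.na(anomaly)],
    true_silhouette_diff = names(config$silhouette_perturbation),
    true_efficiencies = if (!is.null(fs))
      setNames(fs$efficiency, fs$gene) else numeric(0),
    fold_changes = config$fold_changes)
  genome_bundle(genome, genes, contaminants = rrna, truth = truth)
}

# Per-gene baseline codon-level weights, identical across libraries; plus
# the condition-B perturbation multipliers for genes listed in
# silhouette_perturbation (identical across B replicates).
gene_codon_weights <- function(config, gene_id, n_codons, condition) {
  fs <- config$frameshift_loci
  if (!is.null(fs) && gene_id %in% fs$gene) {
    row <- fs[fs$gene == gene_id, ][1L, ]
    w <- rep(1, n_codons)
    k0 <- row$shift_pos %/% 3L
    if (k0 < n_codons) w[(k0 + 1L):n_codons] <- row$efficiency
    return(w)
  }
  set.seed(derive_seed(config$seed, "profile", gene_id))
  w <- exp(rnorm(n_codons, 0, 0.5))
  sd_g <- config$silhouette_perturbation[gene_id]
  if (condition == "B" && !is.na(sd_g) && length(sd_g)) {
    set.seed(derive_seed(config$seed, "perturb", gene_id))
    w <- w * exp(rnorm(n_codons, 0, sd_g))
  }
  w
}

default_barcode <- function(condition, replicate) {
  table <- c(A1 = "ACGTA", A2 = "CATGC", A3 = "GAGAG", A4 = "TCTAG",
             B1 = "GTACG", B2 = "TGCAT", B3 = "CTCTC", B4 = "AGATC")
  key <- paste0(condition, replicate)
  if (!key %in% names(table)) stop("no default barcode for library ", key)
  unname(table[key])
}

gene_rates <- function(bundle, config, condition) {
  rates <- bundle$truth$expression
  if (condition == "B" && length(config$fold_changes)) {
    fc <- config$fold_changes
    rates[names(fc)] <- rates[names(fc)] * fc
  }
  rates
}

check_condition <- function(condition) {
  if (!condition %in% c("A", "B"))
    stop("unknown condition label: ", condition, " (use \"A\" or \"B\")")
  condition
}

#' Simulate a ribosome-profiling library
#'
#' Footprint 3' ends are placed within gene bodies at per-gene rates equal
#' to expression (times the fold change in condition "B") and per-codon
#' silhouette weights; the 3'-end frame relative to the reading frame
#' follows the configured triplet periodicity, and footprint lengths follow
#' the configured length distribution. Raw reads carry the library layout
#' expected by the preprocessing stage: 2 nt UMI prefix + footprint +
#' 5 nt UMI suffix + 5 nt sample barcode at the 3' end. Genes listed as
#' frameshift loci emit downstream-of-shift footprints at `efficiency`
#' times the upstream rate. Total emitted reads equals `depth` exactly and
#' every read is attributed to its generating gene in the audit table.
#'
#' @param bundle A [simulate_genome()] result.
#' @param config The same [sim_config()].
#' @param condition Condition label, `"A"` or `"B"`.
#' @param replicate Replicate number.
#' @param barcode 5-mer sample barcode; default derived from the library
#'   label.
#' @return A `read_set`: list with `alignments` (BED-like data frame:
#'   contig, start, end, read_id, length, strand), `reads` (raw sequences),
#'   `audit` (reads per generating gene) and `meta`.
#' @export
simulate_riboseq <- function(bundle, config, condition = "A",
                             replicate = 1L, barcode = NULL) {
  check_condition(condition)
  if (is.null(barcode)) barcode <- default_barcode(condition, replicate)
  genes <- bundle$genes
  rates <- gene_rates(bundle, config, condition)[genes$gene_id]

  cf <- config$contaminant_fraction
  units <- c(genes$gene_id, if (cf > 0) "rRNA")
  prob <- c(rates, if (cf > 0) sum(rates) * cf / (1 - cf))

  set.seed(derive_seed(config$seed, "riboseq", condition, replicate))
  counts <- as.vector(stats::rmultinom(1, config$depth, prob))
  names(counts) <- units
  lens_all <- as.integer(names(config$read_length_dist))

  out <- vector("list", length(units))
  for (i in seq_along(units)) {
    m <- counts[i]
    if (m == 0L) { out[[i]] <- NULL; next }
    if (units[i] == "rRNA") {
      iv <- bundle$contaminants[1L, ]
      L <- sample(lens_all, m, replace = TRUE, prob = config$read_length_dist)
      e3 <- sample(iv$start:(iv$end - 1L), m, replace = TRUE)
      st <- pmax(0L, e3 - L + 1L)
      out[[i]] <- data.frame(contig = iv$contig, start = st, end = e3 + 1L,
                             gene = "rRNA", length = e3 + 1L - st,
                             strand = "+", stringsAsFactors = FALSE)
      next
    }
    g <- genes[i, ]
    n_codons <- (g$end - g$start) %/% 3L
    w <- gene_codon_weights(config, g$gene_id, n_codons, condition)
    k <- sample.int(n_codons, m, replace = TRUE, prob = w) - 1L
    f <- sample(0:2, m, replace = TRUE, prob = config$periodicity)
    pos <- 3L * k + f                      # gene-local 3'-end offset
    L <- sample(lens_all, m, replace = TRUE, prob = config$read_length_dist)
    if (g$strand == "+") {
      e3 <- g$start + pos
      st <- pmax(0L, e3 - L + 1L); en <- e3 + 1L
    } else {
      e3 <- g$end - 1L - pos
      st <- e3; en <- pmin(bundle$contig_lengths[[g$contig]], e3 + L)
    }
    out[[i]] <- data.frame(contig = g$contig, start = st, end = en,
                           gene = g$gene_id, length = en - st,
                           strand = g$strand, stringsAsFactors = FALSE)
  }
  ali <- do.call(rbind, out)
  if (is.null(ali))
    ali <- data.frame(contig = character(), start = integer(),
                      end = integer(), gene = character(),
                      length = integer(), strand = character())
  lib <- paste0("ribo_", condition, replicate)
  ali$read_id <- sprintf("%s_%06d|%s", lib, seq_len(nrow(ali)), ali$gene)
  audit <- counts

  fp <- character(nrow(ali))
  for (ct in unique(ali$contig)) {
    sel <- ali$contig == ct
    fp[sel] <- substring(bundle$genome[[ct]], ali$start[sel] + 1L,
                         ali$end[sel])
  }
  minus <- ali$strand == "-"
  if (any(minus)) fp[minus] <- revcomp(fp[minus])
  umi2 <- vapply(seq_len(nrow(ali)), function(i) random_bases(2L), "")
  umi5 <- vapply(seq_len(nrow(ali)), function(i) random_bases(5L), "")
  reads <- data.frame(id = ali$read_id,
                      seq = paste0(umi2, fp, umi5, barcode),
                      stringsAsFactors = FALSE)

  ali <- ali[, c("contig", "start", "end", "read_id", "length", "strand")]
  structure(list(alignments = ali, reads = reads, audit = audit,
                 meta = list(assay = "riboseq", condition = condition,
                             replicate = replicate, barcode = barcode)),
            class = "read_set")
}

transcript_interval <- function(g) {
  # 0-based half-open genomic interval from TSS to the gene's 3' end
  if (g$strand == "+") c(g$tss, g$end) else c(g$start, g$tss + 1L)
}

#' Simulate an end-enriched (Rend-seq) library
#'
#' Each transcript gets uniform per-position 5'-end coverage over its body
#' plus excess reads whose 5' end is exactly the TSS, calibrated so the
#' expected ratio of the TSS end-count to the mean body end-count equals
#' `rendseq_end_enrichment`.
#'
#' @inheritParams simulate_riboseq
#' @return A `read_set` (alignments + audit; no raw reads).
#' @export
simulate_rendseq <- function(bundle, config) {
  genes <- bundle$genes
  rates <- bundle$truth$expression[genes$gene_id]
  set.seed(derive_seed(config$seed, "rendseq"))
  counts <- as.vector(stats::rmultinom(1, config$depth, rates))
  E <- config$rendseq_end_enrichment
  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    m <- counts[i]
    if (m == 0L) next
    g <- genes[i, ]
    iv <- transcript_interval(g)
    Lt <- iv[2] - iv[1]
    tss_local <- if (g$strand == "+") 0L else Lt - 1L
    p_tss <- E / (E + Lt - 1)
    at_tss <- runif(m) < p_tss
    loc <- integer(m)
    loc[at_tss] <- tss_local
    n_body <- sum(!at_tss)
    if (n_body > 0) {
      body <- setdiff(seq_len(Lt) - 1L, tss_local)
      loc[!at_tss] <- sample(body, n_body, replace = TRUE)
    }
    p5 <- iv[1] + loc
    if (g$strand == "+") {
      st <- p5; en <- pmin(bundle$contig_lengths[[g$contig]], p5 + 25L)
    } else {
      st <- pmax(0L, p5 - 24L); en <- p5 + 1L
    }
    out[[i]] <- data.frame(contig = g$contig, start = st, end = en,
                           gene = g$gene_id, length = en - st,
                           strand = g$strand, stringsAsFactors = FALSE)
  }
  ali <- do.call(rbind, out)
  if (is.null(ali))
    ali <- data.frame(contig = character(), start = integer(),
                      end = integer(), gene = character(),
                      length = integer(), strand = character())
  ali$read_id <- sprintf("rend_%06d|%s", seq_len(nrow(ali)), ali$gene)
  ali <- ali[, c("contig", "start", "end", "read_id", "length", "strand")]
  structure(list(alignments = ali, reads = NULL,
                 audit = setNames(counts, genes$gene_id),
                 meta = list(assay = "rendseq")),
            class = "read_set")
}

#' Simulate an RNA-seq library (no frame structure)
#'
#' Uniform coverage over each transcript at expression-proportional rates,
#' with the fold-change map applied in condition "B". Serves as the
#' periodicity-free control for phasing analyses.
#'
#' @inheritParams simulate_riboseq
#' @return A `read_set`.
#' @export
simulate_rnaseq <- function(bundle, config, condition = "A",
                            replicate = 1L) {
  check_condition(condition)
  genes <- bundle$genes
  rates <- gene_rates(bundle, config, condition)[genes$gene_id]
  set.seed(derive_seed(config$seed, "rnaseq", condition, replicate))
  counts <- as.vector(stats::rmultinom(1, config$depth, rates))
  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    m <- counts[i]
    if (m == 0L) next
    g <- genes[i, ]
    iv <- transcript_interval(g)
    p5 <- sample(iv[1]:(iv[2] - 1L), m, replace = TRUE)
    if (g$strand == "+") {
      st <- p5; en <- pmin(bundle$contig_lengths[[g$contig]], p5 + 30L)
    } else {
      st <- pmax(0L, p5 - 29L); en <- p5 + 1L
    }
    out[[i]] <- data.frame(contig = g$contig, start = st, end = en,
                           gene = g$gene_id, length = en - st,
                           strand = g$strand, stringsAsFactors = FALSE)
  }
  ali <- do.call(rbind, out)
  if (is.null(ali))
    ali <- data.frame(contig = character(), start = integer(),
                      end = integer(), gene = character(),
                      length = integer(), strand = character())
  lib <- paste0("rna_", condition, replicate)
  ali$read_id <- sprintf("%s_%06d|%s", lib, seq_len(nrow(ali)), ali$gene)
  ali <- ali[, c("contig", "start", "end", "read_id", "length", "strand")]
  structure(list(alignments = ali, reads = NULL,
                 audit = setNames(counts, genes$gene_id),
                 meta = list(assay = "rnaseq", condition = condition,
                             replicate = replicate)),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat("read_set (", x$meta$assay, "):", nrow(x$alignments), "alignments")
  if (!is.null(x$meta$condition))
    cat(", condition", x$meta$condition, "rep", x$meta$replicate)
  cat("\n")
  invisible(x)
}
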