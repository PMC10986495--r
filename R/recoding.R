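# Translated-pseudogene flagging, ORF re-annotation from footprint
# profiles, frameshift/readthrough efficiency, and slippery-motif scan.

gene_anomalies <- function(seq) {
  cod <- codons_of(seq)
  n <- length(cod)
  out <- character(0)
  if (cod[1L] != "ATG") out <- c(out, "non_ATG_start")
  if (!cod[n] %in% STOP_CODONS) out <- c(out, "missing_stop")
  if (n > 2L && any(cod[2:(n - 1L)] %in% STOP_CODONS))
    out <- c(out, "internal_stop")
  out
}

#' Flag pseudogene-like annotations and rank them by footprint support
#'
#' Scans every annotated gene for three sequence anomalies: a non-ATG
#' first codon, a last codon that is not a stop (TAA/TAG/TGA), or an
#' in-frame stop inside the coding region. Anomalous genes are ranked by
#' descending total footprint count (ties: genomic coordinate).
#'
#' @param bundle A [genome_bundle()].
#' @param track An `end_track` supplying footprint counts.
#' @return Data frame: gene, anomalies (comma-joined), total_footprints,
#'   rank; empty when no gene is anomalous.
#' @export
flag_pseudogenes <- function(bundle, track) {
  genes <- bundle$genes
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    an <- gene_anomalies(gene_sequence(bundle, g$gene_id))
    if (length(an) == 0L) next
    rows[[g$gene_id]] <- data.frame(
      gene = g$gene_id, anomalies = paste(an, collapse = ","),
      total_footprints = sum(gene_local_counts(track, g)),
      start = g$start, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(gene = character(), anomalies = character(),
                      total_footprints = integer(), rank = integer()))
  out <- do.call(rbind, rows)
  out <- out[order(-out$total_footprints, out$start), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$start <- NULL
  rownames(out) <- NULL
  out
}

# Candidate ORFs inside a locus sequence: each start (ancestral position 0
# always included; otherwise any ATG) extended to the first in-frame stop.
# Local 0-based half-open coordinates on the locus.
candidate_orfs <- function(seq) {
  L <- nchar(seq)
  starts <- unique(c(0L, gregexpr("ATG", seq)[[1]] - 1L))
  starts <- starts[starts >= 0L & starts <= L - 6L]
  rows <- list()
  for (s in starts) {
    cod <- codons_of(substring(seq, s + 1L, L))
    stop_i <- which(cod %in% STOP_CODONS)
    if (length(stop_i) == 0L) next
    e <- s + 3L * stop_i[1L]
    rows[[length(rows) + 1L]] <- data.frame(
      start = s, end = e, ancestral = s == 0L)
  }
  if (length(rows) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      ancestral = logical()))
  unique(do.call(rbind, rows))
}

#' Propose a corrected ORF for a flagged gene from its footprint profile
#'
#' Candidate ORFs run from the ancestral (annotated) start, or any
#' in-locus ATG, to the first in-frame stop. Each candidate is scored by
#' the fraction of locus footprints falling inside it, penalised by
#' relative length: `score = in_orf_fraction - lambda * orf_len /
#' locus_len`. Ties prefer the ancestral start, then the longest, then the
#' 5'-most candidate.
#'
#' @param bundle A [genome_bundle()].
#' @param gene_id Flagged gene.
#' @param track An `end_track`.
#' @param lambda Length penalty (default 0.1).
#' @param min_footprints Coverage floor; below it the proposal errors.
#' @return List: gene, local `start`/`end` (0-based, gene-local),
#'   genomic `g_start`/`g_end`, `in_orf_fraction`, `uses_ancestral_start`,
#'   `score`.
#' @export
propose_orf <- function(bundle, gene_id, track, lambda = 0.1,
                        min_footprints = 20L) {
  g <- bundle$genes[bundle$genes$gene_id == gene_id, ]
  if (nrow(g) != 1L) stop("unknown gene: ", gene_id)
  counts <- gene_local_counts(track, g)
  total <- sum(counts)
  if (total < min_footprints)
    stop("insufficient coverage for ", gene_id, " (", total,
         " < ", min_footprints, " footprints)")
  seq <- gene_sequence(bundle, gene_id)
  cand <- candidate_orfs(seq)
  if (nrow(cand) == 0L) stop("no candidate ORF in ", gene_id)
  L <- nchar(seq)
  frac <- vapply(seq_len(nrow(cand)), function(i)
    sum(counts[(cand$start[i] + 1L):cand$end[i]]) / total, numeric(1))
  len <- cand$end - cand$start
  score <- frac - lambda * len / L
  best <- which(score == max(score))
  if (length(best) > 1L) {
    anc <- best[cand$ancestral[best]]
    best <- if (length(anc)) anc else best
    best <- best[order(-len[best], cand$start[best])][1L]
  }
  b <- cand[best, ]
  g_coords <- if (g$strand == "+")
    c(g$start + b$start, g$start + b$end)
  else c(g$end - b$end, g$end - b$start)
  list(gene = gene_id, start = b$start, end = b$end,
       g_start = g_coords[1], g_end = g_coords[2],
       in_orf_fraction = frac[best], uses_ancestral_start = b$ancestral,
       score = score[best])
}

#' Frameshift / readthrough efficiency of a two-ORF locus
#'
#' Ratio of the mean per-nucleotide footprint-end density downstream of
#' the shift site to the mean density upstream of it, each computed after
#' excluding `margin` nt at every ORF boundary (the margins remove
#' initiation and termination peaks). Undefined when the upstream mean
#' is zero.
#'
#' @param bundle A [genome_bundle()].
#' @param gene_id The two-ORF locus.
#' @param track An `end_track`.
#' @param shift_pos Gene-local shift position (0-based nt).
#' @param margin Boundary exclusion in nt (default 9).
#' @return List: gene, shift_pos, upstream_mean, downstream_mean,
#'   `efficiency` (fraction, or `NA` when undefined).
#' @export
shift_efficiency <- function(bundle, gene_id, track, shift_pos,
                             margin = 9L) {
  g <- bundle$genes[bundle$genes$gene_id == gene_id, ]
  if (nrow(g) != 1L) stop("unknown gene: ", gene_id)
  counts <- gene_local_counts(track, g)
  L <- length(counts)
  up_idx <- (margin + 1L):(shift_pos - margin)
  down_idx <- (shift_pos + margin + 1L):(L - margin)
  if (length(up_idx) < 1L || length(down_idx) < 1L ||
      up_idx[1] > up_idx[length(up_idx)] ||
      down_idx[1] > down_idx[length(down_idx)])
    stop("exclusion margins exhaust an ORF segment")
  up <- mean(counts[up_idx])
  down <- mean(counts[down_idx])
  eff <- if (up == 0) NA_real_ else down / up
  list(gene = gene_id, shift_pos = shift_pos, upstream_mean = up,
       downstream_mean = down, efficiency = eff)
}

#' Scan for slippery sequences and transcriptional-slippage candidates
#'
#' Reports (i) classical -1 frameshifting X_XXY_YYZ heptamers (two
#' adjacent homopolymeric triplets; X may equal Y, giving a 6-nt
#' homopolymer), (ii) homopolymeric A/T runs of at least `min_run` nt, and
#' (iii) 13-nt windows containing at least 12 A/T, the signature of
#' slippage-prone repetitive A-T tracts.
#'
#' @param seq Nucleotide sequence (gene-strand).
#' @param min_run Minimum A/T homopolymer run length (default 8).
#' @return List of data frames: `slippery` (0-based position, heptamer),
#'   `at_runs`, `at_rich_windows`.
#' @export
detect_slippery <- function(seq, min_run = 8L) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  slippery <- list()
  if (L >= 7L) {
    for (i in seq_len(L - 6L)) {
      x <- ch[i:(i + 2L)]; y <- ch[(i + 3L):(i + 5L)]
      if (length(unique(x)) == 1L && length(unique(y)) == 1L)
        slippery[[length(slippery) + 1L]] <- data.frame(
          position = i - 1L,
          heptamer = paste(ch[i:(i + 6L)], collapse = ""))
    }
  }
  at <- ch %in% c("A", "T")
  runs <- rle(ch)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  run_keep <- which(runs$values %in% c("A", "T") &
                    runs$lengths >= min_run)
  at_runs <- data.frame(position = starts[run_keep] - 1L,
                        length = runs$lengths[run_keep],
                        base = runs$values[run_keep])
  win <- integer(0)
  if (L >= 13L) {
    cs <- c(0L, cumsum(at))
    n_at <- cs[14:(L + 1L)] - cs[1:(L - 12L)]
    win <- which(n_at >= 12L) - 1L
  }
  list(slippery = if (length(slippery)) do.call(rbind, slippery)
       else data.frame(position = integer(), heptamer = character()),
       at_runs = at_runs,
       at_rich_windows = data.frame(position = win, at_count = if
         (length(win)) (c(0L, cumsum(at))[win + 14L] -
                          c(0L, cumsum(at))[win + 1L]) else integer(0)))
}
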