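# Read preprocessing: barcode demultiplexing, PCR deduplication, UMI
# stripping, contaminant filtering, and strand-aware end-coverage tracks.
# The pipeline order is fixed: demultiplex -> deduplicate on the full
# sequence (UMI still attached) -> strip UMI -> length filter.

check_batch <- function(batch) {
  stopifnot(is.data.frame(batch), all(c("id", "seq") %in% names(batch)))
  if (nrow(batch) && any(!grepl("^[ACGTN]+$", batch$seq)))
    stop("read sequences must be non-empty over alphabet ACGTN")
  invisible(batch)
}

#' Demultiplex reads by their 3'-terminal 5-nt barcode
#'
#' Each read is assigned by exact match of its last five nucleotides; the
#' barcode is removed from assigned reads. Non-matching reads are routed to
#' an `"unassigned"` bin (barcode retained). The assignment is a partition:
#' every read lands in exactly one bin.
#'
#' @param batch Data frame with columns `id`, `seq`.
#' @param barcodes Named character vector, label to 5-mer.
#' @return Named list of read batches, one per label plus `"unassigned"`.
#' @export
demultiplex <- function(batch, barcodes) {
  check_batch(batch)
  stopifnot(all(nchar(barcodes) == 5L))
  if (anyDuplicated(names(barcodes)) || anyDuplicated(barcodes))
    stop("barcode labels and sequences must be distinct")
  tail5 <- substring(batch$seq, nchar(batch$seq) - 4L, nchar(batch$seq))
  hit <- match(tail5, barcodes)
  out <- lapply(seq_along(barcodes), function(i) {
    b <- batch[!is.na(hit) & hit == i, , drop = FALSE]
    b$seq <- substring(b$seq, 1L, nchar(b$seq) - 5L)
    rownames(b) <- NULL
    b
  })
  names(out) <- names(barcodes)
  un <- batch[is.na(hit), , drop = FALSE]
  rownames(un) <- NULL
  out$unassigned <- un
  out
}

#' Collapse PCR duplicates
#'
#' Keeps exactly one record per distinct sequence string (first occurrence;
#' stable order). Run before UMI removal, so reads sharing a footprint but
#' carrying different UMIs all survive.
#'
#' @param batch Data frame with columns `id`, `seq`.
#' @return The deduplicated batch; the number of removed records is
#'   attached as attribute `n_removed`.
#' @export
deduplicate <- function(batch) {
  check_batch(batch)
  keep <- !duplicated(batch$seq)
  out <- batch[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Strip the UMI and drop short reads
#'
#' Removes the 2-nt UMI prefix and 5-nt UMI suffix from each
#' (already demultiplexed) read. Reads shorter than 7 nt cannot be stripped
#' and are dropped; stripped reads shorter than 5 nt are dropped.
#'
#' @param batch Data frame with columns `id`, `seq` (barcode already
#'   removed).
#' @return The stripped batch, with attribute `report` = counts of
#'   `input`, `kept`, `dropped_short` (< 5 nt after stripping) and
#'   `dropped_unstrippable` (< 7 nt before stripping).
#' @export
strip_umi_and_filter <- function(batch) {
  check_batch(batch)
  n <- nchar(batch$seq)
  unstrippable <- n < 7L
  seq2 <- substring(batch$seq, 3L, n - 5L)
  short <- !unstrippable & nchar(seq2) < 5L
  keep <- !unstrippable & !short
  out <- batch[keep, , drop = FALSE]
  out$seq <- seq2[keep]
  rownames(out) <- NULL
  attr(out, "report") <- c(input = nrow(batch), kept = sum(keep),
                           dropped_short = sum(short),
                           dropped_unstrippable = sum(unstrippable))
  out
}

#' Remove alignments overlapping contaminant (rRNA/tRNA) intervals
#'
#' Any read whose alignment overlaps a contaminant interval by at least
#' one nucleotide is discarded, regardless of strand.
#'
#' @param alignments BED-like data frame (`contig`, `start`, `end`, ...).
#' @param intervals Data frame of contaminant intervals (`contig`,
#'   `start`, `end`), 0-based half-open.
#' @return Surviving alignments; attribute `n_removed` reports the count.
#' @export
filter_contaminants <- function(alignments, intervals) {
  if (nrow(alignments) == 0L || is.null(intervals) || nrow(intervals) == 0L) {
    attr(alignments, "n_removed") <- 0L
    return(alignments)
  }
  q <- GenomicRanges::GRanges(alignments$contig,
         IRanges::IRanges(alignments$start + 1L, alignments$end))
  s <- GenomicRanges::GRanges(intervals$contig,
         IRanges::IRanges(intervals$start + 1L, intervals$end))
  hit <- IRanges::overlapsAny(q, s, minoverlap = 1L)
  out <- alignments[!hit, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(hit)
  out
}

# Strand-aware biological end position of each alignment (0-based):
# 5' end of a plus-strand read is its lowest coordinate; the 3' end of a
# minus-strand read is also its lowest coordinate.
end_positions <- function(alignments, end_choice = c("3p", "5p")) {
  end_choice <- match.arg(end_choice)
  plus <- alignments$strand == "+"
  if (end_choice == "3p") ifelse(plus, alignments$end - 1L, alignments$start)
  else ifelse(plus, alignments$start, alignments$end - 1L)
}

#' Build a strand-aware end-coverage track
#'
#' For every alignment one count is added at its biological 5' or 3' end.
#' With `unambiguous_only = TRUE` (the default for quantitative stages),
#' reads whose id has more than one reported alignment are dropped first.
#'
#' @param alignments BED-like data frame (`contig`, `start`, `end`,
#'   `read_id`, `length`, `strand`).
#' @param contig_lengths Named integer vector of contig lengths.
#' @param end_choice `"3p"` (default) or `"5p"`.
#' @param unambiguous_only Drop multi-mapped reads (shared `read_id`).
#' @param meta Optional library metadata list.
#' @return An `end_track`: per-contig list of `plus`/`minus` integer count
#'   vectors of the contig length, plus `end_choice`, `n_reads`, `meta`.
#' @export
build_end_track <- function(alignments, contig_lengths,
                            end_choice = c("3p", "5p"),
                            unambiguous_only = FALSE, meta = list()) {
  end_choice <- match.arg(end_choice)
  if (unambiguous_only && nrow(alignments)) {
    multi <- alignments$read_id %in%
      alignments$read_id[duplicated(alignments$read_id)]
    alignments <- alignments[!multi, , drop = FALSE]
  }
  if (nrow(alignments)) {
    if (any(alignments$start < 0) ||
        any(alignments$end > contig_lengths[alignments$contig]))
      stop("alignment beyond contig bounds")
  }
  pos <- end_positions(alignments, end_choice)
  counts <- lapply(names(contig_lengths), function(ct) {
    L <- contig_lengths[[ct]]
    sel <- alignments$contig == ct
    mk <- function(strand) {
      v <- integer(L)
      p <- pos[sel & alignments$strand == strand]
      if (length(p)) {
        t <- tabulate(p + 1L, nbins = L)
        v <- as.integer(t)
      }
      v
    }
    list(plus = mk("+"), minus = mk("-"))
  })
  names(counts) <- names(contig_lengths)
  structure(list(counts = counts, end_choice = end_choice,
                 contig_lengths = contig_lengths,
                 n_reads = nrow(alignments), meta = meta),
            class = "end_track")
}

#' @export
print.end_track <- function(x, ...) {
  cat("end_track (", x$end_choice, "ends):", x$n_reads, "reads over",
      length(x$counts), "contig(s)\n")
  invisible(x)
}

# Per-gene vector of end counts in gene-local coordinates (5'->3').
gene_local_counts <- function(track, gene) {
  v <- track$counts[[gene$contig]][[if (gene$strand == "+") "plus"
                                    else "minus"]]
  seg <- v[(gene$start + 1L):gene$end]
  if (gene$strand == "-") seg <- rev(seg)
  seg
}

#' Read-fate report for a preprocessing run
#'
#' Runs the fixed preprocessing order (demultiplex, per-bin deduplicate,
#' UMI strip + length filter) and tabulates read fates per library,
#' together with the footprint-length distribution of the kept reads
#' (fraction of footprints of 16--26 nt is reported as `pct_16_26`).
#'
#' @param batch Raw multiplexed read batch (`id`, `seq`).
#' @param barcodes Named character vector of 5-mer barcodes.
#' @return List with `fates` (data frame: library, input, deduplicated,
#'   kept, dropped counts), `lengths` (footprint-length tables) and
#'   `pct_16_26` per library.
#' @export
ingest_report <- function(batch, barcodes) {
  bins <- demultiplex(batch, barcodes)
  libs <- setdiff(names(bins), "unassigned")
  rows <- list(); lens <- list(); pct <- numeric(0)
  for (lb in libs) {
    d <- deduplicate(bins[[lb]])
    s <- strip_umi_and_filter(d)
    rep <- attr(s, "report")
    rows[[lb]] <- data.frame(library = lb, demultiplexed = nrow(bins[[lb]]),
                             deduplicated = nrow(d), kept = rep[["kept"]],
                             dropped_short = rep[["dropped_short"]],
                             dropped_unstrippable =
                               rep[["dropped_unstrippable"]])
    L <- nchar(s$seq)
    lens[[lb]] <- table(L)
    pct[lb] <- if (length(L)) 100 * mean(L >= 16L & L <= 26L) else NA_real_
  }
  list(fates = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       n_unassigned = nrow(bins$unassigned),
       lengths = lens, pct_16_26 = pct)
}
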