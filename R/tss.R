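# Rend-seq transcription start site calling. Two per-position statistics
# drive the caller, computed over a 200 nt window (100 nt each side):
#
#   peak_density(n)  = RNA(n) / ( sum_{m=-100..100} RNA(n+m) / 200 )
#   delta_density(n) = ( sum_{m=-100..0} RNA(n+m) + 0.001 )
#                    / ( sum_{m=1..100}  RNA(n+m) + 0.001 )
#
# peak_density is large at a sharp 5'-end spike. delta_density is the
# upstream-sum over downstream-sum ratio (numerator includes the peak
# position itself, window limits -100..0 and 1..100 exactly); on coverage
# data it is SMALL at a true TSS, where signal lies downstream, so a low
# delta is TSS-like. The surrounding prose of the source method describes
# delta as an "increase", which points the opposite way; this
# implementation follows the formula as printed. "Upstream" is 5' on the
# feature's own strand; minus-strand positions are evaluated on the
# flipped orientation.

TSS_W <- 100L
TSS_EPS <- 0.001

win_sums <- function(v, lo, hi) {
  # sum of v over offsets lo..hi around every position, NA where truncated
  L <- length(v)
  S <- c(0, cumsum(as.numeric(v)))
  i <- seq_len(L)
  a <- i + lo; b <- i + hi
  out <- rep(NA_real_, L)
  ok <- a >= 1L & b <= L
  out[ok] <- S[b[ok] + 1L] - S[a[ok]]
  out
}

#' Peak density of every position of a track
#'
#' Ratio of the count at each position to the mean count over the
#' surrounding 200 nt window (201 positions, self included, divided by
#' 200 per the definition). Positions whose window is truncated by a
#' contig edge are `NA`; an all-zero window gives 0.
#'
#' @param rna Numeric per-position count/density vector (one contig, one
#'   strand, genomic order).
#' @return Numeric vector of the same length.
#' @export
peak_density <- function(rna) {
  tot <- win_sums(rna, -TSS_W, TSS_W)
  out <- ifelse(is.na(tot), NA_real_,
                ifelse(tot == 0, 0, as.numeric(rna) / (tot / (2 * TSS_W))))
  out
}

#' Delta density of every position of a track
#'
#' Upstream-window sum (offsets -100..0, peak included) over
#' downstream-window sum (offsets 1..100), each stabilised by the 0.001
#' pseudocount. Orientation follows the strand: on the minus strand
#' upstream offsets run toward higher genomic coordinates.
#'
#' @param rna Numeric per-position vector (genomic order).
#' @param strand `"+"` or `"-"`.
#' @return Numeric vector; `NA` where the window is truncated.
#' @export
delta_density <- function(rna, strand = "+") {
  if (strand == "-") return(rev(delta_density(rev(rna), "+")))
  up <- win_sums(rna, -TSS_W, 0L)
  down <- win_sums(rna, 1L, TSS_W)
  (up + TSS_EPS) / (down + TSS_EPS)
}

#' Prefilter candidate TSS positions
#'
#' Positions with at least `min_reads` mapped reads and a mean read
#' density of at least `min_density` per nucleotide across the 200 nt
#' window. Positions whose window is truncated at a contig edge are
#' excluded and recorded in the `excluded_edge` attribute.
#'
#' @param rna Numeric per-position vector.
#' @param min_reads Count threshold at the position itself (inclusive).
#' @param min_density Window mean-density threshold (inclusive).
#' @return Integer vector of 0-based positions.
#' @export
tss_prefilter <- function(rna, min_reads = 5, min_density = 0.1) {
  hit <- which(rna >= min_reads)
  tot <- win_sums(rna, -TSS_W, TSS_W)
  edge <- hit[is.na(tot[hit])]
  hit <- hit[!is.na(tot[hit])]
  keep <- hit[tot[hit] / (2 * TSS_W + 1) >= min_density]
  out <- as.integer(keep - 1L)
  attr(out, "excluded_edge") <- as.integer(edge - 1L)
  out
}

# Collapse runs of passing positions closer than `gap` nt to the
# maximal-peak position; ties resolved to the 5'-most on the strand.
collapse_candidates <- function(pos, peak, strand, gap = 5L) {
  if (length(pos) == 0L) return(integer(0))
  o <- order(pos)
  pos <- pos[o]; peak <- peak[o]
  grp <- cumsum(c(1L, diff(pos) >= gap))
  keep <- integer(max(grp))
  for (g in seq_len(max(grp))) {
    idx <- which(grp == g)
    best <- idx[peak[idx] == max(peak[idx])]
    keep[g] <- if (strand == "+") best[1L] else best[length(best)]
  }
  pos[keep]
}

#' Call transcription start sites
#'
#' Runs the prefilter and both density statistics on each strand of each
#' contig, keeps positions with `peak_density >= min_peak` and
#' `delta_density <= max_delta`, collapses runs of passing positions
#' closer than 5 nt to the maximal peak (ties: 5'-most), and assigns each
#' candidate to the nearest downstream gene start on the same strand
#' within `max_span` nt. The leader length is the distance from the TSS to
#' that start codon. Candidates with no gene in range are retained
#' unassigned.
#'
#' @param peak_track An `end_track` feeding `peak_density` (typically
#'   Rend-seq 5' ends).
#' @param bundle A [genome_bundle()].
#' @param delta_track Track feeding `delta_density` (defaults to
#'   `peak_track`; can be an RNA-seq coverage track or an aggregate).
#' @param min_peak Minimum peak density.
#' @param max_delta Maximum delta density.
#' @param max_span Maximum TSS-to-start distance for gene assignment (nt).
#' @param min_reads,min_density Prefilter thresholds.
#' @return Data frame of candidates: `position` (0-based), `strand`,
#'   `peak_density`, `delta_density`, `gene`, `leader_length`, `status`.
#' @export
call_tss <- function(peak_track, bundle, delta_track = peak_track,
                     min_peak = 10, max_delta = 0.5, max_span = 500L,
                     min_reads = 5, min_density = 0.1) {
  rows <- list()
  for (ct in names(peak_track$counts)) {
    for (sd in c("+", "-")) {
      key <- if (sd == "+") "plus" else "minus"
      v_peak <- peak_track$counts[[ct]][[key]]
      v_delta <- delta_track$counts[[ct]][[key]]
      pre <- tss_prefilter(v_peak, min_reads, min_density)
      if (length(pre) == 0L) next
      pk <- peak_density(v_peak)[pre + 1L]
      dl <- delta_density(v_delta, sd)[pre + 1L]
      ok <- !is.na(pk) & !is.na(dl) & pk >= min_peak & dl <= max_delta
      if (!any(ok)) next
      pos <- collapse_candidates(pre[ok], pk[ok], sd)
      pk2 <- peak_density(v_peak)[pos + 1L]
      dl2 <- delta_density(v_delta, sd)[pos + 1L]
      gi <- bundle$genes[bundle$genes$contig == ct &
                         bundle$genes$strand == sd, , drop = FALSE]
      gene <- rep(NA_character_, length(pos))
      leader <- rep(NA_integer_, length(pos))
      for (j in seq_along(pos)) {
        d <- if (sd == "+") gi$start - pos[j] else pos[j] - (gi$end - 1L)
        d[d < 0] <- NA
        if (all(is.na(d))) next
        k <- which.min(d)
        if (d[k] <= max_span) {
          gene[j] <- gi$gene_id[k]
          leader[j] <- as.integer(d[k])
        }
      }
      rows[[paste(ct, sd)]] <- data.frame(
        position = pos, strand = sd, contig = ct,
        peak_density = pk2, delta_density = dl2,
        gene = gene, leader_length = leader, status = "auto",
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(position = integer(), strand = character(),
                      contig = character(), peak_density = numeric(),
                      delta_density = numeric(), gene = character(),
                      leader_length = integer(), status = character()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise leader lengths of assigned TSS candidates
#'
#' Classifies leaders as leaderless (< 5 nt), leadered (>= 15 nt) or
#' anomalous (5--14 nt, inside the gap the class boundaries assume empty),
#' and reports the length histogram together with the gap check.
#'
#' @param candidates Output of [call_tss()] (assigned candidates only are
#'   used).
#' @return List: `histogram` (table of leader lengths), `classes` (counts
#'   per class), `gap_empty` (no 5--14 nt leaders observed) and the
#'   per-candidate class labels.
#' @export
leader_summary <- function(candidates) {
  x <- candidates[!is.na(candidates$gene), , drop = FALSE]
  l <- x$leader_length
  cls <- ifelse(l < 5L, "leaderless", ifelse(l >= 15L, "leadered",
                                             "anomalous"))
  list(histogram = table(l),
       classes = c(leaderless = sum(cls == "leaderless"),
                   leadered = sum(cls == "leadered"),
                   anomalous = sum(cls == "anomalous")),
       gap_empty = !any(cls == "anomalous"),
       labels = data.frame(gene = x$gene, leader_length = l, class = cls,
                           stringsAsFactors = FALSE))
}
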