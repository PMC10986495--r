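# The differential ribosome-silhouette statistic. A "silhouette" is the
# per-position footprint-end count vector over one gene body: it captures
# the shape, not the depth, of ribosome coverage. Shapes are compared by
# Spearman rank correlation after removing positions empty in both
# profiles, since at modest depth the shared zeros would manufacture
# spurious agreement.

#' Extract per-gene silhouettes from an end track
#'
#' @param track An `end_track`.
#' @param bundle A [genome_bundle()].
#' @param gene_ids Genes to extract (default: all).
#' @return Named list of integer vectors in gene-local 5'->3' coordinates.
#' @export
build_silhouettes <- function(track, bundle, gene_ids = NULL) {
  genes <- bundle$genes
  if (!is.null(gene_ids)) genes <- genes[genes$gene_id %in% gene_ids, ]
  out <- lapply(seq_len(nrow(genes)),
                function(i) gene_local_counts(track, genes[i, ]))
  names(out) <- genes$gene_id
  out
}

#' Compress a silhouette pair
#'
#' Removes positions where both silhouettes are zero; positions where
#' exactly one is zero are retained. The two output vectors stay aligned.
#'
#' @param a,b Equal-length non-negative count vectors.
#' @return List of the two compressed vectors.
#' @export
compress_pair <- function(a, b) {
  if (length(a) != length(b)) stop("silhouettes must have equal length")
  keep <- a != 0 | b != 0
  list(a = a[keep], b = b[keep])
}

#' Spearman similarity of two silhouettes
#'
#' Spearman rank correlation (average ranks for ties) on the compressed
#' pair. Undefined (NA) when fewer than two positions survive compression
#' or either compressed vector is constant; undefined values are
#' propagated, never coerced to zero.
#'
#' @param a,b Equal-length count vectors.
#' @return Correlation in \[-1, 1\], or `NA`.
#' @export
silhouette_similarity <- function(a, b) {
  cp <- compress_pair(a, b)
  if (length(cp$a) < 2L) return(NA_real_)
  if (length(unique(cp$a)) < 2L || length(unique(cp$b)) < 2L)
    return(NA_real_)
  cor(cp$a, cp$b, method = "spearman")
}

#' Silhouette eligibility
#'
#' A profile qualifies for comparison when it carries at least 50 mapped
#' reads spread over at least 10 distinct positions.
#'
#' @param s Count vector.
#' @param min_reads,min_positions Thresholds (inclusive).
#' @return Logical.
#' @export
silhouette_eligible <- function(s, min_reads = 50L, min_positions = 10L) {
  sum(s) >= min_reads && sum(s > 0) >= min_positions
}

#' Compare silhouettes within replicates versus between states
#'
#' Computes the median pairwise Spearman similarity among replicate pairs
#' within each state (pooled across both states by default) and the median
#' across all between-state pairs; cross-state pairs of bitwise-identical
#' profiles (which only degenerate duplicated inputs can produce) are
#' excluded from the between-state median. A gene is flagged as having a
#' differential silhouette when `median_within - median_between` exceeds
#' `margin`. All participating silhouettes must be eligible.
#'
#' @param state_a,state_b Lists of replicate count vectors (>= 2 each for
#'   the within-state median).
#' @param margin Flagging margin on `median_within - median_between`
#'   (default 0).
#' @param pool_within Pool within-state pairs across both states
#'   (default); otherwise only state-A pairs feed the within median.
#' @param min_reads,min_positions Eligibility thresholds.
#' @return List: `eligible`, `median_within`, `median_between`,
#'   `n_positions_used`, `flag`.
#' @export
compare_states <- function(state_a, state_b, margin = 0,
                           pool_within = TRUE,
                           min_reads = 50L, min_positions = 10L) {
  if (length(state_a) < 2L || length(state_b) < 2L)
    stop("need >= 2 replicates per state for the within-state median")
  all_s <- c(state_a, state_b)
  if (!all(vapply(all_s, silhouette_eligible, logical(1),
                  min_reads = min_reads, min_positions = min_positions))) {
    return(list(eligible = FALSE, median_within = NA_real_,
                median_between = NA_real_, n_positions_used = NA_integer_,
                flag = FALSE))
  }
  pairs_of <- function(lst) {
    idx <- utils::combn(length(lst), 2L)
    vapply(seq_len(ncol(idx)), function(j)
      silhouette_similarity(lst[[idx[1, j]]], lst[[idx[2, j]]]), numeric(1))
  }
  within <- pairs_of(state_a)
  if (pool_within) within <- c(within, pairs_of(state_b))
  # Cross-state pairs of bitwise-identical profiles carry no comparative
  # information (they only arise from degenerate duplicated inputs) and
  # are excluded; real libraries are never identical, so this is a no-op
  # on data.
  between <- numeric(0)
  for (a in state_a) for (b in state_b)
    if (!identical(as.numeric(a), as.numeric(b)))
      between <- c(between, silhouette_similarity(a, b))
  if (length(between) == 0L) between <- NA_real_
  used <- sum(Reduce(`+`, all_s) > 0)
  mw <- median(within, na.rm = TRUE)
  mb <- median(between, na.rm = TRUE)
  list(eligible = TRUE, median_within = mw, median_between = mb,
       n_positions_used = used,
       flag = is.finite(mw) && is.finite(mb) && (mw - mb) > margin)
}

#' Differential-silhouette screen over all genes
#'
#' Runs [compare_states()] for every gene, from per-library end tracks.
#'
#' The screen's default flagging margin is 0.1: on replicate-level count
#' data the within-minus-between difference of an unchanged gene stays
#' within a few hundredths of zero, while genuine shape changes shift it
#' by several tenths, so 0.1 clears the null spread with a wide buffer.
#'
#' @param tracks_a,tracks_b Lists of `end_track`s (replicates of each
#'   state).
#' @param bundle A [genome_bundle()].
#' @param margin Flagging margin (see above).
#' @param ... Passed to [compare_states()].
#' @return Data frame: gene, eligible, median_within, median_between,
#'   n_positions, flag.
#' @export
silhouette_screen <- function(tracks_a, tracks_b, bundle, margin = 0.1,
                              ...) {
  sa <- lapply(tracks_a, build_silhouettes, bundle = bundle)
  sb <- lapply(tracks_b, build_silhouettes, bundle = bundle)
  ids <- bundle$genes$gene_id
  rows <- lapply(ids, function(g) {
    r <- compare_states(lapply(sa, `[[`, g), lapply(sb, `[[`, g),
                        margin = margin, ...)
    data.frame(gene = g, eligible = r$eligible,
               median_within = r$median_within,
               median_between = r$median_between,
               n_positions = r$n_positions_used, flag = r$flag)
  })
  do.call(rbind, rows)
}
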