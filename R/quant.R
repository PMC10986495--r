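# Gene-level counting, median-of-ratios size factors, and log2
# fold-change estimation. Differential testing proper (dispersion
# shrinkage, Wald statistics) is deliberately left to dedicated packages;
# only what fold-change estimation needs is implemented here.

#' Count reads per gene by assigned end position
#'
#' A read is counted for the single gene containing its chosen end
#' position on the same strand. Reads landing in no gene, or at a
#' position covered by more than one same-strand gene, are left uncounted
#' and tallied.
#'
#' @param alignments BED-like data frame.
#' @param bundle A [genome_bundle()].
#' @param end_choice Read end used for assignment (default 3').
#' @return Named integer vector of per-gene counts with attribute
#'   `uncounted`.
#' @export
count_genes <- function(alignments, bundle, end_choice = c("3p", "5p")) {
  end_choice <- match.arg(end_choice)
  genes <- bundle$genes
  counts <- setNames(integer(nrow(genes)), genes$gene_id)
  if (nrow(alignments) == 0L) {
    attr(counts, "uncounted") <- 0L
    return(counts)
  }
  pos <- end_positions(alignments, end_choice)
  n_hit <- integer(nrow(alignments))
  hit_gene <- rep(NA_integer_, nrow(alignments))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    sel <- alignments$contig == g$contig & alignments$strand == g$strand &
      pos >= g$start & pos < g$end
    n_hit[sel] <- n_hit[sel] + 1L
    hit_gene[sel] <- i
  }
  ok <- n_hit == 1L
  t <- table(factor(hit_gene[ok], levels = seq_len(nrow(genes))))
  counts[] <- as.integer(t)
  attr(counts, "uncounted") <- sum(!ok)
  counts
}

#' Assemble a count matrix from per-library alignments
#'
#' @param align_list Named list of BED-like alignment data frames.
#' @param bundle A [genome_bundle()].
#' @param end_choice Read end used for assignment.
#' @return Integer matrix genes x libraries.
#' @export
count_matrix <- function(align_list, bundle, end_choice = "3p") {
  cols <- lapply(align_list, count_genes, bundle = bundle,
                 end_choice = end_choice)
  m <- do.call(cbind, lapply(cols, as.vector))
  dimnames(m) <- list(bundle$genes$gene_id, names(align_list))
  m
}

#' Median-of-ratios size factors
#'
#' For each library, the median over genes (restricted to genes with
#' nonzero counts in every library) of the ratio of that library's count
#' to the gene's geometric mean across libraries.
#'
#' @param counts Genes x libraries count matrix.
#' @return Named numeric vector of positive factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  keep <- apply(counts, 1L, function(r) all(r > 0))
  if (!any(keep))
    stop("no gene has nonzero counts in all libraries; ",
         "add a pseudocount or drop empty libraries")
  sub <- counts[keep, , drop = FALSE]
  log_gm <- rowMeans(log(sub))
  f <- apply(sub, 2L, function(col) exp(median(log(col) - log_gm)))
  if (any(f <= 0)) stop("non-positive size factor")
  f
}

#' Log2 fold change between two conditions
#'
#' Counts are divided by their size factors, averaged within each
#' condition, and compared as `log2((mean_B + c) / (mean_A + c))` with
#' pseudocount `c`. Repression in condition B is negative. The linear
#' fold-change magnitude `2^|lfc|` is reported alongside.
#'
#' @param counts Genes x libraries count matrix.
#' @param condition Character vector (one label per column).
#' @param cond_a,cond_b The two condition labels (A = reference).
#' @param pseudocount Stabilising constant c (default 0.5).
#' @param factors Optional precomputed size factors.
#' @return Data frame: gene, mean_a, mean_b, log2fc, fold_magnitude.
#' @export
log2_fold_change <- function(counts, condition, cond_a, cond_b,
                             pseudocount = 0.5, factors = NULL) {
  counts <- as.matrix(counts)
  stopifnot(length(condition) == ncol(counts))
  if (!any(condition == cond_a) || !any(condition == cond_b))
    stop("need >= 1 library per condition")
  if (is.null(factors)) factors <- size_factors(counts)
  norm <- sweep(counts, 2L, factors, `/`)
  ma <- rowMeans(norm[, condition == cond_a, drop = FALSE])
  mb <- rowMeans(norm[, condition == cond_b, drop = FALSE])
  lfc <- log2(mb + pseudocount) - log2(ma + pseudocount)
  data.frame(gene = rownames(counts) %||% seq_len(nrow(counts)),
             mean_a = ma, mean_b = mb, log2fc = lfc,
             fold_magnitude = 2^abs(lfc), row.names = NULL)
}
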