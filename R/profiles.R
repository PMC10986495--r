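# Sub-codon phasing and start/stop metagene profiles.

#' Sub-codon phase decomposition of footprint ends
#'
#' Every footprint end falling inside an annotated CDS contributes to
#' frame `(local offset from the start codon) mod 3`, tabulated per read
#' length. Genes whose length is not a multiple of 3 are excluded with a
#' warning. No P-site offset is applied; frame is defined directly from the
#' annotated start codon.
#'
#' @param alignments BED-like data frame (`contig`, `start`, `end`,
#'   `read_id`, `length`, `strand`).
#' @param bundle A [genome_bundle()].
#' @param end_choice Which read end defines the position (default 3').
#' @return A `phasing_table`: matrix of counts (read length x frames
#'   f0/f1/f2) plus the overall phase-fraction vector.
#' @export
phase_decomposition <- function(alignments, bundle,
                                end_choice = c("3p", "5p")) {
  end_choice <- match.arg(end_choice)
  genes <- bundle$genes
  div3 <- (genes$end - genes$start) %% 3L == 0L
  if (any(!div3)) {
    warning("excluding ", sum(!div3), " gene(s) with length not divisible by 3")
    genes <- genes[div3, , drop = FALSE]
  }
  pos <- end_positions(alignments, end_choice)
  frame <- integer(0); rlen <- integer(0)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    sel <- alignments$contig == g$contig & alignments$strand == g$strand &
      pos >= g$start & pos < g$end
    if (!any(sel)) next
    local <- if (g$strand == "+") pos[sel] - g$start
             else (g$end - 1L) - pos[sel]
    frame <- c(frame, local %% 3L)
    rlen <- c(rlen, alignments$length[sel])
  }
  tab <- table(factor(rlen), factor(frame, levels = 0:2))
  m <- matrix(as.integer(tab), nrow = nrow(tab), ncol = 3L,
              dimnames = list(rownames(tab), c("f0", "f1", "f2")))
  total <- length(frame)
  fractions <- if (total > 0) as.vector(table(factor(frame, levels = 0:2))) /
    total else rep(NA_real_, 3)
  structure(list(table = m, fractions = setNames(fractions,
                                                 c("f0", "f1", "f2")),
                 n_reads = total),
            class = "phasing_table")
}

#' @export
print.phasing_table <- function(x, ...) {
  cat("phasing_table:", x$n_reads, "CDS-assigned reads; frame fractions",
      paste(sprintf("%.3f", x$fractions), collapse = "/"), "\n")
  invisible(x)
}

# Genes isolated from every other annotated gene by >= min_isolation nt on
# both flanks (half-open gap), on the same contig, either strand.
isolated_genes <- function(genes, min_isolation) {
  keep <- logical(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    others <- genes[-i, , drop = FALSE]
    others <- others[others$contig == g$contig, , drop = FALSE]
    keep[i] <- !any(others$start < g$end + min_isolation &
                    others$end > g$start - min_isolation)
  }
  keep
}

#' Metagene profile anchored at the start or stop codon
#'
#' Includes coding genes isolated from any other annotated gene by at least
#' `min_isolation` nt on both flanks and carrying strictly more than
#' `min_reads` mapped ends in the gene body. Each included gene's window
#' vector (offsets `-window..+window` around the anchor, in the gene's own
#' 5'->3' orientation) is divided by its own mean over the window, then
#' averaged position-wise with equal gene weight, so doubling one gene's
#' depth leaves the profile unchanged.
#'
#' @param track An `end_track`.
#' @param bundle A [genome_bundle()].
#' @param anchor `"start"` (offset 0 = first nt of the start codon) or
#'   `"stop"` (offset 0 = first nt of the stop codon).
#' @param window Half-width W of the offset window, in nt.
#' @param min_isolation Minimum flank distance to another gene (nt).
#' @param min_reads Gene-body read-count threshold (strictly greater-than).
#' @return A `metagene_profile`: offsets, mean normalised density,
#'   number of contributing genes, and an `empty` flag when no gene
#'   qualifies.
#' @export
metagene <- function(track, bundle, anchor = c("start", "stop"),
                     window = 50L, min_isolation = 50L, min_reads = 10L) {
  anchor <- match.arg(anchor)
  stopifnot(window >= 1L)
  genes <- bundle$genes
  cand <- genes[genes$class == "coding", , drop = FALSE]
  cand <- cand[isolated_genes(genes, min_isolation)[
    match(cand$gene_id, genes$gene_id)], , drop = FALSE]
  offs <- seq(-window, window)
  acc <- numeric(length(offs)); n_used <- 0L
  for (i in seq_len(nrow(cand))) {
    g <- cand[i, ]
    body <- gene_local_counts(track, g)
    if (sum(body) <= min_reads) next
    if (g$strand == "+") {
      a <- if (anchor == "start") g$start else g$end - 3L
      p <- a + offs
    } else {
      a <- if (anchor == "start") g$end - 1L else g$start + 2L
      p <- a - offs
    }
    L <- track$contig_lengths[[g$contig]]
    if (any(p < 0L) || any(p >= L)) next
    v <- track$counts[[g$contig]][[if (g$strand == "+") "plus"
                                   else "minus"]][p + 1L]
    mu <- mean(v)
    if (mu == 0) next
    acc <- acc + v / mu
    n_used <- n_used + 1L
  }
  empty <- n_used == 0L
  structure(list(offsets = offs,
                 density = if (empty) rep(NA_real_, length(offs))
                           else acc / n_used,
                 n_genes = n_used, anchor = anchor, empty = empty),
            class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  if (x$empty) cat("metagene_profile (", x$anchor, "): empty\n")
  else cat("metagene_profile (", x$anchor, "):", x$n_genes,
           "genes, offsets", min(x$offsets), "..", max(x$offsets), "\n")
  invisible(x)
}

#' @export
as.data.frame.metagene_profile <- function(x, ...) {
  data.frame(offset = x$offsets, density = x$density, n_genes = x$n_genes)
}
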