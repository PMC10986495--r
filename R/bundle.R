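#' Genome bundle: sequences plus gene models in one coordinate frame
#'
#' Container shared by all analysis stages. All coordinates are 0-based,
#' half-open and strand-explicit; "upstream" always means 5' of a feature on
#' its own strand. GFF3's 1-based inclusive convention is converted at the
#' I/O boundary only.
#'
#' @param genome Named character vector (or `DNAStringSet`) of contig
#'   sequences.
#' @param genes Data frame with columns `gene_id`, `contig`, `start`, `end`
#'   (0-based half-open), `strand` ("+"/"-"), `class` ("coding" or
#'   "pseudogene") and optionally `tss` and `leader_length`.
#' @param contaminants Optional data frame of rRNA/tRNA-like intervals
#'   (`contig`, `start`, `end`).
#' @param truth Optional ground-truth list attached by the simulator.
#' @return An object of class `genome_bundle`.
#' @export
genome_bundle <- function(genome, genes, contaminants = NULL, truth = NULL) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  genome <- as.list(genome)
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "contig", "start", "end", "strand", "class")
                %in% names(genes)),
            all(genes$strand %in% c("+", "-")),
            all(genes$start >= 0), all(genes$end > genes$start),
            !anyDuplicated(genes$gene_id))
  lens <- vapply(genome, nchar, integer(1))
  bad <- genes$end > lens[genes$contig]
  if (any(bad)) stop("gene beyond contig bounds: ",
                     paste(genes$gene_id[bad], collapse = ", "))
  structure(list(genome = genome, contig_lengths = lens, genes = genes,
                 contaminants = contaminants, truth = truth),
            class = "genome_bundle")
}

#' @export
print.genome_bundle <- function(x, ...) {
  cat("genome_bundle:", length(x$genome), "contig(s),",
      sum(x$contig_lengths), "bp,", nrow(x$genes), "genes (",
      sum(x$genes$class == "pseudogene"), "pseudogene-like,",
      sum(x$genes$strand == "-"), "minus-strand )\n")
  if (!is.null(x$truth)) cat("  ground truth attached\n")
  invisible(x)
}
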