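#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor median rlnorm rnorm rpois runif setNames
#' @importFrom utils head read.table write.table
NULL

# Deterministic 32-bit sub-seed from a base seed and a label, so that each
# simulated library has its own reproducible stream.
derive_seed <- function(seed, ...) {
  label <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (v in utf8ToInt(label)) h <- (h * 31 + v) %% 2147483629L
  as.integer(h + 1L)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

sense_codons <- function() {
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, STOP_CODONS)
}

codons_of <- function(seq) {
  n <- nchar(seq) %/% 3L
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Gene-strand (5'->3') nucleotide sequence of a gene given its genomic record.
gene_sequence <- function(bundle, gene_id) {
  g <- bundle$genes[bundle$genes$gene_id == gene_id, ]
  if (nrow(g) != 1L) stop("unknown gene: ", gene_id)
  s <- substr(as.character(bundle$genome[[g$contig]]), g$start + 1L, g$end)
  if (g$strand == "-") s <- revcomp(s)
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
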