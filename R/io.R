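# Format readers/writers shared by all stages. Every genomic coordinate
# crosses module boundaries as 0-based half-open with explicit strand;
# GFF3's 1-based inclusive convention and BED/bedGraph files are converted
# here and only here.

#' Read / write genome FASTA
#'
#' @param path File path.
#' @param genome Named character vector of contig sequences.
#' @return `read_fasta` returns a named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(unlist(genome)), path)
  invisible(path)
}

#' Read / write raw reads as FASTQ
#'
#' Structural problems (a record count not divisible by four, a missing
#' `@`/`+` header) raise an error naming the offending record.
#'
#' @param path File path.
#' @param batch Data frame with columns `id`, `seq`.
#' @return `read_fastq` returns a data frame with `id`, `seq`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop("truncated FASTQ: record ", length(lines) %/% 4L + 1L,
         " is incomplete in ", path)
  if (length(lines) == 0L) return(data.frame(id = character(),
                                             seq = character()))
  hdr <- lines[seq(1L, length(lines), 4L)]
  plus <- lines[seq(3L, length(lines), 4L)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+"))
  if (length(bad))
    stop("malformed FASTQ record ", bad[1L], " in ", path)
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(id = sub("\\s.*$", "", names(x)),
             seq = unname(as.character(x)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname read_fastq
#' @export
write_fastq <- function(batch, path) {
  check_batch(batch)
  s <- Biostrings::DNAStringSet(batch$seq)
  names(s) <- batch$id
  q <- Biostrings::BStringSet(strrep("I", nchar(batch$seq)))
  Biostrings::writeXStringSet(s, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read / write gene annotations as GFF3
#'
#' Internal 0-based half-open coordinates are converted to GFF3's 1-based
#' inclusive convention at this boundary. Pseudogene-like genes carry the
#' `pseudo=true` attribute; `tss` and `leader_length` round-trip as
#' attributes when present.
#'
#' @param path File path.
#' @param genes Gene table of a [genome_bundle()].
#' @return `read_gff3` returns a gene data frame in internal coordinates.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  pseudo <- if ("pseudo" %in% names(mc))
    !is.na(mc$pseudo) & tolower(mc$pseudo) == "true" else
      rep(FALSE, length(gr))
  out <- data.frame(
    gene_id = as.character(mc$ID),
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    class = ifelse(pseudo, "pseudogene", "coding"),
    stringsAsFactors = FALSE)
  if ("tss" %in% names(mc)) out$tss <- as.integer(mc$tss)
  if ("leader_length" %in% names(mc))
    out$leader_length <- as.integer(mc$leader_length)
  out
}

#' @rdname read_gff3
#' @export
write_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    genes$contig,
    IRanges::IRanges(genes$start + 1L, genes$end),
    strand = genes$strand)
  mc <- S4Vectors::DataFrame(source = "riboscope", type = "gene",
                             ID = genes$gene_id)
  if (any(genes$class == "pseudogene"))
    mc$pseudo <- ifelse(genes$class == "pseudogene", "true", NA_character_)
  if ("tss" %in% names(genes)) mc$tss <- as.character(genes$tss)
  if ("leader_length" %in% names(genes))
    mc$leader_length <- as.character(genes$leader_length)
  S4Vectors::mcols(gr) <- mc
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read / write alignments as BED6
#'
#' Columns: chrom, start, end, read id (name), read length (score),
#' strand. BED is 0-based half-open on disk, matching the internal
#' convention.
#'
#' @param path File path.
#' @param alignments BED-like data frame.
#' @return `read_bed` returns the alignment data frame.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             read_id = gr$name,
             length = as.integer(gr$score),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' @rdname read_bed
#' @export
write_bed <- function(alignments, path) {
  gr <- GenomicRanges::GRanges(
    alignments$contig,
    IRanges::IRanges(alignments$start + 1L, alignments$end),
    strand = alignments$strand)
  gr$name <- alignments$read_id
  gr$score <- alignments$length
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Write / read an end track as bedGraph (one file per strand)
#'
#' bedGraph intervals are 0-based half-open; zero runs are omitted on
#' disk and restored on read, so a write/read round trip reproduces the
#' count vectors exactly.
#'
#' @param track An `end_track`.
#' @param path_plus,path_minus Output paths for the two strands.
#' @param contig_lengths Named integer vector (needed on read to restore
#'   vector lengths).
#' @param end_choice,meta Metadata restored onto the re-read track.
#' @return `read_bedgraph_track` returns an `end_track`.
#' @export
write_bedgraph_track <- function(track, path_plus, path_minus) {
  wr <- function(strand_key, path) {
    grs <- list()
    for (ct in names(track$counts)) {
      v <- track$counts[[ct]][[strand_key]]
      r <- rle(v)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      nz <- r$values != 0
      if (any(nz))
        grs[[ct]] <- GenomicRanges::GRanges(
          ct, IRanges::IRanges(starts[nz], ends[nz]), score = r$values[nz])
    }
    gr <- if (length(grs)) suppressWarnings(do.call(c, unname(grs)))
      else GenomicRanges::GRanges(score = numeric(0))
    rtracklayer::export(gr, path, format = "bedGraph")
  }
  wr("plus", path_plus)
  wr("minus", path_minus)
  invisible(c(path_plus, path_minus))
}

#' @rdname write_bedgraph_track
#' @export
read_bedgraph_track <- function(path_plus, path_minus, contig_lengths,
                                end_choice = "3p", meta = list()) {
  rd <- function(path) {
    gr <- rtracklayer::import(path, format = "bedGraph")
    out <- lapply(names(contig_lengths), function(ct) {
      v <- integer(contig_lengths[[ct]])
      g <- gr[as.character(GenomicRanges::seqnames(gr)) == ct]
      for (i in seq_along(g)) {
        v[GenomicRanges::start(g)[i]:GenomicRanges::end(g)[i]] <-
          as.integer(g$score[i])
      }
      v
    })
    names(out) <- names(contig_lengths)
    out
  }
  plus <- rd(path_plus); minus <- rd(path_minus)
  counts <- lapply(names(contig_lengths), function(ct)
    list(plus = plus[[ct]], minus = minus[[ct]]))
  names(counts) <- names(contig_lengths)
  structure(list(counts = counts, end_choice = end_choice,
                 contig_lengths = contig_lengths,
                 n_reads = sum(vapply(counts, function(x)
                   sum(x$plus) + sum(x$minus), numeric(1))),
                 meta = meta),
            class = "end_track")
}
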