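# End-to-end orchestration over a simulated (or pre-loaded) data set:
# simulate -> preprocess -> end tracks -> phasing/metagene, silhouette
# screen, TSS calling, pseudogene flagging, counting + fold changes.

#' Run the full analysis pipeline on a simulated data set
#'
#' Generates a genome and libraries from `config`, runs preprocessing on
#' the raw reads, builds 3' (Ribo-seq) and 5' (Rend-seq) end tracks with
#' contaminant filtering, and executes each analysis stage. When `outdir`
#' is given, fixtures (FASTA, GFF3, BED, FASTQ, ground-truth JSON) and
#' per-stage TSV outputs are written there; the run report records every
#' threshold in effect. Identical config and seed give identical outputs.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory, or `NULL` to skip file output.
#' @param replicates Replicates per condition (default 2).
#' @param silhouette_margin Flagging margin for the silhouette screen.
#' @param tss_min_peak,tss_max_delta TSS-calling thresholds.
#' @return A run report list with per-stage results.
#' @export
run_pipeline <- function(config, outdir = NULL, replicates = 2L,
                         silhouette_margin = 0.1,
                         tss_min_peak = 10, tss_max_delta = 0.5) {
  validate_sim_config(config)
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  bundle <- simulate_genome(config)

  libs <- list()
  for (cond in c("A", "B")) for (r in seq_len(replicates))
    libs[[paste0("ribo_", cond, r)]] <-
      simulate_riboseq(bundle, config, cond, r)
  rend <- simulate_rendseq(bundle, config)
  rna <- simulate_rnaseq(bundle, config, "A", 1L)

  # preprocessing on the pooled raw reads, against each library's barcode
  pooled <- do.call(rbind, lapply(libs, `[[`, "reads"))
  barcodes <- vapply(libs, function(x) x$meta$barcode, "")
  fates <- ingest_report(pooled, barcodes)

  clens <- bundle$contig_lengths
  tracks <- lapply(libs, function(x) {
    ali <- filter_contaminants(x$alignments, bundle$contaminants)
    build_end_track(ali, clens, "3p", unambiguous_only = TRUE,
                    meta = x$meta)
  })
  rend_track <- build_end_track(rend$alignments, clens, "5p",
                                meta = rend$meta)

  phasing <- phase_decomposition(libs[["ribo_A1"]]$alignments, bundle)
  meta_start <- metagene(tracks[["ribo_A1"]], bundle, "start")

  is_a <- grepl("^ribo_A", names(tracks))
  sil <- silhouette_screen(tracks[is_a], tracks[!is_a], bundle,
                           margin = silhouette_margin)

  tss <- call_tss(rend_track, bundle, min_peak = tss_min_peak,
                  max_delta = tss_max_delta)
  leaders <- leader_summary(tss)

  pseudo <- flag_pseudogenes(bundle, tracks[["ribo_A1"]])

  cm <- count_matrix(lapply(libs, `[[`, "alignments"), bundle)
  cond <- ifelse(is_a, "A", "B")
  fc <- log2_fold_change(cm, cond, "A", "B")

  report <- list(
    seed = config$seed,
    parameters = list(replicates = replicates,
                      silhouette_margin = silhouette_margin,
                      tss_min_peak = tss_min_peak,
                      tss_max_delta = tss_max_delta,
                      metagene = c(window = 50, min_isolation = 50,
                                   min_reads = 10),
                      eligibility = c(min_reads = 50, min_positions = 10),
                      prefilter = c(min_reads = 5, min_density = 0.1)),
    read_fates = fates$fates, pct_16_26 = fates$pct_16_26,
    phasing = phasing$fractions, metagene_genes = meta_start$n_genes,
    n_silhouette_flagged = sum(sil$flag, na.rm = TRUE),
    n_tss = nrow(tss), leader_classes = leaders$classes,
    n_pseudogene_flags = nrow(pseudo),
    results = list(silhouette = sil, tss = tss, pseudogenes = pseudo,
                   fold_changes = fc, counts = cm,
                   metagene_start = meta_start))

  if (!is.null(outdir)) {
    write_fasta(bundle$genome, file.path(outdir, "genome.fa"))
    write_gff3(bundle$genes, file.path(outdir, "genes.gff3"))
    jsonlite::write_json(bundle$truth, file.path(outdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    for (nm in names(libs)) {
      write_bed(libs[[nm]]$alignments,
                file.path(outdir, paste0(nm, ".bed")))
      write_fastq(libs[[nm]]$reads,
                  file.path(outdir, paste0(nm, ".fastq")))
    }
    write_bed(rend$alignments, file.path(outdir, "rendseq.bed"))
    write_bed(rna$alignments, file.path(outdir, "rnaseq.bed"))
    wt <- function(df, f) write.table(df, file.path(outdir, f),
                                      sep = "\t", quote = FALSE,
                                      row.names = FALSE)
    wt(sil, "silhouette.tsv")
    wt(tss, "tss.tsv")
    wt(pseudo, "pseudogenes.tsv")
    wt(fc, "fold_changes.tsv")
    wt(as.data.frame(meta_start), "metagene_start.tsv")
    jsonlite::write_json(report[setdiff(names(report), "results")],
                         file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}
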