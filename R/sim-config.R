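#' Default footprint length distribution
#'
#' Probability vector over read lengths 15--45 nt calibrated so that 80% of
#' the mass falls on 16--26 nt, the range that dominates short bacterial
#' ribosome footprints, with a triangular mode at 21 nt and a geometric tail
#' for longer fragments.
#'
#' @return Named numeric vector over lengths 15..45 summing to 1.
#' @export
default_read_length_dist <- function() {
  lens <- 15:45
  w <- numeric(length(lens))
  names(w) <- lens
  core <- c(1, 2, 3, 4, 5, 6, 5, 4, 3, 2, 1) # lengths 16..26, peak at 21
  w[as.character(16:26)] <- 0.80 * core / sum(core)
  w["15"] <- 0.04
  tail <- 0.75^seq_along(27:45)
  w[as.character(27:45)] <- 0.16 * tail / sum(tail)
  w / sum(w)
}

#' Simulation configuration
#'
#' Builds and validates the parameter set for the synthetic-data generator.
#' Defaults encode the study conditions the downstream analyses are designed
#' for: short footprints (80% within 16--26 nt), strong triplet periodicity,
#' a bimodal 5' leader mixture with an empty 4--14 nt gap, and Rend-seq
#' 5'-end peaks 30-fold over transcript body coverage.
#'
#' @param seed Integer seed; all generator randomness derives from it.
#' @param n_genes Number of genes to place on the genome.
#' @param genome_length Genome size in bp, or `NULL` to size automatically.
#' @param leader_model List with `fraction_leaderless`, `leaderless_max`,
#'   `leadered_mean`, `leadered_sd` and `forbidden_range` (nt interval in
#'   which no leader is ever emitted).
#' @param read_length_dist Probability vector over footprint lengths
#'   15--45 nt.
#' @param periodicity Length-3 probability vector over 3'-end frames
#'   (relative to the reading frame).
#' @param expression_dist Log-normal parameters (`meanlog`, `sdlog`) for
#'   per-gene expression rates.
#' @param fold_changes Named numeric vector, gene id to true fold change
#'   applied in condition "B" (values > 1 induce, < 1 repress).
#' @param silhouette_perturbation Named numeric vector, gene id to the
#'   log-sd of per-position rate multipliers applied in condition "B" only.
#' @param frameshift_loci Data frame with columns `gene`, `shift_pos`
#'   (gene-local nt, 0-based) and `efficiency` in \[0,1\]: footprint rate
#'   downstream of `shift_pos` is `efficiency` times the upstream rate.
#' @param depth Reads per simulated library.
#' @param rendseq_end_enrichment Expected ratio of the 5'-end count at the
#'   transcription start site to the mean per-position body count.
#' @param pseudogene_fraction Fraction of genes carrying a pseudogene-like
#'   defect (internal stop, non-ATG start, or missing terminal stop).
#' @param minus_fraction Fraction of genes placed on the minus strand.
#' @param min_spacing Minimum intergenic spacing in nt.
#' @param contaminant_fraction Fraction of Ribo-seq reads emitted from the
#'   designated rRNA interval instead of genes.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 50L,
                       genome_length = NULL,
                       leader_model = list(fraction_leaderless = 0.6,
                                           leaderless_max = 3L,
                                           leadered_mean = 40,
                                           leadered_sd = 8,
                                           forbidden_range = c(4L, 14L)),
                       read_length_dist = default_read_length_dist(),
                       periodicity = c(0.8, 0.1, 0.1),
                       expression_dist = list(meanlog = 4, sdlog = 0.5),
                       fold_changes = numeric(0),
                       silhouette_perturbation = numeric(0),
                       frameshift_loci = NULL,
                       depth = 1e5,
                       rendseq_end_enrichment = 30,
                       pseudogene_fraction = 0.1,
                       minus_fraction = 0.4,
                       min_spacing = 150L,
                       contaminant_fraction = 0) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              genome_length = genome_length, leader_model = leader_model,
              read_length_dist = read_length_dist, periodicity = periodicity,
              expression_dist = expression_dist, fold_changes = fold_changes,
              silhouette_perturbation = silhouette_perturbation,
              frameshift_loci = frameshift_loci, depth = depth,
              rendseq_end_enrichment = rendseq_end_enrichment,
              pseudogene_fraction = pseudogene_fraction,
              minus_fraction = minus_fraction,
              min_spacing = as.integer(min_spacing),
              contaminant_fraction = contaminant_fraction)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$seed) == 1L, cfg$n_genes >= 1L)
  if (abs(sum(cfg$read_length_dist) - 1) > 1e-9)
    stop("read_length_dist must sum to 1 (within 1e-9)")
  if (length(cfg$periodicity) != 3L || abs(sum(cfg$periodicity) - 1) > 1e-9)
    stop("periodicity must be a length-3 probability vector summing to 1")
  if (any(cfg$read_length_dist < 0) || any(cfg$periodicity < 0))
    stop("probability vectors must be non-negative")
  lm <- cfg$leader_model
  if (lm$fraction_leaderless < 0 || lm$fraction_leaderless > 1)
    stop("fraction_leaderless must be in [0,1]")
  if (length(cfg$fold_changes) && any(cfg$fold_changes <= 0))
    stop("fold changes must be > 0")
  fs <- cfg$frameshift_loci
  if (!is.null(fs)) {
    stopifnot(is.data.frame(fs),
              all(c("gene", "shift_pos", "efficiency") %in% names(fs)))
    if (any(fs$efficiency < 0 | fs$efficiency > 1))
      stop("frameshift efficiency must be in [0,1]")
  }
  if (cfg$rendseq_end_enrichment < 1)
    stop("rendseq_end_enrichment must be >= 1")
  if (cfg$depth <= 0) stop("depth must be > 0")
  if (cfg$contaminant_fraction < 0 || cfg$contaminant_fraction >= 1)
    stop("contaminant_fraction must be in [0,1)")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat("  seed:", x$seed, "  genes:", x$n_genes,
      "  depth:", format(x$depth, scientific = FALSE), "\n")
  cat("  leaderless fraction:", x$leader_model$fraction_leaderless,
      "  forbidden leader range:",
      paste(x$leader_model$forbidden_range, collapse = "-"), "nt\n")
  cat("  periodicity:", paste(x$periodicity, collapse = "/"),
      "  Rend-seq end enrichment:", x$rendseq_end_enrichment, "\n")
  invisible(x)
}

#' Read or write a simulation configuration as YAML
#'
#' @param path File path.
#' @param cfg A `sim_config` object.
#' @return `read_sim_config` returns a `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$read_length_dist)) {
    w <- unlist(raw$read_length_dist)
    # YAML serialisation rounds doubles; restore exact normalisation
    if (abs(sum(w) - 1) < 1e-6) w <- w / sum(w)
    raw$read_length_dist <- w
  }
  if (!is.null(raw$periodicity) &&
      abs(sum(unlist(raw$periodicity)) - 1) < 1e-6)
    raw$periodicity <- unlist(raw$periodicity) /
      sum(unlist(raw$periodicity))
  if (!is.null(raw$fold_changes)) raw$fold_changes <- unlist(raw$fold_changes)
  if (!is.null(raw$silhouette_perturbation))
    raw$silhouette_perturbation <- unlist(raw$silhouette_perturbation)
  if (!is.null(raw$frameshift_loci))
    raw$frameshift_loci <- as.data.frame(do.call(rbind, lapply(
      raw$frameshift_loci, as.data.frame)))
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(cfg, path) {
  out <- unclass(cfg)
  # named atomic vectors must become YAML maps or their names are lost
  out$read_length_dist <- as.list(out$read_length_dist)
  if (length(out$fold_changes)) out$fold_changes <-
    as.list(out$fold_changes) else out$fold_changes <- NULL
  if (length(out$silhouette_perturbation)) out$silhouette_perturbation <-
    as.list(out$silhouette_perturbation) else
      out$silhouette_perturbation <- NULL
  if (!is.null(out$frameshift_loci))
    out$frameshift_loci <- lapply(seq_len(nrow(out$frameshift_loci)),
                                  function(i) as.list(out$frameshift_loci[i, ]))
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}
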