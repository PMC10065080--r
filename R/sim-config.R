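#' Synthetic rescue-assay study configuration
#'
#' Builds and validates the configuration of the synthetic data generator.
#' The defaults emulate the structure of a four-condition genetic-rescue
#' experiment: wild-type cells carrying an empty vector (`WT_empty`),
#' enhancer-knockout cells with an empty vector (`KO_empty`), and knockout
#' cells rescued with the wild-type factor (`KO_rescue`) or a pathogenic
#' variant (`KO_variant`), four biological replicates each. Per-gene
#' regulatory categories, negative-binomial counts, accessibility peaks
#' linked to genes, and random DNA with planted GATA/E-box/ETS/EBF motifs
#' are all driven by this one object.
#'
#' Category proportions default to the observed scale of the study system:
#' roughly 1,061 factor-activated and 1,077 factor-repressed genes out of
#' ~14,000, of which 144 and 381 are also variant-regulated, plus 414
#' ectopically variant-regulated genes (132 activated, 282 repressed) and a
#' block of enhancer-only genes. The remainder of the genome is unregulated.
#'
#' @param n_genes number of simulated genes.
#' @param n_replicates biological replicates per condition.
#' @param conditions ordered condition labels; the second is the reference.
#' @param category_proportions named fractions per regulatory category;
#'   must sum to at most 1 (the remainder is unregulated).
#' @param effect_size_lfc named log2 fold-change magnitudes per category
#'   (all non-negative).
#' @param retained_scale factor applied to the variant-contrast effect of
#'   shared (mutually regulated) genes, activated and repressed sides.
#' @param dispersion negative-binomial dispersion alpha (variance =
#'   mu + alpha * mu^2); 0 gives Poisson counts.
#' @param library_size_range range from which per-sample library sizes are
#'   drawn log-uniformly.
#' @param baseline_range range of per-gene baseline mean counts
#'   (log-uniform).
#' @param gene_length_range range of gene lengths in bp (for TPM).
#' @param peak_rate mean number of accessibility peaks per gene (Poisson).
#' @param peak_link_probabilities per expression class (`activated`,
#'   `repressed`, `none`), probabilities that a gene's chromatin opens or
#'   closes in a contrast where it is regulated.
#' @param peak_shift_lfc log2 magnitude of a designated accessibility shift.
#' @param peak_width_range peak width range in bp.
#' @param peak_window peaks are placed within this distance of their gene's
#'   TSS (bp).
#' @param peak_baseline_range per-peak baseline accessibility mean counts.
#' @param motif_densities named list: motif name -> list(consensus = IUPAC
#'   string, per_kb = named planted occurrences per kb for peak classes
#'   `activated`, `repressed`, `none`).
#' @param genome_size synthetic chromosome length in bp.
#' @param chrom synthetic chromosome name.
#' @param seed master integer seed; all stages draw from sub-streams derived
#'   from it, so adding a stage never changes earlier draws.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 14000L,
                       n_replicates = 4L,
                       conditions = c("WT_empty", "KO_empty",
                                      "KO_rescue", "KO_variant"),
                       category_proportions = c(
                         gata2_activated_only = 917 / 14000,
                         gata2_repressed_only = 696 / 14000,
                         shared_activated     = 144 / 14000,
                         shared_repressed     = 381 / 14000,
                         ectopic_activated    = 132 / 14000,
                         ectopic_repressed    = 282 / 14000,
                         enhancer_only        = 1100 / 14000),
                       effect_size_lfc = c(
                         gata2_activated_only = 2,
                         gata2_repressed_only = 2,
                         shared_activated     = 2,
                         shared_repressed     = 2,
                         ectopic_activated    = 2,
                         ectopic_repressed    = 2,
                         enhancer_only        = 2),
                       retained_scale = c(activated = 0.65,
                                          repressed = 0.56),
                       dispersion = 0.05,
                       library_size_range = c(5e5, 2e6),
                       baseline_range = c(1, 1000),
                       gene_length_range = c(500, 5000),
                       peak_rate = 1.5,
                       peak_link_probabilities = list(
                         activated = c(open = 0.35, close = 0.086),
                         repressed = c(open = 0.05, close = 0.40),
                         none      = c(open = 0.02, close = 0.02)),
                       peak_shift_lfc = 2,
                       peak_width_range = c(200, 600),
                       peak_window = 5e4,
                       peak_baseline_range = c(50, 500),
                       motif_densities = list(
                         GATA = list(consensus = "WGATAR",
                                     per_kb = c(activated = 1.5,
                                                repressed = 0.6,
                                                none = 0.4)),
                         EBOX = list(consensus = "CANNTG",
                                     per_kb = c(activated = 1.0,
                                                repressed = 1.0,
                                                none = 1.0)),
                         ETS = list(consensus = "AGGAAR",
                                    per_kb = c(activated = 0.4,
                                               repressed = 1.2,
                                               none = 0.5)),
                         EBF = list(consensus = "TCCCNNGGGA",
                                    per_kb = c(activated = 0.1,
                                               repressed = 0.1,
                                               none = 0.1))),
                       genome_size = 2e9,
                       chrom = "chrS",
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_replicates = as.integer(n_replicates),
    conditions = conditions,
    category_proportions = category_proportions,
    effect_size_lfc = effect_size_lfc,
    retained_scale = retained_scale,
    dispersion = dispersion,
    library_size_range = library_size_range,
    baseline_range = baseline_range,
    gene_length_range = gene_length_range,
    peak_rate = peak_rate,
    peak_link_probabilities = peak_link_probabilities,
    peak_shift_lfc = peak_shift_lfc,
    peak_width_range = peak_width_range,
    peak_window = peak_window,
    peak_baseline_range = peak_baseline_range,
    motif_densities = motif_densities,
    genome_size = genome_size,
    chrom = chrom,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @param config a `sim_config` object to validate.
#' @export
validate_sim_config <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_genes < 0L) stop("n_genes must be non-negative")
  if (config$n_replicates < 1L) stop("n_replicates must be positive")
  if (length(config$conditions) != 4L)
    stop("exactly four conditions are required")
  p <- config$category_proportions
  if (any(p < 0)) stop("category proportions must be non-negative")
  if (sum(p) > 1 + 1e-12)
    stop("category proportions sum to more than 1 (",
         signif(sum(p), 4), "); the remainder must be unregulated")
  missing_eff <- setdiff(names(p), names(config$effect_size_lfc))
  if (length(missing_eff))
    stop("effect_size_lfc missing for: ", paste(missing_eff, collapse = ", "))
  if (any(config$effect_size_lfc < 0))
    stop("effect sizes must be non-negative")
  if (config$dispersion < 0) stop("dispersion must be >= 0")
  stopifnot(length(config$library_size_range) == 2,
            all(config$library_size_range > 0),
            diff(config$library_size_range) >= 0)
  if (max(config$peak_width_range) > config$genome_size)
    stop("peak width exceeds genome size")
  if (config$genome_size < max(config$gene_length_range))
    stop("genome_size too small for the configured gene lengths")
  invisible(config)
}

# categories known to the generator, in a fixed order
sim_categories <- function() {
  c("gata2_activated_only", "gata2_repressed_only",
    "shared_activated", "shared_repressed",
    "ectopic_activated", "ectopic_repressed",
    "enhancer_only", "unregulated")
}
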