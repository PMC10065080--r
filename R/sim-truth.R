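#' Simulate per-gene ground truth for the rescue assay
#'
#' Assigns each gene a regulatory category and the true log2 fold changes of
#' the three study contrasts, all oriented as log2(condition / KO_empty):
#' `lfc_enh` for WT_empty vs KO_empty (the enhancer contrast), `lfc_rescue`
#' for KO_rescue vs KO_empty, and `lfc_variant` for KO_variant vs KO_empty.
#' Under this orientation a factor-activated gene has positive `lfc_rescue`.
#'
#' Category semantics: genes activated (repressed) by the factor carry the
#' effect in both the enhancer and rescue contrasts, because the wild-type
#' cells express the factor endogenously; shared genes additionally carry a
#' scaled effect (`retained_scale`) in the variant contrast; ectopic genes
#' carry an effect only in the variant contrast; enhancer-only genes differ
#' between WT and KO but respond to neither rescue construct (direction
#' drawn at random); unregulated genes have zero effect everywhere.
#'
#' @param config a [sim_config()] object.
#' @return object of class `sim_truth`: a list with `genes`, a data frame of
#'   gene_id, category, baseline (mean KO_empty count), lfc_enh,
#'   lfc_rescue, lfc_variant.
#' @export
simulate_truth <- function(config) {
  validate_sim_config(config)
  seeds <- stage_seeds(config$seed)
  set.seed(seeds[1])

  n <- config$n_genes
  gene_id <- sprintf("gene_%05d", seq_len(n))
  props <- config$category_proportions
  cats <- c(names(props), "unregulated")
  probs <- c(props, unregulated = 1 - sum(props))
  category <- if (n > 0) {
    sample(cats, n, replace = TRUE, prob = probs)
  } else character(0)

  eff <- config$effect_size_lfc
  e <- ifelse(category == "unregulated", 0, eff[category])
  lfc_enh <- lfc_rescue <- lfc_variant <- numeric(n)

  act <- category %in% c("gata2_activated_only", "shared_activated")
  rep_ <- category %in% c("gata2_repressed_only", "shared_repressed")
  lfc_enh[act] <- e[act];      lfc_rescue[act] <- e[act]
  lfc_enh[rep_] <- -e[rep_];   lfc_rescue[rep_] <- -e[rep_]
  sa <- category == "shared_activated"
  sr <- category == "shared_repressed"
  lfc_variant[sa] <- e[sa] * config$retained_scale[["activated"]]
  lfc_variant[sr] <- -e[sr] * config$retained_scale[["repressed"]]
  ea <- category == "ectopic_activated"
  er <- category == "ectopic_repressed"
  lfc_variant[ea] <- e[ea]
  lfc_variant[er] <- -e[er]
  eo <- category == "enhancer_only"
  if (any(eo)) {
    dir_eo <- sample(c(1, -1), sum(eo), replace = TRUE)
    lfc_enh[eo] <- dir_eo * e[eo]
  }

  lb <- log(config$baseline_range)
  baseline <- exp(stats::runif(n, lb[1], lb[2]))

  out <- list(genes = data.frame(
    gene_id = gene_id,
    category = category,
    baseline = baseline,
    lfc_enh = lfc_enh,
    lfc_rescue = lfc_rescue,
    lfc_variant = lfc_variant,
    stringsAsFactors = FALSE
  ))
  class(out) <- "sim_truth"
  out
}

#' Simulate a minimal gene annotation
#'
#' Places genes on a single synthetic chromosome with 0-based TSS
#' coordinates, random strands and lengths. Coordinates are 0-based
#' half-open throughout the package.
#'
#' @param config a [sim_config()] object.
#' @return data frame with gene_id, chrom, strand, tss, length.
#' @export
simulate_annotation <- function(config) {
  validate_sim_config(config)
  seeds <- stage_seeds(config$seed)
  set.seed(seeds[2])
  n <- config$n_genes
  len <- config$gene_length_range
  length_bp <- if (n > 0) {
    as.integer(round(stats::runif(n, len[1], len[2])))
  } else integer(0)
  tss_max <- config$genome_size - max(c(length_bp, 1L)) - 1L
  data.frame(
    gene_id = sprintf("gene_%05d", seq_len(n)),
    chrom = rep(config$chrom, n),
    strand = if (n > 0) sample(c("+", "-"), n, replace = TRUE) else character(0),
    tss = if (n > 0) floor(stats::runif(n, 0, tss_max)) else numeric(0),
    length = length_bp,
    stringsAsFactors = FALSE
  )
}
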