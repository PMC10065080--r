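#' Simulate a gene x sample count table
#'
#' Draws negative-binomial counts (variance mu + alpha * mu^2) for every
#' gene and sample. The expected count of gene g in condition c is
#' baseline_g * 2^lfc(g -> c) * s_j, where s_j is the sample's library-size
#' factor (library sizes drawn log-uniformly within
#' `config$library_size_range` and converted to factors with mean 1).
#' With `dispersion = 0` counts are Poisson.
#'
#' @param config a [sim_config()] object.
#' @param truth a [simulate_truth()] result.
#' @param annotation matching [simulate_annotation()] data frame (used to
#'   check gene agreement; lengths feed TPM downstream).
#' @return integer matrix genes x samples with a `sample_info` attribute
#'   (data frame sample, condition) and a `size_factor_truth` attribute.
#' @export
simulate_counts <- function(config, truth, annotation) {
  validate_sim_config(config)
  stopifnot(inherits(truth, "sim_truth"))
  if (!identical(truth$genes$gene_id, annotation$gene_id))
    stop("truth and annotation must cover the same genes in the same order")
  seeds <- stage_seeds(config$seed)
  set.seed(seeds[3])

  g <- truth$genes
  n <- nrow(g)
  conds <- config$conditions
  reps <- config$n_replicates
  if (n == 0L) {
    samples <- paste(rep(conds, each = reps), seq_len(reps), sep = "_")
    out <- matrix(0L, 0L, length(samples),
                  dimnames = list(character(0), samples))
    attr(out, "sample_info") <- data.frame(
      sample = samples, condition = rep(conds, each = reps),
      stringsAsFactors = FALSE)
    attr(out, "size_factor_truth") <- rep(1, length(samples))
    return(out)
  }
  samples <- paste(rep(conds, each = reps), seq_len(reps), sep = "_")
  condition <- rep(conds, each = reps)
  ns <- length(samples)

  lr <- log(config$library_size_range)
  lib <- exp(stats::runif(ns, lr[1], lr[2]))
  sf <- lib / mean(lib)

  # per-gene expected mean by condition, relative to KO_empty
  lfc_by_cond <- cbind(WT_empty = g$lfc_enh, KO_empty = 0,
                       KO_rescue = g$lfc_rescue, KO_variant = g$lfc_variant)
  colnames(lfc_by_cond) <- conds
  mu <- matrix(0, n, ns, dimnames = list(g$gene_id, samples))
  for (j in seq_len(ns)) {
    mu[, j] <- g$baseline * 2^lfc_by_cond[, condition[j]] * sf[j]
  }

  counts <- matrix(0L, n, ns, dimnames = dimnames(mu))
  if (n > 0) {
    if (config$dispersion > 0) {
      counts[] <- stats::rnbinom(length(mu), mu = mu,
                                 size = 1 / config$dispersion)
    } else {
      counts[] <- stats::rpois(length(mu), lambda = mu)
    }
  }
  attr(counts, "sample_info") <- data.frame(
    sample = samples, condition = condition, stringsAsFactors = FALSE)
  attr(counts, "size_factor_truth") <- sf
  counts
}
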