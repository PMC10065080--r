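#' Simulate accessibility peaks, counts and peak sequences
#'
#' Each gene receives a Poisson number of peaks placed within
#' `peak_window` bp of its TSS. For each contrast (rescue and variant) a
#' gene's chromatin is designated opening, closing or unchanged with
#' probabilities keyed on its expression class in that contrast
#' (`peak_link_probabilities`); a designated gene is guaranteed at least one
#' peak, and its first peak carries the true accessibility shift
#' (`peak_shift_lfc` log2 units, signed). Peak counts follow the same
#' negative-binomial model as the expression counts. Peak sequences are
#' uniform-random DNA with motifs planted at class-dependent densities
#' (`motif_densities`); every planted instance is recorded in the manifest.
#'
#' @param config a [sim_config()] object.
#' @param truth a [simulate_truth()] result.
#' @param annotation matching [simulate_annotation()] data frame.
#' @return list with elements `peaks` (data frame: peak_id, chrom, start,
#'   end, gene_id, class, shift_rescue, shift_variant, baseline), `counts`
#'   (peak x sample integer matrix with `sample_info` attribute),
#'   `sequences` (named character vector, one per peak) and `manifest`
#'   (data frame: seq_id, motif, start, strand, instance).
#' @export
simulate_peaks_and_sequences <- function(config, truth, annotation) {
  validate_sim_config(config)
  stopifnot(inherits(truth, "sim_truth"))
  if (!identical(truth$genes$gene_id, annotation$gene_id))
    stop("truth and annotation must cover the same genes in the same order")
  seeds <- stage_seeds(config$seed)
  set.seed(seeds[4])

  g <- truth$genes
  n <- nrow(g)
  expr_class <- function(lfc) {
    ifelse(lfc > 0, "activated", ifelse(lfc < 0, "repressed", "none"))
  }
  class_rescue <- expr_class(g$lfc_rescue)
  class_variant <- expr_class(g$lfc_variant)

  designate <- function(cls) {
    # exclusive open/close/none draw per gene and contrast
    p <- config$peak_link_probabilities
    u <- stats::runif(length(cls))
    po <- vapply(cls, function(k) p[[k]][["open"]], numeric(1))
    pc <- vapply(cls, function(k) p[[k]][["close"]], numeric(1))
    ifelse(u < po, "open", ifelse(u < po + pc, "close", "none"))
  }
  t_rescue <- designate(class_rescue)
  t_variant <- designate(class_variant)

  npk <- stats::rpois(n, config$peak_rate)
  needs_peak <- t_rescue != "none" | t_variant != "none"
  npk[needs_peak & npk == 0L] <- 1L

  gene_idx <- rep(seq_len(n), npk)
  np <- length(gene_idx)
  first_of_gene <- !duplicated(gene_idx)

  shift_sign <- function(t) ifelse(t == "open", 1, ifelse(t == "close", -1, 0))
  shift_rescue <- numeric(np)
  shift_variant <- numeric(np)
  shift_rescue[first_of_gene] <-
    shift_sign(t_rescue[gene_idx[first_of_gene]]) * config$peak_shift_lfc
  shift_variant[first_of_gene] <-
    shift_sign(t_variant[gene_idx[first_of_gene]]) * config$peak_shift_lfc

  w <- config$peak_width_range
  width <- as.integer(round(stats::runif(np, w[1], w[2])))
  center <- annotation$tss[gene_idx] +
    round(stats::runif(np, -config$peak_window, config$peak_window))
  start <- pmax(0, pmin(center - width %/% 2L,
                        config$genome_size - width))
  end <- start + width

  # motif-planting class follows the linked gene's strongest expression class
  pk_class <- class_rescue[gene_idx]
  pk_class[pk_class == "none"] <- class_variant[gene_idx][pk_class == "none"]

  peaks <- data.frame(
    peak_id = sprintf("peak_%06d", seq_len(np)),
    chrom = rep(config$chrom, np),
    start = start, end = end,
    gene_id = g$gene_id[gene_idx],
    class = pk_class,
    shift_rescue = shift_rescue,
    shift_variant = shift_variant,
    stringsAsFactors = FALSE
  )

  # --- peak counts (same NB model as expression) ---
  conds <- config$conditions
  reps <- config$n_replicates
  samples <- paste(rep(conds, each = reps), seq_len(reps), sep = "_")
  condition <- rep(conds, each = reps)
  ns <- length(samples)
  lr <- log(config$library_size_range)
  sf <- exp(stats::runif(ns, lr[1], lr[2]))
  sf <- sf / mean(sf)
  pb <- log(config$peak_baseline_range)
  baseline <- exp(stats::runif(np, pb[1], pb[2]))
  peaks$baseline <- baseline
  lfc_by_cond <- cbind(WT_empty = shift_rescue, KO_empty = 0,
                       KO_rescue = shift_rescue, KO_variant = shift_variant)
  colnames(lfc_by_cond) <- conds
  mu <- matrix(0, np, ns, dimnames = list(peaks$peak_id, samples))
  for (j in seq_len(ns)) {
    mu[, j] <- baseline * 2^lfc_by_cond[, condition[j]] * sf[j]
  }
  counts <- matrix(0L, np, ns, dimnames = dimnames(mu))
  if (np > 0) {
    if (config$dispersion > 0) {
      counts[] <- stats::rnbinom(length(mu), mu = mu,
                                 size = 1 / config$dispersion)
    } else {
      counts[] <- stats::rpois(length(mu), lambda = mu)
    }
  }
  attr(counts, "sample_info") <- data.frame(
    sample = samples, condition = condition, stringsAsFactors = FALSE)

  # --- sequences with planted motifs ---
  total <- sum(width)
  bases <- c("A", "C", "G", "T")
  big <- paste(sample(bases, total, replace = TRUE), collapse = "")
  ends_c <- cumsum(width)
  seqs <- substring(big, ends_c - width + 1L, ends_c)
  names(seqs) <- peaks$peak_id

  manifest <- list()
  for (mname in names(config$motif_densities)) {
    spec <- config$motif_densities[[mname]]
    mlen <- nchar(spec$consensus)
    dens <- spec$per_kb[pk_class]
    dens[is.na(dens)] <- 0
    n_plant <- stats::rpois(np, dens * width / 1000)
    n_plant[width < mlen] <- 0L
    idx <- rep(seq_len(np), n_plant)
    if (!length(idx)) next
    pos <- as.integer(floor(stats::runif(length(idx)) *
                              (width[idx] - mlen + 1L)))
    strand <- sample(c("+", "-"), length(idx), replace = TRUE)
    inst <- realize_iupac(spec$consensus, length(idx))
    planted <- ifelse(strand == "+", inst, reverse_complement(inst))
    for (k in seq_along(idx)) {
      i <- idx[k]
      substr(seqs[i], pos[k] + 1L, pos[k] + mlen) <- planted[k]
    }
    manifest[[mname]] <- data.frame(
      seq_id = peaks$peak_id[idx], motif = mname, start = pos,
      strand = strand, instance = inst, stringsAsFactors = FALSE)
  }
  manifest <- if (length(manifest)) {
    do.call(rbind, c(manifest, list(make.row.names = FALSE)))
  } else {
    data.frame(seq_id = character(0), motif = character(0),
               start = integer(0), strand = character(0),
               instance = character(0), stringsAsFactors = FALSE)
  }

  list(peaks = peaks, counts = counts, sequences = seqs, manifest = manifest)
}

# draw n concrete realizations of an IUPAC consensus
realize_iupac <- function(consensus, n) {
  codes <- strsplit(toupper(consensus), "")[[1]]
  cols <- lapply(codes, function(cd) {
    opts <- strsplit(iupac_bases(cd), "")[[1]]
    sample(opts, n, replace = TRUE)
  })
  do.call(paste0, cols)
}
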