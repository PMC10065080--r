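#' Pipeline configuration
#'
#' Bundles either a synthetic-data configuration or paths to real input
#' files with the analysis thresholds. Exactly one of `sim` and `paths`
#' must be provided.
#'
#' @param sim a [sim_config()] for synthetic mode.
#' @param paths named list of input files for real-data mode (counts,
#'   samples, annotation, peaks, peak_counts, peak_samples, sequences).
#' @param lfc_min DEG log2 fold-change threshold (inclusive).
#' @param alpha adjusted-p cutoff.
#' @param tpm_min expression filter threshold.
#' @param atac_lfc accessibility log2 fold-change threshold (strict).
#' @param promoter_upstream,promoter_downstream promoter window in bp.
#' @param max_link_dist optional peak-to-gene distance cap in bp.
#' @param out_dir optional output directory; intermediates are written
#'   under it when set.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, paths = NULL,
                            lfc_min = 1, alpha = 0.05, tpm_min = 1,
                            atac_lfc = 1,
                            promoter_upstream = 2000,
                            promoter_downstream = 100,
                            max_link_dist = 1e5,
                            out_dir = NULL) {
  if (is.null(sim) == is.null(paths))
    stop("provide exactly one of `sim` (synthetic mode) or `paths`")
  stopifnot(lfc_min > 0, alpha > 0, tpm_min >= 0, atac_lfc > 0)
  structure(list(sim = sim, paths = paths, lfc_min = lfc_min,
                 alpha = alpha, tpm_min = tpm_min, atac_lfc = atac_lfc,
                 promoter_upstream = promoter_upstream,
                 promoter_downstream = promoter_downstream,
                 max_link_dist = max_link_dist, out_dir = out_dir),
            class = "pipeline_config")
}

samples_of <- function(sample_info, condition) {
  sample_info$sample[sample_info$condition == condition]
}

# synthetic occupancy sets derived from the simulated peaks: the factor
# occupies peaks at its regulated genes (high probability) plus scattered
# background; the variant retains occupancy mostly at shared genes
simulate_occupancy <- function(config, truth, peak_sim,
                               occ_rate = 0.85, retain_shared = 0.8,
                               retain_other = 0.03) {
  seeds <- stage_seeds(config$seed)
  set.seed(seeds[5])
  pk <- peak_sim$peaks
  g <- truth$genes
  reg <- g$gene_id[g$lfc_rescue != 0]
  shared <- g$gene_id[g$lfc_rescue != 0 & g$lfc_variant != 0]
  at_reg <- pk$gene_id %in% reg
  factor_idx <- which(at_reg & stats::runif(nrow(pk)) < occ_rate)
  keep_p <- ifelse(pk$gene_id[factor_idx] %in% shared,
                   retain_shared, retain_other)
  variant_idx <- factor_idx[stats::runif(length(factor_idx)) < keep_p]
  list(factor = pk[factor_idx, , drop = FALSE],
       variant = pk[variant_idx, , drop = FALSE])
}

#' Validate pipeline inputs
#'
#' Checks a configuration (and, in real-data mode, the referenced files):
#' file formats, presence of all four conditions with at least two
#' replicates each, interval sanity (start < end, with the offending line
#' reported), and id concordance between the peak BED and the FASTA
#' (mismatches degrade to a warning and intersection mode). Returns a
#' report distinguishing warnings from fatal errors.
#'
#' @param config a [pipeline_config()].
#' @return list: `ok` (no fatal entries), `report` data frame (level,
#'   message).
#' @export
validate_inputs <- function(config) {
  entries <- list()
  note <- function(level, msg) {
    entries[[length(entries) + 1L]] <<- data.frame(
      level = level, message = msg, stringsAsFactors = FALSE)
  }
  if (!is.null(config$sim)) {
    tryCatch(validate_sim_config(config$sim),
             error = function(e) note("fatal", conditionMessage(e)))
  } else {
    p <- config$paths
    needed <- c("counts", "samples")
    for (nm in needed) {
      if (is.null(p[[nm]]) || !file.exists(p[[nm]]))
        note("fatal", paste0("missing input file: ", nm))
    }
    if (!length(entries)) {
      si <- read_samples_tsv(p$samples)
      conds <- c("WT_empty", "KO_empty", "KO_rescue", "KO_variant")
      missing <- setdiff(conds, si$condition)
      if (length(missing))
        note("fatal", paste0("missing condition: ",
                             paste(missing, collapse = ", ")))
      few <- names(which(table(si$condition) < 2))
      if (length(few))
        note("fatal", paste0("fewer than 2 replicates for: ",
                             paste(few, collapse = ", ")))
      counts <- read_counts_tsv(p$counts)
      if (!all(si$sample %in% colnames(counts)))
        note("fatal", "sample sheet and count columns disagree")
      if (!is.null(p$peaks) && file.exists(p$peaks)) {
        bed <- utils::read.delim(p$peaks, header = FALSE,
                                 stringsAsFactors = FALSE)
        bad <- which(bed[[2]] >= bed[[3]])
        if (length(bad))
          note("fatal", paste0("BED line ", bad[1],
                               ": start >= end"))
        if (!is.null(p$sequences) && file.exists(p$sequences)) {
          seqs <- read_sequences_fasta(p$sequences)
          ids <- bed[[4]]
          if (!all(ids %in% names(seqs)) || !all(names(seqs) %in% ids))
            note("warning",
                 "FASTA ids do not match peak ids; intersection used")
        }
      }
    }
  }
  report <- if (length(entries)) {
    do.call(rbind, entries)
  } else {
    data.frame(level = character(0), message = character(0))
  }
  list(ok = !any(report$level == "fatal"), report = report)
}

#' Run the full rescue-assay analysis pipeline
#'
#' Executes all stages in order on a synthetic dataset: simulation,
#' normalization and TPM, the three expression contrasts, DEG calling and
#' the regulatory catalog, summary fractions, robustness scans, retained
#' activity, differential accessibility with nearest-DEG linking and
#' transition proportions, promoter-window signal, motif statistics by
#' peak class, occupancy comparison, and (synthetic mode) a
#' truth-vs-inferred confusion table. Deterministic for a fixed
#' configuration seed. All numbers in the report come straight from the
#' module outputs; the report layer never recomputes.
#'
#' @param config a [pipeline_config()] (synthetic mode).
#' @return nested report list of class `pipeline_report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  v <- validate_inputs(config)
  if (!v$ok)
    stop("input validation failed: ",
         paste(v$report$message[v$report$level == "fatal"],
               collapse = "; "))
  if (is.null(config$sim))
    stop("real-data mode runs stage functions directly; run_pipeline ",
         "currently orchestrates synthetic mode")
  sim <- config$sim

  truth <- simulate_truth(sim)
  annotation <- simulate_annotation(sim)
  if (sim$n_genes == 0) {
    return(structure(list(empty = TRUE, n_genes = 0L),
                     class = "pipeline_report"))
  }
  counts <- simulate_counts(sim, truth, annotation)
  peak_sim <- simulate_peaks_and_sequences(sim, truth, annotation)
  si <- attr(counts, "sample_info")

  sf <- size_factors(counts, pseudo_reference = TRUE)
  tpm <- compute_tpm(counts, annotation$length)
  ko <- samples_of(si, "KO_empty")
  contrasts <- list(
    enh = nb_wald_contrast(counts, ko, samples_of(si, "WT_empty"),
                           size_factors = sf, tpm = tpm),
    rescue = nb_wald_contrast(counts, ko, samples_of(si, "KO_rescue"),
                              size_factors = sf, tpm = tpm),
    variant = nb_wald_contrast(counts, ko, samples_of(si, "KO_variant"),
                               size_factors = sf, tpm = tpm))

  degs <- lapply(contrasts, call_degs,
                 lfc_min = config$lfc_min, alpha = config$alpha)
  catalog <- build_catalog(degs$enh, degs$rescue, degs$variant,
                           universe = annotation$gene_id)
  cat_tab <- table(catalog$catalog$category)
  n_act <- sum(cat_tab[c("I.I", "I.II")], na.rm = TRUE)
  n_rep <- sum(cat_tab[c("II.I", "II.II")], na.rm = TRUE)
  fractions <- summarize_fractions(
    x = c(cat_tab["I.II"], cat_tab["II.II"],
          cat_tab["I.I"], cat_tab["II.I"]),
    n = c(n_act, n_rep, n_act, n_rep),
    label = c("activated_not_variant", "repressed_not_variant",
              "activated_shared", "repressed_shared"),
    digits = 1)

  rf <- rescue_fraction(contrasts$enh, contrasts$rescue)
  ra <- retained_activity(contrasts$rescue, contrasts$variant, tpm,
                          samples_rescue = samples_of(si, "KO_rescue"),
                          samples_empty = ko,
                          lfc_min = config$lfc_min,
                          min_tpm = config$tpm_min)
  scans <- list(
    ectopic = cutoff_robustness_scan(contrasts$rescue, contrasts$variant,
                                     lfc_min = config$lfc_min,
                                     mode = "ectopic"),
    impairment = cutoff_robustness_scan(contrasts$rescue,
                                        contrasts$variant,
                                        lfc_min = config$lfc_min,
                                        mode = "impairment"))

  # --- chromatin accessibility ---
  pk_counts <- peak_sim$counts
  pk_si <- attr(pk_counts, "sample_info")
  pk_sf <- size_factors(pk_counts, pseudo_reference = TRUE)
  pko <- samples_of(pk_si, "KO_empty")
  atac <- list(
    rescue = differential_peaks(pk_counts, pko,
                                samples_of(pk_si, "KO_rescue"),
                                size_factors = pk_sf,
                                lfc_thresh = config$atac_lfc,
                                alpha = config$alpha),
    variant = differential_peaks(pk_counts, pko,
                                 samples_of(pk_si, "KO_variant"),
                                 size_factors = pk_sf,
                                 lfc_thresh = config$atac_lfc,
                                 alpha = config$alpha))
  links <- link_to_nearest_deg(peak_sim$peaks, degs$rescue, annotation,
                               max_dist = config$max_link_dist)
  cohorts <- list(
    activated = degs$rescue$gene_id[degs$rescue$direction == "activated"],
    repressed = degs$rescue$gene_id[degs$rescue$direction == "repressed"])
  transitions <- classify_transitions(
    links, atac$rescue[, c("peak_id", "accessibility")], cohorts)

  prom <- promoter_signal(peak_sim$peaks, pk_counts, annotation,
                          size_factors = pk_sf,
                          upstream = config$promoter_upstream,
                          downstream = config$promoter_downstream)
  prom_change <- log2((rowMeans(prom[, samples_of(pk_si, "KO_rescue"),
                                     drop = FALSE]) + 0.5) /
                      (rowMeans(prom[, pko, drop = FALSE]) + 0.5))
  prom_tests <- lapply(cohorts, function(ids) {
    v <- prom_change[ids]
    v <- v[is.finite(v) & v != 0]
    if (length(v) >= 5) {
      rank_tests(v, kind = "rank_sum_vs_zero_shift")$p.value
    } else NA_real_
  })

  # --- motifs by inferred peak class ---
  linked_dir <- links$gene_id
  dir_map <- stats::setNames(degs$rescue$direction, degs$rescue$gene_id)
  pk_dir <- dir_map[linked_dir]
  is_diff <- atac$rescue$accessibility != "unchanged"
  seq_sets <- list(
    activated = peak_sim$sequences[which(pk_dir == "activated" & is_diff)],
    repressed = peak_sim$sequences[which(pk_dir == "repressed" & is_diff)])
  motif_stats <- if (all(lengths(seq_sets) >= 1)) {
    peak_set_motif_stats(seq_sets)
  } else NULL

  # --- occupancy ---
  occ <- simulate_occupancy(sim, truth, peak_sim)
  occ_overlap <- overlap_sets(occ$factor, occ$variant)
  occ_links_f <- link_occupancy_to_catalog(occ$factor, catalog, annotation,
                                           max_dist = config$max_link_dist)
  shared_f <- occ$factor[occ_overlap$a_hit, , drop = FALSE]
  occ_links_shared <- link_occupancy_to_catalog(shared_f, catalog,
                                                annotation,
                                                max_dist = config$max_link_dist)
  occ_loss <- occupancy_loss_summary(
    occ_links_f$counts[["activated"]],
    occ_links_shared$counts[["activated"]],
    occ_links_f$counts[["repressed"]],
    occ_links_shared$counts[["repressed"]])
  occ_seq_act <- peak_sim$sequences[occ$factor$peak_id[
    !is.na(occ_links_f$links$cohort) &
      occ_links_f$links$cohort == "activated"]]
  occ_seq_rep <- peak_sim$sequences[occ$factor$peak_id[
    !is.na(occ_links_f$links$cohort) &
      occ_links_f$links$cohort == "repressed"]]
  occ_wgatar <- if (length(occ_seq_act) && length(occ_seq_rep)) {
    wgatar_distribution_compare(occ_seq_act, occ_seq_rep)
  } else NULL

  # --- truth-vs-inferred confusion ---
  expected <- c(gata2_activated_only = "I.II", shared_activated = "I.I",
                gata2_repressed_only = "II.II", shared_repressed = "II.I",
                ectopic_activated = "III", ectopic_repressed = "IV",
                enhancer_only = "none", unregulated = "none")
  g <- truth$genes
  inferred <- catalog$catalog$category[
    match(g$gene_id, catalog$catalog$gene_id)]
  confusion <- table(truth = expected[g$category], inferred = inferred)
  lfcs <- abs(cbind(g$lfc_enh, g$lfc_rescue, g$lfc_variant))
  min_nonzero <- apply(lfcs, 1, function(r) {
    nz <- r[r > 0]
    if (length(nz)) min(nz) else Inf
  })
  strong <- g$baseline >= 50 & min_nonzero >= 1.5
  recovery <- list(
    overall_pct = 100 * mean(expected[g$category] == inferred),
    strong_pct = 100 * mean(expected[g$category][strong] ==
                              inferred[strong]),
    n_strong = sum(strong))

  report <- list(
    n_genes = sim$n_genes,
    size_factors = sf,
    contrasts = contrasts,
    degs = degs,
    deg_counts = vapply(degs, nrow, integer(1)),
    catalog = catalog,
    category_counts = cat_tab,
    fractions = fractions,
    rescue_fraction = rf,
    retained_activity = ra,
    robustness = scans,
    atac = atac,
    links = links,
    transitions = transitions,
    promoter_tests = prom_tests,
    motif_stats = motif_stats,
    occupancy = list(overlap = occ_overlap[c("shared_pairs", "a_shared",
                                             "a_only", "b_shared",
                                             "b_only")],
                     counts = occ_links_f$counts,
                     loss = occ_loss, wgatar = occ_wgatar),
    confusion = confusion,
    recovery = recovery)
  class(report) <- "pipeline_report"

  if (!is.null(config$out_dir)) write_report(report, config, truth,
                                             annotation, counts, peak_sim)
  report
}

# serialize report components under the configured output tree
write_report <- function(report, config, truth, annotation, counts,
                         peak_sim) {
  out <- config$out_dir
  for (d in c("contrasts", "catalog", "chromatin", "motifs", "occupancy",
              "report", "inputs")) {
    dir.create(file.path(out, d), recursive = TRUE, showWarnings = FALSE)
  }
  write_sim_dataset(config$sim, truth, annotation, counts, peak_sim,
                    file.path(out, "inputs"))
  for (nm in names(report$contrasts)) {
    utils::write.table(report$contrasts[[nm]],
                       file.path(out, "contrasts", paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(report$catalog$catalog,
                     file.path(out, "catalog", "catalog.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(report$robustness)) {
    utils::write.table(report$robustness[[nm]]$scan,
                       file.path(out, "catalog",
                                 paste0("robustness_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(report$links,
                     file.path(out, "chromatin", "peak_gene_links.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(
    deg_counts = as.list(report$deg_counts),
    category_counts = as.list(report$category_counts),
    recovery = report$recovery,
    occupancy_loss = report$occupancy$loss,
    transitions = report$transitions$proportions)
  jsonlite::write_json(summary, file.path(out, "report", "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out)
}

#' Digest of a pipeline report
#'
#' MD5 of the serialized report, for determinism checks (identical seed
#' and configuration must give identical digests).
#'
#' @param report a `pipeline_report`.
#' @return character MD5 digest.
#' @export
report_digest <- function(report) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(report, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}
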