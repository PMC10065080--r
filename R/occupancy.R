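#' Compare two occupancy peak sets by interval overlap
#'
#' Classifies peaks of two occupancy sets (e.g. wild-type factor vs
#' variant) by whether they overlap a peak of the other set by at least
#' `min_overlap` bp. The shared count is the number of overlapping pairs
#' and is therefore symmetric in the two sets.
#'
#' @param a,b data frames (chrom, start, end; 0-based half-open) or
#'   `GRanges`.
#' @param min_overlap minimum overlap in bp (default 1).
#' @return list: `shared_pairs`, `a_shared`, `a_only`, `b_shared`,
#'   `b_only` (counts) and logical vectors `a_hit`, `b_hit`.
#' @export
overlap_sets <- function(a, b, min_overlap = 1) {
  ga <- if (inherits(a, "GRanges")) a else df_to_granges(a)
  gb <- if (inherits(b, "GRanges")) b else df_to_granges(b)
  ov <- GenomicRanges::findOverlaps(ga, gb, minoverlap = min_overlap)
  a_hit <- seq_along(ga) %in% S4Vectors::queryHits(ov)
  b_hit <- seq_along(gb) %in% S4Vectors::subjectHits(ov)
  list(shared_pairs = length(ov),
       a_shared = sum(a_hit), a_only = sum(!a_hit),
       b_shared = sum(b_hit), b_only = sum(!b_hit),
       a_hit = a_hit, b_hit = b_hit)
}

#' Link occupancy peaks to regulatory-catalog cohorts
#'
#' Assigns each occupancy peak to the nearest factor-regulated gene of the
#' catalog (classes I.* activated and II.* repressed), reusing the
#' nearest-TSS linking of the chromatin module, and counts linked peaks
#' per cohort.
#'
#' @param peaks occupancy peak data frame (peak_id, chrom, start, end).
#' @param catalog a [build_catalog()] result.
#' @param annotation gene annotation (gene_id, chrom, strand, tss).
#' @param max_dist optional distance cap in bp.
#' @return list: `links` (per-peak assignment with cohort), `counts`
#'   (activated, repressed, unlinked).
#' @export
link_occupancy_to_catalog <- function(peaks, catalog, annotation,
                                      max_dist = NULL) {
  cat_df <- catalog$catalog
  act <- cat_df$gene_id[cat_df$category %in% c("I.I", "I.II")]
  rep_ <- cat_df$gene_id[cat_df$category %in% c("II.I", "II.II")]
  universe <- data.frame(gene_id = c(act, rep_), stringsAsFactors = FALSE)
  if (!nrow(universe)) {
    return(list(
      links = data.frame(peak_id = peaks$peak_id,
                         gene_id = NA_character_, cohort = NA_character_,
                         stringsAsFactors = FALSE),
      counts = c(activated = 0L, repressed = 0L,
                 unlinked = nrow(peaks))))
  }
  links <- link_to_nearest_deg(peaks, universe, annotation,
                               max_dist = max_dist)
  cohort <- ifelse(is.na(links$gene_id), NA_character_,
                   ifelse(links$gene_id %in% act, "activated", "repressed"))
  links$cohort <- cohort
  list(links = links,
       counts = c(activated = sum(cohort == "activated", na.rm = TRUE),
                  repressed = sum(cohort == "repressed", na.rm = TRUE),
                  unlinked = sum(is.na(cohort))))
}

#' Occupancy-loss percentages and fold-ratio
#'
#' Operationalizes "reduced occupancy" as factor-occupied loci with no
#' overlapping variant peak: loss = 100 * (factor - shared) / factor per
#' cohort, rounded half-up at the printed precision, plus the activated
#' vs repressed fold-ratio of factor peak counts (1 decimal).
#'
#' @param factor_activated,shared_activated factor peak count and shared
#'   (factor-and-variant) peak count at activated loci.
#' @param factor_repressed,shared_repressed the same at repressed loci.
#' @param digits decimals for the loss percentages.
#' @return list: `loss` data frame (cohort, factor, shared, lost,
#'   loss_percent) and `fold_activated_vs_repressed`.
#' @export
occupancy_loss_summary <- function(factor_activated, shared_activated,
                                   factor_repressed, shared_repressed,
                                   digits = 0) {
  loss <- data.frame(
    cohort = c("activated", "repressed"),
    factor = c(factor_activated, factor_repressed),
    shared = c(shared_activated, shared_repressed),
    stringsAsFactors = FALSE)
  loss$lost <- loss$factor - loss$shared
  loss$loss_percent <- percent_of(loss$lost, loss$factor, digits)
  list(loss = loss,
       fold_activated_vs_repressed = fold_ratio(factor_activated,
                                                factor_repressed))
}

#' Compare WGATAR distributions between occupancy cohorts
#'
#' Fraction of peaks carrying at least one WGATAR (or other consensus)
#' per cohort, compared with the two-proportion continuity-corrected
#' test.
#'
#' @param seqs_activated,seqs_repressed character vectors of peak
#'   sequences for the two cohorts (both non-empty).
#' @param consensus IUPAC consensus to scan (default "WGATAR").
#' @return list: per-cohort n, n_with_motif and fraction, plus the
#'   proportion-test statistic and p-value.
#' @export
wgatar_distribution_compare <- function(seqs_activated, seqs_repressed,
                                        consensus = "WGATAR") {
  if (!length(seqs_activated) || !length(seqs_repressed))
    stop("both cohorts must contain at least one sequence")
  hit <- function(seqs) {
    vapply(seqs, function(s) nrow(scan_iupac(s, consensus)) > 0, logical(1))
  }
  ha <- hit(seqs_activated); hr <- hit(seqs_repressed)
  pt <- proportion_test(sum(ha), length(ha), sum(hr), length(hr))
  list(activated = list(n = length(ha), n_with_motif = sum(ha),
                        fraction = mean(ha)),
       repressed = list(n = length(hr), n_with_motif = sum(hr),
                        fraction = mean(hr)),
       statistic = pt$statistic, p.value = pt$p.value)
}
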