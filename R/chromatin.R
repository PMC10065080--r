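#' Differential accessibility peaks
#'
#' Runs the negative-binomial Wald engine on a peak x sample count table
#' and classifies every peak as `opening` (log2FC > `lfc_thresh`, strictly,
#' and adjusted p < `alpha`), `closing` (log2FC < -`lfc_thresh`) or
#' `unchanged`. The strict inequality on the fold change follows the
#' accessibility analysis convention (|log2FC| > 1), in contrast to the
#' inclusive expression DEG threshold.
#'
#' @param peak_counts peak x sample count matrix (rownames = peak ids).
#' @param samples_A,samples_B the two groups' columns (>= 2 replicates).
#' @param size_factors optional per-sample factors.
#' @param lfc_thresh strict log2 fold-change threshold (default 1).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @return [nb_wald_contrast()] data frame with `peak_id` and an
#'   `accessibility` class column.
#' @export
differential_peaks <- function(peak_counts, samples_A, samples_B,
                               size_factors = NULL,
                               lfc_thresh = 1, alpha = 0.05) {
  res <- nb_wald_contrast(peak_counts, samples_A, samples_B,
                          size_factors = size_factors)
  names(res)[names(res) == "gene_id"] <- "peak_id"
  sig <- !is.na(res$padj) & res$padj < alpha
  res$accessibility <- ifelse(sig & res$log2fc > lfc_thresh, "opening",
                       ifelse(sig & res$log2fc < -lfc_thresh, "closing",
                              "unchanged"))
  res
}

#' Link peaks to the nearest differentially expressed gene
#'
#' Assigns each peak to the DEG whose TSS is closest to the peak midpoint
#' on the same chromosome. Ties are broken deterministically toward the
#' lexicographically smaller gene id. Peaks farther than `max_dist` (when
#' set) or on chromosomes without any DEG remain unlinked (`NA` gene).
#' The reported distance is strand-aware: positive when the peak midpoint
#' lies downstream of the TSS in the gene's orientation.
#'
#' @param peaks data frame with peak_id, chrom, start, end (0-based
#'   half-open).
#' @param degs a [call_degs()] data frame (or any data frame with a
#'   gene_id column) restricting the candidate genes.
#' @param annotation gene annotation (gene_id, chrom, strand, tss).
#' @param max_dist optional cap on |midpoint - TSS| in bp.
#' @return data frame: peak_id, gene_id, distance (signed, bp),
#'   abs_distance, link_rule.
#' @export
link_to_nearest_deg <- function(peaks, degs, annotation, max_dist = NULL) {
  cand <- annotation[annotation$gene_id %in% degs$gene_id, , drop = FALSE]
  mid <- floor((peaks$start + peaks$end) / 2)
  gene_id <- rep(NA_character_, nrow(peaks))
  dist_signed <- rep(NA_real_, nrow(peaks))
  rule <- rep("no_deg_on_chrom", nrow(peaks))

  for (ch in unique(peaks$chrom)) {
    pk_i <- which(peaks$chrom == ch)
    g <- cand[cand$chrom == ch, , drop = FALSE]
    if (!nrow(g)) next
    # sort genes by (tss, gene_id) so equal-TSS ties resolve by id
    g <- g[order(g$tss, g$gene_id), , drop = FALSE]
    pos <- g$tss
    idx <- findInterval(mid[pk_i], pos)
    for (k in seq_along(pk_i)) {
      i <- pk_i[k]
      lo <- idx[k]; hi <- lo + 1L
      cand_j <- c(lo, hi)
      cand_j <- cand_j[cand_j >= 1 & cand_j <= nrow(g)]
      bestd <- min(abs(mid[i] - pos[cand_j]))
      # all genes at the winning distance (TSS at mid - d or mid + d, any
      # of which may be duplicated); tie-break to the smallest gene id
      ties <- which(pos == mid[i] - bestd | pos == mid[i] + bestd)
      best <- ties[order(g$gene_id[ties])[1]]
      if (!is.null(max_dist) && bestd > max_dist) {
        rule[i] <- "beyond_max_dist"
      } else {
        gene_id[i] <- g$gene_id[best]
        raw <- mid[i] - pos[best]
        dist_signed[i] <- if (g$strand[best] == "-") -raw else raw
        rule[i] <- "nearest_tss"
      }
    }
  }
  data.frame(peak_id = peaks$peak_id, gene_id = gene_id,
             distance = dist_signed, abs_distance = abs(dist_signed),
             link_rule = rule, stringsAsFactors = FALSE)
}

#' Classify per-gene chromatin transitions
#'
#' A gene is labeled `opening` if at least one linked peak is opening and
#' `closing` if at least one linked peak is closing; a gene with both
#' kinds of peaks counts in both proportions (the cohort proportions are
#' reported independently and need not partition). Cohort proportions
#' use the supplied gene sets as denominators; an empty cohort reports
#' undefined (`NA`) proportions.
#'
#' @param links a [link_to_nearest_deg()] table.
#' @param peak_classes data frame peak_id, accessibility (from
#'   [differential_peaks()]).
#' @param cohorts named list of gene-id vectors (e.g. activated,
#'   repressed).
#' @return list: `genes` (gene_id, opening, closing), `proportions`
#'   (cohort, n, n_opening, n_closing, pct_opening, pct_closing).
#' @export
classify_transitions <- function(links, peak_classes, cohorts) {
  m <- merge(links[!is.na(links$gene_id), c("peak_id", "gene_id")],
             peak_classes[, c("peak_id", "accessibility")], by = "peak_id")
  if (nrow(m)) {
    opening <- tapply(m$accessibility == "opening", m$gene_id, any)
    closing <- tapply(m$accessibility == "closing", m$gene_id, any)
    gene_tab <- data.frame(gene_id = names(opening),
                           opening = as.logical(opening),
                           closing = as.logical(closing[names(opening)]),
                           stringsAsFactors = FALSE, row.names = NULL)
  } else {
    gene_tab <- data.frame(gene_id = character(0), opening = logical(0),
                           closing = logical(0), stringsAsFactors = FALSE)
  }
  props <- do.call(rbind, lapply(names(cohorts), function(nm) {
    ids <- cohorts[[nm]]
    n <- length(ids)
    no <- sum(gene_tab$opening[gene_tab$gene_id %in% ids])
    nc <- sum(gene_tab$closing[gene_tab$gene_id %in% ids])
    data.frame(cohort = nm, n = n, n_opening = no, n_closing = nc,
               pct_opening = if (n > 0) 100 * no / n else NA_real_,
               pct_closing = if (n > 0) 100 * nc / n else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(genes = gene_tab, proportions = props)
}

#' Two-sample test for equality of proportions
#'
#' Classical pooled-variance chi-square test (1 df) with optional Yates
#' continuity correction, as used for cohort comparisons.
#'
#' @param x1,n1,x2,n2 successes and totals of the two samples.
#' @param continuity apply the continuity correction (default `TRUE`).
#' @return list: statistic (chi-square), p.value, estimate (the two
#'   proportions).
#' @export
proportion_test <- function(x1, n1, x2, n2, continuity = TRUE) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  ht <- suppressWarnings(
    stats::prop.test(c(x1, x2), c(n1, n2), correct = continuity))
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       estimate = unname(ht$estimate))
}

#' Wilcoxon / Mann-Whitney rank tests
#'
#' Dispatches the three rank statistics used in the analysis:
#' `rank_sum_vs_zero_shift` (one-sample Wilcoxon signed rank of `x`
#' against a zero shift), `signed_rank_paired` (paired signed rank of
#' `x` vs `y`) and `mann_whitney_two_sample` (two-sample rank sum).
#' Small samples without ties use the exact distribution; otherwise the
#' normal approximation with continuity and tie correction applies.
#' All-zero paired differences return p = 1 with a warning.
#'
#' @param x numeric values (or first sample / paired member).
#' @param y second sample or paired member, where applicable.
#' @param kind which statistic to compute.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @param exact force exact (`TRUE`) or asymptotic (`FALSE`) mode;
#'   `NULL` chooses exact for n <= 25 without ties.
#' @return list: statistic, p.value, method.
#' @export
rank_tests <- function(x, y = NULL,
                       kind = c("mann_whitney_two_sample",
                                "signed_rank_paired",
                                "rank_sum_vs_zero_shift"),
                       alternative = "two.sided", exact = NULL) {
  kind <- match.arg(kind)
  if (kind == "rank_sum_vs_zero_shift") {
    d <- x
  } else if (kind == "signed_rank_paired") {
    stopifnot(length(x) == length(y))
    d <- x - y
  }
  if (kind != "mann_whitney_two_sample") {
    if (all(d == 0)) {
      warning("all paired differences are zero; p = 1")
      return(list(statistic = 0, p.value = 1,
                  method = "wilcoxon_signed_rank"))
    }
    if (is.null(exact)) exact <- sum(d != 0) <= 25 && !any(duplicated(abs(d[d != 0])))
    ht <- suppressWarnings(stats::wilcox.test(
      d, mu = 0, alternative = alternative, exact = exact, correct = TRUE))
    return(list(statistic = unname(ht$statistic), p.value = ht$p.value,
                method = "wilcoxon_signed_rank"))
  }
  if (is.null(exact)) {
    exact <- max(length(x), length(y)) <= 25 && !any(duplicated(c(x, y)))
  }
  ht <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = alternative, exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       method = "mann_whitney")
}

#' Aggregate accessibility signal in promoter windows
#'
#' Sums size-factor-normalized peak counts over peaks overlapping each
#' gene's strand-oriented promoter window, by default 2 kb upstream to
#' 100 bp downstream of the TSS: a plus-strand gene with TSS t gets the
#' half-open window \[t - upstream, t + downstream), a minus-strand gene
#' \[t - downstream, t + upstream). Genes without overlapping peaks
#' report zero signal.
#'
#' @param peaks peak table (peak_id, chrom, start, end).
#' @param peak_counts peak x sample count matrix.
#' @param annotation gene annotation (gene_id, chrom, strand, tss).
#' @param size_factors optional per-sample normalization factors.
#' @param upstream,downstream window extents in bp.
#' @return gene x sample matrix of summed normalized counts.
#' @export
promoter_signal <- function(peaks, peak_counts, annotation,
                            size_factors = NULL,
                            upstream = 2000, downstream = 100) {
  if (is.null(size_factors)) {
    size_factors <- size_factors(peak_counts, pseudo_reference = TRUE)
  }
  norm <- t(t(as.matrix(peak_counts)) / size_factors)
  win_start <- ifelse(annotation$strand == "-",
                      annotation$tss - downstream,
                      annotation$tss - upstream)
  win_end <- ifelse(annotation$strand == "-",
                    annotation$tss + upstream,
                    annotation$tss + downstream)
  out <- matrix(0, nrow(annotation), ncol(norm),
                dimnames = list(annotation$gene_id, colnames(norm)))
  win <- GenomicRanges::GRanges(
    annotation$chrom,
    IRanges::IRanges(start = win_start + 1L, end = win_end))
  pk <- df_to_granges(peaks)
  ov <- GenomicRanges::findOverlaps(win, pk)
  if (length(ov)) {
    qi <- S4Vectors::queryHits(ov)
    si <- S4Vectors::subjectHits(ov)
    rows <- match(peaks$peak_id[si], rownames(norm))
    for (j in seq_len(ncol(norm))) {
      sums <- tapply(norm[rows, j], qi, sum)
      out[as.integer(names(sums)), j] <- sums
    }
  }
  out
}
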