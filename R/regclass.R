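#' Build the regulatory catalog from three DEG sets
#'
#' Combines the enhancer, rescue and variant contrast DEG calls into the
#' per-gene category scheme: I (factor-activated, split into I.I also
#' variant-activated and I.II only factor-activated), II
#' (factor-repressed, split into II.I and II.II analogously), III
#' (ectopically activated: variant-activated but not factor-activated)
#' and IV (ectopically repressed). Genes in none of the rescue/variant
#' sets are labeled `none`. A gene regulated in opposite directions by
#' the rescue and variant contrasts keeps its per-contrast directions and
#' is flagged in the discordance report rather than force-resolved.
#'
#' @param deg_enh,deg_rescue,deg_variant [call_degs()] results for the
#'   enhancer, rescue and variant contrasts.
#' @param universe optional character vector of all tested genes; defaults
#'   to the union of the three sets.
#' @return list of class `regulatory_catalog`: `catalog` (data frame
#'   gene_id, enh_dir, rescue_dir, variant_dir, category, venn_region,
#'   discordant), `venn` (activated- and repressed-side region counts) and
#'   `discordant` (the flagged subset).
#' @export
build_catalog <- function(deg_enh, deg_rescue, deg_variant,
                          universe = NULL) {
  dir_of <- function(degs, genes) {
    d <- rep("none", length(genes))
    m <- match(genes, degs$gene_id)
    d[!is.na(m)] <- degs$direction[m[!is.na(m)]]
    d
  }
  if (is.null(universe)) {
    universe <- sort(unique(c(deg_enh$gene_id, deg_rescue$gene_id,
                              deg_variant$gene_id)))
  }
  enh <- dir_of(deg_enh, universe)
  res <- dir_of(deg_rescue, universe)
  var <- dir_of(deg_variant, universe)

  category <- rep("none", length(universe))
  category[res == "activated" & var == "activated"] <- "I.I"
  category[res == "activated" & var != "activated"] <- "I.II"
  category[res == "repressed" & var == "repressed"] <- "II.I"
  category[res == "repressed" & var != "repressed"] <- "II.II"
  category[res == "none" & var == "activated"] <- "III"
  category[res == "none" & var == "repressed"] <- "IV"
  discordant <- res != "none" & var != "none" & res != var

  venn_label <- function(dirs, side) {
    members <- c("enh", "rescue", "variant")[dirs == side]
    if (!length(members)) "" else paste(members, collapse = "+")
  }
  venn_region <- vapply(seq_along(universe), function(i) {
    act <- venn_label(c(enh[i], res[i], var[i]), "activated")
    rep_ <- venn_label(c(enh[i], res[i], var[i]), "repressed")
    paste0(ifelse(nzchar(act), paste0("act:", act), ""),
           ifelse(nzchar(act) && nzchar(rep_), ";", ""),
           ifelse(nzchar(rep_), paste0("rep:", rep_), ""))
  }, character(1))

  catalog <- data.frame(
    gene_id = universe, enh_dir = enh, rescue_dir = res,
    variant_dir = var, category = category,
    venn_region = venn_region, discordant = discordant,
    stringsAsFactors = FALSE
  )
  venn_counts <- function(side) {
    lab <- vapply(seq_along(universe), function(i) {
      venn_label(c(enh[i], res[i], var[i]), side)
    }, character(1))
    table(lab[nzchar(lab)])
  }
  out <- list(catalog = catalog,
              venn = list(activated = venn_counts("activated"),
                          repressed = venn_counts("repressed")),
              discordant = catalog[discordant, , drop = FALSE])
  class(out) <- "regulatory_catalog"
  out
}

#' Summary percentages and fold-ratios from class counts
#'
#' Reports 100 * x / n rounded half-up at the printed precision for each
#' labeled count pair; a zero denominator yields an undefined (`NA`)
#' entry, never 0.
#'
#' @param x numerator count(s).
#' @param n denominator count(s).
#' @param label optional labels for the rows.
#' @param digits decimals to keep (0 = integer percentages).
#' @return data frame: label, x, n, percent.
#' @export
summarize_fractions <- function(x, n, label = NULL, digits = 0) {
  stopifnot(length(x) == length(n), all(x >= 0), all(n >= 0))
  if (is.null(label)) label <- paste0("frac_", seq_along(x))
  data.frame(label = label, x = x, n = n,
             percent = percent_of(x, n, digits),
             stringsAsFactors = FALSE)
}

#' Fraction of endogenously regulated genes rescued by the factor
#'
#' Among genes whose enhancer contrast shows any expression change
#' (|log2FC| > 0) in a given direction, the fraction whose rescue
#' contrast changes in the sign-concordant direction with |log2FC| > 0.
#' No significance cutoff is applied on either side.
#'
#' @param contrast_enh,contrast_rescue [nb_wald_contrast()] results on the
#'   same genes (enhancer contrast oriented WT vs KO, rescue contrast
#'   rescue vs KO, so positive log2FC = activated by the factor).
#' @param digits decimals for the formatted percentage (default 0,
#'   integer percentages).
#' @return list with `activated` and `repressed`, each holding x, n,
#'   fraction and percent.
#' @export
rescue_fraction <- function(contrast_enh, contrast_rescue, digits = 0) {
  stopifnot(identical(contrast_enh$gene_id, contrast_rescue$gene_id))
  le <- contrast_enh$log2fc
  lr <- contrast_rescue$log2fc
  side <- function(sgn) {
    in_side <- is.finite(le) & sign(le) == sgn & abs(le) > 0
    n <- sum(in_side)
    x <- sum(in_side & is.finite(lr) & sign(lr) == sgn & abs(lr) > 0)
    list(x = x, n = n,
         fraction = if (n > 0) x / n else NA_real_,
         percent = percent_of(x, n, digits))
  }
  list(activated = side(1), repressed = side(-1))
}

#' Retained activity of the variant relative to the factor
#'
#' For genes regulated by both the rescue and the variant construct in
#' the same direction (|log2FC| >= `lfc_min` in both contrasts by
#' default, or rescue only with `require_both = FALSE`), computes the
#' variant's effect as a percentage of the factor's. The default scale is
#' the log2 fold-change ratio (100 * log2FC_variant / log2FC_rescue);
#' `scale = "linear"` uses the linear fold effects
#' 100 * (2^|lfc_v| - 1) / (2^|lfc_r| - 1) instead. Expression filtering
#' follows the study design: activation requires TPM >= `min_tpm` in all
#' replicates of the rescue condition, repression in all replicates of
#' the empty (knockout) condition.
#'
#' @param contrast_rescue,contrast_variant [nb_wald_contrast()] results on
#'   the same genes.
#' @param tpm TPM matrix (genes x samples, rownames = gene ids).
#' @param samples_rescue,samples_empty columns of `tpm` holding the rescue
#'   and knockout-empty replicates.
#' @param lfc_min magnitude threshold applied to the contrasts.
#' @param min_tpm TPM floor applied to every required replicate.
#' @param require_both require |log2FC| >= lfc_min in both contrasts
#'   (`TRUE`) or in the rescue contrast only (`FALSE`).
#' @param scale `"log"` (default) or `"linear"`.
#' @return list: `genes` (per-gene table with direction and retained
#'   percentage), `summary` (counts and median retained percentage per
#'   direction), `n_filtered_tpm` (genes dropped by the TPM filter).
#' @export
retained_activity <- function(contrast_rescue, contrast_variant, tpm,
                              samples_rescue, samples_empty,
                              lfc_min = 1, min_tpm = 1,
                              require_both = TRUE,
                              scale = c("log", "linear")) {
  scale <- match.arg(scale)
  stopifnot(identical(contrast_rescue$gene_id, contrast_variant$gene_id))
  lr <- contrast_rescue$log2fc
  lv <- contrast_variant$log2fc
  gid <- contrast_rescue$gene_id

  concordant <- sign(lr) == sign(lv) & lr != 0
  pass_lfc <- abs(lr) >= lfc_min &
    (if (require_both) abs(lv) >= lfc_min else TRUE)
  direction <- ifelse(lr > 0, "activated", "repressed")

  tpm_ok <- rep(TRUE, length(gid))
  m <- match(gid, rownames(tpm))
  has_tpm <- !is.na(m)
  act <- direction == "activated"
  tpm_ok[act & has_tpm] <- apply(
    tpm[m[act & has_tpm], samples_rescue, drop = FALSE] >= min_tpm, 1, all)
  tpm_ok[!act & has_tpm] <- apply(
    tpm[m[!act & has_tpm], samples_empty, drop = FALSE] >= min_tpm, 1, all)

  eligible <- concordant & pass_lfc
  n_filtered <- sum(eligible & !tpm_ok)
  keep <- eligible & tpm_ok

  retained <- if (scale == "log") {
    100 * lv / lr
  } else {
    100 * sign(lv) * (2^abs(lv) - 1) / (2^abs(lr) - 1) * sign(lr)
  }
  genes <- data.frame(
    gene_id = gid[keep], direction = direction[keep],
    log2fc_rescue = lr[keep], log2fc_variant = lv[keep],
    retained_percent = retained[keep], stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(c("activated", "repressed"), function(d) {
    v <- genes$retained_percent[genes$direction == d]
    data.frame(direction = d, n = length(v),
               median_retained = if (length(v)) stats::median(v) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(genes = genes, summary = summ, n_filtered_tpm = n_filtered)
}

#' Robustness of set differences to the adjusted-p cutoff
#'
#' Re-calls DEG sets (|log2FC| >= `lfc_min`, adjusted p < cutoff) at each
#' cutoff and reports, per direction, the percentage of one set not in
#' the other: mode `"ectopic"` measures variant-regulated genes that are
#' not rescue-regulated; mode `"impairment"` measures rescue-regulated
#' genes that are not variant-regulated. The activated and repressed
#' percentage series are compared with a two-sided Mann-Whitney U test.
#'
#' @param contrast_rescue,contrast_variant [nb_wald_contrast()] results on
#'   a shared gene universe.
#' @param cutoffs adjusted-p cutoffs (>= 2 values; default ten values
#'   0.01, 0.02, ..., 0.10).
#' @param lfc_min magnitude threshold for the DEG calls.
#' @param mode `"ectopic"` or `"impairment"`.
#' @return list of class `robustness_scan`: `scan` (data frame cutoff,
#'   pct_activated, pct_repressed, with the underlying counts) and
#'   `mann_whitney_p`.
#' @export
cutoff_robustness_scan <- function(contrast_rescue, contrast_variant,
                                   cutoffs = seq(0.01, 0.10, by = 0.01),
                                   lfc_min = 1,
                                   mode = c("ectopic", "impairment")) {
  mode <- match.arg(mode)
  if (length(cutoffs) < 2) stop("at least two cutoffs are required")
  rows <- lapply(cutoffs, function(a) {
    dr <- call_degs(contrast_rescue, lfc_min = lfc_min, alpha = a)
    dv <- call_degs(contrast_variant, lfc_min = lfc_min, alpha = a)
    one <- function(dirn) {
      r <- dr$gene_id[dr$direction == dirn]
      v <- dv$gene_id[dv$direction == dirn]
      if (mode == "ectopic") {
        n <- length(v); x <- length(setdiff(v, r))
      } else {
        n <- length(r); x <- length(setdiff(r, v))
      }
      c(x = x, n = n,
        pct = if (n > 0) 100 * x / n else NA_real_)
    }
    a_ <- one("activated"); r_ <- one("repressed")
    data.frame(cutoff = a,
               x_activated = a_[["x"]], n_activated = a_[["n"]],
               pct_activated = a_[["pct"]],
               x_repressed = r_[["x"]], n_repressed = r_[["n"]],
               pct_repressed = r_[["pct"]])
  })
  scan <- do.call(rbind, rows)
  pa <- scan$pct_activated[is.finite(scan$pct_activated)]
  pr <- scan$pct_repressed[is.finite(scan$pct_repressed)]
  mw_p <- if (length(pa) && length(pr) &&
              length(unique(c(pa, pr))) > 1) {
    rank_tests(pa, pr, kind = "mann_whitney_two_sample")$p.value
  } else NA_real_  # degenerate series carry no rank information
  out <- list(scan = scan, mode = mode, mann_whitney_p = mw_p)
  class(out) <- "robustness_scan"
  out
}

#' Percent of maximal regulation for rescue variants
#'
#' Expresses a variant's effect on one gene as a percentage of the
#' dynamic range defined by the empty-vector (0%) and full-rescue (100%)
#' conditions: 100 * (v - empty) / (full - empty). The same formula
#' serves activation and repression (for repression both numerator and
#' denominator flip sign). Values outside \[0, 100\] are possible. A gene
#' with zero dynamic range is undefined and returned as `NA` with a
#' warning. Classification at the 50% line counts exactly 50% as
#' retained (>= 50).
#'
#' @param empty,full,v numeric expression values (empty vector,
#'   full rescue, variant), recycled to a common length.
#' @return data frame: percent, retained_at_50.
#' @export
percent_max_regulation <- function(empty, full, v) {
  k <- max(length(empty), length(full), length(v))
  empty <- rep_len(empty, k); full <- rep_len(full, k); v <- rep_len(v, k)
  rng <- full - empty
  pct <- ifelse(rng != 0, 100 * (v - empty) / rng, NA_real_)
  if (any(rng == 0))
    warning(sum(rng == 0), " gene(s) with zero dynamic range excluded")
  data.frame(percent = pct, retained_at_50 = !is.na(pct) & pct >= 50)
}

#' Row z-scores of log10(FPKM + 1e-3)
#'
#' Standardizes each gene's expression across all samples on the
#' log10(FPKM + 1e-3) scale using the population standard deviation, the
#' transform used for expression heatmaps. Zero-variance rows become
#' all-zero and are flagged in the `flat_rows` attribute.
#'
#' @param fpkm non-negative FPKM matrix (genes x samples).
#' @return matrix of z-scores with per-row mean 0 and population SD 1.
#' @export
zscore_expression <- function(fpkm) {
  fpkm <- as.matrix(fpkm)
  if (any(fpkm < 0)) stop("FPKM values must be non-negative")
  lx <- log10(fpkm + 1e-3)
  mu <- rowMeans(lx)
  sdp <- sqrt(rowMeans((lx - mu)^2))
  flat <- sdp == 0
  z <- (lx - mu) / ifelse(sdp == 0, 1, sdp)
  z[flat, ] <- 0
  attr(z, "flat_rows") <- which(flat)
  z
}

#' Expression filter on TPM
#'
#' Returns genes meeting `TPM >= min_tpm` (inclusive) in every replicate
#' of one condition (`scope = "all_replicates_of_condition"`) or in every
#' sample of the table (`scope = "all_conditions"`).
#'
#' @param tpm TPM matrix with gene rownames.
#' @param min_tpm inclusive threshold.
#' @param scope filtering scope.
#' @param samples columns to test when scoping to one condition.
#' @return character vector of passing gene ids.
#' @export
expressed_filter <- function(tpm, min_tpm = 1,
                             scope = c("all_replicates_of_condition",
                                       "all_conditions"),
                             samples = NULL) {
  scope <- match.arg(scope)
  cols <- if (scope == "all_conditions") seq_len(ncol(tpm)) else {
    if (is.null(samples))
      stop("samples must name the condition's replicates for this scope")
    samples
  }
  sub <- tpm[, cols, drop = FALSE]
  rownames(tpm)[rowSums(sub >= min_tpm) == ncol(sub)]
}
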