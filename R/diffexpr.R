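#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed against the geometric-mean
#' pseudo-reference: for each sample, the median of its count ratios to
#' the reference across genes, rescaled so the factors have geometric
#' mean 1. With no gene expressed in every sample the strict reference is
#' undefined; `pseudo_reference = TRUE` falls back to geometric means over
#' positive counts only.
#'
#' @param counts gene x sample count matrix.
#' @param pseudo_reference allow the positive-counts fallback reference.
#' @return named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts, pseudo_reference = FALSE) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) >= 1)
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos)) {
    if (!pseudo_reference)
      stop("no gene has nonzero counts in all samples; rerun with ",
           "pseudo_reference = TRUE to use the positive-count fallback")
    use <- rowSums(counts > 0) > 0
    logref <- apply(counts[use, , drop = FALSE], 1, function(x) {
      mean(log(x[x > 0]))
    })
    sub <- counts[use, , drop = FALSE]
  } else {
    sub <- counts[all_pos, , drop = FALSE]
    logref <- rowMeans(log(sub))
  }
  sf <- apply(sub, 2, function(x) {
    r <- log(x) - logref
    exp(stats::median(r[is.finite(r)]))
  })
  sf <- sf / geo_mean(sf)
  stats::setNames(sf, colnames(counts))
}

#' Transcripts per million
#'
#' Length-normalizes counts to rates and scales every sample to one
#' million, so each column sums to 1e6.
#'
#' @param counts gene x sample count matrix.
#' @param gene_lengths per-gene lengths in bp (all >= 1), in row order.
#' @return numeric matrix of TPM values.
#' @export
compute_tpm <- function(counts, gene_lengths) {
  counts <- as.matrix(counts)
  stopifnot(length(gene_lengths) == nrow(counts))
  if (any(gene_lengths < 1)) stop("gene lengths must be >= 1")
  rate <- counts / gene_lengths
  cs <- colSums(rate)
  if (any(cs == 0)) cs[cs == 0] <- 1  # all-zero sample stays all-zero
  t(t(rate) / cs) * 1e6
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate correction; a thin validated wrapper over
#' the standard implementation.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NAs propagated).
#' @return adjusted p-values, capped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Negative-binomial Wald contrast (B vs A)
#'
#' Two-group differential test replacing a DESeq2-style call. Counts are
#' normalized by median-of-ratios size factors; per-gene dispersion is
#' estimated by method of moments from the pooled within-group variance
#' and shrunk 50/50 toward a lowess mean-dispersion trend fitted on the
#' log scale; the log2 fold change is log2((mu_B + eps)/(mu_A + eps)) with
#' a pseudo-count of `eps = 0.5` normalized counts; the Wald statistic
#' uses a delta-method standard error and is referred to a moderated t
#' distribution whose degrees of freedom are the two-group residual df
#' augmented by an equal prior df, reflecting the equal-weight dispersion
#' shrinkage (with four replicates per group: df = 2 x 6 = 12). This
#' small-sample correction keeps the type-I error near nominal where a
#' plain normal reference is anti-conservative. Benjamini-Hochberg
#' adjustment is applied across all genes that are not all-zero (all-zero
#' genes get log2FC 0, p 1 and are excluded from the correction).
#' Orientation: positive log2FC means higher in group B.
#'
#' @param counts gene x sample count matrix.
#' @param samples_A,samples_B column names (or indices) of the two groups;
#'   at least two replicates each.
#' @param size_factors optional per-sample factors covering both groups;
#'   computed from the two groups' columns when `NULL`.
#' @param pseudocount eps added to each group mean for the fold change.
#' @param tpm optional TPM matrix (same rows) used to report per-group
#'   mean TPM columns.
#' @return data frame (one row per gene): gene_id, base_mean, log2fc, se,
#'   stat, pvalue, padj, dispersion, tpm_mean_A, tpm_mean_B.
#' @export
nb_wald_contrast <- function(counts, samples_A, samples_B,
                             size_factors = NULL, pseudocount = 0.5,
                             tpm = NULL) {
  counts <- as.matrix(counts)
  A <- samples_A; B <- samples_B
  if (length(A) < 2 || length(B) < 2)
    stop("each group needs at least two replicates")
  sub <- counts[, c(A, B), drop = FALSE]
  if (is.null(size_factors)) {
    size_factors <- size_factors(sub, pseudo_reference = TRUE)
    sf <- size_factors
  } else {
    sf <- if (!is.null(names(size_factors)) && is.character(c(A, B))) {
      size_factors[c(A, B)]
    } else size_factors
  }
  norm <- t(t(sub) / sf)
  nA <- length(A); nB <- length(B)
  iA <- seq_len(nA); iB <- nA + seq_len(nB)
  muA <- rowMeans(norm[, iA, drop = FALSE])
  muB <- rowMeans(norm[, iB, drop = FALSE])
  vA <- apply(norm[, iA, drop = FALSE], 1, stats::var)
  vB <- apply(norm[, iB, drop = FALSE], 1, stats::var)

  mu0 <- (nA * muA + nB * muB) / (nA + nB)
  w <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
  raw <- ifelse(mu0 > 0, (w - mu0) / mu0^2, NA_real_)
  raw <- pmax(raw, 0)

  # lowess trend of log dispersion over log mean, fitted on genes with a
  # positive raw estimate; rule-2 extrapolation at the extremes
  fit_ok <- is.finite(raw) & raw > 0 & mu0 > 0
  if (sum(fit_ok) >= 10) {
    lo <- stats::lowess(log(mu0[fit_ok]), log(raw[fit_ok]), f = 0.5)
    trend_fun <- stats::approxfun(lo$x, lo$y, rule = 2, ties = mean)
    trend <- exp(trend_fun(log(pmax(mu0, min(mu0[fit_ok])))))
  } else {
    trend <- rep(stats::median(raw[fit_ok], na.rm = TRUE), length(raw))
    trend[!is.finite(trend)] <- 0.01
  }
  disp <- pmax(1e-8, 0.5 * ifelse(is.finite(raw), raw, 0) + 0.5 * trend)

  eps <- pseudocount
  log2fc <- log2((muB + eps) / (muA + eps))
  varlog <- function(mu, n) (mu + disp * mu^2) / (n * (mu + eps)^2)
  se <- sqrt(varlog(muA, nA) + varlog(muB, nB)) / log(2)
  stat <- ifelse(se > 0, log2fc / se, 0)
  # moderated-t reference: residual df plus an equal prior df from the
  # 50/50 dispersion shrinkage toward the trend
  df_mod <- 2 * (nA + nB - 2)
  pvalue <- 2 * stats::pt(-abs(stat), df = df_mod)

  allzero <- muA == 0 & muB == 0
  log2fc[allzero] <- 0
  stat[allzero] <- 0
  pvalue[allzero] <- 1
  padj <- rep(NA_real_, length(pvalue))
  padj[!allzero] <- bh_adjust(pvalue[!allzero])

  gene_id <- rownames(counts)
  if (is.null(gene_id)) gene_id <- sprintf("gene_%05d", seq_len(nrow(counts)))
  res <- data.frame(
    gene_id = gene_id,
    base_mean = rowMeans(norm),
    log2fc = log2fc, se = se, stat = stat,
    pvalue = pvalue, padj = padj, dispersion = disp,
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (!is.null(tpm)) {
    res$tpm_mean_A <- rowMeans(tpm[, A, drop = FALSE])
    res$tpm_mean_B <- rowMeans(tpm[, B, drop = FALSE])
  }
  res
}

#' Call differentially expressed genes
#'
#' Applies the study thresholds |log2FC| >= `lfc_min` (inclusive) and
#' adjusted p < `alpha` (strict). Direction follows the contrast
#' orientation: positive log2FC (higher in group B) is `activated`,
#' negative is `repressed`.
#'
#' @param result a [nb_wald_contrast()] data frame.
#' @param lfc_min minimum absolute log2 fold change (default 1).
#' @param alpha adjusted-p cutoff (default 0.05, strict inequality).
#' @return data frame `deg_set`: gene_id, direction.
#' @export
call_degs <- function(result, lfc_min = 1, alpha = 0.05) {
  keep <- !is.na(result$padj) &
    abs(result$log2fc) >= lfc_min & result$padj < alpha
  out <- data.frame(
    gene_id = result$gene_id[keep],
    direction = ifelse(result$log2fc[keep] > 0, "activated", "repressed"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("deg_set", class(out))
  out
}
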