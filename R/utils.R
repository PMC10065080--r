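#' Round half-up at a fixed number of decimals
#'
#' Plain commercial rounding (0.5 always rounds away from zero for positive
#' input), used for all reported percentages and fold-ratios so that printed
#' summaries are reproducible independent of the IEEE round-half-even rule.
#'
#' @param x numeric vector (non-negative in all internal uses).
#' @param digits number of decimal places to keep.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of x out of n, rounded half-up
#'
#' @param x numerator count(s).
#' @param n denominator count(s); a zero denominator yields `NA` (undefined,
#'   never reported as 0).
#' @param digits decimals to keep (0 where integers are printed, 1 where one
#'   decimal is printed).
#' @return numeric percentage(s) in \[0, 100\] (or beyond if x > n).
#' @export
percent_of <- function(x, n, digits = 1) {
  stopifnot(all(x >= 0, na.rm = TRUE), all(n >= 0, na.rm = TRUE))
  out <- ifelse(n > 0, round_half_up(100 * x / n, digits), NA_real_)
  out
}

#' Fold-ratio rounded to one decimal
#'
#' @param a,b positive counts; returns `NA` when `b` is zero.
#' @return `a / b` rounded half-up to 1 decimal.
#' @export
fold_ratio <- function(a, b) {
  ifelse(b > 0, round_half_up(a / b, 1), NA_real_)
}

# geometric mean of strictly positive values
geo_mean <- function(x) exp(mean(log(x)))

# internal: 0-based half-open data frame -> GRanges (1-based closed)
df_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if ("strand" %in% names(df)) df$strand else "*"
  )
}

# internal: independent sub-stream seeds derived once from a master seed, so
# that adding a pipeline stage never perturbs the draws of earlier stages
stage_seeds <- function(seed, n = 16L) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
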