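# Independent reference implementations used as oracles. These are kept
# deliberately naive (brute force, closed form, enumeration) and share no
# code with the package internals they check.

# step-up BH by the textbook definition
bh_reference <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# median-of-ratios size factors, computed directly
size_factors_reference <- function(counts) {
  keep <- apply(counts > 0, 1, all)
  logref <- rowMeans(log(counts[keep, , drop = FALSE]))
  sf <- vapply(seq_len(ncol(counts)), function(j) {
    exp(median(log(counts[keep, j]) - logref))
  }, numeric(1))
  sf / exp(mean(log(sf)))
}

# two-proportion z test with Yates correction, textbook formula
prop_test_reference <- function(x1, n1, x2, n2, continuity = TRUE) {
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  d <- abs(p1 - p2)
  if (continuity) d <- max(0, d - 0.5 * (1 / n1 + 1 / n2))
  z <- d / se
  list(statistic = z^2, p.value = 2 * pnorm(-z))
}

# exact two-sided Mann-Whitney p by enumeration over label assignments
# (small n only, no ties)
mw_exact_reference <- function(x, y) {
  nx <- length(x); ny <- length(y)
  all_v <- c(x, y)
  combs <- combn(nx + ny, nx)
  u_obs <- sum(rank(all_v)[seq_len(nx)]) - nx * (nx + 1) / 2
  us <- apply(combs, 2, function(idx) {
    sum(rank(all_v)[idx]) - nx * (nx + 1) / 2
  })
  mu <- nx * ny / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# exact two-sided one-sample signed-rank p by sign enumeration (no ties,
# no zeros)
signed_rank_exact_reference <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  vs <- as.matrix(signs) %*% r
  mu <- n * (n + 1) / 4
  mean(abs(vs - mu) >= abs(v_obs - mu) - 1e-9)
}

# naive sliding-window IUPAC matcher (forward strand, 0-based starts)
iupac_sets <- c(A = "A", C = "C", G = "G", T = "T",
                R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
                B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGTN")
naive_iupac_starts <- function(sequence, consensus) {
  s <- strsplit(toupper(sequence), "")[[1]]
  pat <- strsplit(toupper(consensus), "")[[1]]
  w <- length(pat)
  if (length(s) < w) return(integer(0))
  hits <- integer(0)
  for (i in seq_len(length(s) - w + 1)) {
    ok <- TRUE
    for (k in seq_len(w)) {
      if (!grepl(s[i + k - 1], iupac_sets[[pat[k]]], fixed = TRUE)) {
        ok <- FALSE; break
      }
    }
    if (ok) hits <- c(hits, i - 1L)
  }
  hits
}

# brute-force nearest-DEG assignment (all-pairs distances)
nearest_reference <- function(peaks, degs, annotation, max_dist = NULL) {
  cand <- annotation[annotation$gene_id %in% degs$gene_id, , drop = FALSE]
  mid <- floor((peaks$start + peaks$end) / 2)
  out <- rep(NA_character_, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    g <- cand[cand$chrom == peaks$chrom[i], , drop = FALSE]
    if (!nrow(g)) next
    d <- abs(mid[i] - g$tss)
    best <- min(d)
    ids <- sort(g$gene_id[d == best])
    if (is.null(max_dist) || best <= max_dist) out[i] <- ids[1]
  }
  out
}

# brute-force interval overlap counts (0-based half-open)
overlap_reference <- function(a, b, min_overlap = 1) {
  hit_a <- logical(nrow(a)); hit_b <- logical(nrow(b)); pairs <- 0L
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
      if (ov >= min_overlap) {
        hit_a[i] <- TRUE; hit_b[j] <- TRUE; pairs <- pairs + 1L
      }
    }
  }
  list(shared_pairs = pairs, a_shared = sum(hit_a), a_only = sum(!hit_a),
       b_shared = sum(hit_b), b_only = sum(!hit_b))
}

random_dna <- function(n, width) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
          collapse = "")
  }, character(1))
}
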