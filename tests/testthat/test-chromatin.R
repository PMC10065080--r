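test_that("differential peaks are classified consistently with the strict thresholds", {
  set.seed(21)
  n <- 900
  mu <- rep(200, n)
  shift <- sample(c(0, 2, -2), n, replace = TRUE)
  counts <- cbind(
    matrix(rnbinom(4 * n, mu = rep(mu, 4), size = 20), n, 4),
    matrix(rnbinom(4 * n, mu = rep(mu * 2^shift, 4), size = 20), n, 4))
  rownames(counts) <- sprintf("p%03d", 1:n)
  colnames(counts) <- paste0("s", 1:8)
  res <- differential_peaks(counts, paste0("s", 1:4), paste0("s", 5:8),
                            size_factors = setNames(rep(1, 8),
                                                    paste0("s", 1:8)))
  sig <- !is.na(res$padj) & res$padj < 0.05
  expect_identical(res$accessibility == "opening",
                   sig & res$log2fc > 1)
  expect_identical(res$accessibility == "closing",
                   sig & res$log2fc < -1)
  # strong designed shifts are recovered with high power
  expect_gte(mean(res$accessibility[shift == 2] == "opening"), 0.95)
  expect_gte(mean(res$accessibility[shift == -2] == "closing"), 0.95)
  # null peaks keep roughly nominal raw significance
  expect_lt(mean(res$pvalue[shift == 0] < 0.05), 0.08)
})

test_that("nearest-DEG linking matches brute force and breaks ties lexicographically", {
  ann <- data.frame(
    gene_id = c("gB", "gA", "gC"),
    chrom = "chr1", strand = c("+", "+", "-"),
    tss = c(15000, 5000, 40000), length = 1000,
    stringsAsFactors = FALSE)
  degs <- data.frame(gene_id = c("gA", "gB", "gC"),
                     stringsAsFactors = FALSE)
  # midpoint exactly at a TSS
  pk0 <- data.frame(peak_id = "p0", chrom = "chr1",
                    start = 4950, end = 5050, stringsAsFactors = FALSE)
  l0 <- link_to_nearest_deg(pk0, degs, ann)
  expect_identical(l0$gene_id, "gA")
  expect_equal(l0$distance, 0)
  # equidistant between gA (5000) and gB (15000): midpoint 10000
  pk1 <- data.frame(peak_id = "p1", chrom = "chr1",
                    start = 9950, end = 10050, stringsAsFactors = FALSE)
  expect_identical(link_to_nearest_deg(pk1, degs, ann)$gene_id, "gA")
  # minus-strand gene flips the sign of the distance
  pk2 <- data.frame(peak_id = "p2", chrom = "chr1",
                    start = 40950, end = 41050, stringsAsFactors = FALSE)
  l2 <- link_to_nearest_deg(pk2, degs, ann)
  expect_identical(l2$gene_id, "gC")
  expect_equal(l2$distance, -1000)

  set.seed(22)
  ann_r <- data.frame(
    gene_id = sprintf("g%03d", 1:80),
    chrom = sample(c("chr1", "chr2"), 80, replace = TRUE),
    strand = sample(c("+", "-"), 80, replace = TRUE),
    tss = sample.int(1e6, 80), length = 1000,
    stringsAsFactors = FALSE)
  degs_r <- data.frame(gene_id = sample(ann_r$gene_id, 40),
                       stringsAsFactors = FALSE)
  st <- sample.int(1e6 - 500, 1000)
  pk_r <- data.frame(peak_id = sprintf("p%04d", 1:1000),
                     chrom = sample(c("chr1", "chr2"), 1000, replace = TRUE),
                     start = st, end = st + sample(100:500, 1000, TRUE),
                     stringsAsFactors = FALSE)
  links <- link_to_nearest_deg(pk_r, degs_r, ann_r)
  expect_identical(links$gene_id,
                   nearest_reference(pk_r, degs_r, ann_r))
  capped <- link_to_nearest_deg(pk_r, degs_r, ann_r, max_dist = 20000)
  expect_identical(capped$gene_id,
                   nearest_reference(pk_r, degs_r, ann_r,
                                     max_dist = 20000))
})

test_that("transition classification counts mixed genes in both proportions", {
  links <- data.frame(peak_id = c("p1", "p2", "p3"),
                      gene_id = c("g1", "g1", "g2"),
                      stringsAsFactors = FALSE)
  classes <- data.frame(peak_id = c("p1", "p2", "p3"),
                        accessibility = c("opening", "closing",
                                          "unchanged"),
                        stringsAsFactors = FALSE)
  tr <- classify_transitions(links, classes,
                             cohorts = list(both = c("g1", "g2"),
                                            empty = character(0)))
  g1 <- tr$genes[tr$genes$gene_id == "g1", ]
  expect_true(g1$opening && g1$closing)
  pr <- tr$proportions
  expect_equal(pr$pct_opening[pr$cohort == "both"], 50)
  expect_equal(pr$pct_closing[pr$cohort == "both"], 50)
  expect_true(is.na(pr$pct_opening[pr$cohort == "empty"]))
})

test_that("the proportion test reproduces the continuity-corrected formula", {
  same <- proportion_test(30, 100, 30, 100)
  expect_equal(same$p.value, 1)
  ref <- prop_test_reference(35, 100, 40, 100)
  got <- proportion_test(35, 100, 40, 100)
  expect_equal(got$p.value, ref$p.value, tolerance = 1e-10)
  expect_equal(got$statistic, ref$statistic, tolerance = 1e-10)
  # correction exceeding the difference floors the statistic
  tiny <- proportion_test(50, 100, 51, 100)
  expect_equal(tiny$p.value, 1)
  expect_error(proportion_test(1, 0, 1, 2))
  set.seed(23)
  for (i in 1:200) {
    n1 <- sample(20:200, 1); n2 <- sample(20:200, 1)
    x1 <- rbinom(1, n1, 0.4); x2 <- rbinom(1, n2, 0.5)
    ref <- prop_test_reference(x1, n1, x2, n2)
    got <- proportion_test(x1, n1, x2, n2)
    expect_equal(got$p.value, ref$p.value, tolerance = 1e-8)
  }
})

test_that("rank tests match exact enumeration and the asymptotic regime", {
  # constant +1 shift, n = 6, exact signed rank: p = 2/64
  sr <- rank_tests(rep(1, 6) + (1:6) * 1e-9, kind = "rank_sum_vs_zero_shift")
  expect_equal(sr$p.value, 2 / 64, tolerance = 1e-9)
  expect_warning(z <- rank_tests(numeric(5), rep(0, 5),
                                 kind = "signed_rank_paired"),
                 "all paired differences")
  expect_equal(z$p.value, 1)
  ident <- suppressWarnings(
    rank_tests(rep(1:5, 2), rep(1:5, 2), kind = "mann_whitney_two_sample"))
  expect_equal(ident$p.value, 1)
  set.seed(24)
  # exact enumeration oracle, small n without ties
  for (i in 1:20) {
    x <- rnorm(6); y <- rnorm(7) + 0.5
    got <- rank_tests(x, y, kind = "mann_whitney_two_sample")
    expect_equal(got$p.value, mw_exact_reference(x, y), tolerance = 1e-9)
    d <- rnorm(7) + 0.3
    gsr <- rank_tests(d, kind = "rank_sum_vs_zero_shift")
    expect_equal(gsr$p.value, signed_rank_exact_reference(d),
                 tolerance = 1e-9)
  }
  # exact vs normal approximation agree closely at n = 20
  for (i in 1:100) {
    x <- rnorm(20); y <- rnorm(20) + runif(1, 0, 1)
    pe <- rank_tests(x, y, kind = "mann_whitney_two_sample",
                     exact = TRUE)$p.value
    pa <- rank_tests(x, y, kind = "mann_whitney_two_sample",
                     exact = FALSE)$p.value
    expect_lt(abs(pe - pa), 0.01)
  }
  # complete separation at n = 10 vs 10: exact two-sided p = 2/choose(20,10)
  sep <- rank_tests(101:110 + runif(10), 1:10 + runif(10),
                    kind = "mann_whitney_two_sample", exact = TRUE)
  expect_equal(sep$p.value, 2 / choose(20, 10), tolerance = 1e-12)
})

test_that("promoter windows are strand-aware and sums match brute force", {
  ann <- data.frame(gene_id = c("plus", "minus"), chrom = "chr1",
                    strand = c("+", "-"), tss = c(10000, 10000),
                    length = 1000, stringsAsFactors = FALSE)
  # peak inside [8000, 10100) only
  pk <- data.frame(peak_id = c("a", "b"), chrom = "chr1",
                   start = c(8000, 11000), end = c(8100, 11100),
                   stringsAsFactors = FALSE)
  cnt <- matrix(c(10, 20, 30, 40), 2, 2,
                dimnames = list(c("a", "b"), c("s1", "s2")))
  ps <- promoter_signal(pk, cnt, ann, size_factors = c(s1 = 1, s2 = 1))
  expect_equal(unname(ps["plus", ]), c(10, 30))   # peak a only
  expect_equal(unname(ps["minus", ]), c(20, 40))  # peak b only

  set.seed(25)
  ann_r <- data.frame(gene_id = sprintf("g%02d", 1:30), chrom = "chr1",
                      strand = sample(c("+", "-"), 30, TRUE),
                      tss = sample.int(2e5, 30), length = 1000,
                      stringsAsFactors = FALSE)
  st <- sample.int(2e5, 200)
  pk_r <- data.frame(peak_id = sprintf("p%03d", 1:200), chrom = "chr1",
                     start = st, end = st + 300, stringsAsFactors = FALSE)
  cnt_r <- matrix(rpois(400, 50), 200, 2,
                  dimnames = list(pk_r$peak_id, c("s1", "s2")))
  got <- promoter_signal(pk_r, cnt_r, ann_r,
                         size_factors = c(s1 = 1, s2 = 1))
  ws <- ifelse(ann_r$strand == "-", ann_r$tss - 100, ann_r$tss - 2000)
  we <- ifelse(ann_r$strand == "-", ann_r$tss + 2000, ann_r$tss + 100)
  for (i in seq_len(30)) {
    ov <- pk_r$start < we[i] & pk_r$end > ws[i]
    expect_equal(unname(got[i, ]),
                 unname(colSums(cnt_r[ov, , drop = FALSE])))
  }
})
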