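deg <- function(ids, dir = "activated") {
  data.frame(gene_id = ids, direction = rep(dir, length(ids)),
             stringsAsFactors = FALSE)
}

test_that("catalog categories follow the definitions", {
  d_enh <- deg(character(0))
  d_res <- rbind(deg(c("g1", "g2")), deg("g3", "repressed"))
  d_var <- rbind(deg("g2"), deg(c("g4")), deg("g5", "repressed"))
  cat <- build_catalog(d_enh, d_res, d_var)
  df <- cat$catalog
  lab <- setNames(df$category, df$gene_id)
  expect_identical(lab[["g1"]], "I.II")  # rescue-activated only
  expect_identical(lab[["g2"]], "I.I")   # rescue- and variant-activated
  expect_identical(lab[["g3"]], "II.II")
  expect_identical(lab[["g4"]], "III")   # ectopically activated
  expect_identical(lab[["g5"]], "IV")
})

test_that("catalog set identities hold on random DEG sets", {
  set.seed(11)
  for (i in 1:20) {
    genes <- sprintf("g%03d", 1:200)
    pick <- function() {
      ids <- sample(genes, 60)
      data.frame(gene_id = ids,
                 direction = sample(c("activated", "repressed"), 60,
                                    replace = TRUE),
                 stringsAsFactors = FALSE)
    }
    cat <- build_catalog(pick(), pick(), pick(), universe = genes)
    df <- cat$catalog
    I <- df$gene_id[df$category %in% c("I.I", "I.II")]
    expect_identical(sort(I),
                     sort(df$gene_id[df$rescue_dir == "activated"]))
    expect_length(intersect(df$gene_id[df$category == "I.I"],
                            df$gene_id[df$category == "I.II"]), 0)
    # III/IV never overlap I/II
    ect <- df$gene_id[df$category %in% c("III", "IV")]
    expect_length(intersect(ect, df$gene_id[df$rescue_dir != "none"]), 0)
    # discordant genes are exactly the opposite-direction ones
    disc <- df$rescue_dir != "none" & df$variant_dir != "none" &
      df$rescue_dir != df$variant_dir
    expect_identical(df$discordant, disc)
  }
})

test_that("fraction summaries round half-up at printed precision", {
  expect_equal(summarize_fractions(0, 10, digits = 1)$percent, 0)
  expect_true(is.na(summarize_fractions(0, 0)$percent))
  expect_equal(percent_of(144, 1061, 0), 14)   # 13.57 rounds up
  expect_equal(percent_of(381, 1077, 0), 35)   # 35.38 rounds down
  expect_equal(fold_ratio(561, 190), 3.0)
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(86.45, 1), 86.5)
})

test_that("rescue fraction is 1 for self-comparison and ~0.5 under independence", {
  set.seed(12)
  lfc <- rnorm(4000)
  a <- fake_contrast(sprintf("g%04d", 1:4000), lfc)
  expect_equal(rescue_fraction(a, a)$activated$fraction, 1)
  expect_equal(rescue_fraction(a, a)$repressed$fraction, 1)
  b <- fake_contrast(a$gene_id, rnorm(4000))
  rf <- rescue_fraction(a, b)
  n <- rf$activated$n
  expect_lt(abs(rf$activated$fraction - 0.5), 3 * sqrt(0.25 / n))
  expect_lt(abs(rf$repressed$fraction - 0.5),
            3 * sqrt(0.25 / rf$repressed$n))
})

test_that("retained activity implements both scale definitions", {
  g <- c("g1", "g2")
  tpm <- matrix(10, 2, 8, dimnames = list(g, paste0("s", 1:8)))
  resc <- fake_contrast(g, c(2, -2))
  # identical contrasts: everything retained at 100%
  ra <- retained_activity(resc, resc, tpm, samples_rescue = paste0("s", 1:4),
                          samples_empty = paste0("s", 5:8))
  expect_equal(ra$genes$retained_percent, c(100, 100))
  # halved variant effect: 50 on the log scale, 33.3 on the linear scale
  var <- fake_contrast(g, c(1, -1))
  ra_log <- retained_activity(resc, var, tpm, paste0("s", 1:4),
                              paste0("s", 5:8))
  expect_equal(ra_log$genes$retained_percent, c(50, 50))
  ra_lin <- retained_activity(resc, var, tpm, paste0("s", 1:4),
                              paste0("s", 5:8), scale = "linear")
  expect_equal(ra_lin$genes$retained_percent, 100 * c(1, 1) / 3,
               tolerance = 1e-12)
})

test_that("retained-activity medians recover a designed 0.6x attenuation", {
  set.seed(13)
  n <- 800
  lr <- runif(n, 1.5, 3) * sample(c(1, -1), n, replace = TRUE)
  lv <- 0.6 * lr + rnorm(n, sd = 0.05)
  g <- sprintf("g%04d", 1:n)
  tpm <- matrix(10, n, 8, dimnames = list(g, paste0("s", 1:8)))
  ra <- retained_activity(fake_contrast(g, lr), fake_contrast(g, lv),
                          tpm, paste0("s", 1:4), paste0("s", 5:8))
  med <- ra$summary$median_retained
  expect_true(all(abs(med - 60) < 5))
})

test_that("retained activity applies the TPM filter to the stated condition", {
  g <- c("up", "down")
  tpm <- matrix(10, 2, 8, dimnames = list(g, paste0("s", 1:8)))
  tpm["up", "s2"] <- 0.5    # fails in rescue replicates -> drops activation
  resc <- fake_contrast(g, c(2, -2))
  ra <- retained_activity(resc, resc, tpm, samples_rescue = paste0("s", 1:4),
                          samples_empty = paste0("s", 5:8))
  expect_identical(ra$genes$gene_id, "down")
  expect_equal(ra$n_filtered_tpm, 1)
})

test_that("the cutoff scan tabulates set differences without forcing monotonicity", {
  g <- sprintf("g%02d", 1:40)
  resc <- fake_contrast(g, rep(2, 40), padj = runif(40, 0, 0.2))
  expect_error(cutoff_robustness_scan(resc, resc, cutoffs = 0.05),
               "two cutoffs")
  scan0 <- cutoff_robustness_scan(resc, resc, mode = "ectopic")
  expect_equal(scan0$scan$pct_activated,
               ifelse(scan0$scan$n_activated > 0, 0, NA_real_))
  expect_equal(nrow(scan0$scan), 10)
  expect_equal(scan0$scan$cutoff, seq(0.01, 0.10, by = 0.01))
})

test_that("percent of maximal regulation handles boundaries and ties", {
  pm <- percent_max_regulation(empty = 10, full = 50, v = c(50, 10, 30))
  expect_equal(pm$percent, c(100, 0, 50))
  expect_true(pm$retained_at_50[3])  # exactly 50% counts as retained
  expect_warning(out <- percent_max_regulation(10, 10, 10),
                 "zero dynamic range")
  expect_true(is.na(out$percent))
  # repression direction: same formula after sign flips
  expect_equal(percent_max_regulation(50, 10, 30)$percent, 50)
})

test_that("expression z-scores standardize rows of log10(FPKM + 1e-3)", {
  flat <- matrix(5, 1, 4)
  expect_equal(unname(zscore_expression(flat)), matrix(0, 1, 4),
               ignore_attr = TRUE)
  zz <- zscore_expression(matrix(0, 1, 2))
  expect_equal(unname(zz), matrix(0, 1, 2), ignore_attr = TRUE)
  set.seed(14)
  r <- matrix(rexp(8), 1, 8)
  z <- zscore_expression(r)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-12)
})

test_that("expression filter is inclusive and scope-aware", {
  tpm <- rbind(exact = c(1, 1, 1, 1), low = c(1, 0.99, 1, 1))
  colnames(tpm) <- paste0("s", 1:4)
  keep <- expressed_filter(tpm, scope = "all_replicates_of_condition",
                           samples = paste0("s", 1:4))
  expect_identical(keep, "exact")
  set.seed(15)
  tpm26 <- matrix(runif(26 * 4, 0.5, 2), 26, 4,
                  dimnames = list(sprintf("ets%02d", 1:26), paste0("s", 1:4)))
  pass <- rownames(tpm26)[rowSums(tpm26 >= 1) == 4]
  expect_identical(expressed_filter(tpm26, scope = "all_conditions"),
                   pass)
})
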