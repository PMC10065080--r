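test_that("zeroed proportions give an entirely unregulated genome", {
  props <- c(gata2_activated_only = 0, gata2_repressed_only = 0,
             shared_activated = 0, shared_repressed = 0,
             ectopic_activated = 0, ectopic_repressed = 0,
             enhancer_only = 0)
  cfg <- small_config(n_genes = 500, category_proportions = props)
  truth <- simulate_truth(cfg)
  expect_true(all(truth$genes$category == "unregulated"))
  expect_true(all(truth$genes$lfc_enh == 0))
  expect_true(all(truth$genes$lfc_rescue == 0))
  expect_true(all(truth$genes$lfc_variant == 0))
})

test_that("default category counts match their expectations within binomial error", {
  cfg <- sim_config(seed = 42)
  truth <- simulate_truth(cfg)
  tab <- table(truth$genes$category)
  n <- cfg$n_genes
  for (nm in names(cfg$category_proportions)) {
    expected <- n * cfg$category_proportions[[nm]]
    sd <- sqrt(expected * (1 - cfg$category_proportions[[nm]]))
    expect_lt(abs(tab[[nm]] - expected), 4 * sd)
  }
  # the headline totals: ~1,061 activated and ~1,077 repressed genes
  act <- sum(tab[c("gata2_activated_only", "shared_activated")])
  rep_ <- sum(tab[c("gata2_repressed_only", "shared_repressed")])
  expect_lt(abs(act - 1061), 4 * sqrt(1061))
  expect_lt(abs(rep_ - 1077), 4 * sqrt(1077))
})

test_that("category proportions summing over one are rejected", {
  props <- c(gata2_activated_only = 0.7, gata2_repressed_only = 0.5)
  expect_error(
    sim_config(category_proportions = props,
               effect_size_lfc = c(gata2_activated_only = 2,
                                   gata2_repressed_only = 2)),
    "sum to more than 1")
})

test_that("simulation is deterministic for a fixed seed", {
  cfg <- small_config(n_genes = 300, seed = 9)
  t1 <- simulate_truth(cfg); t2 <- simulate_truth(cfg)
  expect_identical(t1, t2)
  a1 <- simulate_annotation(cfg); a2 <- simulate_annotation(cfg)
  expect_identical(a1, a2)
  c1 <- simulate_counts(cfg, t1, a1); c2 <- simulate_counts(cfg, t2, a2)
  expect_identical(c1, c2)
  p1 <- simulate_peaks_and_sequences(cfg, t1, a1)
  p2 <- simulate_peaks_and_sequences(cfg, t2, a2)
  expect_identical(p1, p2)
})

test_that("counts approach the Poisson limit as dispersion vanishes", {
  cfg <- small_config(n_genes = 60, n_replicates = 150, dispersion = 0,
                      library_size_range = c(1e6, 1e6),
                      baseline_range = c(100, 100), seed = 5)
  truth <- simulate_truth(cfg)
  ann <- simulate_annotation(cfg)
  counts <- simulate_counts(cfg, truth, ann)
  ko <- grepl("^KO_empty", colnames(counts))
  vm <- apply(counts[, ko], 1, var) / rowMeans(counts[, ko])
  expect_lt(abs(mean(vm) - 1), 0.1)
})

test_that("empirical mean ratios recover the designed fold change", {
  props <- c(gata2_activated_only = 1, gata2_repressed_only = 0,
             shared_activated = 0, shared_repressed = 0,
             ectopic_activated = 0, ectopic_repressed = 0,
             enhancer_only = 0)
  cfg <- small_config(n_genes = 40, n_replicates = 2000,
                      category_proportions = props,
                      baseline_range = c(100, 100),
                      library_size_range = c(1e6, 1e6), seed = 3)
  truth <- simulate_truth(cfg)
  ann <- simulate_annotation(cfg)
  counts <- simulate_counts(cfg, truth, ann)
  ko <- grepl("^KO_empty", colnames(counts))
  resc <- grepl("^KO_rescue", colnames(counts))
  ratio <- rowMeans(counts[, resc]) / rowMeans(counts[, ko])
  expect_true(all(abs(ratio - 4) / 4 < 0.05))
})

test_that("peak and motif truth respects its declared invariants", {
  cfg <- small_config(n_genes = 400, seed = 21)
  truth <- simulate_truth(cfg)
  ann <- simulate_annotation(cfg)
  ps <- simulate_peaks_and_sequences(cfg, truth, ann)
  expect_true(all(ps$peaks$start < ps$peaks$end))
  expect_true(all(ps$peaks$start >= 0 & ps$peaks$end <= cfg$genome_size))
  expect_true(all(ps$peaks$gene_id %in% ann$gene_id))
  widths <- nchar(ps$sequences)[ps$manifest$seq_id]
  mlen <- nchar(vapply(cfg$motif_densities[ps$manifest$motif],
                       `[[`, character(1), "consensus"))
  expect_true(all(ps$manifest$start >= 0))
  expect_true(all(ps$manifest$start + mlen <= widths))
})

test_that("certain opening probability guarantees a shifted peak per activated gene", {
  plp <- list(activated = c(open = 1, close = 0),
              repressed = c(open = 0, close = 1),
              none = c(open = 0, close = 0))
  cfg <- small_config(n_genes = 400, seed = 13,
                      peak_link_probabilities = plp)
  truth <- simulate_truth(cfg)
  ann <- simulate_annotation(cfg)
  ps <- simulate_peaks_and_sequences(cfg, truth, ann)
  act_genes <- truth$genes$gene_id[truth$genes$lfc_rescue > 0]
  shifted <- ps$peaks$gene_id[ps$peaks$shift_rescue > 0]
  expect_true(all(act_genes %in% shifted))
})

test_that("zero motif densities leave only chance-level consensus hits", {
  dens <- list(GATA = list(consensus = "WGATAR",
                           per_kb = c(activated = 0, repressed = 0,
                                      none = 0)))
  cfg <- small_config(n_genes = 150, seed = 77, peak_rate = 2,
                      motif_densities = dens)
  truth <- simulate_truth(cfg)
  ann <- simulate_annotation(cfg)
  ps <- simulate_peaks_and_sequences(cfg, truth, ann)
  hits <- sum(vapply(ps$sequences, function(s) {
    nrow(scan_iupac(s, "WGATAR"))
  }, numeric(1)))
  # per-position forward match probability of WGATAR on uniform DNA
  p1 <- 0.5 * 0.25^4 * 0.5
  positions <- sum(nchar(ps$sequences) - 6 + 1)
  expected <- 2 * p1 * positions  # both strands
  expect_lt(abs(hits - expected), 3 * sqrt(expected))
})

test_that("written datasets round-trip through the package readers", {
  cfg <- small_config(n_genes = 120, seed = 31)
  truth <- simulate_truth(cfg)
  ann <- simulate_annotation(cfg)
  counts <- simulate_counts(cfg, truth, ann)
  ps <- simulate_peaks_and_sequences(cfg, truth, ann)
  dir <- withr::local_tempdir()
  write_sim_dataset(cfg, truth, ann, counts, ps, dir)

  counts2 <- read_counts_tsv(file.path(dir, "counts.tsv"))
  expect_equal(unname(as.matrix(counts2)), unname(unclass(counts)[,]),
               ignore_attr = TRUE)
  expect_identical(rownames(counts2), rownames(counts))
  si <- read_samples_tsv(file.path(dir, "samples.tsv"))
  expect_identical(si, attr(counts, "sample_info"))
  ann2 <- read_annotation_tsv(file.path(dir, "annotation.tsv"))
  expect_equal(ann2, ann)
  pk2 <- read_peaks_bed(file.path(dir, "peaks.bed"))
  expect_identical(pk2$peak_id, ps$peaks$peak_id)
  expect_equal(pk2$start, ps$peaks$start)
  expect_equal(pk2$end, ps$peaks$end)
  sq2 <- read_sequences_fasta(file.path(dir, "sequences.fa"))
  expect_identical(sq2, ps$sequences)
  tr2 <- read_truth_json(file.path(dir, "truth.json"))
  expect_equal(tr2$genes, truth$genes, tolerance = 1e-12)
  cfg2 <- read_config_yaml(file.path(dir, "config.yaml"))
  expect_equal(cfg2$category_proportions, cfg$category_proportions)
  expect_identical(cfg2$seed, cfg$seed)
})
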