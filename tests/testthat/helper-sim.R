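# small configurations used across test files; kept at the generator's
# default study conditions except for problem size
small_config <- function(n_genes = 1000, seed = 101, ...) {
  sim_config(n_genes = n_genes, seed = seed, ...)
}

# a fabricated contrast-result data frame with the columns downstream
# operations rely on
fake_contrast <- function(gene_id, log2fc, padj = rep(1e-6, length(log2fc)),
                          pvalue = padj) {
  data.frame(gene_id = gene_id, base_mean = 100, log2fc = log2fc,
             se = 0.1, stat = log2fc / 0.1, pvalue = pvalue, padj = padj,
             dispersion = 0.05, stringsAsFactors = FALSE)
}
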