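#' Read and write pipeline file formats
#'
#' Plain-text serialization used by the pipeline: counts as TSV with a
#' header row of sample ids, a sample sidecar TSV mapping sample to
#' condition, gene annotation as TSV (0-based TSS), peaks as BED6
#' (0-based half-open, natively), sequences as FASTA, the simulation
#' truth as JSON and configurations as YAML. Every writer has a matching
#' reader and the pair round-trips without loss.
#'
#' @param counts gene x sample integer matrix.
#' @param path file path.
#' @name regrescue-io
NULL

#' @rdname regrescue-io
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), as.data.frame(counts),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname regrescue-io
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}

#' @rdname regrescue-io
#' @param sample_info data frame with sample, condition columns.
#' @export
write_samples_tsv <- function(sample_info, path) {
  utils::write.table(sample_info, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' @rdname regrescue-io
#' @export
read_samples_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname regrescue-io
#' @param annotation gene annotation data frame.
#' @export
write_annotation_tsv <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' @rdname regrescue-io
#' @export
read_annotation_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname regrescue-io
#' @param peaks peak data frame (peak_id, chrom, start, end; 0-based
#'   half-open).
#' @export
write_peaks_bed <- function(peaks, path) {
  gr <- df_to_granges(peaks)
  names(gr) <- peaks$peak_id
  score <- if ("score" %in% names(peaks)) peaks$score else 0
  S4Vectors::mcols(gr)$score <- score
  rtracklayer::export(gr, path, format = "BED")
}

#' @rdname regrescue-io
#' @export
read_peaks_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(
    peak_id = if (!is.null(gr$name)) gr$name else
      sprintf("peak_%06d", seq_along(gr)),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' @rdname regrescue-io
#' @param sequences named character vector of DNA sequences.
#' @export
write_sequences_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
}

#' @rdname regrescue-io
#' @export
read_sequences_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname regrescue-io
#' @param truth a `sim_truth` object (gene table plus optional peak truth
#'   and motif manifest).
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, dataframe = "columns",
                       digits = NA, auto_unbox = TRUE)
}

#' @rdname regrescue-io
#' @export
read_truth_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(raw, function(el) {
    if (is.list(el) && !is.data.frame(el)) as.data.frame(el) else el
  })
  class(out) <- "sim_truth"
  out
}

#' @rdname regrescue-io
#' @param config a `sim_config` object.
#' @export
write_config_yaml <- function(config, path) {
  x <- unclass(config)
  # named numeric vectors serialize as YAML maps, not bare sequences
  for (nm in c("category_proportions", "effect_size_lfc",
               "retained_scale")) {
    x[[nm]] <- as.list(x[[nm]])
  }
  x$peak_link_probabilities <- lapply(x$peak_link_probabilities, as.list)
  x$motif_densities <- lapply(x$motif_densities, function(m) {
    m$per_kb <- as.list(m$per_kb)
    m
  })
  yaml::write_yaml(x, path, precision = 15)
}

#' @rdname regrescue-io
#' @export
read_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$category_proportions <- unlist(raw$category_proportions)
  raw$effect_size_lfc <- unlist(raw$effect_size_lfc)
  raw$retained_scale <- unlist(raw$retained_scale)
  raw$peak_link_probabilities <-
    lapply(raw$peak_link_probabilities, unlist)
  raw$motif_densities <- lapply(raw$motif_densities, function(m) {
    m$per_kb <- unlist(m$per_kb)
    m
  })
  raw$library_size_range <- unlist(raw$library_size_range)
  raw$baseline_range <- unlist(raw$baseline_range)
  raw$gene_length_range <- unlist(raw$gene_length_range)
  raw$peak_width_range <- unlist(raw$peak_width_range)
  raw$peak_baseline_range <- unlist(raw$peak_baseline_range)
  raw$conditions <- unlist(raw$conditions)
  do.call(sim_config, raw[setdiff(names(raw), character(0))])
}

#' Write a complete synthetic dataset to a directory
#'
#' Emits counts.tsv, samples.tsv, annotation.tsv, peaks.bed,
#' peak_counts.tsv, peak_samples.tsv, sequences.fa, truth.json and
#' config.yaml.
#'
#' @param config,truth,annotation,counts,peak_sim components produced by
#'   the simulate_* functions.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_sim_dataset <- function(config, truth, annotation, counts, peak_sim,
                              dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_counts_tsv(counts, file.path(dir, "counts.tsv"))
  write_samples_tsv(attr(counts, "sample_info"),
                    file.path(dir, "samples.tsv"))
  write_annotation_tsv(annotation, file.path(dir, "annotation.tsv"))
  write_peaks_bed(peak_sim$peaks, file.path(dir, "peaks.bed"))
  write_counts_tsv(peak_sim$counts, file.path(dir, "peak_counts.tsv"))
  write_samples_tsv(attr(peak_sim$counts, "sample_info"),
                    file.path(dir, "peak_samples.tsv"))
  write_sequences_fasta(peak_sim$sequences, file.path(dir, "sequences.fa"))
  full_truth <- truth
  full_truth$peaks <- peak_sim$peaks
  full_truth$manifest <- peak_sim$manifest
  write_truth_json(full_truth, file.path(dir, "truth.json"))
  write_config_yaml(config, file.path(dir, "config.yaml"))
  invisible(dir)
}
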