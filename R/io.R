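# TSV readers/writers for the pipeline's interchange formats.

#' Read a count matrix TSV
#'
#' First column = feature IDs, remaining columns = samples (header row of
#' sample labels).
#'
#' @param path TSV path.
#' @return numeric matrix with feature row names.
#' @export
read_count_matrix <- function(path) {
  df <- read_tsv_strict(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop2("non-numeric counts in ", path)
  rownames(m) <- df[[1]]
  m
}

#' Write a count or score matrix as TSV
#'
#' @param m matrix with row names.
#' @param path output path.
#' @param id_col name of the feature-ID column (default `feature_id`).
#' @export
write_count_matrix <- function(m, path, id_col = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv(df, path)
}

#' Write simulated ChIP samples in the pipeline's TSV schema
#'
#' Produces `chip_counts.tsv` (long table: sample_id, locus_id, ip_count,
#' input_count), `chip_samples.tsv` (sample sheet with spike totals) and
#' `chip_truth.tsv`.
#'
#' @param sim result of [simulate_chip()].
#' @param dir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_chip_tables <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts <- do.call(rbind, lapply(sim$samples, function(s) {
    data.frame(sample_id = s$sample_id, locus_id = names(s$ip_counts),
               ip_count = unname(s$ip_counts),
               input_count = unname(s$input_counts),
               stringsAsFactors = FALSE)
  }))
  sheet <- do.call(rbind, lapply(sim$samples, function(s) {
    data.frame(sample_id = s$sample_id, genotype = s$genotype,
               state = s$state, ip_spike_total = s$ip_spike_total,
               input_spike_total = s$input_spike_total,
               stringsAsFactors = FALSE)
  }))
  truth <- data.frame(locus_id = names(sim$truth$occupied),
                      occupied = unname(sim$truth$occupied),
                      base_score = unname(sim$truth$base_score),
                      effect = unname(sim$truth$effect),
                      stringsAsFactors = FALSE)
  paths <- c(counts = file.path(dir, "chip_counts.tsv"),
             samples = file.path(dir, "chip_samples.tsv"),
             truth = file.path(dir, "chip_truth.tsv"))
  write_tsv(counts, paths["counts"])
  write_tsv(sheet, paths["samples"])
  write_tsv(truth, paths["truth"])
  invisible(paths)
}

#' Read ChIP samples from the pipeline's TSV schema
#'
#' @param counts_path long count table (sample_id, locus_id, ip_count,
#'   input_count).
#' @param sheet_path sample sheet (sample_id, genotype, state,
#'   ip_spike_total, input_spike_total).
#' @return list of [chip_sample()] objects.
#' @export
read_chip_tables <- function(counts_path, sheet_path) {
  counts <- read_tsv_strict(counts_path)
  sheet <- read_tsv_strict(sheet_path)
  req_c <- c("sample_id", "locus_id", "ip_count", "input_count")
  req_s <- c("sample_id", "genotype", "state", "ip_spike_total",
             "input_spike_total")
  if (!all(req_c %in% names(counts))) {
    stop2(counts_path, " needs columns: ", paste(req_c, collapse = ", "))
  }
  if (!all(req_s %in% names(sheet))) {
    stop2(sheet_path, " needs columns: ", paste(req_s, collapse = ", "))
  }
  lapply(seq_len(nrow(sheet)), function(i) {
    sid <- sheet$sample_id[i]
    sub <- counts[counts$sample_id == sid, ]
    if (nrow(sub) == 0L) stop2("no counts for sample ", sid)
    chip_sample(sid, sheet$genotype[i], sheet$state[i],
                setNames(sub$ip_count, sub$locus_id),
                setNames(sub$input_count, sub$locus_id),
                sheet$ip_spike_total[i], sheet$input_spike_total[i])
  })
}
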