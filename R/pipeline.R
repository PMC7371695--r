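# Config-driven end-to-end runs over the analysis graph:
# chip scoring -> differential occupancy -> partitions/aggregation;
# rnaseq DE -> reverse cumulative curves; ribo NTC -> TE -> shift ->
# differential TE; enrichment overlap of the DE and TE gene sets.

PIPELINE_DEFAULTS <- list(
  alpha = 0.01,
  pseudocount = 0.5,
  quantiles = 5,
  cutoff = "mixture",
  lfc_min = 0.5,
  cpm_min = 1,
  seed = 1
)

KNOWN_KEYS <- c("inputs", "params", "output_dir")
KNOWN_INPUT_KEYS <- c("chip_counts", "chip_samples", "rnaseq_counts",
                      "rnaseq_groups", "rf_counts", "rna_counts",
                      "transcript_map", "ribo_groups", "catalog")

#' Validate a pipeline configuration file
#'
#' Reads a YAML config, rejects unknown keys (with a closest-match
#' suggestion), range-checks parameter values, and fills defaults
#' (`alpha = 0.01`, `pseudocount = 0.5`, `quantiles = 5`,
#' `cutoff = "mixture"`, `lfc_min = 0.5`, `cpm_min = 1`, `seed = 1`).
#' Referenced input paths must exist.
#'
#' @param path YAML config path.
#' @return validated config list of class `pol3_config`.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop2("config not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop2("config must be a YAML mapping")

  check_keys <- function(keys, known, where) {
    unknown <- setdiff(keys, known)
    if (length(unknown)) {
      hints <- vapply(unknown, function(k) {
        hit <- agrep(k, known, max.distance = 2, value = TRUE)
        if (length(hit)) paste0(" (did you mean '", hit[1], "'?)") else ""
      }, character(1))
      stop2("unknown ", where, " key(s): ",
            paste0(unknown, hints, collapse = ", "))
    }
  }
  check_keys(names(cfg), KNOWN_KEYS, "config")
  if (!is.null(cfg$inputs)) {
    check_keys(names(cfg$inputs), KNOWN_INPUT_KEYS, "inputs")
    for (k in names(cfg$inputs)) {
      if (!file.exists(cfg$inputs[[k]])) {
        stop2("input path for '", k, "' does not exist: ", cfg$inputs[[k]])
      }
    }
  }
  params <- cfg$params %||% list()
  check_keys(names(params), names(PIPELINE_DEFAULTS), "params")
  params <- modifyList(PIPELINE_DEFAULTS, params)
  if (params$alpha <= 0 || params$alpha >= 1) {
    stop2("alpha must be in (0, 1), got ", params$alpha)
  }
  if (params$pseudocount < 0) stop2("pseudocount must be >= 0")
  if (params$quantiles < 2) stop2("quantiles must be >= 2")
  if (!(is.numeric(params$cutoff) ||
        identical(params$cutoff, "mixture"))) {
    stop2("cutoff must be 'mixture' or a fixed numeric threshold")
  }
  if (params$lfc_min < 0 || params$cpm_min < 0) {
    stop2("lfc_min and cpm_min must be >= 0")
  }
  cfg$params <- params
  if (is.null(cfg$output_dir)) cfg$output_dir <- "pol3seq_out"
  structure(cfg, class = c("pol3_config", "list"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the analysis pipeline
#'
#' Executes the requested stages on the inputs named in the config and
#' writes TSV outputs plus a run manifest (config hash, package version,
#' per-stage output checksums and wall-clock times) to the output
#' directory. Deterministic stages are checksum-stable across re-runs.
#'
#' Stages: `chip` (scores, occupied calls, quantile classes, differential
#' occupancy), `rnaseq` (DE with the dual cut-off, reverse cumulative
#' curves of the selected genes), `ribo` (spike-anchored NTC, TE, global
#' shift, differential TE), `enrich` (overlap of the RNA-seq and TE
#' significant sets; requires rnaseq and ribo).
#'
#' @param config a `pol3_config` from [validate_config()].
#' @param stages character subset of
#'   `c("chip", "rnaseq", "ribo", "enrich")`.
#' @return the manifest list, invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config,
                         stages = c("chip", "rnaseq", "ribo", "enrich")) {
  if (!inherits(config, "pol3_config")) {
    stop2("config must come from validate_config()")
  }
  stages <- match.arg(stages, several.ok = TRUE)
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  p <- config$params
  inp <- config$inputs
  need <- function(key, stage) {
    if (is.null(inp[[key]])) {
      stop2("stage '", stage, "' needs input '", key, "'")
    }
    inp[[key]]
  }
  manifest <- list(
    package_version = as.character(packageVersion("pol3seq")),
    config_hash = config_hash(config),
    stages = list()
  )
  state <- new.env()

  log_msg <- function(...) {
    message(format(Sys.time(), "%H:%M:%S"), " [pol3seq] ", ...)
  }

  run_stage <- function(name, fun) {
    t0 <- Sys.time()
    log_msg("stage ", name, " started")
    files <- fun()
    elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    manifest$stages[[name]] <<- list(
      outputs = as.list(tools::md5sum(files)),
      seconds = round(elapsed, 3)
    )
    log_msg("stage ", name, " done (", round(elapsed, 2), "s)")
  }

  if ("chip" %in% stages) {
    run_stage("chip", function() {
      samples <- read_chip_tables(need("chip_counts", "chip"),
                                  need("chip_samples", "chip"))
      scores <- score_chip_samples(samples, p$pseudocount)
      cond <- attr(scores, "conditions")
      cutoff <- if (is.numeric(p$cutoff)) p$cutoff
                else estimate_occupancy_cutoff(as.vector(scores))$cutoff
      occupied <- scores >= cutoff
      classes <- assign_quantile_classes(scores[, 1], p$quantiles)
      occ_tab <- data.frame(locus_id = rownames(scores), scores,
                            occupied_any = apply(occupied, 1, any),
                            quantile_class = classes,
                            check.names = FALSE)
      f_occ <- file.path(out, "chip_occupancy.tsv")
      write_tsv(occ_tab, f_occ)
      groups <- factor(cond$genotype)
      res <- differential_occupancy(scores, groups, alpha = p$alpha,
                                    cutoff = cutoff)
      f_diff <- file.path(out, "chip_differential.tsv")
      write_tsv(res, f_diff)
      state$chip_scores <- scores
      c(f_occ, f_diff)
    })
  }

  if ("rnaseq" %in% stages) {
    run_stage("rnaseq", function() {
      counts <- read_count_matrix(need("rnaseq_counts", "rnaseq"))
      groups_df <- read_tsv_strict(need("rnaseq_groups", "rnaseq"))
      g <- groups_df$group[match(colnames(counts), groups_df$sample_id)]
      groups <- factor(g, levels = unique(g)) # level 1 = first listed
      de <- de_analysis(counts, groups, alpha = p$alpha,
                        lfc_min = p$lfc_min, cpm_min = p$cpm_min)
      f_de <- file.path(out, "rnaseq_de.tsv")
      write_tsv(de$results, f_de)
      f_sum <- file.path(out, "rnaseq_summary.json")
      jsonlite::write_json(de$summary, f_sum, auto_unbox = TRUE)
      sel <- de$results$feature_id[de$results$selected]
      files <- c(f_de, f_sum)
      if (length(sel) >= 2) {
        lev <- levels(groups)
        lcpm <- log_cpm(counts[rownames(counts) %in% sel, , drop = FALSE])
        vals <- list(rowMeans(lcpm[, groups == lev[1], drop = FALSE]),
                     rowMeans(lcpm[, groups == lev[2], drop = FALSE]))
        names(vals) <- lev
        rc <- reverse_cumulative(vals)
        f_rc <- file.path(out, "rnaseq_revcum.tsv")
        write_tsv(rc$curves, f_rc)
        files <- c(files, f_rc)
      }
      state$de <- de
      files
    })
  }

  if ("ribo" %in% stages) {
    run_stage("ribo", function() {
      rf <- read_count_matrix(need("rf_counts", "ribo"))
      rna <- read_count_matrix(need("rna_counts", "ribo"))
      map <- read_tsv_strict(need("transcript_map", "ribo"))
      groups_df <- read_tsv_strict(need("ribo_groups", "ribo"))
      g <- groups_df$group[match(colnames(rf), groups_df$sample_id)]
      groups <- factor(g, levels = unique(g)) # level 1 = first listed
      is_spike <- map$species[match(rownames(rf), map$transcript_id)] ==
        "spike"
      rf_n <- normalize_with_spike(rf, is_spike,
                                   pseudocount = p$pseudocount)
      rna_n <- normalize_with_spike(rna, is_spike,
                                    pseudocount = p$pseudocount)
      mouse <- !is_spike
      rf_g <- gene_scores(rf_n$ntc[mouse, , drop = FALSE], map)
      rna_g <- gene_scores(rna_n$ntc[mouse, , drop = FALSE], map)
      te <- translation_efficiency(rf_g, rna_g)
      f_te <- file.path(out, "ribo_te.tsv")
      write_count_matrix(te, f_te, id_col = "gene_id")
      lev <- levels(groups)
      shift <- global_te_shift(te[, groups == lev[1], drop = FALSE],
                               te[, groups == lev[2], drop = FALSE])
      f_shift <- file.path(out, "ribo_shift.json")
      jsonlite::write_json(shift, f_shift, auto_unbox = TRUE, digits = NA)
      dte <- differential_te(te, groups)
      f_dte <- file.path(out, "ribo_differential.tsv")
      write_tsv(dte, f_dte)
      state$dte <- dte
      c(f_te, f_shift, f_dte)
    })
  }

  if ("enrich" %in% stages) {
    run_stage("enrich", function() {
      if (is.null(state$de) || is.null(state$dte)) {
        stop2("stage 'enrich' needs the rnaseq and ribo stages in the ",
              "same run")
      }
      de_set <- state$de$results$feature_id[state$de$results$selected]
      te_set <- state$dte$feature_id[state$dte$sig_10]
      universe <- union(state$de$results$feature_id,
                        state$dte$feature_id)
      ov <- set_overlap_test(de_set, te_set, length(universe))
      f_ov <- file.path(out, "enrich_overlap.json")
      jsonlite::write_json(ov, f_ov, auto_unbox = TRUE, digits = NA)
      f_ov
    })
  }

  f_manifest <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, f_manifest, auto_unbox = TRUE)
  invisible(manifest)
}

# Stable hash of the validated config (paths + parameters).
config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(yaml::as.yaml(unclass(config)), tf)
  unname(tools::md5sum(tf))
}
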