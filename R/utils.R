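# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

stop2 <- function(...) stop(..., call. = FALSE)

assert_count_matrix <- function(counts, arg = "counts") {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop2(arg, " must be a numeric matrix")
  }
  if (any(!is.finite(counts))) stop2(arg, " contains non-finite values")
  if (any(counts < 0)) stop2(arg, " contains negative entries")
  invisible(counts)
}

# Two-level grouping factor aligned with the columns of a matrix.
check_groups <- function(groups, n_col, col_names = NULL) {
  groups <- as.factor(groups)
  if (length(groups) != n_col) {
    stop2("groups has length ", length(groups), " but there are ", n_col,
          " samples")
  }
  if (nlevels(droplevels(groups)) != 2L) {
    stop2("groups must have exactly 2 levels, got ",
          nlevels(droplevels(groups)))
  }
  droplevels(groups)
}

read_tsv_strict <- function(path, ...) {
  if (!file.exists(path)) stop2("file not found: ", path)
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE, quote = "", comment.char = "", ...)
}

write_tsv <- function(x, path, row_names = FALSE) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = row_names,
              col.names = TRUE)
  invisible(path)
}
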