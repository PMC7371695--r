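# Catalog of annotated pol III loci: tRNA genes (with isotype/anticodon),
# 5S and 4.5S rRNA genes, SINEs, type-3-promoter genes, and others.

GENE_CLASSES <- c("tRNA", "5S", "4.5S", "SINE", "type3", "other")

# 20 standard amino acids plus initiator Met and selenocysteine: the 22
# isotype classes, with iMet counted separately from elongator Met.
TRNA_ISOTYPES <- c(
  "Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His", "Ile",
  "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp", "Tyr", "Val",
  "iMet", "SeC"
)

#' Construct a pol III locus catalog
#'
#' @param loci data.frame with columns `locus_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `gene_class`, `isotype`, `anticodon`.
#' @return object of class `pol3_catalog`.
#' @export
pol3_catalog <- function(loci) {
  req <- c("locus_id", "chrom", "start", "end", "strand", "gene_class",
           "isotype", "anticodon")
  missing_cols <- setdiff(req, names(loci))
  if (length(missing_cols)) {
    stop2("catalog is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  loci <- loci[, req]
  if (anyDuplicated(loci$locus_id)) {
    dup <- unique(loci$locus_id[duplicated(loci$locus_id)])
    stop2("duplicate locus_id: ", paste(head(dup, 5), collapse = ", "))
  }
  if (nrow(loci) && any(loci$start >= loci$end)) {
    stop2("start must be < end for every locus")
  }
  bad_class <- setdiff(unique(loci$gene_class), GENE_CLASSES)
  if (length(bad_class)) {
    stop2("unknown gene_class: ", paste(bad_class, collapse = ", "))
  }
  is_trna <- loci$gene_class == "tRNA"
  if (any(is_trna & (is.na(loci$isotype) | is.na(loci$anticodon)))) {
    stop2("tRNA loci must have isotype and anticodon")
  }
  if (any(!is_trna & (!is.na(loci$isotype) | !is.na(loci$anticodon)))) {
    stop2("non-tRNA loci must have NA isotype and anticodon")
  }
  structure(list(loci = loci), class = "pol3_catalog")
}

#' @export
print.pol3_catalog <- function(x, ...) {
  cat("pol3_catalog with", nrow(x$loci), "loci\n")
  if (nrow(x$loci)) print(table(x$loci$gene_class))
  invisible(x)
}

#' @export
length.pol3_catalog <- function(x) nrow(x$loci)

#' Read a pol III locus catalog from a BED file
#'
#' Reads a BED6(+) file of pol III loci and classifies each record. If an
#' annotation table is supplied (`locus_id`, `gene_class`, `isotype`,
#' `anticodon`, tab-separated with a header), classes come from it —
#' this is how non-systematic locus abbreviations (e.g. "n-Ti16") are
#' resolved. Otherwise names of the form `tRNA-<isotype>-<anticodon>` are
#' parsed as tRNA genes, names containing `Rn5s`/`5S` as 5S genes,
#' `Rn4.5s`/`4.5S` as 4.5S genes, `SINE` as SINEs, and everything else is
#' classed `"other"`.
#'
#' @param bed_path path to a BED file with >= 6 columns and no header.
#' @param annotation_path optional annotation TSV as above.
#' @return a [pol3_catalog()].
#' @export
read_locus_catalog <- function(bed_path, annotation_path = NULL) {
  if (!file.exists(bed_path)) stop2("BED file not found: ", bed_path)
  lines <- readLines(bed_path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty BED file: returning an empty catalog")
    empty <- data.frame(locus_id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        strand = character(), gene_class = character(),
                        isotype = character(), anticodon = character(),
                        stringsAsFactors = FALSE)
    return(pol3_catalog(empty))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  rows <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) < 6L) {
      stop2("BED line ", i, ": expected >= 6 columns, got ", length(f))
    }
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end)) {
      stop2("BED line ", i, ": non-integer coordinates")
    }
    if (start >= end) {
      stop2("BED line ", i, ": start (", start, ") must be < end (", end, ")")
    }
    if (!f[6] %in% c("+", "-")) stop2("BED line ", i, ": bad strand '", f[6], "'")
    data.frame(locus_id = f[4], chrom = f[1], start = start, end = end,
               strand = f[6], stringsAsFactors = FALSE)
  })
  loci <- do.call(rbind, rows)
  if (anyDuplicated(loci$locus_id)) {
    dup <- unique(loci$locus_id[duplicated(loci$locus_id)])
    stop2("duplicate locus_id in BED: ", paste(head(dup, 5), collapse = ", "))
  }

  annot <- NULL
  if (!is.null(annotation_path)) {
    annot <- read_tsv_strict(annotation_path)
    req <- c("locus_id", "gene_class", "isotype", "anticodon")
    if (!all(req %in% names(annot))) {
      stop2("annotation TSV needs columns: ", paste(req, collapse = ", "))
    }
  }

  cls <- classify_locus_names(loci$locus_id, annot)
  loci$gene_class <- cls$gene_class
  loci$isotype <- cls$isotype
  loci$anticodon <- cls$anticodon
  pol3_catalog(loci)
}

classify_locus_names <- function(names, annot = NULL) {
  n <- length(names)
  gene_class <- rep("other", n)
  isotype <- rep(NA_character_, n)
  anticodon <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    nm <- names[i]
    if (!is.null(annot) && nm %in% annot$locus_id) {
      j <- match(nm, annot$locus_id)
      gene_class[i] <- annot$gene_class[j]
      iso <- annot$isotype[j]; ac <- annot$anticodon[j]
      isotype[i] <- if (is.na(iso) || !nzchar(iso)) NA_character_ else iso
      anticodon[i] <- if (is.na(ac) || !nzchar(ac)) NA_character_ else ac
    } else if (grepl("^tRNA-", nm)) {
      parsed <- parse_trna_name(nm)
      gene_class[i] <- "tRNA"
      isotype[i] <- parsed$isotype
      anticodon[i] <- parsed$anticodon
    } else if (grepl("Rn4\\.5s|4\\.5S", nm)) {
      gene_class[i] <- "4.5S"
    } else if (grepl("Rn5s|5S", nm, ignore.case = FALSE)) {
      gene_class[i] <- "5S"
    } else if (grepl("SINE", nm, ignore.case = TRUE)) {
      gene_class[i] <- "SINE"
    }
  }
  list(gene_class = gene_class, isotype = isotype, anticodon = anticodon)
}

#' Parse a tRNA gene name into isotype and anticodon
#'
#' Accepts the systematic dialect `tRNA-<isotype>-<anticodon>` (e.g.
#' `tRNA-Ile-TAT`), with `iMet` kept distinct from elongator `Met` and
#' `SeC` accepted for selenocysteine. Abbreviated catalog names (such as
#' `n-Ti16`) are not systematic and must be resolved through an annotation
#' table (`annotation` argument, a data.frame with `locus_id`, `isotype`,
#' `anticodon`).
#'
#' @param name gene name.
#' @param annotation optional lookup table for non-systematic names.
#' @return list with `isotype` and `anticodon`.
#' @export
parse_trna_name <- function(name, annotation = NULL) {
  if (!is.null(annotation) && name %in% annotation$locus_id) {
    j <- match(name, annotation$locus_id)
    return(list(isotype = annotation$isotype[j],
                anticodon = annotation$anticodon[j]))
  }
  m <- regmatches(name, regexec("^tRNA-([A-Za-z]{3,4})-([ACGTUacgtu]{3})$", name))[[1]]
  if (length(m) == 3L && m[2] %in% TRNA_ISOTYPES) {
    return(list(isotype = m[2], anticodon = toupper(m[3])))
  }
  stop2("unrecognized tRNA name '", name, "'. Accepted dialects: ",
        "'tRNA-<isotype>-<anticodon>' (isotype one of ",
        paste(TRNA_ISOTYPES, collapse = ", "),
        "), or an abbreviation resolvable via an annotation table")
}

#' Group catalog loci by isotype, isoacceptor or gene class
#'
#' tRNA loci are partitioned by the amino acid they carry (`isotype`;
#' initiator Met is its own class) or by anticodon within isotype
#' (`isoacceptor`). At `gene_class` level all loci are grouped.
#'
#' @param catalog a [pol3_catalog()].
#' @param level one of `"isotype"`, `"isoacceptor"`, `"gene_class"`.
#' @return named list mapping group name to character vector of locus IDs.
#' @export
group_loci <- function(catalog, level = c("isotype", "isoacceptor",
                                          "gene_class")) {
  if (!inherits(catalog, "pol3_catalog")) stop2("catalog must be a pol3_catalog")
  level <- match.arg(level)
  loci <- catalog$loci
  if (nrow(loci) == 0L) return(setNames(list(), character(0)))
  if (level == "gene_class") {
    return(split(loci$locus_id, loci$gene_class))
  }
  trna <- loci[loci$gene_class == "tRNA", , drop = FALSE]
  if (nrow(trna) == 0L) return(setNames(list(), character(0)))
  key <- if (level == "isotype") trna$isotype
         else paste(trna$isotype, trna$anticodon, sep = "-")
  split(trna$locus_id, key)
}

#' Write a catalog to its canonical TSV form
#'
#' @param catalog a [pol3_catalog()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  if (!inherits(catalog, "pol3_catalog")) stop2("catalog must be a pol3_catalog")
  write_tsv(catalog$loci, path)
}

#' Read a canonical catalog TSV written by [write_catalog()]
#'
#' @param path catalog TSV path.
#' @return a [pol3_catalog()].
#' @export
read_catalog_tsv <- function(path) {
  df <- read_tsv_strict(path, colClasses = c(
    locus_id = "character", chrom = "character", start = "integer",
    end = "integer", strand = "character", gene_class = "character",
    isotype = "character", anticodon = "character"
  ))
  pol3_catalog(df)
}
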