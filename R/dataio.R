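# Readers, writers and validators for the file formats the pipeline touches:
# tab-delimited gene x sample matrices, GCT 1.2, GMT gene-set collections,
# BED4 gene positions, and clinical / copy-number / protein tables.

#' Validate a gene-by-sample expression matrix
#'
#' Expression values are expected on the log2(RPM + 1) scale: finite and
#' non-negative, with unique gene and sample identifiers.
#'
#' @param x numeric matrix with gene ids as rownames and sample ids as
#'   colnames.
#' @param what label used in error messages.
#' @param min_value smallest admissible value (`0` for expression, `-Inf`
#'   for copy-number or protein tables).
#' @return the validated matrix, invisibly unchanged.
#' @export
validate_matrix <- function(x, what = "expression matrix", min_value = 0) {
  if (!is.matrix(x) || !is.numeric(x)) stopf("%s must be a numeric matrix", what)
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stopf("%s must carry gene rownames and sample colnames", what)
  }
  if (anyDuplicated(rownames(x))) stopf("%s has duplicate gene ids", what)
  if (anyDuplicated(colnames(x))) stopf("%s has duplicate sample ids", what)
  if (any(!is.finite(x))) stopf("%s contains non-finite values", what)
  if (min_value > -Inf && any(x < min_value)) {
    stopf("%s contains values below %g", what, min_value)
  }
  invisible(x)
}

#' Validate a clinical follow-up table
#'
#' @param x data.frame with columns `sample`, `time` (days, >= 0) and
#'   `event` (1 = death observed, 0 = censored).
#' @return the validated data.frame, invisibly.
#' @export
validate_clinical <- function(x) {
  need <- c("sample", "time", "event")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    stopf("clinical table needs columns: %s", paste(need, collapse = ", "))
  }
  if (anyDuplicated(x$sample)) stopf("clinical table has duplicate sample ids")
  if (any(!is.finite(x$time)) || any(x$time < 0)) {
    stopf("clinical times must be finite and >= 0")
  }
  if (!all(x$event %in% c(0, 1))) stopf("clinical event flags must be 0 or 1")
  invisible(x)
}

#' Validate a gene position table
#'
#' Positions are 1-based starts on chromosomes 1..22, X, Y.
#'
#' @param x data.frame with columns `gene`, `chrom`, `start`.
#' @return the validated data.frame, invisibly.
#' @export
validate_positions <- function(x) {
  need <- c("gene", "chrom", "start")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    stopf("position table needs columns: %s", paste(need, collapse = ", "))
  }
  if (anyDuplicated(x$gene)) stopf("position table has duplicate gene ids")
  normalize_chrom(x$chrom)
  if (any(!is.finite(x$start)) || any(x$start < 1)) {
    stopf("positions must be 1-based (start >= 1)")
  }
  invisible(x)
}

#' Validate a gene-set collection
#'
#' @param x named list of character vectors of gene ids.
#' @return the validated list, invisibly.
#' @export
validate_collection <- function(x) {
  if (!is.list(x) || is.null(names(x)) || any(names(x) == "")) {
    stopf("gene-set collection must be a fully named list")
  }
  if (anyDuplicated(names(x))) stopf("gene-set names must be unique")
  if (any(lengths(x) == 0)) stopf("gene sets must be non-empty")
  invisible(x)
}

read_delim_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stopf("malformed matrix file (need id column + samples): %s", path)
  ids <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(v) & !is.na(vals[[j]]))
    if (length(bad) > 0) {
      stopf("non-numeric cell at row %d, column '%s' in %s",
            bad[1], names(vals)[j], path)
    }
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  m
}

collapse_duplicate_genes <- function(m) {
  if (!anyDuplicated(rownames(m))) return(m)
  ids <- rownames(m)
  keep <- rep(TRUE, nrow(m))
  for (g in unique(ids[duplicated(ids)])) {
    rows <- which(ids == g)
    best <- rows[which.max(rowMeans(m[rows, , drop = FALSE]))]
    keep[setdiff(rows, best)] <- FALSE
  }
  warnf("collapsed %d duplicate gene row(s), keeping highest-mean row",
        sum(!keep))
  m[keep, , drop = FALSE]
}

#' Read a gene-by-sample expression matrix
#'
#' Reads either a plain tab-delimited matrix (first column gene ids, remaining
#' columns samples) or a GCT 1.2 file (the `Description` column is ignored).
#' Duplicate gene rows are collapsed by keeping the row with the highest mean,
#' with a warning.
#'
#' @param path file path.
#' @param dialect `"tsv"`, `"gct"`, or `"auto"` (sniff the `#1.2` magic line).
#' @return validated numeric matrix (genes x samples), values >= 0.
#' @export
read_expression <- function(path, dialect = c("auto", "tsv", "gct")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    first <- readLines(path, n = 1L)
    dialect <- if (startsWith(first, "#1.2")) "gct" else "tsv"
  }
  m <- if (dialect == "gct") read_gct(path) else read_delim_matrix(path)
  m <- collapse_duplicate_genes(m)
  validate_matrix(m, "expression matrix", min_value = 0)
  m
}

read_gct <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3 || !startsWith(lines[1], "#1.2")) {
    stopf("malformed GCT header (expected '#1.2'): %s", path)
  }
  dims <- suppressWarnings(as.integer(strsplit(lines[2], "\t")[[1]]))
  if (length(dims) < 2 || any(is.na(dims[1:2]))) {
    stopf("malformed GCT dims line: %s", path)
  }
  con <- textConnection(lines[-(1:2)])
  on.exit(close(con))
  df <- utils::read.delim(con, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) stopf("GCT needs Name, Description and sample columns: %s", path)
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  if (!is.numeric(m)) stopf("non-numeric GCT body: %s", path)
  rownames(m) <- as.character(df[[1]])
  if (nrow(m) != dims[1] || ncol(m) != dims[2]) {
    stopf("GCT dims line (%d x %d) disagrees with body (%d x %d)",
          dims[1], dims[2], nrow(m), ncol(m))
  }
  m
}

#' Write a gene-by-sample matrix
#'
#' Emits UTF-8, LF endings, full float precision (round-trip safe).
#'
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @param dialect `"tsv"` or `"gct"`.
#' @param id_name header for the gene-id column in the TSV dialect.
#' @export
write_matrix <- function(m, path, dialect = c("tsv", "gct"), id_name = "gene") {
  dialect <- match.arg(dialect)
  con <- file(path, open = "wb")
  on.exit(close(con))
  body <- apply(m, 1, function(r) paste(format(r, digits = 17, trim = TRUE,
                                               scientific = FALSE),
                                        collapse = "\t"))
  if (dialect == "gct") {
    writeLines(c("#1.2", paste(nrow(m), ncol(m), sep = "\t"),
                 paste(c("Name", "Description", colnames(m)), collapse = "\t"),
                 paste(rownames(m), "na", body, sep = "\t")),
               con, sep = "\n", useBytes = TRUE)
  } else {
    writeLines(c(paste(c(id_name, colnames(m)), collapse = "\t"),
                 paste(rownames(m), body, sep = "\t")),
               con, sep = "\n", useBytes = TRUE)
  }
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Each line: set name, description, then one or more gene ids, tab-delimited.
#' Genes repeated within a line are de-duplicated.
#'
#' @param path GMT file path.
#' @param source label stored as the collection's `source` attribute.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path, source = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) {
    stopf("GMT line %d has fewer than 3 fields in %s", short[1], path)
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  attr(sets, "description") <- vapply(fields, `[[`, "", 2L)
  attr(sets, "source") <- source
  validate_collection(sets)
  sets
}

#' Write a gene-set collection as GMT
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional per-set description field (defaults to "na").
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  validate_collection(sets)
  if (is.null(descriptions)) {
    descriptions <- attr(sets, "description") %||% rep("na", length(sets))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, ""), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a clinical follow-up table
#'
#' Expects tab-delimited columns `sample`, `time` (days since diagnosis) and
#' `event` (1 = death observed, 0 = censored at last visit).
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  validate_clinical(df)
  df[, c("sample", "time", "event")]
}

#' Write a clinical table
#' @param clinical data.frame with `sample`, `time`, `event`.
#' @param path output path.
#' @export
write_clinical <- function(clinical, path) {
  validate_clinical(clinical)
  write_tsv_lf(clinical[, c("sample", "time", "event")], path)
}

#' Read gene positions from a BED4 file
#'
#' BED starts are 0-based half-open; the returned table carries 1-based starts
#' (`start = bed_start + 1`), so a gene whose BED start is 21,077,103 begins at
#' nucleotide 21,077,104. "chr" prefixes are stripped; strand is ignored.
#'
#' @param path BED file (chrom, start, end, name).
#' @return data.frame with columns `gene`, `chrom`, `start` (1-based).
#' @export
read_positions <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4) stopf("BED4 needs chrom, start, end, name columns: %s", path)
  out <- data.frame(gene = as.character(df[[4]]),
                    chrom = normalize_chrom(df[[1]]),
                    start = as.numeric(df[[2]]) + 1,
                    stringsAsFactors = FALSE)
  validate_positions(out)
  out
}

#' Write gene positions as BED4
#'
#' Inverse of [read_positions()]: 1-based starts are converted back to 0-based
#' BED starts with a 1-nucleotide interval.
#'
#' @param positions data.frame with `gene`, `chrom`, `start`.
#' @param path output path.
#' @export
write_positions <- function(positions, path) {
  validate_positions(positions)
  bed <- data.frame(chrom = positions$chrom,
                    start = format(positions$start - 1, scientific = FALSE,
                                   trim = TRUE),
                    end = format(positions$start, scientific = FALSE,
                                 trim = TRUE),
                    name = positions$gene)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(do.call(paste, c(bed, sep = "\t")), con, sep = "\n",
             useBytes = TRUE)
  invisible(path)
}

#' Read a gene-level copy-number (or protein) table
#'
#' GISTIC2-style gene x sample numeric values; 0 is copy-neutral on the
#' log2-ratio scale, so negative values are allowed.
#'
#' @param path tab-delimited file, first column gene ids.
#' @return validated numeric matrix.
#' @export
read_cnv <- function(path) {
  m <- read_delim_matrix(path)
  m <- collapse_duplicate_genes(m)
  validate_matrix(m, "copy-number table", min_value = -Inf)
  m
}

#' Write a copy-number (or protein) table
#' @param m numeric matrix.
#' @param path output path.
#' @export
write_cnv <- function(m, path) {
  validate_matrix(m, "copy-number table", min_value = -Inf)
  write_matrix(m, path, dialect = "tsv")
}

write_tsv_lf <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) format(v, digits = 17, trim = TRUE,
                                                scientific = FALSE))
  writeLines(c(paste(names(df), collapse = "\t"),
               do.call(paste, c(df, sep = "\t"))),
             con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Intersect the samples of an expression matrix and a clinical table
#'
#' Samples present in only one input are dropped (never imputed); the dropped
#' counts are reported with a message.
#'
#' @param expr expression matrix.
#' @param clinical clinical data.frame.
#' @return list with aligned `expr` and `clinical`.
#' @export
intersect_samples <- function(expr, clinical) {
  validate_clinical(clinical)
  common <- intersect(colnames(expr), clinical$sample)
  if (length(common) == 0) stopf("no samples shared by expression and clinical")
  drop_e <- ncol(expr) - length(common)
  drop_c <- nrow(clinical) - length(common)
  if (drop_e + drop_c > 0) {
    message(sprintf("sample intersection: dropped %d expression-only, %d clinical-only",
                    drop_e, drop_c))
  }
  list(expr = expr[, common, drop = FALSE],
       clinical = clinical[match(common, clinical$sample), , drop = FALSE])
}
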