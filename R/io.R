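# TSV dialect used throughout: tab-separated, UTF-8, '.' decimal, mandatory
# header row; lines starting with '#' are provenance comments and ignored on
# read.

.readTsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read a sequence-level count table (and optional sample metadata)
#'
#' The counts file must have columns `seq_id`, `locus`, optionally
#' `sequence`, followed by one integer column per sample. Malformed content
#' (missing columns, non-integer or negative counts, duplicate sequence IDs)
#' raises an error naming the offending rows.
#'
#' @param path counts TSV path.
#' @param samplesPath optional sample-metadata TSV (see [readSampleTable()]).
#' @return a raw sequence-level [MirCountSet-class].
#' @export
readCountTable <- function(path, samplesPath = NULL) {
  df <- .readTsv(path)
  need <- c("seq_id", "locus")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("counts file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  meta <- intersect(c("seq_id", "locus", "sequence"), colnames(df))
  sampleCols <- setdiff(colnames(df), meta)
  if (!length(sampleCols)) stop("counts file has no sample columns")
  dup <- df$seq_id[duplicated(df$seq_id)]
  if (length(dup))
    stop("duplicate sequence IDs: ", paste(unique(dup), collapse = ", "))
  bad <- which(!nzchar(df$locus) | is.na(df$locus))
  if (length(bad))
    stop("empty locus ID at data row(s): ", paste(bad, collapse = ", "))
  m <- as.matrix(df[sampleCols])
  if (!is.numeric(m) || anyNA(m) || any(m < 0) ||
      any(abs(m - round(m)) > 1e-8)) {
    offenders <- which(apply(df[sampleCols], 1, function(r) {
      v <- suppressWarnings(as.numeric(r))
      anyNA(v) || any(v < 0) || any(abs(v - round(v)) > 1e-8)
    }))
    stop("non-integer or negative counts at data row(s): ",
         paste(offenders, collapse = ", "))
  }
  storage.mode(m) <- "integer"
  rownames(m) <- df$seq_id
  samples <- if (!is.null(samplesPath)) readSampleTable(samplesPath) else NULL
  x <- MirCountSet(m, sampleData = samples, locus = df$locus)
  if ("sequence" %in% colnames(df)) rowData(x)$sequence <- df$sequence
  x
}

#' Write a sequence-level count table
#'
#' Inverse of [readCountTable()]: `writeCountTable` then `readCountTable`
#' reproduces the counts, locus assignment and sequence strings exactly.
#'
#' @param x a sequence-level `MirCountSet` with raw counts.
#' @param path output TSV path.
#' @param comment optional provenance line written as a leading `#` comment.
#' @export
writeCountTable <- function(x, path, comment = NULL) {
  stopifnot(is(x, "MirCountSet"))
  df <- data.frame(seq_id = rownames(x),
                   locus = rowData(x)$locus,
                   check.names = FALSE)
  if ("sequence" %in% colnames(rowData(x)))
    df$sequence <- rowData(x)$sequence
  df <- cbind(df, as.data.frame(assay(x, "counts"), check.names = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write per-sample metadata
#'
#' Metadata TSVs require columns `sample_id`, `group` and `mappable_reads`;
#' `sex`, `age` and `prep_batch` are carried when present. Group labels must
#' cover exactly two classes and mappable-read totals must be positive.
#'
#' @param path TSV path.
#' @return `readSampleTable`: a `data.frame` keyed by `sample_id`.
#' @export
readSampleTable <- function(path) {
  df <- .readTsv(path)
  need <- c("sample_id", "group", "mappable_reads")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("sample table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample IDs in ", path)
  if (length(unique(df$group)) != 2L)
    stop("group labels must cover exactly two classes")
  if (anyNA(df$mappable_reads) || any(df$mappable_reads <= 0))
    stop("mappable_reads must be positive")
  df
}

#' @rdname readSampleTable
#' @param samples a `data.frame` of sample metadata (or the `colData` of a
#'   `MirCountSet`).
#' @param comment optional provenance comment line.
#' @export
writeSampleTable <- function(samples, path, comment = NULL) {
  df <- as.data.frame(samples)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a (normalized) expression matrix
#'
#' Locus- or sequence-level matrices are written as `id` plus one column per
#' sample, with the normalization tag and level preserved in a `#` header
#' comment so that `readExpressionMatrix` restores the object state.
#'
#' @param x a `MirCountSet`.
#' @param path TSV path.
#' @export
writeExpressionMatrix <- function(x, path) {
  stopifnot(is(x, "MirCountSet"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# exomiR expression matrix; level=%s; normalization=%s",
                     exprLevel(x), normMethod(x)), con)
  df <- data.frame(id = rownames(x), locus = rowData(x)$locus,
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(assay(x, "counts"), check.names = FALSE))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeExpressionMatrix
#' @param samples optional sample metadata `data.frame` to attach.
#' @export
readExpressionMatrix <- function(path, samples = NULL) {
  first <- readLines(path, n = 1L)
  level <- sub(".*level=([a-z]+).*", "\\1", first)
  norm <- sub(".*normalization=([a-z_]+).*", "\\1", first)
  if (!level %in% c("sequence", "locus")) level <- "locus"
  if (!norm %in% c("raw", "cpm_mappable", "spike_geomean")) norm <- "raw"
  df <- .readTsv(path)
  m <- as.matrix(df[setdiff(colnames(df), c("id", "locus"))])
  rownames(m) <- df$id
  MirCountSet(m, sampleData = samples, locus = df$locus,
              normalization = norm, level = level)
}
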