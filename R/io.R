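# Reading and writing view matrices as delimited text.

.missing_markers <- c("", "NA", "NaN", "na", "nan", "Na", "NAN", "Nan")

.infer_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an omics view from a delimited matrix file
#'
#' Expects a features x samples layout: the first row holds sample IDs, the
#' first column feature IDs. Empty cells, `NA` and `NaN` (any case) are read
#' as missing and left unimputed; run [filter_missing()] afterwards. The
#' header row may or may not carry a corner label for the feature-ID column.
#'
#' @param path path to a TSV or CSV file; the delimiter is inferred from the
#'   extension (`.csv` -> comma, otherwise tab) unless `sep` is given.
#' @param name,modality passed to [omics_view()].
#' @param sep optional field delimiter override.
#' @return an [omics_view()] with missing entries recorded as `NA`.
#' @export
read_view <- function(path, name = basename(path),
                      modality = c("other", "sequence_expression",
                                   "methylation_beta", "protein"),
                      sep = NULL) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .infer_sep(path, sep)
  hdr <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1L]]
  body <- utils::read.table(path, sep = sep, skip = 1L, header = FALSE,
                            colClasses = "character", quote = "\"",
                            comment.char = "", check.names = FALSE)
  nfield <- ncol(body)
  sample_ids <- if (length(hdr) == nfield) hdr[-1L]
  else if (length(hdr) == nfield - 1L) hdr
  else stop("header has ", length(hdr), " fields but data rows have ", nfield)
  feature_ids <- body[[1L]]
  vals <- as.matrix(body[, -1L, drop = FALSE])
  vals[trimws(vals) %in% .missing_markers] <- NA
  X <- matrix(NA_real_, nrow(vals), ncol(vals))
  suppressWarnings(X[] <- as.numeric(vals))
  bad <- which(is.na(X) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-numeric cell at data row ", bad[1L, 1L], ", column ", bad[1L, 2L],
         ": '", vals[bad[1L, , drop = FALSE]], "'")
  }
  omics_view(X, name = name, modality = modality,
             feature_ids = feature_ids, sample_ids = sample_ids)
}

#' Write an omics view to a delimited matrix file
#'
#' Inverse of [read_view()]: features x samples with a corner-labelled header
#' row. Missing entries are written as `NA`.
#'
#' @param view an [omics_view()].
#' @param path output path; delimiter inferred from extension unless `sep`
#'   is given.
#' @param sep optional field delimiter override.
#' @return `path`, invisibly.
#' @export
write_view <- function(view, path, sep = NULL) {
  stopifnot(inherits(view, "omics_view"))
  sep <- .infer_sep(path, sep)
  utils::write.table(view$X, path, sep = sep, quote = FALSE,
                     col.names = NA, row.names = TRUE, na = "NA")
  invisible(path)
}
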