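#' Construct an omics view
#'
#' An omics view is one molecular data layer (mRNA expression, miRNA
#' expression, DNA methylation beta values, protein abundance, ...) measured
#' on a common set of samples, stored as a features x samples numeric matrix
#' with unique feature and sample identifiers.
#'
#' @param X numeric matrix, features in rows and samples in columns. Missing
#'   values may be present before preprocessing (`NA`).
#' @param name short text label for the view (e.g. `"mRNA"`).
#' @param modality one of `"sequence_expression"`, `"methylation_beta"`,
#'   `"protein"`, `"other"`. Sequence-based expression views are eligible for
#'   [log_transform()]; methylation beta values must lie in \[0, 1\].
#' @param feature_ids,sample_ids character vectors of unique identifiers;
#'   default to the dimnames of `X`.
#' @param is_logged logical; whether the view has already been log-transformed.
#'
#' @return an object of class `omics_view`: a list with elements `X`, `name`,
#'   `modality`, `feature_ids`, `sample_ids`, `is_logged`.
#' @seealso [read_view()], [filter_missing()], [log_transform()],
#'   [variance_filter()], [align_samples()]
#' @export
omics_view <- function(X, name = "view",
                       modality = c("other", "sequence_expression",
                                    "methylation_beta", "protein"),
                       feature_ids = rownames(X), sample_ids = colnames(X),
                       is_logged = FALSE) {
  modality <- match.arg(modality)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(nrow(X)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(X)))
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(feature_ids) != nrow(X)) {
    stop("feature_ids length (", length(feature_ids), ") does not match nrow(X) (", nrow(X), ")")
  }
  if (length(sample_ids) != ncol(X)) {
    stop("sample_ids length (", length(sample_ids), ") does not match ncol(X) (", ncol(X), ")")
  }
  dup <- feature_ids[duplicated(feature_ids)]
  if (length(dup)) stop("duplicated feature ID(s): ", paste(unique(dup), collapse = ", "))
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup)) stop("duplicated sample ID(s): ", paste(unique(dup), collapse = ", "))
  if (modality == "methylation_beta") {
    rng <- range(X, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 1) {
      stop("methylation_beta view '", name, "' has entries outside [0, 1]")
    }
  }
  dimnames(X) <- list(feature_ids, sample_ids)
  structure(list(X = X, name = name, modality = modality,
                 feature_ids = feature_ids, sample_ids = sample_ids,
                 is_logged = is_logged),
            class = "omics_view")
}

#' @export
print.omics_view <- function(x, ...) {
  cat("omics view '", x$name, "' (", x$modality, "): ",
      nrow(x$X), " features x ", ncol(x$X), " samples",
      if (x$is_logged) ", log10-transformed" else "",
      "\n", sep = "")
  nmiss <- sum(!is.finite(x$X))
  if (nmiss > 0) cat("  ", nmiss, " missing entries (not yet imputed)\n", sep = "")
  invisible(x)
}

#' @export
dim.omics_view <- function(x) dim(x$X)

#' Bundle sample-matched omics views into a multi-omics dataset
#'
#' All views must cover the same samples in the same order (use
#' [align_samples()] first if they do not).
#'
#' @param views list of [omics_view()] objects with identical `sample_ids`.
#' @return an object of class `multi_omics_dataset` with elements `views`
#'   (named list), `sample_ids`, `n` (number of samples) and `M` (number of
#'   views).
#' @export
multi_omics_dataset <- function(views) {
  if (inherits(views, "omics_view")) views <- list(views)
  stopifnot(length(views) >= 1L)
  for (v in views) {
    if (!inherits(v, "omics_view")) stop("all elements must be omics_view objects")
  }
  ids <- views[[1L]]$sample_ids
  if (length(ids) < 2L) stop("need at least 2 samples")
  for (v in views[-1L]) {
    if (!identical(v$sample_ids, ids)) {
      stop("view '", v$name, "' has sample IDs differing from view '",
           views[[1L]]$name, "'; run align_samples() first")
    }
  }
  names(views) <- vapply(views, function(v) v$name, character(1L))
  structure(list(views = views, sample_ids = ids,
                 n = length(ids), M = length(views)),
            class = "multi_omics_dataset")
}

#' @export
print.multi_omics_dataset <- function(x, ...) {
  cat("multi-omics dataset: ", x$M, " view(s), ", x$n, " samples\n", sep = "")
  for (v in x$views) {
    cat("  - ", v$name, " (", v$modality, "): ", nrow(v$X), " features\n", sep = "")
  }
  invisible(x)
}
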