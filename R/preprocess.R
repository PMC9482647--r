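# Preprocessing rules applied per view before graph construction:
# missing-value filter -> log transform (sequence expression only) ->
# variance filter, then sample alignment across views.

#' Drop features with too many missing values, zero-impute the rest
#'
#' Features whose fraction of missing entries exceeds `max_missing_frac` are
#' removed; the remaining missing entries are replaced with 0. Feature order
#' is otherwise preserved. The filter is applied per view independently.
#'
#' @param view an [omics_view()].
#' @param max_missing_frac maximum tolerated per-feature missing fraction
#'   (default 0.05, i.e. features with more than 5% missing are dropped).
#' @return the filtered [omics_view()] with all entries finite.
#' @export
filter_missing <- function(view, max_missing_frac = 0.05) {
  stopifnot(inherits(view, "omics_view"))
  miss <- !is.finite(view$X)
  frac <- rowMeans(miss)
  keep <- frac <= max_missing_frac
  if (!any(keep)) stop("no features survive missing filter in view '", view$name, "'")
  X <- view$X[keep, , drop = FALSE]
  X[!is.finite(X)] <- 0
  omics_view(X, name = view$name, modality = view$modality,
             feature_ids = view$feature_ids[keep], sample_ids = view$sample_ids,
             is_logged = view$is_logged)
}

#' Base-10 log transform of sequence-based expression values
#'
#' Zero entries are replaced with 1 before taking `log10`, so both 0 and 1
#' map to 0 (a deliberate collapse: the transform is monotone on the
#' remaining values). Only views flagged `sequence_expression` are eligible;
#' methylation beta values are left on their natural scale.
#'
#' @param view an [omics_view()] with `modality = "sequence_expression"`,
#'   nonnegative entries and `is_logged = FALSE`.
#' @return the transformed [omics_view()] with `is_logged = TRUE`.
#' @export
log_transform <- function(view) {
  stopifnot(inherits(view, "omics_view"))
  if (view$modality != "sequence_expression") {
    stop("log_transform applies only to sequence_expression views, not '",
         view$modality, "'")
  }
  if (isTRUE(view$is_logged)) stop("view '", view$name, "' is already log-transformed")
  if (any(view$X < 0, na.rm = TRUE)) {
    stop("negative entries in view '", view$name, "': cannot log-transform")
  }
  X <- view$X
  X[X == 0] <- 1
  X <- log10(X)
  omics_view(X, name = view$name, modality = view$modality,
             feature_ids = view$feature_ids, sample_ids = view$sample_ids,
             is_logged = TRUE)
}

#' Keep the most variable features
#'
#' Retains the `top_n` features by sample variance (denominator n - 1) across
#' samples; ties at the boundary are broken by original feature order, and
#' kept features retain their original relative order. If `top_n` is at least
#' the number of features the view is returned unchanged.
#'
#' @param view an [omics_view()] with finite entries.
#' @param top_n number of features to keep (default 2000, the conventional
#'   cut for expression and CpG methylation views).
#' @return the filtered [omics_view()].
#' @export
variance_filter <- function(view, top_n = 2000L) {
  stopifnot(inherits(view, "omics_view"), top_n >= 1L)
  d <- nrow(view$X)
  if (top_n >= d) return(view)
  mu <- rowMeans(view$X)
  v <- rowSums((view$X - mu)^2) / (ncol(view$X) - 1L)
  keep <- sort(order(v, decreasing = TRUE)[seq_len(top_n)])
  omics_view(view$X[keep, , drop = FALSE], name = view$name,
             modality = view$modality, feature_ids = view$feature_ids[keep],
             sample_ids = view$sample_ids, is_logged = view$is_logged)
}

#' Restrict views to their common samples
#'
#' Intersects the sample IDs of all views and reorders every view to the
#' order in which the surviving IDs appear in the first view.
#'
#' @param views list of [omics_view()] objects (at least one).
#' @return a [multi_omics_dataset()].
#' @export
align_samples <- function(views) {
  if (inherits(views, "omics_view")) views <- list(views)
  stopifnot(length(views) >= 1L)
  common <- Reduce(intersect, lapply(views, function(v) v$sample_ids))
  if (length(common) == 0L) stop("no samples shared by all views")
  ids <- views[[1L]]$sample_ids[views[[1L]]$sample_ids %in% common]
  aligned <- lapply(views, function(v) {
    j <- match(ids, v$sample_ids)
    omics_view(v$X[, j, drop = FALSE], name = v$name, modality = v$modality,
               feature_ids = v$feature_ids, sample_ids = ids,
               is_logged = v$is_logged)
  })
  multi_omics_dataset(aligned)
}

#' Standard preprocessing pipeline for one view
#'
#' Convenience wrapper applying, in order: [filter_missing()],
#' [log_transform()] (only when `log` is `TRUE` and the view is unlogged
#' sequence expression), and [variance_filter()].
#'
#' @param view an [omics_view()].
#' @param max_missing_frac passed to [filter_missing()].
#' @param log whether to log-transform sequence-expression views.
#' @param top_n passed to [variance_filter()].
#' @return the preprocessed [omics_view()].
#' @export
preprocess_view <- function(view, max_missing_frac = 0.05, log = NULL,
                            top_n = 2000L) {
  v <- filter_missing(view, max_missing_frac)
  do_log <- log %||% (v$modality == "sequence_expression" && !v$is_logged)
  if (isTRUE(do_log)) v <- log_transform(v)
  variance_filter(v, top_n)
}
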