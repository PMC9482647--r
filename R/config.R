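# End-to-end orchestration from a plain-text (YAML) run configuration, and
# writers for the result artefacts. A thin command-line wrapper lives at
# inst/exec/risyng.

#' Run the full pipeline from a configuration file
#'
#' The configuration is a YAML document:
#' \preformatted{
#' k: 3
#' seed: 42
#' alpha: 0.1            # optional; any risyng_control() field may appear
#' views:
#'   - name: mrna
#'     path: mrna.tsv
#'     modality: sequence_expression
#'     log_transform: true     # optional; defaults by modality
#'     top_n: 2000             # optional variance-filter cut
#'   - name: meth
#'     path: meth.csv
#'     modality: methylation_beta
#' }
#' Views are read, preprocessed (missing filter, optional log transform,
#' variance filter), sample-aligned, and clustered by [risyng()]. All
#' effective parameters are echoed into the run log.
#'
#' @param config path to the YAML configuration, or an already-parsed list.
#' @param out_dir optional directory; when given, [write_results()] is called.
#' @param quiet suppress the run log on stderr.
#' @return the [risyng()] fit, invisibly when `out_dir` is given.
#' @export
run_from_config <- function(config, out_dir = NULL, quiet = FALSE) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    yaml::read_yaml(config)
  } else config
  if (is.null(cfg$k)) stop("config must set k")
  if (is.null(cfg$views) || length(cfg$views) == 0L) stop("config must list views")
  seed <- as.integer(cfg$seed %||% 1L)
  ctrl_fields <- intersect(names(cfg), names(formals(risyng_control)))
  control <- do.call(risyng_control, cfg[ctrl_fields])
  log_msg <- function(...) if (!quiet) message("[risyng] ", ...)
  log_msg("k = ", cfg$k, ", seed = ", seed, ", ",
          paste(names(unlist(control)), unlist(control), sep = "=", collapse = ", "))
  base <- if (is.character(config)) dirname(config) else "."
  views <- lapply(cfg$views, function(v) {
    if (is.null(v$path)) stop("every view needs a path")
    path <- if (file.exists(v$path)) v$path else file.path(base, v$path)
    vw <- read_view(path, name = v$name %||% basename(v$path),
                    modality = v$modality %||% "other", sep = v$sep)
    log_msg("view '", vw$name, "': ", nrow(vw$X), " x ", ncol(vw$X))
    preprocess_view(vw,
                    max_missing_frac = v$max_missing_frac %||% 0.05,
                    log = v$log_transform,
                    top_n = v$top_n %||% 2000L)
  })
  dataset <- align_samples(views)
  log_msg(dataset$n, " aligned samples across ", dataset$M, " views")
  fit <- risyng(dataset, k = as.integer(cfg$k), seed = seed, control = control)
  if (!is.null(out_dir)) {
    write_results(fit, out_dir)
    log_msg("results written to ", out_dir)
    return(invisible(fit))
  }
  fit
}

#' Write clustering results to a directory
#'
#' Writes `labels.tsv` (sample_id, cluster), `diagnostics.tsv` (one row per
#' view: name, beta, silhouette, rank) and `basis.tsv` (the n x k accretive
#' basis, the final sample embedding).
#'
#' @param fit a [risyng()] fit.
#' @param out_dir output directory, created if absent.
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(fit, out_dir) {
  stopifnot(inherits(fit, "risyng"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  labels <- data.frame(sample_id = names(fit$labels), cluster = unname(fit$labels))
  utils::write.table(labels, file.path(out_dir, "labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fit$per_view, file.path(out_dir, "diagnostics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  basis <- fit$basis
  rownames(basis) <- names(fit$labels)
  colnames(basis) <- paste0("dim", seq_len(ncol(basis)))
  utils::write.table(basis, file.path(out_dir, "basis.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  invisible(out_dir)
}

#' Evaluate a partition with every applicable validity index
#'
#' Computes the internal indices when `points` is given and the external
#' indices when `truth` is given, mirroring the layout of a comparative
#' cluster-analysis table.
#'
#' @param labels predicted cluster labels.
#' @param truth optional reference labels.
#' @param points optional n x d matrix the internal indices are computed on
#'   (e.g. the accretive basis, or an original view).
#' @return one-row data frame of index values.
#' @export
evaluate_partition <- function(labels, truth = NULL, points = NULL) {
  out <- list()
  if (!is.null(points)) {
    points <- as.matrix(points)
    out$silhouette <- silhouette_index(points, labels)
    out$dunn <- dunn_index(points, labels)
    out$davies_bouldin <- tryCatch(davies_bouldin(points, labels),
                                   error = function(e) NA_real_)
    out$xie_beni <- tryCatch(xie_beni(points, labels),
                             error = function(e) NA_real_)
  }
  if (!is.null(truth)) {
    pp <- partition_pair(labels, truth)
    out$f_measure <- f_measure(pp)
    out$ari <- adjusted_rand(pp)
    out$nmi <- nmi(pp)
    out$jaccard <- jaccard_index(pp)
    out$purity <- purity(pp)
  }
  if (length(out) == 0L) stop("supply points and/or truth")
  as.data.frame(out)
}
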