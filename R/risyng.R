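#' Control parameters for a RISynG fit
#'
#' @param alpha beta-grid step in (0, 1); 0.1 scans 11 values including both
#'   endpoints.
#' @param eig_mode which end of the synergy spectrum to embed: `"smallest"`
#'   (the algorithmic default; the shifted Laplacian places the informative
#'   eigenvectors there) or `"largest"`.
#' @param scale_factor heat-kernel bandwidth multiplier (1 divides distances
#'   by their maximum; 0.5 uses half the maximum).
#' @param gramian_squared square the Gramian's exponential factor.
#' @param zero_diagonal drop self-similarities before the Laplacian.
#' @param use_shifted_laplacian combine the Gramian with the shifted
#'   Laplacian (default) rather than the raw normalised Laplacian.
#' @param literal_power use the plain elementwise power in the relevance
#'   attenuation instead of the sign-preserving one.
#' @param reorthonormalize re-orthonormalise the accretive basis after each
#'   merge.
#' @param beta_restarts k-means restarts inside the provisional beta scan.
#' @param kmeans_restarts k-means restarts for the final clustering.
#' @param t_max k-means iteration cap.
#' @return a named list of class `risyng_control`.
#' @export
risyng_control <- function(alpha = 0.1,
                           eig_mode = c("smallest", "largest"),
                           scale_factor = 1,
                           gramian_squared = FALSE,
                           zero_diagonal = FALSE,
                           use_shifted_laplacian = TRUE,
                           literal_power = FALSE,
                           reorthonormalize = FALSE,
                           beta_restarts = 10L,
                           kmeans_restarts = 50L,
                           t_max = 300L) {
  eig_mode <- match.arg(eig_mode)
  stopifnot(alpha > 0, alpha < 1, scale_factor > 0, t_max >= 1L,
            beta_restarts >= 1L, kmeans_restarts >= 1L)
  structure(list(alpha = alpha, eig_mode = eig_mode,
                 scale_factor = scale_factor,
                 gramian_squared = isTRUE(gramian_squared),
                 zero_diagonal = isTRUE(zero_diagonal),
                 use_shifted_laplacian = isTRUE(use_shifted_laplacian),
                 literal_power = isTRUE(literal_power),
                 reorthonormalize = isTRUE(reorthonormalize),
                 beta_restarts = as.integer(beta_restarts),
                 kmeans_restarts = as.integer(kmeans_restarts),
                 t_max = as.integer(t_max)),
            class = "risyng_control")
}

#' Integrative multi-omics clustering by recursive synergy integration
#'
#' Fits the full pipeline on preprocessed, sample-aligned views: per view,
#' the correlation-kernel Gramian and the shifted normalised Laplacian are
#' built and fused into a synergy matrix whose mixing weight beta is chosen
#' by a provisional silhouette scan; views are ranked by that silhouette;
#' the relevance-ordered eigenbases are merged into an accretive basis by
#' recursive orthogonalise-normalise-attenuate updates; and k-means on the
#' rows of the final basis yields the sample clusters. Fully deterministic
#' given `seed`.
#'
#' @param data a [multi_omics_dataset()], a list of [omics_view()] objects
#'   sharing sample IDs, or a list of features x samples matrices.
#' @param k number of clusters (>= 2).
#' @param seed master integer seed; every stochastic step (per-view beta
#'   scan, final k-means) draws a named substream from it.
#' @param control a [risyng_control()] list.
#' @return an object of class `risyng`: list with `labels` (named integer
#'   vector in 1..k), `basis` (n x k accretive basis, the final sample
#'   embedding), `per_view` (data frame: view, beta, silhouette, rank),
#'   `views` (ranked `synergy_view` list), `k`, `seed`, `control`, `call`.
#' @examples
#' sim <- make_multiview(synthetic_spec(n = 60, k = 2, views = list(
#'   list(d = 40, separation = 6), list(d = 30, separation = 6)), seed = 7))
#' fit <- risyng(sim$dataset, k = 2, seed = 7)
#' table(fit$labels, sim$labels)
#' @export
risyng <- function(data, k, seed = 1L, control = risyng_control()) {
  cl <- match.call()
  if (!inherits(data, "multi_omics_dataset")) {
    if (is.matrix(data)) data <- list(data)
    if (is.list(data)) {
      data <- lapply(seq_along(data), function(i) {
        v <- data[[i]]
        if (inherits(v, "omics_view")) v
        else omics_view(as.matrix(v), name = names(data)[i] %||% paste0("view", i))
      })
      data <- multi_omics_dataset(data)
    } else stop("data must be a multi_omics_dataset, a list of views, or a matrix")
  }
  stopifnot(inherits(control, "risyng_control"))
  if (k < 2L) stop("k must be at least 2")
  if (k >= data$n) stop("k (", k, ") must be smaller than the number of samples (", data$n, ")")

  svs <- lapply(data$views, function(v) {
    rep <- build_representations(v, scale_factor = control$scale_factor,
                                 gramian_squared = control$gramian_squared,
                                 zero_diagonal = control$zero_diagonal)
    L <- if (control$use_shifted_laplacian) rep$Lmod else rep$Lnorm
    select_beta(rep$G, L, k, alpha = control$alpha,
                seed = substream_seed(seed, paste0("beta_scan/", v$name)),
                mode = control$eig_mode, restarts = control$beta_restarts,
                t_max = control$t_max, name = v$name)
  })
  ranked <- rank_views(svs)
  basis <- integrate_views(ranked, literal_power = control$literal_power,
                           reorthonormalize = control$reorthonormalize)
  labels <- cluster_accretive(basis, k,
                              seed = substream_seed(seed, "final_kmeans"),
                              restarts = control$kmeans_restarts,
                              t_max = control$t_max)
  names(labels) <- data$sample_ids
  per_view <- data.frame(
    view = vapply(ranked, function(s) s$name, character(1L)),
    beta = vapply(ranked, function(s) s$beta, numeric(1L)),
    silhouette = vapply(ranked, function(s) s$silhouette, numeric(1L)),
    rank = vapply(ranked, function(s) s$rank, integer(1L)),
    stringsAsFactors = FALSE)
  empty <- setdiff(seq_len(k), unique(labels))
  if (length(empty)) warning("empty cluster(s): ", paste(empty, collapse = ", "))
  structure(list(labels = labels, basis = basis$b, per_view = per_view,
                 views = ranked, k = k, seed = seed, control = control,
                 n = data$n, call = cl),
            class = "risyng")
}

#' @export
print.risyng <- function(x, ...) {
  cat("RISynG clustering: ", x$n, " samples, ", nrow(x$per_view),
      " view(s), k = ", x$k, "\n", sep = "")
  cat("cluster sizes:\n")
  print(table(cluster = x$labels))
  invisible(x)
}

#' @export
summary.risyng <- function(object, ...) {
  structure(list(k = object$k, n = object$n, seed = object$seed,
                 per_view = object$per_view,
                 sizes = table(cluster = object$labels),
                 silhouette = silhouette_index(object$basis, object$labels)),
            class = "summary.risyng")
}

#' @export
print.summary.risyng <- function(x, ...) {
  cat("RISynG clustering of", x$n, "samples into", x$k, "clusters (seed", paste0(x$seed, ")\n"))
  cat("\nper-view diagnostics (relevance order):\n")
  print(x$per_view, row.names = FALSE)
  cat("\ncluster sizes:\n")
  print(x$sizes)
  cat("\nsilhouette on the integrated embedding:", format(round(x$silhouette, 4)), "\n")
  invisible(x)
}

#' Scatter plot of the integrated embedding
#'
#' Plots two columns of the accretive basis, points coloured by cluster.
#'
#' @param x a `risyng` fit.
#' @param dims length-2 integer vector of basis columns to plot.
#' @param ... passed to [graphics::plot()].
#' @export
plot.risyng <- function(x, dims = c(1L, 2L), ...) {
  stopifnot(length(dims) == 2L, all(dims <= ncol(x$basis)))
  graphics::plot(x$basis[, dims[1L]], x$basis[, dims[2L]],
                 col = grDevices::hcl.colors(x$k, "Dark 3")[x$labels],
                 pch = 19, xlab = paste("basis dim", dims[1L]),
                 ylab = paste("basis dim", dims[2L]), ...)
  invisible(x)
}

#' @export
fitted.risyng <- function(object, ...) object$labels
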