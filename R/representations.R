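# Per-view graph representations: pairwise distance matrices, heat-kernel
# similarities (Gramian G and Euclidean-kernel W), degrees, the normalised
# graph Laplacian and its shifted variant.

#' Pairwise sample distances
#'
#' Computes an n x n distance matrix over the columns (samples) of a view
#' matrix. `"correlation"` gives 1 - Pearson correlation (range \[0, 2\]):
#' two samples are similar when the trends across their features correlate,
#' regardless of magnitude. `"squared_euclidean"` gives the squared Euclidean
#' distance.
#'
#' @param X numeric d x n matrix (features x samples), n >= 2.
#' @param metric `"correlation"` or `"squared_euclidean"`.
#' @return object of class `distance_matrix`: list with `Dmat` (n x n,
#'   symmetric, zero diagonal, nonnegative), `metric` and `max_value`
#'   (the largest pairwise distance, the heat-kernel scale).
#' @export
pairwise_distances <- function(X, metric = c("correlation", "squared_euclidean")) {
  metric <- match.arg(metric)
  X <- as.matrix(X)
  n <- ncol(X)
  if (n < 2L) stop("need at least 2 samples")
  if (metric == "correlation") {
    sds <- apply(X, 2L, stats::sd)
    if (any(sds == 0)) {
      bad <- colnames(X)[which(sds == 0)[1L]] %||% which(sds == 0)[1L]
      stop("zero-variance sample under correlation distance: ", bad)
    }
    D <- 1 - stats::cor(X)
    D <- pmax(D, 0)
  } else {
    D <- as.matrix(stats::dist(t(X)))^2
  }
  D <- (D + t(D)) / 2
  diag(D) <- 0
  structure(list(Dmat = D, metric = metric, max_value = max(D)),
            class = "distance_matrix")
}

#' Heat-kernel similarity from a distance matrix
#'
#' Entrywise `exp(-d_ij / (scale_factor * max(d)))`. Dividing by the maximum
#' pairwise distance makes the kernel scale-free per view; `scale_factor =
#' 0.5` reproduces the alternative bandwidth of half the maximum distance.
#' Applied to correlation distances this yields the Gramian G; applied to
#' squared Euclidean distances it yields the similarity matrix W feeding the
#' Laplacian. If all points coincide (`max(d) = 0`) an all-ones matrix is
#' returned.
#'
#' @param dist a `distance_matrix` from [pairwise_distances()].
#' @param scale_factor positive bandwidth multiplier (default 1).
#' @param squared if `TRUE`, square the exponential factor (equivalent to
#'   halving the bandwidth); off by default.
#' @return symmetric n x n matrix with unit diagonal and entries in (0, 1\].
#' @export
heat_kernel <- function(dist, scale_factor = 1, squared = FALSE) {
  stopifnot(inherits(dist, "distance_matrix"), scale_factor > 0)
  if (dist$max_value <= 1e-12) {   # all points numerically identical
    n <- nrow(dist$Dmat)
    return(matrix(1, n, n))
  }
  K <- exp(-dist$Dmat / (scale_factor * dist$max_value))
  if (isTRUE(squared)) K <- K * K
  K <- (K + t(K)) / 2
  diag(K) <- 1
  K
}

#' Node degrees of a weighted graph
#'
#' Row sums of the similarity matrix, diagonal (self-similarity) included.
#'
#' @param W symmetric nonnegative n x n similarity matrix.
#' @return length-n numeric vector of degrees.
#' @export
degree_matrix <- function(W) {
  W <- as.matrix(W)
  if (any(W < 0)) stop("similarity matrix has negative entries")
  rowSums(W)
}

#' Symmetric normalised graph Laplacian
#'
#' `L = I - D^{-1/2} W D^{-1/2}`. Symmetric and positive semi-definite; its
#' bottom eigenvectors carry the graph partition structure (normalised-cut
#' relaxation).
#'
#' @param W symmetric nonnegative n x n similarity matrix.
#' @param d length-n degree vector (defaults to [degree_matrix()] of `W`);
#'   all entries must be strictly positive.
#' @return symmetric n x n matrix.
#' @export
normalized_laplacian <- function(W, d = degree_matrix(W)) {
  W <- as.matrix(W)
  if (any(d <= 0)) stop("zero or negative degree at node ", which(d <= 0)[1L])
  s <- 1 / sqrt(d)
  L <- -W * tcrossprod(s)
  diag(L) <- diag(L) + 1
  (L + t(L)) / 2
}

#' Shift the trivial Laplacian eigenvector to the top of the spectrum
#'
#' `L_shift = L + (2/n) 1 1'`. Every eigenvector orthogonal to the constant
#' vector keeps its eigenpair; on a regular graph the constant eigenvector
#' moves from eigenvalue 0 to eigenvalue 2, so the informative bottom
#' eigenvectors can be taken directly without discarding the first one.
#'
#' @param Lnorm symmetric n x n normalised Laplacian.
#' @param n number of samples (defaults to `nrow(Lnorm)`).
#' @return symmetric n x n shifted Laplacian.
#' @export
shift_laplacian <- function(Lnorm, n = nrow(Lnorm)) {
  Lnorm <- as.matrix(Lnorm)
  Lnorm + 2 / n
}

#' Build both graph representations of one view
#'
#' Assembles, from a preprocessed view: the Gramian `G` (heat kernel of
#' correlation distances), the similarity `W` (heat kernel of squared
#' Euclidean distances), degrees `D`, the normalised Laplacian `Lnorm` and
#' the shifted Laplacian `Lmod`.
#'
#' @param view an [omics_view()] (or bare features x samples matrix) with
#'   finite entries.
#' @param scale_factor,gramian_squared passed to [heat_kernel()]
#'   (`gramian_squared` affects `G` only).
#' @param zero_diagonal if `TRUE`, self-similarities are removed from `W`
#'   before the degree and Laplacian computation.
#' @return object of class `representation_pair`: list with `name`, `G`,
#'   `W`, `D`, `Lnorm`, `Lmod`, `n`.
#' @export
build_representations <- function(view, scale_factor = 1,
                                  gramian_squared = FALSE,
                                  zero_diagonal = FALSE) {
  if (inherits(view, "omics_view")) {
    X <- view$X
    name <- view$name
  } else {
    X <- as.matrix(view)
    name <- "view"
  }
  if (any(!is.finite(X))) stop("view '", name, "' has non-finite entries; preprocess first")
  G <- heat_kernel(pairwise_distances(X, "correlation"),
                   scale_factor = scale_factor, squared = gramian_squared)
  W <- heat_kernel(pairwise_distances(X, "squared_euclidean"),
                   scale_factor = scale_factor)
  if (isTRUE(zero_diagonal)) diag(W) <- 0
  D <- degree_matrix(W)
  Lnorm <- normalized_laplacian(W, D)
  structure(list(name = name, G = G, W = W, D = D, Lnorm = Lnorm,
                 Lmod = shift_laplacian(Lnorm), n = ncol(X)),
            class = "representation_pair")
}

#' @export
print.representation_pair <- function(x, ...) {
  cat("graph representations of view '", x$name, "' (n = ", x$n, ")\n", sep = "")
  invisible(x)
}
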