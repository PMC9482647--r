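# Recursive multi-kernel integration: each new view's eigenbasis is projected
# off the current accretive subspace, orthogonalised, attenuated by a
# relevance-dependent elementwise power, and added to the accretive basis.
# Only the n x k basis is ever carried; the full n x n accretive matrix is
# never materialised (every downstream use needs only the basis, and the
# basis recursion is O(n k) per step instead of O(n^3)).

#' Projection of a view basis onto the accretive subspace
#'
#' `P = b b' U`: the component of each column of `U` lying in the span of the
#' accretive basis `b` (an orthogonal projection when `b` has orthonormal
#' columns).
#'
#' @param b n x k accretive basis.
#' @param U n x k eigenbasis of the incoming view.
#' @return n x k matrix.
#' @export
project_basis <- function(b, U) {
  b <- as.matrix(b); U <- as.matrix(U)
  if (nrow(b) != nrow(U)) stop("row mismatch: ", nrow(b), " vs ", nrow(U))
  b %*% crossprod(b, U)
}

#' Residual of a view basis after projection
#'
#' `Q = U - P`: the component of the incoming eigenbasis not already captured
#' by the accretive subspace. When `P = b b' U` with orthonormal `b`, the
#' columns of `Q` are orthogonal to the span of `b`.
#'
#' @param U,P n x k matrices of equal shape.
#' @return n x k matrix.
#' @export
residual_basis <- function(U, P) {
  if (!identical(dim(as.matrix(U)), dim(as.matrix(P)))) stop("shape mismatch")
  U - P
}

#' Modified Gram-Schmidt orthonormalisation with rank handling
#'
#' Orthonormalises the columns of `Q` in order. Columns whose residual norm
#' falls below `tol` are numerically dependent and are replaced by zero
#' columns, so the output keeps the input shape and the basis sum downstream
#' stays well-defined.
#'
#' @param Q n x k matrix.
#' @param tol dependence threshold on the residual column norm.
#' @return n x k matrix whose nonzero columns are orthonormal.
#' @export
gram_schmidt <- function(Q, tol = 1e-10) {
  Q <- as.matrix(Q)
  R <- matrix(0, nrow(Q), ncol(Q))
  kept <- integer(0L)
  for (j in seq_len(ncol(Q))) {
    v <- Q[, j]
    for (i in kept) v <- v - sum(R[, i] * v) * R[, i]
    nv <- sqrt(sum(v^2))
    if (nv >= tol) {
      R[, j] <- v / nv
      kept <- c(kept, j)
    }
  }
  R
}

#' Relevance-dependent attenuation of an orthonormal residual basis
#'
#' Applies the elementwise sign-preserving power `sign(x) |x|^(eta + 1)` to
#' the orthonormalised residual basis. Because the entries of a unit-norm
#' basis vector have magnitude at most 1, later recursion steps (larger
#' `eta`, i.e. less relevant views) contribute strictly less: the attenuation
#' that protects the accretive basis from irrelevant views. The
#' sign-preserving power keeps the sign structure of the eigenvector entries
#' under even exponents; `literal_power` applies the plain power
#' `x^(eta + 1)` instead.
#'
#' With `normalize = "rows"` each nonzero row of `R` is first rescaled to
#' unit Euclidean norm (zero rows stay zero) before the power is applied.
#' That variant inflates every residual direction - noise included - to
#' full row scale, which overwhelms the accretive basis whenever the
#' residual is mostly noise, so it is not the default; it is kept for
#' comparison with the spectral-clustering convention of row-normalised
#' embeddings.
#'
#' @param R n x k matrix with orthonormal nonzero columns (typically from
#'   [gram_schmidt()]).
#' @param eta recursion step index, >= 1 (the view being merged is the
#'   (eta + 1)-th most relevant).
#' @param literal_power use `x^(eta + 1)` rather than `sign(x)|x|^(eta + 1)`.
#' @param normalize `"basis"` (default: columns are already unit norm from
#'   Gram-Schmidt, attenuate directly) or `"rows"` (row-normalise first).
#' @return n x k weighted matrix `V`.
#' @export
orthonorm_weight <- function(R, eta, literal_power = FALSE,
                             normalize = c("basis", "rows")) {
  stopifnot(eta >= 0)
  normalize <- match.arg(normalize)
  R <- as.matrix(R)
  if (normalize == "rows") {
    rn <- sqrt(rowSums(R^2))
    nz <- rn > 0
    R[nz, ] <- R[nz, , drop = FALSE] / rn[nz]
  }
  p <- eta + 1
  if (isTRUE(literal_power)) R^p else sign(R) * abs(R)^p
}

#' Recursive integration of relevance-ordered synergy views
#'
#' Starting from the most relevant view's eigenbasis `b = U(1)`, each further
#' view contributes only the orthogonalised, relevance-attenuated residual of
#' its eigenbasis: for step `eta = 1, ..., M - 1`,
#' `V = orthonorm_weight(gram_schmidt(U(eta+1) - b b' U(eta+1)), eta)` and
#' `b <- b + V`. A view whose eigenspace is already contained in the
#' accretive subspace therefore contributes nothing, and less relevant views
#' (merged later) are damped progressively harder. The summed basis is not
#' re-orthonormalised between steps unless `reorthonormalize` is set.
#'
#' @param svs list of `synergy_view` objects in relevance order (see
#'   [rank_views()]), all with the same n and k.
#' @param literal_power,normalize passed to [orthonorm_weight()].
#' @param reorthonormalize orthonormalise the accretive basis after each
#'   merge (off by default).
#' @param tol Gram-Schmidt dependence threshold.
#' @return object of class `accretive_basis`: list with `b` (n x k final
#'   basis), `steps` (number of merges performed) and `k`.
#' @export
integrate_views <- function(svs, literal_power = FALSE,
                            normalize = c("basis", "rows"),
                            reorthonormalize = FALSE, tol = 1e-10) {
  normalize <- match.arg(normalize)
  if (inherits(svs, "synergy_view")) svs <- list(svs)
  stopifnot(length(svs) >= 1L)
  n <- nrow(svs[[1L]]$U)
  k <- ncol(svs[[1L]]$U)
  b <- svs[[1L]]$U
  if (length(svs) > 1L) {
    for (eta in seq_len(length(svs) - 1L)) {
      U <- svs[[eta + 1L]]$U
      if (nrow(U) != n || ncol(U) != k) {
        stop("view '", svs[[eta + 1L]]$name, "' basis is ", nrow(U), " x ", ncol(U),
             ", expected ", n, " x ", k)
      }
      # project off the span of the accretive basis; once merges have been
      # added b itself is no longer orthonormal, so the projection uses an
      # orthonormalisation of it (at step 1 this is b exactly)
      ob <- gram_schmidt(b, tol)
      Q <- residual_basis(U, project_basis(ob, U))
      V <- orthonorm_weight(gram_schmidt(Q, tol), eta, literal_power, normalize)
      b <- b + V
      if (isTRUE(reorthonormalize)) b <- gram_schmidt(b, tol)
    }
  }
  structure(list(b = b, steps = length(svs) - 1L, k = k),
            class = "accretive_basis")
}

#' k-means on the rows of the accretive basis
#'
#' Final clustering step: seeded k-means (k-means++ initialisation, best of
#' `restarts` by within-cluster sum of squares) on the n rows of the basis.
#' Labels are canonicalised by first occurrence, so the first sample always
#' gets label 1.
#'
#' @param b n x k accretive basis (or an `accretive_basis` object).
#' @param k number of clusters.
#' @param seed integer seed.
#' @param restarts,t_max k-means restarts and iteration cap.
#' @return integer vector of cluster labels in 1..k.
#' @export
cluster_accretive <- function(b, k, seed = 1L, restarts = 50L, t_max = 300L) {
  if (inherits(b, "accretive_basis")) b <- b$b
  seeded_kmeans(b, k, seed, restarts = restarts, t_max = t_max)$labels
}
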