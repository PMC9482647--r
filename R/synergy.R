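# Per-view synergy matrices: convex combination of the Gramian and the
# (shifted) Laplacian, beta selected by a provisional silhouette scan, and
# relevance ranking of views.

#' Synergy matrix of one view
#'
#' Convex combination `H = beta * G + (1 - beta) * L` fusing the two graph
#' representations of a view. As a convex combination of positive
#' semi-definite matrices, `H` is symmetric positive semi-definite for every
#' `beta` in \[0, 1\].
#'
#' @param G,L symmetric n x n representation matrices (Gramian and shifted
#'   Laplacian).
#' @param beta mixing weight in \[0, 1\]; `beta = 1` gives `G`, `beta = 0`
#'   gives `L`.
#' @return symmetric n x n matrix.
#' @export
synergy_matrix <- function(G, L, beta) {
  if (!is.numeric(beta) || length(beta) != 1L || beta < 0 || beta > 1) {
    stop("beta must be a single value in [0, 1], got ", beta)
  }
  stopifnot(identical(dim(G), dim(L)))
  beta * G + (1 - beta) * L
}

#' Eigenbasis embedding of a synergy matrix
#'
#' Returns the n x k matrix of unit eigenvectors of `H` for the k smallest
#' (default) or k largest eigenvalues, columns ordered by eigenvalue
#' (ascending for `"smallest"`, descending for `"largest"`). Sign convention:
#' in each column the entry of largest magnitude is made positive, so the
#' embedding is deterministic up to eigenvalue degeneracy.
#'
#' @param H symmetric n x n matrix.
#' @param k embedding dimension, `1 <= k < n`.
#' @param mode `"smallest"` or `"largest"`.
#' @return n x k matrix with orthonormal columns.
#' @export
embed_basis <- function(H, k, mode = c("smallest", "largest")) {
  mode <- match.arg(mode)
  n <- nrow(H)
  if (k < 1L || k >= n) stop("need 1 <= k < n, got k = ", k, ", n = ", n)
  e <- eigen(H, symmetric = TRUE)   # values in decreasing order
  idx <- if (mode == "smallest") rev(seq_len(n))[seq_len(k)] else seq_len(k)
  U <- e$vectors[, idx, drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  U
}

#' Select the synergy weight by a provisional silhouette scan
#'
#' For each beta on the grid `{0, alpha, 2*alpha, ..., 1}` the synergy matrix
#' is built, embedded into its k-dimensional eigenbasis, provisionally
#' clustered by seeded k-means on the embedding rows, and scored by the
#' silhouette index in that embedding (Euclidean distance). The beta with the
#' highest provisional silhouette wins; ties go to the smallest beta. Grid
#' points where k-means fails are skipped with a warning.
#'
#' @param G,L symmetric n x n representation matrices.
#' @param k number of clusters / embedding dimension.
#' @param alpha grid step in (0, 1); the default 0.1 gives 11 grid points.
#' @param seed integer seed; each grid point uses its own derived substream.
#' @param mode eigenvector side passed to [embed_basis()].
#' @param restarts,t_max k-means restarts and iteration cap for the
#'   provisional clustering.
#' @param name view label carried through to diagnostics.
#' @return object of class `synergy_view`: list with `name`, `H`, `beta`,
#'   `U` (n x k basis at the selected beta), `silhouette`,
#'   `labels_provisional`, and `scan` (data frame of the full beta grid with
#'   silhouettes, `NA` where skipped).
#' @export
select_beta <- function(G, L, k, alpha = 0.1, seed = 1L,
                        mode = c("smallest", "largest"),
                        restarts = 10L, t_max = 300L, name = "view") {
  mode <- match.arg(mode)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  grid <- seq(0, 1, by = alpha)
  if (grid[length(grid)] < 1) grid <- c(grid, 1)
  sil <- rep(NA_real_, length(grid))
  fits <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    b <- grid[i]
    res <- tryCatch({
      H <- synergy_matrix(G, L, b)
      U <- embed_basis(H, k, mode)
      # one substream per view, reused across the grid: identical embeddings
      # (e.g. G == L) then score identically, so ties resolve to smallest beta
      km <- seeded_kmeans(U, k, substream_seed(seed, paste0("beta_scan/", name)),
                          restarts = restarts, t_max = t_max)
      list(H = H, U = U, labels = km$labels,
           sil = silhouette_index(U, km$labels))
    }, error = function(e) {
      warning("beta = ", b, " skipped for view '", name, "': ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
    if (!is.null(res)) {
      sil[i] <- res$sil
      fits[[i]] <- res
    }
  }
  if (all(is.na(sil))) stop("provisional clustering failed at every beta for view '", name, "'")
  # ties (within numerical jitter) resolve to the smallest beta
  best <- which(!is.na(sil) & sil >= max(sil, na.rm = TRUE) - 1e-9)[1L]
  f <- fits[[best]]
  structure(list(name = name, H = f$H, beta = grid[best], U = f$U,
                 silhouette = f$sil, labels_provisional = f$labels,
                 scan = data.frame(beta = grid, silhouette = sil)),
            class = "synergy_view")
}

#' @export
print.synergy_view <- function(x, ...) {
  cat("synergy view '", x$name, "': beta = ", format(x$beta),
      ", provisional silhouette = ", format(round(x$silhouette, 4)), "\n", sep = "")
  invisible(x)
}

#' Rank synergy views by relevance
#'
#' Sorts views by provisional silhouette, most relevant first (that view
#' leads the recursive integration). Ties preserve input order.
#'
#' @param svs list of `synergy_view` objects.
#' @return the same list, sorted, each element gaining a `rank` field.
#' @export
rank_views <- function(svs) {
  if (inherits(svs, "synergy_view")) svs <- list(svs)
  stopifnot(length(svs) >= 1L)
  sil <- vapply(svs, function(s) s$silhouette, numeric(1L))
  ord <- order(-sil)   # stable: ties keep input order
  out <- svs[ord]
  for (i in seq_along(out)) out[[i]]$rank <- i
  out
}
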