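# Cluster validity indices and enrichment quantification.
#
# Internal indices (silhouette, Dunn, Davies-Bouldin, Xie-Beni) score a
# partition against the geometry of the points; external indices (F-measure,
# ARI, NMI, Jaccard, purity) score it against reference class labels through
# the R x C contingency table. Enrichment scores summarise user-supplied
# term/p-value tables; the Fisher overlap test scores a 2x2 gene-overlap
# contingency table.

.check_points_labels <- function(points, labels, min_clusters = 2L) {
  points <- as.matrix(points)
  labels <- as.vector(labels)
  if (nrow(points) != length(labels)) stop("points/labels length mismatch")
  cl <- unique(labels)
  if (length(cl) < min_clusters) {
    stop("need at least ", min_clusters, " clusters, got ", length(cl))
  }
  list(points = points, labels = labels, clusters = cl)
}

#' Silhouette index
#'
#' Unweighted mean over clusters of the per-cluster mean silhouette width.
#' For each point, `s = (b - a) / max(a, b)` with `a` the mean Euclidean
#' distance to the other members of its own cluster and `b` the smallest mean
#' distance to any other cluster. Singleton points get `s = 0`. Values lie in
#' \[-1, 1\]; higher is better.
#'
#' @param points n x d numeric matrix.
#' @param labels length-n cluster labels (at least 2 distinct).
#' @return a single number in \[-1, 1\].
#' @export
silhouette_index <- function(points, labels) {
  z <- .check_points_labels(points, labels)
  D <- as.matrix(stats::dist(z$points))
  n <- length(z$labels)
  f <- factor(z$labels)
  Z <- stats::model.matrix(~ f - 1)            # n x C cluster indicator
  counts <- colSums(Z)
  S <- D %*% Z                                 # per-point distance sums by cluster
  own <- as.integer(f)
  iown <- cbind(seq_len(n), own)
  a <- S[iown] / pmax(counts[own] - 1, 1)      # mean distance within own cluster
  Sother <- S / rep(counts, each = n)
  Sother[iown] <- Inf
  b <- apply(Sother, 1L, min)                  # nearest other cluster
  s <- ifelse(pmax(a, b) > 0, (b - a) / pmax(a, b), 0)
  s[counts[own] == 1] <- 0                     # singleton convention
  mean(tapply(s, f, mean))
}

#' Dunn index
#'
#' Smallest single-linkage inter-cluster distance divided by the largest
#' cluster diameter (complete-diameter). Higher is better. Single-point
#' clusters have diameter 0; if every cluster is a singleton the denominator
#' vanishes and an error is raised.
#'
#' @inheritParams silhouette_index
#' @return a nonnegative number.
#' @export
dunn_index <- function(points, labels) {
  z <- .check_points_labels(points, labels)
  D <- as.matrix(stats::dist(z$points))
  idx <- split(seq_along(z$labels), z$labels)
  diam <- vapply(idx, function(j) {
    if (length(j) < 2L) 0 else max(D[j, j])
  }, numeric(1L))
  if (max(diam) == 0) stop("all clusters are singletons: Dunn index undefined")
  cl <- names(idx)
  delta <- Inf
  for (i in seq_along(cl)[-length(cl)]) {
    for (j in seq.int(i + 1L, length(cl))) {
      delta <- min(delta, min(D[idx[[i]], idx[[j]]]))
    }
  }
  delta / max(diam)
}

#' Davies-Bouldin index
#'
#' Mean over clusters of the worst-case ratio `(S_i + S_j) / M_ij`, where `S`
#' is the mean Euclidean distance of a cluster's points to its centroid and
#' `M_ij` the distance between centroids. Lower is better.
#'
#' @inheritParams silhouette_index
#' @return a nonnegative number.
#' @export
davies_bouldin <- function(points, labels) {
  z <- .check_points_labels(points, labels)
  idx <- split(seq_along(z$labels), z$labels)
  C <- length(idx)
  cent <- do.call(rbind, lapply(idx, function(j) {
    colMeans(z$points[j, , drop = FALSE])
  }))
  S <- vapply(seq_len(C), function(i) {
    mean(sqrt(rowSums((z$points[idx[[i]], , drop = FALSE] -
                         matrix(cent[i, ], length(idx[[i]]), ncol(cent), byrow = TRUE))^2)))
  }, numeric(1L))
  M <- as.matrix(stats::dist(cent))
  if (any(M[upper.tri(M)] == 0)) stop("coincident centroids: Davies-Bouldin undefined")
  db <- vapply(seq_len(C), function(i) {
    max((S[i] + S[-i]) / M[i, -i])
  }, numeric(1L))
  mean(db)
}

#' Xie-Beni index
#'
#' Mean squared distance of points to their own cluster barycentre, divided
#' by the smallest squared distance between barycentres. Lower is better.
#'
#' @inheritParams silhouette_index
#' @return a nonnegative number.
#' @export
xie_beni <- function(points, labels) {
  z <- .check_points_labels(points, labels)
  idx <- split(seq_along(z$labels), z$labels)
  cent <- do.call(rbind, lapply(idx, function(j) {
    colMeans(z$points[j, , drop = FALSE])
  }))
  wgss <- sum(vapply(seq_along(idx), function(i) {
    sum((z$points[idx[[i]], , drop = FALSE] -
           matrix(cent[i, ], length(idx[[i]]), ncol(cent), byrow = TRUE))^2)
  }, numeric(1L)))
  M2 <- as.matrix(stats::dist(cent))^2
  m <- min(M2[upper.tri(M2)])
  if (m == 0) stop("coincident barycentres: Xie-Beni undefined")
  (wgss / length(z$labels)) / m
}

#' Contingency table of two partitions
#'
#' @param predicted,truth equal-length label vectors.
#' @return object of class `partition_pair`: list with `contingency` (R x C
#'   counts), `n`, and the two label vectors.
#' @export
partition_pair <- function(predicted, truth) {
  predicted <- as.vector(predicted); truth <- as.vector(truth)
  if (length(predicted) != length(truth)) stop("label vectors differ in length")
  if (length(predicted) < 1L) stop("empty partitions")
  structure(list(contingency = unclass(table(predicted, truth)),
                 n = length(predicted), predicted = predicted, truth = truth),
            class = "partition_pair")
}

.as_pp <- function(pp, truth = NULL) {
  if (inherits(pp, "partition_pair")) pp else partition_pair(pp, truth)
}

#' F-measure of a clustering against reference classes
#'
#' For every reference class, the best harmonic mean of precision
#' (`n_ij / n_i`) and recall (`n_ij / n_j`) over clusters, averaged with
#' class-size weights. In \[0, 1\]; 1 for identical partitions.
#'
#' @param pp a [partition_pair()], or a predicted label vector (then `truth`
#'   must be given).
#' @param truth reference labels when `pp` is a vector.
#' @return a number in \[0, 1\].
#' @export
f_measure <- function(pp, truth = NULL) {
  pp <- .as_pp(pp, truth)
  N <- pp$contingency
  n <- pp$n
  ni <- rowSums(N)
  nj <- colSums(N)
  fm <- 0
  for (j in seq_along(nj)) {
    prec <- N[, j] / ni
    rec <- N[, j] / nj[j]
    h <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
    fm <- fm + (nj[j] / n) * max(h)
  }
  unname(fm)
}

#' Adjusted Rand index
#'
#' Pair-counting agreement between two partitions, corrected for chance under
#' the hypergeometric model. 1 for identical partitions; can be negative.
#'
#' @inheritParams f_measure
#' @return a number <= 1.
#' @export
adjusted_rand <- function(pp, truth = NULL) {
  pp <- .as_pp(pp, truth)
  N <- pp$contingency
  if (pp$n < 2L) stop("need n >= 2")
  sij <- sum(choose(N, 2))
  si <- sum(choose(rowSums(N), 2))
  sj <- sum(choose(colSums(N), 2))
  stot <- choose(pp$n, 2)
  expected <- si * sj / stot
  denom <- (si + sj) / 2 - expected
  if (denom == 0) return(1)   # both partitions trivial and identical in pair structure
  (sij - expected) / denom
}

#' Normalised mutual information
#'
#' Mutual information of the two label distributions divided by the mean of
#' their entropies (natural logs; the base cancels). 0/0 is defined as 0.
#' In \[0, 1\]; 1 for identical partitions.
#'
#' @inheritParams f_measure
#' @return a number in \[0, 1\].
#' @export
nmi <- function(pp, truth = NULL) {
  pp <- .as_pp(pp, truth)
  P <- pp$contingency / pp$n
  pi <- rowSums(P)
  pj <- colSums(P)
  mi <- 0
  for (i in seq_along(pi)) for (j in seq_along(pj)) {
    if (P[i, j] > 0) mi <- mi + P[i, j] * log(P[i, j] / (pi[i] * pj[j]))
  }
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  denom <- (h(pi) + h(pj)) / 2
  if (denom == 0) return(if (mi == 0) 0 else NaN)
  max(0, min(1, mi / denom))
}

#' Pair-counting Jaccard index of two partitions
#'
#' Ratio of sample pairs co-clustered in both partitions to pairs
#' co-clustered in at least one. In \[0, 1\]; defined as 0 when neither
#' partition co-clusters any pair.
#'
#' @inheritParams f_measure
#' @return a number in \[0, 1\].
#' @export
jaccard_index <- function(pp, truth = NULL) {
  pp <- .as_pp(pp, truth)
  N <- pp$contingency
  if (pp$n < 2L) stop("need n >= 2")
  s11 <- sum(choose(N, 2))                     # co-clustered in both
  a <- sum(choose(rowSums(N), 2))              # co-clustered in predicted
  b <- sum(choose(colSums(N), 2))              # co-clustered in truth
  union <- a + b - s11
  if (union == 0) return(0)
  s11 / union
}

#' Purity of a clustering against reference classes
#'
#' Each cluster is assigned its majority class; purity is the fraction of
#' correctly assigned samples. In (0, 1\]; 1 for identical partitions.
#'
#' @inheritParams f_measure
#' @return a number in (0, 1\].
#' @export
purity <- function(pp, truth = NULL) {
  pp <- .as_pp(pp, truth)
  sum(apply(pp$contingency, 1L, max)) / pp$n
}

#' Mean -log10 p-value enrichment score
#'
#' Summarises a table of significant enrichment terms (pathway, biological
#' process, or disease ontology) by the mean of `-log10(p)` over terms.
#' Higher means stronger enrichment.
#'
#' @param p_values vector of adjusted p-values in (0, 1\].
#' @return a nonnegative number.
#' @export
enrichment_score <- function(p_values) {
  p_values <- as.numeric(p_values)
  if (length(p_values) == 0L) stop("no terms: enrichment score undefined")
  if (any(p_values <= 0 | p_values > 1)) stop("p-values must lie in (0, 1]")
  mean(-log10(p_values))
}

#' Annotation ratio
#'
#' Mean fraction of submitted genes annotated per enriched term:
#' `sum(g_i) / (T * G)` for `T` terms with per-term gene counts `g_i`, out of
#' `G` genes submitted to the enrichment tool.
#'
#' @param gene_counts per-term annotated gene counts (length `T`).
#' @param total_genes `G`, the number of genes submitted (>= 1).
#' @return a nonnegative number.
#' @export
annotation_ratio <- function(gene_counts, total_genes) {
  gene_counts <- as.numeric(gene_counts)
  if (length(gene_counts) == 0L) stop("no terms: annotation ratio undefined")
  if (total_genes < 1) stop("total_genes must be >= 1")
  if (any(gene_counts < 0)) stop("gene counts must be nonnegative")
  sum(gene_counts) / (length(gene_counts) * total_genes)
}

#' Fisher's exact test on a 2x2 overlap table
#'
#' Exact hypergeometric test for the 2x2 contingency table
#' `[[a, b], [c, d]]` (e.g. marker genes overlapping a curated disease gene
#' catalogue vs not). The two-sided p-value sums the probabilities of all
#' tables with the same margins whose probability does not exceed that of the
#' observed table.
#'
#' @param a,b,c,d nonnegative integer cell counts.
#' @param alternative `"two_sided"` (default), `"greater"` or `"less"` (on
#'   the `a` cell).
#' @return the p-value.
#' @export
fisher_overlap <- function(a, b, c, d,
                           alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) stop("counts must be nonnegative integers")
  if (sum(cells) == 0) stop("all counts zero")
  m <- a + b          # row-1 total
  nn <- c + d         # row-2 total
  kk <- a + c         # column-1 total
  lo <- max(0L, kk - nn)
  hi <- min(kk, m)
  x <- lo:hi
  p <- stats::dhyper(x, m, nn, kk)
  obs <- stats::dhyper(a, m, nn, kk)
  switch(alternative,
         two_sided = sum(p[p <= obs * (1 + 1e-7)]),
         greater = sum(p[x >= a]),
         less = sum(p[x <= a]))
}
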