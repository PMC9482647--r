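# Synthetic sample-matched multi-view data with planted cluster structure,
# and small graph fixtures for spectral property checks.

#' Specification of a synthetic multi-view dataset
#'
#' @param n number of samples.
#' @param k number of planted clusters (n >= k).
#' @param views list of per-view settings; each element is a list with
#'   `d` (feature dimension), `separation` (pairwise centroid distance in
#'   units of `noise_sd`; >= 0), `noise_sd` (Gaussian noise SD, > 0) and
#'   `relevant` (logical; irrelevant views are pure noise). Missing fields
#'   take the defaults `separation = 5`, `noise_sd = 1`, `relevant = TRUE`.
#' @param cluster_proportions length-k simplex vector (default uniform).
#' @param seed integer seed.
#' @return a list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n, k, views, cluster_proportions = rep(1 / k, k),
                           seed = 1L) {
  stopifnot(n >= k, k >= 1L, length(views) >= 1L)
  if (length(cluster_proportions) != k) stop("need k cluster proportions")
  if (any(cluster_proportions < 0) || abs(sum(cluster_proportions) - 1) > 1e-12) {
    stop("cluster_proportions must be nonnegative and sum to 1")
  }
  views <- lapply(seq_along(views), function(i) {
    v <- views[[i]]
    list(d = as.integer(v$d %||% stop("view ", i, " needs a dimension d")),
         separation = v$separation %||% 5,
         noise_sd = v$noise_sd %||% 1,
         relevant = v$relevant %||% TRUE,
         name = v$name %||% paste0("view", i))
  })
  structure(list(n = as.integer(n), k = as.integer(k), views = views,
                 cluster_proportions = cluster_proportions,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Largest-remainder allocation of n samples to proportions: sizes are exact
# and deterministic, so size assertions in tests stay exact.
largest_remainder <- function(n, proportions) {
  raw <- n * proportions
  sizes <- floor(raw)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(raw - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1
  }
  as.integer(sizes)
}

#' Generate a synthetic multi-view dataset with planted clusters
#'
#' Cluster sizes are allocated deterministically by largest-remainder
#' rounding of the proportions, then labels are shuffled by the seed. In each
#' relevant view the k cluster centroids sit on a random orthonormal frame
#' scaled so every pairwise centroid distance equals
#' `separation * noise_sd`; samples are centroid plus isotropic Gaussian
#' noise. Irrelevant views are pure noise. The `separation` therefore acts as
#' a between/within-cluster separation ratio. Deterministic given the spec's
#' seed.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `dataset` (a [multi_omics_dataset()]) and `labels`
#'   (the planted integer labels, 1..k).
#' @export
make_multiview <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(substream_seed(spec$seed, "simulate"), {
    sizes <- largest_remainder(spec$n, spec$cluster_proportions)
    labels <- sample(rep.int(seq_len(spec$k), sizes))
    views <- lapply(spec$views, function(v) {
      X <- matrix(stats::rnorm(v$d * spec$n, sd = v$noise_sd), v$d, spec$n)
      if (isTRUE(v$relevant) && v$separation > 0) {
        # orthonormal frame: columns of Q are k orthonormal directions in R^d;
        # scaling by sep/sqrt(2) makes all pairwise centroid distances = sep.
        if (v$d < spec$k) stop("view '", v$name, "': dimension d < k")
        Q <- qr.Q(qr(matrix(stats::rnorm(v$d * spec$k), v$d, spec$k)))
        centroids <- Q * (v$separation * v$noise_sd / sqrt(2))
        X <- X + centroids[, labels, drop = FALSE]
      }
      omics_view(X, name = v$name, modality = "other",
                 feature_ids = paste0(v$name, "_f", seq_len(v$d)),
                 sample_ids = paste0("s", seq_len(spec$n)))
    })
    list(dataset = multi_omics_dataset(views), labels = labels)
  })
}

#' Block or regular similarity-graph fixtures
#'
#' Builds an n x n similarity matrix for spectral property checks:
#' block-constant with unit within-block weight and zero inter-block weight.
#' With `regular = TRUE` the blocks have equal size (requires `blocks` to
#' divide `n`), so every node has the same degree and the graph is regular;
#' the normalised Laplacian then annihilates the constant vector exactly, and
#' the eigenvalue 0 has multiplicity equal to the number of blocks
#' (connected components).
#'
#' @param n number of nodes.
#' @param blocks number of connected components.
#' @param regular require equal block sizes (constant degree).
#' @return symmetric n x n similarity matrix with unit diagonal.
#' @export
make_graph_fixture <- function(n, blocks = 1L, regular = TRUE) {
  stopifnot(n >= 1L, blocks >= 1L, blocks <= n)
  if (regular && n %% blocks != 0L) stop("blocks must divide n for a regular fixture")
  sizes <- if (regular) rep.int(n %/% blocks, blocks)
  else largest_remainder(n, rep(1 / blocks, blocks))
  W <- matrix(0, n, n)
  at <- 0L
  for (s in sizes) {
    idx <- at + seq_len(s)
    W[idx, idx] <- 1
    at <- at + s
  }
  W
}
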