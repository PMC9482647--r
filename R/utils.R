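# Internal helpers: seeded substreams and k-means++ clustering.

# Derive a reproducible substream seed from a master seed and a text tag.
# Keeps results stable when views are added or reordered: each named stage
# gets its own stream. Result is always a valid 32-bit integer seed.
substream_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  cp <- utf8ToInt(tag)
  h <- sum(cp * seq_along(cp)) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 48271 + h * 16807 + 11) %% 2147483587) + 1L
}

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# k-means++ center seeding (Arthur & Vassilvitskii): first center uniform,
# subsequent centers sampled with probability proportional to the squared
# distance to the nearest chosen center. Uses the current RNG stream.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  d2 <- rowSums((x - matrix(centers[1L, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (all(d2 <= 0)) {
      stop("fewer than k distinct rows: cannot seed ", k, " centers")
    }
    idx <- sample.int(n, 1L, prob = d2)
    centers[j, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2))
  }
  centers
}

# Seeded k-means: k-means++ init, `restarts` independent starts, Lloyd
# iterations via stats::kmeans, best solution by total within-cluster SS.
# Labels are canonicalised by order of first occurrence.
seeded_kmeans <- function(x, k, seed, restarts = 50L, t_max = 300L) {
  x <- as.matrix(x)
  if (nrow(x) < k) stop("n < k: cannot form ", k, " clusters from ", nrow(x), " rows")
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      fit <- tryCatch({
        centers <- kmeanspp_centers(x, k)
        suppressWarnings(stats::kmeans(x, centers = centers,
                                       iter.max = t_max, algorithm = "Lloyd"))
      }, error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$tot.withinss < best$tot.withinss)) {
        best <- fit
      }
    }
  })
  if (is.null(best)) stop("k-means failed in all ", restarts, " restarts")
  list(labels = canonical_labels(best$cluster), inertia = best$tot.withinss)
}

# Relabel clusters 1..k by order of first appearance in the label vector.
canonical_labels <- function(labels) {
  u <- unique(labels)
  match(labels, u)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
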