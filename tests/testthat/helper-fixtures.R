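# Fixtures and independent oracles shared across test files.

# Random preprocessed view (features x samples) with optional planted blocks.
random_view <- function(n, d = 30, k = 0, separation = 0, seed = 1,
                        name = "v") {
  set.seed(seed)
  X <- matrix(rnorm(d * n), d, n)
  labels <- NULL
  if (k > 1) {
    labels <- rep(seq_len(k), length.out = n)
    centroids <- qr.Q(qr(matrix(rnorm(d * k), d, k))) * separation / sqrt(2)
    X <- X + centroids[, labels, drop = FALSE]
  }
  list(view = omics_view(X, name = name), labels = labels)
}

# Two-block data (n = 2m samples) where only the correlation structure
# separates the blocks: a strong shared signal plus per-block row-centred
# idiosyncrasies makes within-block correlation strictly lower than
# between-block correlation, while Euclidean distances stay uninformative.
gramian_only_fixture <- function(m = 30, d = 400, gamma = 1.5, seed = 42) {
  set.seed(seed)
  s <- rnorm(d)
  Z1 <- matrix(rnorm(d * m), d, m); Z1 <- Z1 - rowMeans(Z1)
  Z2 <- matrix(rnorm(d * m), d, m); Z2 <- Z2 - rowMeans(Z2)
  list(X = cbind(s + gamma * Z1, s + gamma * Z2), labels = rep(1:2, each = m))
}

# Complement: a global shared signal plus a strong block-shared component.
# Within-block correlation exceeds between-block correlation, which under the
# smallest-eigenvalue embedding places the block indicator at the TOP of the
# Gramian's spectrum: any beta > 0 expels the indicator from the bottom-k
# embedding, so only the Laplacian path reveals the blocks and the scan must
# settle at beta = 0.
laplacian_only_fixture <- function(m = 30, d = 400, seed = 42) {
  set.seed(seed)
  s <- rnorm(d, sd = 2)
  t1 <- rnorm(d, sd = 1.5)
  t2 <- rnorm(d, sd = 1.5)
  X <- cbind(s + t1 + matrix(rnorm(d * m, 0, 0.5), d, m),
             s + t2 + matrix(rnorm(d * m, 0, 0.5), d, m))
  list(X = X, labels = rep(1:2, each = m))
}

# All set partitions of n elements into at most kmax blocks, as canonical
# label vectors (restricted growth strings).
all_partitions <- function(n, kmax = 3) {
  out <- list()
  rec <- function(prefix, maxused) {
    i <- length(prefix) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- prefix
      return()
    }
    for (v in seq_len(min(maxused + 1L, kmax))) {
      rec(c(prefix, v), max(maxused, v))
    }
  }
  rec(integer(0), 0L)
  out
}

# ---- brute-force oracles (independent of the package implementations) ----

# Pair-counting confusion: for every unordered sample pair, whether it is
# co-clustered in each partition.
pair_counts <- function(a, b) {
  n <- length(a)
  s11 <- s10 <- s01 <- s00 <- 0
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    pa <- a[i] == a[j]; pb <- b[i] == b[j]
    if (pa && pb) s11 <- s11 + 1
    else if (pa && !pb) s10 <- s10 + 1
    else if (!pa && pb) s01 <- s01 + 1
    else s00 <- s00 + 1
  }
  c(s11 = s11, s10 = s10, s01 = s01, s00 = s00)
}

oracle_ari <- function(a, b) {
  s <- pair_counts(a, b)
  num <- 2 * (s["s11"] * s["s00"] - s["s10"] * s["s01"])
  den <- (s["s11"] + s["s10"]) * (s["s10"] + s["s00"]) +
    (s["s11"] + s["s01"]) * (s["s01"] + s["s00"])
  if (den == 0) return(1)
  unname(num / den)
}

oracle_jaccard <- function(a, b) {
  s <- pair_counts(a, b)
  den <- s["s11"] + s["s10"] + s["s01"]
  if (den == 0) return(0)
  unname(s["s11"] / den)
}

oracle_fmeasure <- function(pred, truth) {
  n <- length(pred)
  total <- 0
  for (cls in unique(truth)) {
    K <- which(truth == cls)
    best <- 0
    for (cl in unique(pred)) {
      C <- which(pred == cl)
      inter <- length(intersect(C, K))
      if (inter > 0) {
        p <- inter / length(C); r <- inter / length(K)
        best <- max(best, 2 * p * r / (p + r))
      }
    }
    total <- total + length(K) / n * best
  }
  total
}

oracle_nmi <- function(a, b) {
  n <- length(a)
  mi <- 0
  for (ca in unique(a)) for (cb in unique(b)) {
    pab <- sum(a == ca & b == cb) / n
    if (pab > 0) mi <- mi + pab * log2(pab / (sum(a == ca) / n * sum(b == cb) / n))
  }
  ent <- function(x) {
    p <- table(x) / length(x)
    -sum(p * log2(p))
  }
  den <- (ent(a) + ent(b)) / 2
  if (den == 0) return(if (abs(mi) < 1e-14) 0 else NaN)
  mi / den
}

oracle_purity <- function(pred, truth) {
  tot <- 0
  for (cl in unique(pred)) {
    tot <- tot + max(table(truth[pred == cl]))
  }
  tot / length(pred)
}

# Loop-based internal index oracles (explicit sums, no matrix algebra).
oracle_davies_bouldin <- function(pts, lab) {
  cl <- sort(unique(lab))
  C <- length(cl)
  cent <- lapply(cl, function(c) colMeans(pts[lab == c, , drop = FALSE]))
  S <- sapply(seq_len(C), function(i) {
    rows <- which(lab == cl[i])
    mean(sapply(rows, function(r) sqrt(sum((pts[r, ] - cent[[i]])^2))))
  })
  mean(sapply(seq_len(C), function(i) {
    max(sapply(setdiff(seq_len(C), i), function(j) {
      (S[i] + S[j]) / sqrt(sum((cent[[i]] - cent[[j]])^2))
    }))
  }))
}

oracle_xie_beni <- function(pts, lab) {
  cl <- sort(unique(lab))
  cent <- lapply(cl, function(c) colMeans(pts[lab == c, , drop = FALSE]))
  wgss <- 0
  for (i in seq_along(lab)) {
    wgss <- wgss + sum((pts[i, ] - cent[[match(lab[i], cl)]])^2)
  }
  dmin <- Inf
  for (i in seq_along(cl)[-length(cl)]) for (j in seq.int(i + 1, length(cl))) {
    dmin <- min(dmin, sum((cent[[i]] - cent[[j]])^2))
  }
  (wgss / length(lab)) / dmin
}

oracle_dunn <- function(pts, lab) {
  cl <- sort(unique(lab))
  D <- as.matrix(dist(pts))
  diam <- sapply(cl, function(c) {
    rows <- which(lab == c)
    if (length(rows) < 2) 0 else max(D[rows, rows])
  })
  dmin <- Inf
  for (i in seq_along(cl)[-length(cl)]) for (j in seq.int(i + 1, length(cl))) {
    dmin <- min(dmin, min(D[lab == cl[i], lab == cl[j]]))
  }
  dmin / max(diam)
}

# Relative PSD check: smallest eigenvalue bounded below by -tol * spectral norm.
expect_psd <- function(M, tol = 1e-8) {
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -tol * max(abs(ev), 1))
}
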