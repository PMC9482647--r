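# Validity indices: frozen hand-derived values, independent oracles,
# invariances, enrichment scores and the Fisher overlap test.

test_that("silhouette matches the hand-derived four-point value and cluster::silhouette", {
  pts <- matrix(c(0, 0.1, 10, 10.1), 4, 1)
  lab <- c(1, 1, 2, 2)
  expect_equal(silhouette_index(pts, lab), 0.99, tolerance = 1e-6)
  set.seed(11)
  X <- matrix(rnorm(80), 40, 2)
  l <- sample(1:3, 40, replace = TRUE)
  sw <- cluster::silhouette(l, dist(X))[, "sil_width"]
  expect_equal(silhouette_index(X, l), mean(tapply(sw, l, mean)),
               tolerance = 1e-12)
  # identical-centroid interleaved clusters score non-positive
  Y <- matrix(rep(c(0, 1, 0.02, 1.02), each = 2), 8, 1)
  expect_lte(silhouette_index(Y, rep(1:2, 4)), 0)
  # relabelling leaves the index unchanged
  expect_equal(silhouette_index(X, l), silhouette_index(X, c(7, 3, 5)[l]),
               tolerance = 1e-14)
  expect_error(silhouette_index(X, rep(1, 40)), "at least 2")
})

test_that("Dunn, Davies-Bouldin and Xie-Beni match hand values on the line", {
  pts <- matrix(c(0, 1, 10, 11), 4, 1)
  lab <- c(1, 1, 2, 2)
  expect_equal(dunn_index(pts, lab), 9)
  expect_equal(davies_bouldin(pts, lab), 0.1)
  expect_equal(xie_beni(pts, lab), 0.0025)
  # identical points far apart: DB and XB collapse to 0
  pts0 <- matrix(c(0, 0, 9, 9), 4, 1)
  expect_equal(davies_bouldin(pts0, lab), 0)
  expect_equal(xie_beni(pts0, lab), 0)
  expect_error(dunn_index(pts0[c(1, 3), , drop = FALSE], c(1, 2)), "singleton")
})

test_that("internal indices match loop oracles on random configurations", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(12:25, 1)
    pts <- matrix(rnorm(n * 3), n, 3)
    lab <- sample(1:3, n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    expect_equal(davies_bouldin(pts, lab), oracle_davies_bouldin(pts, lab),
                 tolerance = 1e-12)
    expect_equal(xie_beni(pts, lab), oracle_xie_beni(pts, lab),
                 tolerance = 1e-12)
    expect_equal(dunn_index(pts, lab), oracle_dunn(pts, lab),
                 tolerance = 1e-12)
  }
})

test_that("internal indices are invariant under rotation and translation", {
  set.seed(6)
  pts <- matrix(rnorm(60), 30, 2)
  lab <- rep(1:3, each = 10)
  th <- 0.7
  Rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- pts %*% Rot + matrix(c(5, -2), 30, 2, byrow = TRUE)
  for (f in list(silhouette_index, dunn_index, davies_bouldin, xie_beni)) {
    expect_equal(f(moved, lab), f(pts, lab), tolerance = 1e-10)
  }
})

test_that("external indices match frozen hand-derived values", {
  expect_equal(f_measure(c(1, 1, 2, 2), c(1, 1, 1, 2)), 0.75 * 0.8 + 0.25 * 2 / 3,
               tolerance = 1e-12)
  expect_equal(round(f_measure(c(1, 1, 2, 2), c(1, 1, 1, 2)), 4), 0.7667)
  expect_equal(adjusted_rand(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  expect_equal(nmi(c(1, 1, 2, 2), c(1, 2, 1, 2)), 0)
  expect_equal(jaccard_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), 0)
  expect_equal(jaccard_index(c(1, 1, 2, 2), c(1, 1, 1, 2)), 0.25)
  expect_equal(purity(c(1, 1, 2, 2), c(1, 1, 1, 2)), 0.75)
  for (f in list(f_measure, adjusted_rand, nmi, jaccard_index, purity)) {
    expect_equal(f(c(1, 2, 2, 3), c(1, 2, 2, 3)), 1)
  }
})

test_that("ARI agrees with mclust's implementation on random partitions", {
  for (s in 1:10) {
    set.seed(s)
    a <- sample(1:3, 15, replace = TRUE)
    b <- sample(1:3, 15, replace = TRUE)
    expect_equal(adjusted_rand(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
})

test_that("external indices are invariant under relabelling either side", {
  set.seed(4)
  a <- sample(1:3, 12, replace = TRUE)
  b <- sample(1:3, 12, replace = TRUE)
  pa <- c(9, 4, 7)[a]
  pb <- c(2, 8, 5)[b]
  for (f in list(f_measure, adjusted_rand, nmi, jaccard_index, purity)) {
    expect_equal(f(pa, pb), f(a, b), tolerance = 1e-12)
  }
})

test_that("enrichment score and annotation ratio match their formulas", {
  expect_equal(enrichment_score(c(0.01, 0.001)), 2.5)
  expect_equal(enrichment_score(0.05), 1.30103, tolerance = 1e-6)
  expect_equal(enrichment_score(rep(1, 5)), 0)
  expect_error(enrichment_score(numeric(0)), "no terms")
  expect_error(enrichment_score(c(0.5, 0)), "\\(0, 1\\]")
  expect_equal(annotation_ratio(c(10, 30), 100), 0.2)
  expect_equal(annotation_ratio(c(0, 0, 0), 10), 0)
  expect_equal(annotation_ratio(c(5, 5, 5, 5, 5), 50), 0.1)
  expect_error(annotation_ratio(numeric(0), 10), "no terms")
  # linearity in -log10 p and in the summed counts
  set.seed(2)
  p <- runif(6, 0.001, 1)
  expect_equal(enrichment_score(p), mean(-log10(p)), tolerance = 1e-12)
  g <- rpois(6, 8)
  expect_equal(annotation_ratio(g, 40), sum(g) / (6 * 40), tolerance = 1e-12)
})

test_that("fisher_overlap matches stats::fisher.test", {
  expect_equal(fisher_overlap(5, 5, 5, 5), 1)
  set.seed(3)
  for (r in 1:15) {
    tab <- matrix(rpois(4, 12), 2)
    expect_equal(fisher_overlap(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
    expect_equal(fisher_overlap(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2],
                                alternative = "greater"),
                 stats::fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
  expect_error(fisher_overlap(0, 0, 0, 0), "zero")
  expect_error(fisher_overlap(-1, 2, 3, 4), "nonnegative")
})

test_that("partition_pair builds a consistent contingency table", {
  pp <- partition_pair(c(1, 1, 2, 2, 3), c(1, 2, 2, 2, 1))
  expect_equal(sum(pp$contingency), 5)
  expect_equal(rowSums(pp$contingency), c(`1` = 2, `2` = 2, `3` = 1))
  expect_error(partition_pair(1:3, 1:4), "length")
})
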