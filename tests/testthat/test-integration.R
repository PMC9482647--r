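# Recursive integration: projection, residual, Gram-Schmidt, relevance
# attenuation, the accretive recursion and the final clustering.

orthobasis <- function(n, k, seed) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(n * k), n, k)))
}

test_that("project_basis is the projector action on the incoming basis", {
  b <- orthobasis(8, 2, 1)
  # complement directions project to zero
  U_perp <- orthobasis(8, 8, 2)[, 1:2]
  U_perp <- U_perp - b %*% crossprod(b, U_perp)
  expect_lt(max(abs(project_basis(b, U_perp))), 1e-10)
  expect_equal(project_basis(b, b), b, tolerance = 1e-12)
  # triple-product loop oracle on a random 6 x 2 case
  b2 <- orthobasis(6, 2, 3); U <- matrix(rnorm(12), 6, 2)
  P <- project_basis(b2, U)
  oracle <- matrix(0, 6, 2)
  for (i in 1:6) for (j in 1:2) for (l in 1:6) for (m in 1:2) {
    oracle[i, j] <- oracle[i, j] + b2[i, m] * b2[l, m] * U[l, j]
  }
  expect_equal(P, oracle, tolerance = 1e-12)
  expect_error(project_basis(b, matrix(0, 5, 2)), "mismatch")
})

test_that("residuals are orthogonal to the accretive span", {
  b <- orthobasis(10, 3, 4)
  expect_lt(max(abs(residual_basis(b, project_basis(b, b)))), 1e-12)
  U <- matrix(rnorm(30), 10, 3)
  Q <- residual_basis(U, project_basis(b, U))
  expect_lt(max(abs(crossprod(b, Q))), 1e-10)
})

test_that("gram_schmidt orthonormalises and zeroes dependent columns", {
  expect_equal(gram_schmidt(matrix(0, 5, 3)), matrix(0, 5, 3))
  Q <- matrix(rnorm(10), 5, 2)
  R <- gram_schmidt(Q)
  expect_equal(crossprod(R), diag(2), tolerance = 1e-10)
  Qdup <- cbind(Q[, 1], Q[, 1])
  Rdup <- gram_schmidt(Qdup)
  expect_equal(Rdup[, 2], rep(0, 5))
  expect_equal(sum(Rdup[, 1]^2), 1, tolerance = 1e-12)
})

test_that("orthonorm_weight attenuates elementwise; row mode matches hand arithmetic", {
  # literal row-normalised reading: (3,4) -> (0.6,0.8) -> (0.36,0.64)
  V <- orthonorm_weight(matrix(c(3, 4), 1), eta = 1, normalize = "rows")
  expect_equal(V, matrix(c(0.36, 0.64), 1), tolerance = 1e-12)
  # zero rows stay zero
  Z <- orthonorm_weight(rbind(c(3, 4), c(0, 0)), eta = 2, normalize = "rows")
  expect_equal(Z[2, ], c(0, 0))
  # eta = 0 is the identity power
  R <- orthobasis(7, 2, 5)
  expect_equal(orthonorm_weight(R, 0), R, tolerance = 1e-12)
  # sign preservation under even powers
  expect_equal(sign(orthonorm_weight(R, 1)), sign(R))
  # Frobenius attenuation is non-increasing in eta for a fixed basis
  fro <- sapply(1:4, function(e) sqrt(sum(orthonorm_weight(R, e)^2)))
  expect_true(all(diff(fro) <= 1e-12))
  # literal power flips no structure check: plain power squares signs away
  expect_true(all(orthonorm_weight(R, 1, literal_power = TRUE) >= 0))
})

test_that("integration: single view passes through, duplicates are no-ops", {
  sv <- function(U, name = "v") {
    structure(list(name = name, U = U, silhouette = 0.5), class = "synergy_view")
  }
  U1 <- orthobasis(12, 3, 6)
  expect_equal(integrate_views(list(sv(U1)))$b, U1)
  # an identical second view adds nothing
  b2 <- integrate_views(list(sv(U1), sv(U1, "copy")))$b
  expect_lt(max(abs(b2 - U1)), 1e-8)
  # sign-flipped / rotated copy spanning the same subspace adds nothing
  Rot <- qr.Q(qr(matrix(rnorm(9), 3)))
  b3 <- integrate_views(list(sv(U1), sv(U1 %*% Rot, "rot")))$b
  expect_lt(max(abs(b3 - U1)), 1e-8)
})

test_that("each merge step only adds directions orthogonal to the current basis", {
  svs <- lapply(1:3, function(i) {
    structure(list(name = paste0("v", i), U = orthobasis(15, 3, i),
                   silhouette = 0.5), class = "synergy_view")
  })
  b <- svs[[1]]$U
  for (eta in 1:2) {
    U <- svs[[eta + 1]]$U
    ob <- gram_schmidt(b)
    R <- gram_schmidt(residual_basis(U, project_basis(ob, U)))
    expect_lt(max(abs(crossprod(b, R))), 1e-8)
    b <- b + orthonorm_weight(R, eta)
  }
  expect_equal(b, integrate_views(svs)$b, tolerance = 1e-12)
  expect_true(all(is.finite(b)))
})

test_that("cluster_accretive recovers a planted split and is equivariant", {
  set.seed(8)
  b <- rbind(matrix(rnorm(20, 0, .05), 10, 2),
             matrix(rnorm(20, 3, .05), 10, 2))
  truth <- rep(1:2, each = 10)
  lab <- cluster_accretive(b, 2, seed = 3)
  expect_equal(adjusted_rand(lab, truth), 1)
  expect_identical(lab, cluster_accretive(b, 2, seed = 3))  # deterministic
  # permuting rows permutes labels identically (up to canonical relabelling)
  perm <- sample(20)
  lab_p <- cluster_accretive(b[perm, ], 2, seed = 3)
  expect_equal(adjusted_rand(lab_p, truth[perm]), 1)
  expect_error(cluster_accretive(b[1:3, ], 4, seed = 1), "n < k")
})

test_that("risyng with one view reduces to spectral clustering of that view", {
  sim <- make_multiview(synthetic_spec(n = 40, k = 2, views = list(
    list(d = 30, separation = 6)), seed = 13))
  fit <- risyng(sim$dataset, k = 2, seed = 17)
  rep <- build_representations(sim$dataset$views[[1]])
  sv <- select_beta(rep$G, rep$Lmod, 2,
                    seed = risyng:::substream_seed(17, "beta_scan/view1"),
                    name = "view1")
  expect_equal(fit$basis, sv$U)
  lab <- cluster_accretive(sv$U, 2, seed = risyng:::substream_seed(17, "final_kmeans"))
  expect_identical(unname(fit$labels), lab)
})

test_that("risyng is deterministic and labels are canonical", {
  sim <- make_multiview(synthetic_spec(n = 36, k = 2, views = list(
    list(d = 20, separation = 6), list(d = 25, separation = 6)), seed = 2))
  f1 <- risyng(sim$dataset, k = 2, seed = 5)
  f2 <- risyng(sim$dataset, k = 2, seed = 5)
  expect_identical(f1$labels, f2$labels)
  expect_equal(f1$basis, f2$basis)
  expect_identical(unname(f1$labels[1]), 1L)
  expect_s3_class(summary(f1), "summary.risyng")
})
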