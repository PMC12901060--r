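test_that("sparsify_rows thresholds per row and matches a sort oracle", {
  m <- rbind(c(0.1, 0.2, 0.9, 1.0),
             c(1.0, 0.9, 0.2, 0.1))
  expect_identical(sparsify_rows(m, 0), m)
  out <- sparsify_rows(m, 0.5)
  expect_identical(out[1, ], c(0, 0, 0.9, 1.0))
  expect_identical(out[2, ], c(1.0, 0.9, 0, 0))

  set.seed(1)
  r <- matrix(runif(100), 10, 10)
  sp <- sparsify_rows(r, 0.9)
  for (i in 1:10) {
    keep <- which(sp[i, ] != 0)
    # sort-based oracle: survivors are the top ceil(10 * 0.1) entries
    expect_identical(sort(keep), sort(order(r[i, ], decreasing = TRUE)[1]))
    expect_identical(sp[i, keep], r[i, keep])
  }
  expect_error(sparsify_rows(r, 1), "sparsity")
})

test_that("affinity kernels follow their formulas", {
  set.seed(2)
  m <- matrix(rnorm(20), 4, 5)
  m[2, ] <- m[1, ]                 # identical rows
  a_g <- affinity(m, "gaussian", gamma = 0.3)$values
  a_c <- affinity(m, "cosine")$values
  a_n <- affinity(m, "normalized_angle")$values
  expect_equal(a_g[1, 2], 1, tolerance = 1e-12)
  expect_equal(a_c[1, 2], 1, tolerance = 1e-8)
  expect_equal(a_n[1, 2], 1, tolerance = 1e-8)
  # gaussian off-diagonal from the printed formula
  expect_equal(a_g[1, 3], exp(-0.3 * sum((m[1, ] - m[3, ])^2)),
               tolerance = 1e-12)

  # orthogonal rows: cosine 0, normalized angle 0.5
  o <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(affinity(o, "cosine")$values[1, 2], 0, tolerance = 1e-12)
  expect_equal(affinity(o, "normalized_angle")$values[1, 2], 0.5,
               tolerance = 1e-12)

  # spearman equals Pearson of hand-assigned ranks
  s <- rbind(c(3.2, 1.1, 7.4, 5.0), c(2.0, 9.9, 4.4, 4.5),
             c(1, 2, 3, 4), c(4, 3, 2, 1))
  ranks1 <- c(2, 1, 4, 3); ranks2 <- c(1, 4, 2, 3)
  expect_equal(affinity(s, "spearman")$values[1, 2], cor(ranks1, ranks2),
               tolerance = 1e-12)
  # bounds
  expect_true(all(affinity(s, "normalized_angle")$values >= 0 - 1e-12))
  expect_true(all(abs(affinity(s, "pearson")$values) <= 1 + 1e-12))

  z <- rbind(c(0, 0, 0), c(1, 2, 3), c(1, 1, 1))
  expect_error(affinity(z, "cosine"), "zero-norm")
})

test_that("diffusion map separates the blocks of a two-block affinity", {
  aff <- matrix(0.05, 4, 4)
  aff[1:2, 1:2] <- 1; aff[3:4, 3:4] <- 1
  g <- diffusion_map(aff, 1)
  s <- sign(g$components[, 1])
  expect_identical(s[1], s[2])
  expect_identical(s[3], s[4])
  expect_true(s[1] != s[3])
  expect_true(all(g$eigenvalues > 0 & g$eigenvalues < 1))
})

test_that("diffusion map eigenpairs satisfy the transition-operator equation", {
  set.seed(3)
  w <- matrix(runif(64, 0.05, 1), 8, 8); w <- (w + t(w)) / 2
  g <- diffusion_map(w, 4, alpha = 0.5)
  expect_true(all(diff(g$eigenvalues) < 0))
  # independent check: rebuild the transition operator and verify
  # P psi = lambda psi for the unscaled eigenvectors
  d <- rowSums(w)
  w1 <- w / outer(sqrt(d), sqrt(d))
  P <- w1 / rowSums(w1)
  for (k in seq_along(g$eigenvalues)) {
    lam <- g$eigenvalues[k]
    psi <- g$components[, k] / (lam / (1 - lam))  # undo diffusion-time scaling
    expect_equal(drop(P %*% psi), lam * psi, tolerance = 1e-8)
  }
})

test_that("diffusion map is equivariant under parcel permutation", {
  set.seed(4)
  w <- matrix(runif(49, 0.05, 1), 7, 7); w <- (w + t(w)) / 2
  g <- diffusion_map(w, 3)
  perm <- sample(7)
  gp <- diffusion_map(w[perm, perm], 3)
  for (k in 1:3) {
    a <- g$components[perm, k]; b <- gp$components[, k]
    expect_equal(abs(cor(a, b)), 1, tolerance = 1e-8)
    expect_true(isTRUE(all.equal(a, b, tolerance = 1e-6)) ||
                  isTRUE(all.equal(a, -b, tolerance = 1e-6)))
  }
})

test_that("pca embedding matches an independent covariance eigendecomposition", {
  set.seed(5)
  x <- matrix(rnorm(25), 5, 5)
  g <- pca_embed(x, 3)
  ev <- eigen(cov(x), symmetric = TRUE)
  score1 <- scale(x, center = TRUE, scale = FALSE) %*% ev$vectors[, 1]
  expect_equal(abs(cor(g$components[, 1], drop(score1))), 1, tolerance = 1e-8)
  expect_equal(g$eigenvalues, ev$values[1:3], tolerance = 1e-8)
  expect_true(sum(g$eigenvalues) <= sum(diag(cov(x))) + 1e-10)

  # rank-1 input: trailing explained variances vanish
  r1 <- outer(1:5, 2 * (1:5))
  g1 <- pca_embed(r1, 3)
  expect_lt(g1$eigenvalues[2], 1e-10)
  expect_lt(g1$eigenvalues[3], 1e-10)
})

test_that("laplacian eigenmaps drops the trivial eigenvector and bounds eigenvalues", {
  aff <- matrix(0.05, 4, 4)
  aff[1:2, 1:2] <- 1; aff[3:4, 3:4] <- 1
  g <- laplacian_eigenmaps(aff, 2)
  expect_true(all(g$eigenvalues > 1e-12 & g$eigenvalues <= 2 + 1e-10))
  s <- sign(g$components[, 1])
  expect_identical(s[1], s[2])
  expect_true(s[1] != s[3])
  # generalized eigen equation L v = lambda D v, via an independent rebuild
  set.seed(6)
  w <- matrix(runif(36, 0.05, 1), 6, 6); w <- (w + t(w)) / 2
  g2 <- laplacian_eigenmaps(w, 3)
  D <- diag(rowSums(w)); L <- D - w
  for (k in 1:3) {
    v <- g2$components[, k]
    expect_equal(drop(L %*% v), g2$eigenvalues[k] * drop(D %*% v),
                 tolerance = 1e-8)
  }
  # disconnected graph rejected
  disc <- diag(4)
  expect_error(laplacian_eigenmaps(disc, 1), "disconnected")
  expect_error(diffusion_map(disc, 1), "disconnected")
})

test_that("extract_gradients composes the stages deterministically", {
  set.seed(7)
  ts <- matrix(rnorm(900), 45, 20)
  fc <- pearson_fc(ts)
  g1 <- extract_gradients(fc, n_components = 5)
  g2 <- extract_gradients(fc, n_components = 5)
  expect_identical(g1$components, g2$components)
  expect_identical(g1$params$kernel, "normalized_angle")
  expect_true(all(diff(g1$eigenvalues) < 0))
  expect_identical(ncol(g1$components), 5L)

  # pca with kernel "none", sparsity 0 is plain PCA of the FC matrix
  gp <- extract_gradients(fc, kernel_name = "none", sparsity = 0,
                          approach = "pca", n_components = 3)
  direct <- pca_embed(fc, 3)
  expect_equal(gp$components, direct$components, tolerance = 1e-10)
})

test_that("gradient sets round-trip through their text serialization", {
  set.seed(8)
  ts <- matrix(rnorm(800), 40, 20)
  g <- extract_gradients(pearson_fc(ts), n_components = 4,
                         subject_id = "sub-001", session_id = "ses-01")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gradient_set(g, path)
  back <- read_gradient_set(path)
  expect_lt(max(abs(back$components - g$components)), 1e-12)
  expect_equal(back$eigenvalues, g$eigenvalues, tolerance = 1e-15)
  expect_identical(back$method, g$method)
  expect_identical(back$params$kernel, g$params$kernel)
  expect_identical(back$subject_id, "sub-001")
  expect_false(back$aligned)
})
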