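test_that("procrustes recovers identity and sign flips exactly", {
  set.seed(1)
  A <- rand_orthonormal(10, 3)
  res <- fit_procrustes(A, A)
  expect_equal(res$transform, diag(3), tolerance = 1e-10)
  expect_equal(norm(A %*% res$transform - A, "F"), 0, tolerance = 1e-10)

  A2 <- rand_orthonormal(8, 2)
  B2 <- A2 %*% diag(c(1, -1))
  res2 <- fit_procrustes(A2, B2)
  expect_equal(res2$transform, diag(c(1, -1)), tolerance = 1e-10)

  # orthogonality and SVD reconstruction invariants
  set.seed(2)
  for (i in 1:20) {
    A3 <- matrix(rnorm(24), 8, 3); B3 <- matrix(rnorm(24), 8, 3)
    r <- fit_procrustes(A3, B3)
    expect_equal(crossprod(r$transform), diag(3), tolerance = 1e-8)
    expect_equal(r$transform, r$u %*% t(r$v), tolerance = 1e-10)
    expect_true(all(diff(r$singular_values) <= 1e-12))
    expect_true(all(r$singular_values >= 0))
  }
  expect_error(fit_procrustes(matrix(0, 4, 2), matrix(0, 5, 2)), "dimension")
})

test_that("fitted transform beats an exhaustive 2x2 orthogonal grid", {
  set.seed(3)
  angles <- seq(0, 2 * pi, length.out = 1e4)
  for (i in 1:10) {
    A <- matrix(rnorm(16), 8, 2); B <- matrix(rnorm(16), 8, 2)
    res <- fit_procrustes(A, B)
    fitted <- norm(A %*% res$transform - B, "F")
    grid_best <- Inf
    for (refl in c(1, -1)) {
      # residual over the rotation/reflection grid via the trace identity
      C <- crossprod(A, B)
      base <- sum(A^2) + sum(B^2)
      tr <- if (refl == 1)
        (C[1, 1] + C[2, 2]) * cos(angles) + (C[2, 1] - C[1, 2]) * sin(angles)
      else
        (C[1, 1] - C[2, 2]) * cos(angles) + (C[2, 1] + C[1, 2]) * sin(angles)
      grid_best <- min(grid_best, sqrt(pmax(base - 2 * tr, 0)))
    }
    expect_lte(fitted, grid_best + 1e-6)
  }
})

test_that("apply_transform preserves Frobenius norm and permutes columns", {
  set.seed(4)
  A <- matrix(rnorm(30), 10, 3)
  gs <- gradient_set(A, c(3, 2, 1), "dm")
  id_res <- fit_procrustes(A, A)
  expect_identical(apply_transform(gs, id_res)$aligned, TRUE)
  expect_equal(apply_transform(A, id_res), A, tolerance = 1e-10)

  P <- matrix(0, 3, 3); P[1, 2] <- P[2, 3] <- P[3, 1] <- 1
  res <- list(transform = P)
  expect_equal(apply_transform(A, res), A[, c(3, 1, 2)], tolerance = 1e-12)

  Q <- rand_orthogonal(3)
  expect_equal(norm(A %*% Q, "F"), norm(A, "F"), tolerance = 1e-8)
})

test_that("correspondence and transformation magnitudes follow their closed forms", {
  mk <- function(T) structure(list(transform = T), class = "procrustes_result")
  expect_identical(correspondence(mk(matrix(1, 1, 1))), 1)
  expect_identical(correspondence(mk(matrix(-1, 1, 1))), 1)
  T1 <- diag(3); T1[, 1] <- c(0.9, 0.1, 0)
  expect_equal(correspondence(mk(T1)), 0.9)
  T2 <- diag(2); T2[, 1] <- c(0.5, 0.5)
  expect_equal(correspondence(mk(T2)), 0.5)

  m3 <- transformation_magnitudes(mk(diag(3)))
  expect_identical(m3$trans_total, 3)
  expect_identical(m3$trans_pg, 1)
  th <- pi / 4
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  m45 <- transformation_magnitudes(mk(rot))
  expect_equal(m45$trans_total, 4 * sqrt(2) / 2, tolerance = 1e-12)
  expect_equal(m45$trans_pg, sqrt(2), tolerance = 1e-12)
  # signed permutations: trans_total = n, trans_pg = 1
  sp <- matrix(0, 4, 4); sp[cbind(1:4, c(2, 1, 4, 3))] <- c(1, -1, 1, -1)
  msp <- transformation_magnitudes(mk(sp))
  expect_identical(msp$trans_total, 4)
  expect_identical(msp$trans_pg, 1)
})

test_that("correspondence stays within [1/n, 1] for fitted transforms", {
  set.seed(5)
  for (i in 1:50) {
    n <- sample(2:6, 1)
    r <- fit_procrustes(matrix(rnorm(12 * n), 12, n), matrix(rnorm(12 * n), 12, n))
    cc <- correspondence(r)
    expect_gte(cc, 1 / n - 1e-12)
    expect_lte(cc, 1 + 1e-12)
  }
})

test_that("principal angles match an iterative deflation oracle", {
  set.seed(6)
  A <- rand_orthonormal(10, 3)
  B <- rand_orthonormal(10, 3)
  ss <- subspace_similarity(A, B)

  # deflation oracle: repeatedly maximize the cosine between unit vectors of
  # each span, project the maximizers out, recurse
  oracle_angles <- function(Qa, Qb) {
    angles <- numeric(0)
    while (ncol(Qa) >= 1) {
      obj <- function(par) {
        a <- par[seq_len(ncol(Qa))]; b <- par[-seq_len(ncol(Qa))]
        u <- Qa %*% a; v <- Qb %*% b
        -abs(sum(u * v)) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
      }
      best <- Inf; best_par <- NULL
      for (rs in 1:8) {
        p0 <- rnorm(ncol(Qa) + ncol(Qb))
        o <- optim(p0, obj, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-14))
        if (o$value < best) { best <- o$value; best_par <- o$par }
      }
      angles <- c(angles, acos(min(1, -best)))
      if (ncol(Qa) == 1) break
      a <- best_par[seq_len(ncol(Qa))]; b <- best_par[-seq_len(ncol(Qa))]
      u <- Qa %*% a; u <- u / sqrt(sum(u^2))
      v <- Qb %*% b; v <- v / sqrt(sum(v^2))
      Qa <- qr.Q(qr(Qa - u %*% crossprod(u, Qa)))[, 1:(ncol(Qa) - 1), drop = FALSE]
      Qb <- qr.Q(qr(Qb - v %*% crossprod(v, Qb)))[, 1:(ncol(Qb) - 1), drop = FALSE]
    }
    sort(angles)
  }
  expect_equal(ss$theta_vector, oracle_angles(A, B), tolerance = 1e-4)

  # identical subspaces
  same <- subspace_similarity(A, A)
  expect_equal(same$theta_norm, 0, tolerance = 1e-7)
  # orthogonal subspaces: every angle pi/2
  Q <- qr.Q(qr(matrix(rnorm(100), 10, 10)))
  orth <- subspace_similarity(Q[, 1:3], Q[, 4:6])
  expect_equal(orth$theta_norm, (pi / 2) * sqrt(3), tolerance = 1e-8)
  # symmetry and invariance to invertible recombination
  set.seed(7)
  M <- matrix(rnorm(9), 3, 3) + diag(3)
  ss_ab <- subspace_similarity(A, B)
  ss_ba <- subspace_similarity(B, A)
  ss_rec <- subspace_similarity(A %*% M, B)
  expect_equal(ss_ab$theta_norm, ss_ba$theta_norm, tolerance = 1e-8)
  expect_equal(ss_ab$theta_norm, ss_rec$theta_norm, tolerance = 1e-8)
  expect_error(subspace_similarity(cbind(A[, 1], A[, 1]), B[, 1:2]),
               "rank-deficient")
})

test_that("align_to_reference wires selection, fit and diagnostics together", {
  set.seed(8)
  comp <- rand_orthonormal(12, 5)
  ref <- gradient_set(comp, 5:1, "dm", subject_id = "reference")
  subj <- gradient_set(comp, 5:1, "dm", subject_id = "sub-001")

  al1 <- align_to_reference(subj, ref, n_align = 1)
  expect_identical(al1$diagnostics$correspondence, 1)
  expect_identical(al1$diagnostics$trans_total, 1)
  expect_identical(al1$diagnostics$trans_pg, 1)

  al <- align_to_reference(subj, ref, n_align = 5)
  expect_equal(al$aligned$components, comp, tolerance = 1e-10)
  expect_equal(al$diagnostics$theta_norm, 0, tolerance = 1e-7)
  expect_true(al$aligned$aligned)

  # reversed cumulative index subsets are honoured
  alr <- align_to_reference(subj, ref, n_align = 3,
                            component_indices = c(5, 4, 3))
  expect_identical(alr$aligned$params$component_indices, c(5L, 4L, 3L))
  expect_identical(ncol(alr$aligned$components), 3L)
  expect_error(align_to_reference(subj, ref, n_align = 6), "exceed")
})

test_that("alignment capacity never shrinks with added components", {
  # best-case residual of the principal-gradient fit is monotone in capacity
  set.seed(9)
  for (i in 1:10) {
    A <- rand_orthonormal(12, 6)
    B <- rand_orthonormal(12, 6)
    b <- B[, 1]
    resid <- vapply(1:6, function(n) {
      # best achievable ||A[,1:n] t - b|| over unit vectors t (A orthonormal):
      # optimum is t = A'b normalized
      ab <- crossprod(A[, 1:n, drop = FALSE], b)
      nab <- sqrt(sum(ab^2))
      sqrt((1 - nab)^2 + sum(b^2) - nab^2)
    }, 0)
    expect_true(all(diff(resid) <= 1e-10))
  }
})
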