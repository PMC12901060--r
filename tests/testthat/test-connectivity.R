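test_that("pearson_fc matches a covariance/sd hand computation and flags bad input", {
  ts <- cbind(a = c(1, 2, 4, 3, 5),
              b = c(2, 1, 3, 5, 4),
              c = c(5, 3, 1, 2, 2))
  fc <- pearson_fc(ts)
  # formula-by-hand oracle
  hand_r <- function(x, y) {
    n <- length(x)
    cxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
    cxy / (sqrt(sum((x - mean(x))^2) / (n - 1)) * sqrt(sum((y - mean(y))^2) / (n - 1)))
  }
  for (i in 1:3) for (j in 1:3) {
    expected <- if (i == j) 1 else hand_r(ts[, i], ts[, j])
    expect_equal(fc[i, j], expected, tolerance = 1e-12)
  }
  expect_true(isSymmetric(fc))
  expect_identical(unname(diag(fc)), rep(1, 3))

  # identical and anti-correlated columns
  ts2 <- cbind(x = 1:5, y = 1:5, z = -(1:5))
  fc2 <- pearson_fc(ts2)
  expect_equal(fc2["x", "y"], 1)
  expect_equal(fc2["x", "z"], -1)

  # zero-variance parcel named in the error
  ts3 <- cbind(x = 1:5, bad = rep(2, 5))
  expect_error(pearson_fc(ts3), "bad")
})

test_that("pearson_fc is invariant to positive affine rescaling of parcels", {
  set.seed(1)
  ts <- matrix(rnorm(60), 20, 3)
  scaled <- sweep(sweep(ts, 2, c(2, 0.5, 10), "*"), 2, c(-1, 3, 100), "+")
  expect_equal(pearson_fc(ts), pearson_fc(scaled), tolerance = 1e-12)
})

test_that("fisher transform round-trips and matches independent evaluation", {
  expect_identical(fisher_z(0), 0)
  expect_equal(inverse_fisher_z(fisher_z(0.5)), 0.5, tolerance = 1e-12)
  # independent high-precision evaluation of atanh(0.9) via log1p
  expect_equal(fisher_z(0.9), 0.5 * (log1p(0.9) - log1p(-0.9)),
               tolerance = 1e-15)
  expect_warning(z1 <- fisher_z(1), "clipped")
  expect_true(is.finite(z1))
})

test_that("group_mean_fc averages in z space", {
  m <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  expect_equal(group_mean_fc(list(m, m, m)), m, tolerance = 1e-12)

  a <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  b <- matrix(c(1, -0.5, -0.5, 1), 2, 2)
  expect_equal(group_mean_fc(list(a, b))[1, 2], 0, tolerance = 1e-12)

  c1 <- matrix(c(1, 0.3, 0.3, 1), 2, 2)
  c2 <- matrix(c(1, 0.8, 0.8, 1), 2, 2)
  expected <- tanh((0.5 * (log1p(0.3) - log1p(-0.3)) +
                      0.5 * (log1p(0.8) - log1p(-0.8))) / 2)
  got <- group_mean_fc(list(c1, c2))[1, 2]
  expect_equal(got, expected, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(got, 0.55, tolerance = 1e-3)))  # not the arithmetic mean

  # order invariance
  set.seed(2)
  ms <- replicate(4, {
    x <- matrix(runif(9, -0.5, 0.5), 3, 3); x <- (x + t(x)) / 2; diag(x) <- 1; x
  }, simplify = FALSE)
  expect_equal(group_mean_fc(ms), group_mean_fc(rev(ms)), tolerance = 1e-12)
  expect_error(group_mean_fc(list()), "empty")
})

test_that("framewise displacement follows the Power formulation", {
  T <- 6
  tr <- matrix(0, T, 3); rot <- matrix(0, T, 3)
  m0 <- framewise_displacement(tr, rot)
  expect_identical(m0$fd_series, rep(0, T))
  expect_identical(m0$mean_fd, 0)

  tr1 <- tr; tr1[4:T, 1] <- 1  # single 1 mm x-translation step at frame 4
  m1 <- framewise_displacement(tr1, rot)
  expect_identical(m1$fd_series[4], 1)
  expect_identical(sum(m1$fd_series), 1)

  rot1 <- rot; rot1[3:T, 2] <- 0.02  # 0.02 rad step -> 1 mm at 50 mm radius
  m2 <- framewise_displacement(tr, rot1)
  expect_equal(m2$fd_series[3], 1, tolerance = 1e-12)

  # translation invariance: constant offsets leave FD unchanged
  m3 <- framewise_displacement(tr1 + 5, rot1 + 0.3)
  expect_equal(m3$fd_series, framewise_displacement(tr1, rot1)$fd_series,
               tolerance = 1e-12)

  # mean_fd excludes the first frame
  expect_equal(m1$mean_fd, mean(m1$fd_series[-1]))
})

test_that("tfc maps upper-triangle correlation to [0, 1]", {
  set.seed(3)
  g <- matrix(runif(16, -0.8, 0.8), 4, 4); g <- (g + t(g)) / 2; diag(g) <- 1
  expect_equal(tfc(g, g), 1)
  neg <- -g; diag(neg) <- 1
  expect_equal(tfc(neg, g), 0, tolerance = 1e-12)
  # hand-computed oracle on a fixed pair
  a <- matrix(c(1, .2, .4, .2, 1, -.1, .4, -.1, 1), 3, 3)
  b <- matrix(c(1, .3, .1, .3, 1, .5, .1, .5, 1), 3, 3)
  r_hand <- cor(c(.2, .4, -.1), c(.3, .1, .5))
  expect_equal(tfc(a, b), (1 + r_hand) / 2, tolerance = 1e-12)
  expect_error(tfc(diag(3), g[1:3, 1:3]), "constant")
})

test_that("bold_fd_correlations drops frame 1 and matches the Fisher null width", {
  T <- 40
  set.seed(4)
  fd <- c(0, abs(rnorm(T - 1)))
  motion <- motion_series(fd)
  ts <- cbind(match = c(99, fd[-1]), noise = rnorm(T))
  r <- bold_fd_correlations(ts, motion)
  expect_equal(unname(r["match"]), 1, tolerance = 1e-12)

  # null width: pooled sd ~ 1/sqrt(T - 3) for independent series
  T2 <- 300
  set.seed(5)
  rs <- unlist(lapply(1:20, function(i) {
    fd2 <- c(0, abs(rnorm(T2 - 1)))
    bold_fd_correlations(matrix(rnorm(T2 * 50), T2, 50), motion_series(fd2))
  }))
  expect_equal(mean(rs), 0, tolerance = 0.01)
  expect_equal(sd(rs), 1 / sqrt(T2 - 3), tolerance = 0.15)

  expect_error(bold_fd_correlations(ts, motion_series(rep(0, T))), "constant")
})

test_that("ks_compare matches a brute-force ECDF scan", {
  expect_equal(ks_compare(1:10, 1:10)$statistic, 0)
  expect_equal(ks_compare(c(0, 0, 0), c(1, 1, 1))$statistic, 1)
  set.seed(6)
  a <- round(rnorm(10), 2)
  b <- round(rnorm(10, 0.5), 2)
  # ECDF-scan oracle: max gap over all sample points
  pts <- sort(unique(c(a, b)))
  gap <- max(abs(vapply(pts, function(x) mean(a <= x) - mean(b <= x), 0)))
  expect_equal(ks_compare(a, b)$statistic, gap, tolerance = 1e-12)
  # monotone transform leaves D unchanged
  a2 <- a / 3; b2 <- b / 3
  expect_equal(ks_compare(a2, b2, fisher_transform = TRUE)$statistic,
               ks_compare(a2, b2)$statistic, tolerance = 1e-12)
  expect_error(ks_compare(numeric(0), 1:3), "empty")
})
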