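test_that("min-max normalization rescales columns to [0, 1]", {
  expect_equal(as.numeric(minmax_normalize(c(0, 5, 10))), c(0, 0.5, 1))
  expect_equal(as.numeric(minmax_normalize(c(3, 3, 3))), c(0, 0, 0))
  expect_equal(as.numeric(minmax_normalize(c(2, 4, 7))), c(0, 0.4, 1))
  m <- minmax_normalize(cbind(c(0, 5, 10), c(3, 3, 3)))
  expect_equal(m[, 2], c(0, 0, 0))
})

test_that("RBF kernel follows exp(-dist2/d) with the view dimensionality", {
  z <- rbind(c(0, 0), c(1, 1), c(0, 0))
  km <- rbf_kernel(z)
  expect_equal(km$k[1, 3], 1)                 # identical rows
  expect_equal(km$k[1, 2], exp(-2 / 2))       # d = 2
  expect_equal(diag(km$k), rep(1, 3))
  expect_true(isSymmetric(km$k))
  km1 <- rbf_kernel(matrix(c(0, 1), 2, 1))
  expect_equal(km1$k[1, 2], exp(-1))          # d = 1
  expect_equal(km$mu, mean(km$k))
})

test_that("theta matrix balances similar and dissimilar mass", {
  km <- structure(list(k = rbind(c(1, 0.5), c(0.5, 1)), mu = 0.75),
                  class = "kernel_matrix")
  th <- theta_matrix(km)
  expect_equal(th, rbind(c(0.5, -0.5), c(-0.5, 0.5)))
  # positive mass +1, negative mass -1, total 0 on a random kernel
  z <- matrix(stats::rnorm(24), 8, 3)
  th2 <- theta_matrix(rbf_kernel(z))
  expect_equal(sum(th2[th2 > 0]), 1)
  expect_equal(sum(th2[th2 < 0]), -1)
  expect_equal(sum(th2), 0)
  expect_true(isSymmetric(th2))
  const <- structure(list(k = matrix(1, 3, 3), mu = 1),
                     class = "kernel_matrix")
  expect_error(theta_matrix(const), "degenerate")
})

test_that("omega matrix counts ordered labeled pairs", {
  om <- omega_matrix(c(1, -1))
  expect_equal(om, rbind(c(0.5, -0.5), c(-0.5, 0.5)))
  expect_equal(omega_matrix(c(NA, NA, NA)), matrix(0, 3, 3))
  # y = (+1, +1, -1): |M| = 5, |C| = 4 over ordered pairs incl. diagonal
  om3 <- omega_matrix(c(1, 1, -1))
  expect_equal(sum(om3 > 0), 5)
  expect_equal(sum(om3 < 0), 4)
  expect_equal(om3[1, 2], 1 / 5)
  expect_equal(om3[1, 3], -1 / 4)
  # unlabeled rows/columns are zero
  om4 <- omega_matrix(c(1, NA, -1))
  expect_equal(om4[2, ], c(0, 0, 0))
  expect_error(omega_matrix(c(1, 1)), "single-class")
})

test_that("guidance Laplacian identities hold", {
  phi <- rbind(c(0.5, -0.5), c(-0.5, 0.5))
  lap <- build_laplacian(phi)
  expect_equal(lap$L, rbind(c(-0.5, 0.5), c(0.5, -0.5)))
  expect_equal(lap$Lhat, rbind(c(-0.5, 0), c(0, -0.5)))
  expect_equal(as.numeric(lap$L %*% rep(1, 2)), c(0, 0))

  # lambda = 0 collapses to the supervision-only limit
  om <- omega_matrix(c(1, 1, -1))
  th <- matrix(stats::rnorm(9), 3, 3); th <- th + t(th)
  lap0 <- build_laplacian(om, list(th), weights = 0)
  expect_equal(lap0$phi, om)
  expect_error(build_laplacian(om, list(matrix(0, 2, 2))), "shape")
})

test_that("quadratic form identity and diagonal invariance hold on random draws", {
  withr::with_seed(42, {
    for (rep in 1:25) {
      n <- sample(3:10, 1)
      phi <- matrix(rnorm(n * n), n, n)
      phi <- (phi + t(phi)) / 2
      lap <- build_laplacian(phi)
      f <- sample(0:1, n, replace = TRUE)
      q <- as.numeric(t(f) %*% lap$L %*% f)
      pairwise <- 0.5 * sum(phi * outer(f, f, function(a, b) (a - b)^2))
      expect_equal(q, pairwise, tolerance = 1e-9)
      # row sums of L vanish
      expect_equal(as.numeric(lap$L %*% rep(1, n)), rep(0, n),
                   tolerance = 1e-12)
      # perturbing the diagonal of phi leaves the quadratic form unchanged
      phi2 <- phi; diag(phi2) <- diag(phi2) + rnorm(n)
      lap2 <- build_laplacian(phi2)
      q2 <- as.numeric(t(f) %*% lap2$L %*% f)
      expect_equal(q, q2, tolerance = 1e-9)
      # truncation premises
      expect_true(all(lap$Lhat <= lap$L + 1e-15))
      expect_true(all(lap$Lhat <= 0))
    }
  })
})

test_that("consistency test behaves at the symmetric null and rejects separation", {
  # degenerate equal samples: symmetric null
  feats <- matrix(1, 6, 2)  # constant kernel entries
  km <- structure(list(k = matrix(1, 6, 6), mu = 1), class = "kernel_matrix")
  ct <- consistency_test(km, c(1, 1, 1, -1, -1, -1), seed = 1)
  expect_equal(ct$statistic, 0)
  expect_equal(ct$p_value, 0.5)

  # strong class separation in feature space is detected
  withr::with_seed(7, {
    n <- 40; d <- 5
    y <- c(rep(1, 20), rep(-1, 20))
    z <- matrix(rnorm(n * d), n, d)
    z[y > 0, ] <- z[y > 0, ] + 3 / sqrt(d)
    ct2 <- consistency_test(side_view(z), y, seed = 99)
    expect_lt(ct2$p_value, 0.05)
    expect_gt(ct2$statistic, 0)
  })

  # reproducible under the same seed
  withr::with_seed(8, z2 <- matrix(rnorm(30 * 3), 30, 3))
  y2 <- rep(c(1, -1), 15)
  a <- consistency_test(side_view(z2), y2, seed = 5)
  b <- consistency_test(side_view(z2), y2, seed = 5)
  expect_identical(a, b)

  expect_error(consistency_test(km, c(1, 1, 1, 1, 1, 1)),
               "within-class and between-class")
})
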