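# PCA reduction, SOBI joint diagonalization, FastICA.

test_that("PCA on exact rank-2 data puts all variance in two components", {
  n <- 400
  s1 <- sin(2 * pi * 0.2 * (1:n) / 16)
  s2 <- sin(2 * pi * 1.1 * (1:n) / 16 + 0.3)
  A <- matrix(rnorm(2 * 12), 2, 12)
  X <- cbind(s1, s2) %*% A
  m <- as_sg_matrix(X)
  ss <- pca_reduce(m, n_components = 10, standardize = FALSE)
  expect_lt(sum(ss$explained_variance[3:10]), 1e-10)
  expect_equal(sum(ss$explained_variance[1:2]), 1, tolerance = 1e-10)
  # component time series mutually uncorrelated
  cc <- cor(ss$sources[, 1:2])
  expect_lt(abs(cc[1, 2]), 1e-8)
})

test_that("PCA component scores are pairwise uncorrelated on noisy data", {
  ss <- default_pca()
  cc <- cor(ss$sources)
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-8)
  # non-increasing variance fractions
  expect_true(all(diff(ss$explained_variance) <= 1e-12))
  expect_lte(sum(ss$explained_variance), 1)
})

test_that("ten components describe over 90% of default-stack variance", {
  m <- default_sg_matrix()
  ss <- pca_reduce(m, n_components = 10, standardize = FALSE)
  # oracle: direct eigenvalue sum of the column covariance
  ev <- eigen(cov(sweep(m$values, 2, colMeans(m$values))),
              symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(ss$explained_variance), sum(ev[1:10]) / sum(ev),
               tolerance = 1e-10)
  expect_gt(sum(ss$explained_variance), 0.9)
})

test_that("PCA validates component counts", {
  m <- as_sg_matrix(matrix(rnorm(50 * 4), 50, 4))
  expect_error(pca_reduce(m, n_components = 10),
               class = "sgmotion_invalid_parameter")
})

test_that("SOBI unmixes sinusoid mixtures to correlation > 0.999", {
  n <- 2000; fs <- 16
  t <- (1:n) / fs
  S <- cbind(sin(2 * pi * 0.25 * t), sin(2 * pi * 1.1 * t + 1))
  set.seed(5)
  A <- matrix(rnorm(4), 2, 2)
  X <- S %*% t(A)
  ss <- pca_reduce(as_sg_matrix(X, fs_hz = fs), n_components = 2,
                   standardize = FALSE)
  out <- sobi(ss, lags = 1:20)
  C <- abs(cor(out$sources, S))
  # each recovered source matches one truth source up to sign/permutation
  expect_true(all(apply(C, 2, max) > 0.999))
  expect_true(all(apply(C, 1, max) > 0.999))
})

test_that("SOBI is a fixed point on already-diagonal lagged covariances", {
  n <- 3000; fs <- 16
  t <- (1:n) / fs
  # uncorrelated narrowband sources, no mixing: already diagonal
  S <- cbind(sin(2 * pi * 0.2 * t), sin(2 * pi * 1.3 * t + 0.7))
  S <- scale(S)
  ss <- structure(list(sources = S, whitened = S, whitening = NULL,
                       method = "PCA", fs_hz = fs, converged = TRUE),
                  class = "source_set")
  out <- sobi(ss, lags = c(1, 3, 5))
  P <- abs(cor(out$sources, S))
  expect_true(all(apply(P, 2, max) > 1 - 1e-6))
  # off-diagonal criterion cannot increase
  expect_true(all(diff(out$criterion) <= 1e-12))
})

test_that("2x2 joint diagonalization matches an exhaustive angle search", {
  set.seed(11)
  n <- 1500
  S <- cbind(sin(2 * pi * 0.3 * (1:n) / 16), sin(2 * pi * 1.4 * (1:n) / 16))
  A <- matrix(c(1, 0.8, -0.5, 1.2), 2, 2)
  X <- scale(S %*% t(A), scale = FALSE)
  # whiten
  eg <- eigen(cov(X), symmetric = TRUE)
  Z <- X %*% eg$vectors %*% diag(1 / sqrt(eg$values))
  lags <- 1:10
  Rs <- lapply(lags, function(l) {
    C <- crossprod(Z[1:(n - l), ], Z[(l + 1):n, ]) / (n - l)
    (C + t(C)) / 2
  })
  off2 <- function(mats) sum(vapply(mats, function(M) sum(M^2) - sum(diag(M)^2),
                                    numeric(1)))
  rotate_all <- function(th) {
    R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
    lapply(Rs, function(M) t(R) %*% M %*% R)
  }
  # oracle: brute-force grid over rotation angles at 1e-4 rad resolution
  grid <- seq(-pi / 4, pi / 4, by = 1e-4)
  crits <- vapply(grid, function(th) off2(rotate_all(th)), numeric(1))
  th_star <- grid[which.min(crits)]

  jd <- sgmotion:::joint_diagonalize(Rs)
  V <- jd$rotation
  # sources = Z V, so V corresponds to the grid's R(theta) at -theta
  th_hat <- atan2(V[1, 2], V[1, 1])
  # angles are equivalent modulo pi/2 (permutation) and sign
  wrap <- function(x) {
    x <- x %% (pi / 2)
    pmin(x, pi / 2 - x)
  }
  expect_lt(wrap(abs(th_hat - th_star)), 2e-4)
  expect_lte(tail(jd$criterion, 1), min(crits) + 1e-10)
})

test_that("FastICA separates uniform sources and is seed-reproducible", {
  set.seed(3)
  n <- 4000
  S <- cbind(runif(n, -1, 1), runif(n, -1, 1))
  A <- matrix(c(2, 1, 1, 1.5), 2, 2)
  X <- S %*% t(A)
  ss <- pca_reduce(as_sg_matrix(X), n_components = 2, standardize = FALSE)
  out1 <- fastica(ss, seed = 42)
  C <- abs(cor(out1$sources, S))
  expect_true(all(apply(C, 2, max) > 0.99))
  out2 <- fastica(ss, seed = 42)
  expect_identical(out1$sources, out2$sources)
  expect_error(fastica(ss), class = "sgmotion_invalid_parameter")
})

test_that("FastICA handles the Gaussian non-identifiable case gracefully", {
  set.seed(8)
  X <- matrix(rnorm(3000 * 2), ncol = 2) %*% matrix(c(1, 0.4, 0.4, 1), 2, 2)
  ss <- pca_reduce(as_sg_matrix(X), n_components = 2, standardize = FALSE)
  out <- fastica(ss, seed = 1, max_iter = 50)
  # returns a flagged result, never an exception
  expect_type(out$converged, "logical")
  expect_true(all(is.finite(out$sources)))
})

test_that("all methods preserve the whitened subspace variance", {
  pc <- default_pca()
  k <- ncol(pc$whitened)
  total <- sum(apply(pc$whitened, 2, var))
  so <- sobi(pc)
  ic <- fastica(pc, seed = 2)
  expect_equal(sum(apply(so$sources, 2, var)), total, tolerance = 1e-8)
  expect_equal(sum(apply(ic$sources, 2, var)), total, tolerance = 1e-8)
})

test_that("SOBI separates RSA-coupled sources at least as well as PCA", {
  scores <- vapply(1:20, function(s) {
    gt <- simulate_physio(hr_sd_bpm = 2, rsa_gain_bpm = 6, duration_s = 90,
                          seed = s)
    st <- simulate_si_stack(gt, seed = s + 100)
    m <- correct_angular_dependence(assemble_sg_matrix(st))
    pc <- pca_reduce(m)
    so <- sobi(pc)
    truth <- cbind(st$sources$resp, st$sources$cardiac)
    c(pca = amari_from_sources(pc$sources, truth),
      sobi = amari_from_sources(so$sources, truth))
  }, numeric(2))
  expect_lte(mean(scores["sobi", ]), mean(scores["pca", ]))
})
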