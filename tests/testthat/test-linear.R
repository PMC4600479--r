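test_that("whitening normalizes channel noise variance", {
  M <- matrix(1:8, 2)
  G <- matrix(rnorm(6), 2)
  w1 <- whiten(M, G, c(1, 1))
  expect_equal(w1$M_w, M, ignore_attr = TRUE)
  w4 <- whiten(M, G, c(4, 4))
  expect_equal(w4$M_w, M / 2)
  expect_equal(w4$G_w, G / 2)
  set.seed(8)
  E <- diag(c(2, 5)) %*% matrix(rnorm(2e4), 2)
  v <- apply(E, 1, var)
  Ew <- whiten(E, G, v)$M_w
  expect_equal(unname(apply(Ew, 1, var)), c(1, 1), tolerance = 1e-12)
  expect_error(whiten(M, G, c(1, 0)), "> 0")
})

test_that("L-curve quantities are monotone and the corner is found", {
  set.seed(9)
  # ill-posed toy: decaying spectrum plus noise gives a genuine corner
  q <- 40
  U <- qr.Q(qr(matrix(rnorm(q * q), q)))
  V <- qr.Q(qr(matrix(rnorm(120 * q), 120, q)))
  d <- exp(-seq(0, 8, length.out = q))
  G <- U %*% (d * t(V))
  M <- G %*% (V %*% rnorm(q)) + 1e-3 * rnorm(q)
  lc <- lcurve_lambda(M, G)
  expect_true(all(diff(lc$residual_norm) > -1e-12))
  expect_true(all(diff(lc$solution_norm) < 1e-12))
  i <- which(lc$grid == lc$lambda)
  expect_gt(i, 2)
  expect_lt(i, 59)
  # residual at the corner sits near the noise level
  expect_lt(lc$residual_norm[i], 0.1)
  expect_equal(lcurve_lambda(M, G, grid = 0.5)$lambda, 0.5)
  expect_error(lcurve_lambda(matrix(0, 2, 1), matrix(0, 2, 2),
                             grid = c(1, 2, 3)), "degenerate")
})

test_that("a hand-placed corner maximizes the discrete curvature", {
  # piecewise-constructed L: vertical branch then horizontal branch
  rho <- c(1e-3 * (1 + 1e-4 * (1:8)), 10^seq(-2.9, 0, length.out = 8))
  eta <- c(10^seq(2, 0.1, length.out = 8), 1 - 1e-4 * (1:8))
  x <- log(rho); y <- log(eta)
  n <- length(x)
  kap <- rep(-Inf, n)
  for (j in 2:(n - 1)) {
    x1 <- (x[j + 1] - x[j - 1]) / 2; y1 <- (y[j + 1] - y[j - 1]) / 2
    x2 <- x[j + 1] - 2 * x[j] + x[j - 1]
    y2 <- y[j + 1] - 2 * y[j] + y[j - 1]
    kap[j] <- (x1 * y2 - y1 * x2) / (x1^2 + y1^2)^1.5
  }
  expect_true(which.max(kap) %in% c(8, 9))
})

test_that("MNE solves the Tikhonov normal equations", {
  est <- mne_solve(matrix(4, 1, 1), matrix(2, 1, 1), 1)
  expect_equal(est$J[1, 1], 1.6)
  expect_equal(mne_solve(matrix(0, 1, 1), matrix(2, 1, 1), 1)$J[1, 1], 0)
  # lambda -> 0 with square invertible G recovers the direct inverse
  set.seed(10)
  G <- matrix(rnorm(16), 4) + diag(4)
  M <- matrix(rnorm(8), 4)
  est0 <- mne_solve(M, G, 1e-10)
  expect_equal(est0$J, solve(G, M), tolerance = 1e-6)
  # exact linearity in the data
  M1 <- matrix(rnorm(8), 4); M2 <- matrix(rnorm(8), 4)
  ea <- mne_solve(2 * M1 - 3 * M2, G, 0.7)$J
  expect_equal(ea, 2 * mne_solve(M1, G, 0.7)$J -
                 3 * mne_solve(M2, G, 0.7)$J, tolerance = 1e-10)
  expect_error(mne_solve(M, G, 0), "> 0")
})

test_that("dSPM normalizes rows by their noise standard deviation", {
  # scalar toy: output magnitude equals the data under unit noise
  est <- dspm_solve(matrix(3, 1, 1), matrix(0.5, 1, 1), 0.2)
  expect_equal(abs(est$J[1, 1]), 3, tolerance = 1e-12)
  expect_equal(dspm_solve(matrix(0, 1, 1), matrix(0.5, 1, 1), 0.2)$J[1, 1],
               0)
  # invariant to rescaling a row of the MNE operator: normalization
  # divides it out, so doubling noise sd and data together cancels
  set.seed(11)
  G <- matrix(rnorm(30), 5, 6)
  M <- matrix(rnorm(10), 5)
  a <- dspm_solve(M, G, 0.5)
  b <- dspm_solve(3 * M, 3 * G, 0.5 * 9, sigma_d = rep(9, 5))
  expect_equal(abs(a$J), abs(b$J), tolerance = 1e-8)
})

test_that("sLORETA has zero localization error for noiseless dipoles", {
  geo <- tiny_cortex(2)
  lf <- meg_leadfield_sphere(geo$mesh, geo$head, geo$meg)
  Gw <- lf$G / max(abs(lf$G))
  lam <- 1e-4 * sum(Gw^2) / nrow(Gw)
  misses <- 0
  for (j in seq_len(ncol(Gw))) {
    est <- sloreta_solve(Gw[, j, drop = FALSE], Gw, lam)
    if (which.max(abs(est$J[, 1])) != j) misses <- misses + 1
  }
  expect_equal(misses, 0)
  expect_equal(sloreta_solve(matrix(0, nrow(Gw), 1), Gw, lam)$J[, 1],
               numeric(ncol(Gw)))
})

test_that("noise-normalized maps are invariant to global rescaling", {
  set.seed(12)
  G <- matrix(rnorm(40), 5, 8)
  M <- matrix(rnorm(15), 5)
  c0 <- 2.7
  a <- dspm_solve(M, G, 0.5)
  b <- dspm_solve(c0 * M, c0 * G, 0.5 * c0^2, sigma_d = rep(c0^2, 5))
  expect_equal(a$J, b$J, tolerance = 1e-8)
  a2 <- sloreta_solve(M, G, 0.5)
  b2 <- sloreta_solve(c0 * M, c0 * G, 0.5 * c0^2)
  expect_equal(a2$J, b2$J, tolerance = 1e-8)
})

test_that("noise normalization reduces the depth bias of MNE", {
  # truth at the deepest vertex of a strongly folded cortex, noiseless
  geo <- build_synthetic_cortex(2, folding = list(amplitude = 9,
                                                  n_waves = 12,
                                                  frequency = 6),
                                radius = 80, seed = 3)
  lf <- eeg_leadfield_sphere(geo$mesh, geo$head, geo$eeg)
  Gw <- lf$G / max(abs(lf$G))
  r <- memfusion:::row_norms(geo$mesh$vertices)
  j <- which.min(r)
  m <- Gw[, j, drop = FALSE]
  lam <- 1e-3 * sum(Gw^2) / nrow(Gw)
  err <- function(est) {
    k <- which.max(abs(est$J[, 1]))
    sqrt(sum((geo$mesh$vertices[k, ] - geo$mesh$vertices[j, ])^2))
  }
  e_mne <- err(mne_solve(m, Gw, lam))
  expect_lte(err(dspm_solve(m, Gw, lam)), e_mne)
  expect_lte(err(sloreta_solve(m, Gw, lam)), e_mne)
})
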