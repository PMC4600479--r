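test_that("compute_snr is the peak maximum over the baseline std", {
  M <- rbind(c(0, 4, 0), c(1, 2, 1))
  base <- rbind(c(2, -2, 2, -2), c(2, -2, 2, -2))
  # pooled baseline sd: mean 0, squared dev 4 each, n/(n-1) correction
  s <- sqrt(4 * 4 / 3)
  expect_equal(compute_snr(M, base, peak_index = 2), 4 / s)
  expect_equal(compute_snr(matrix(0, 2, 3), base), 0)
  expect_equal(compute_snr(3 * M, base), 3 * compute_snr(M, base))
  expect_error(compute_snr(M, matrix(1, 2, 4)), "constant")
})

test_that("cancellation index limits and hand example hold", {
  g <- matrix(rnorm(10), 10, 1)
  expect_equal(cancellation_index(cbind(g, -g), c(1, 2)), 1)
  expect_equal(cancellation_index(g, 1), 0)
  G <- rbind(c(1, 0), c(0, 1))
  expect_equal(cancellation_index(G, c(1, 2)), 1 - sqrt(2) / 2)
  # scale invariance
  G2 <- matrix(rnorm(40), 8, 5)
  expect_equal(cancellation_index(G2, 1:4),
               cancellation_index(17.3 * G2, 1:4), tolerance = 1e-12)
  expect_error(cancellation_index(matrix(0, 3, 2), 1), "zero")
  expect_error(cancellation_index(G2, integer(0)), "empty")
})

test_that("white background matches the requested std and is centred", {
  N <- generate_background(6, 1e4, spectral_slope = 0, alpha_power = 0,
                           target_sd = 2, seed = 3)
  sds <- apply(N, 1, sd)
  expect_true(all(abs(sds - 2) / 2 < 0.05))
  expect_true(all(abs(rowMeans(N)) < 3 * sds / sqrt(1e4)))
  expect_identical(N, generate_background(6, 1e4, spectral_slope = 0,
                                          alpha_power = 0, target_sd = 2,
                                          seed = 3))
})

test_that("coloured background is reproducible and distinct across seeds", {
  a <- generate_background(4, 512, seed = 9)
  b <- generate_background(4, 512, seed = 9)
  d <- generate_background(4, 512, seed = 10)
  expect_identical(a, b)
  expect_false(identical(a, d))
})

test_that("brain-noise generator shares latent activity across modalities", {
  geo <- tiny_cortex(2)
  lfs <- list(EEG = eeg_leadfield_sphere(geo$mesh, geo$head, geo$eeg),
              MEG = meg_leadfield_sphere(geo$mesh, geo$head, geo$meg))
  gen <- brain_noise_generator(lfs, n_latent = 50, white_fraction = 0)
  Ne <- gen("EEG", 54, 128, seed = 4)
  Nm <- gen("MEG", 272, 128, seed = 4)
  expect_identical(Ne, gen("EEG", 54, 128, seed = 4))
  # same latent sources: with no sensor noise both modalities span the
  # same 50-dimensional temporal subspace, so MEG rows project fully
  # onto the EEG temporal space
  Ve <- svd(Ne, nu = 0)$v[, 1:50]
  resid <- Nm - (Nm %*% Ve) %*% t(Ve)
  expect_lt(max(abs(resid)), 1e-8 * max(abs(Nm)))
  expect_equal(mean(apply(Ne, 1, sd)), 1, tolerance = 1e-8)
})

test_that("scale_background hits the target ratio as a fixed point", {
  set.seed(5)
  M0 <- matrix(rnorm(40), 4, 10)
  N <- matrix(rnorm(40), 4, 10)
  out <- scale_background(M0, N, target_ratio = 2)
  expect_equal(compute_snr(M0, out$scaled), 2, tolerance = 1e-9)
  out4 <- scale_background(M0, N, target_ratio = 4)
  expect_equal(out4$scale, out$scale / 2, tolerance = 1e-12)
  expect_error(scale_background(M0, matrix(0, 4, 10), 1), "zero")
})

test_that("static simulation satisfies M = G Jth + scaled noise", {
  geo <- tiny_cortex(2)
  lfs <- list(MEG = meg_leadfield_sphere(geo$mesh, geo$head, geo$meg))
  patch <- grow_patch(geo$mesh, 31, 2)
  spike <- gamma_spike()
  noiseless <- simulate_static(geo$mesh, lfs, patch, spike,
                               noise = list(target_ratio = Inf), seed = 2)
  M0 <- lfs$MEG$G[, patch$vertices] %*%
    (ground_truth_current(noiseless)[patch$vertices, ] * 1e-9)
  expect_equal(noiseless$M$MEG, M0, tolerance = 1e-12)
  # noiseless data are rank one (topography times waveform)
  sv <- svd(noiseless$M$MEG)$d
  expect_lt(sv[2] / sv[1], 1e-10)
  noisy <- simulate_static(geo$mesh, lfs, patch, spike,
                           noise = list(target_ratio = 1), seed = 2)
  expect_identical(noisy$M,
                   simulate_static(geo$mesh, lfs, patch, spike,
                                   noise = list(target_ratio = 1),
                                   seed = 2)$M)
  # forward consistency: recording minus stored noise equals G Jth
  expect_equal(noisy$M$MEG - (noisy$M$MEG - M0), M0)
  expect_gt(noisy$snr$MEG, 0)
})

test_that("SNR at fixed amplitude drops with source depth", {
  geo <- tiny_cortex(1)
  hd <- geo$head
  ico <- memfusion:::icosphere(1)
  N <- generate_background(54, 2 * length(gamma_spike()$w), seed = 8)
  snrs <- vapply(c(85, 70, 55, 40), function(rr) {
    mesh <- cortical_mesh(ico$vertices * rr, ico$faces)
    lf <- eeg_leadfield_sphere(mesh, hd, geo$eeg)
    patch <- grow_patch(mesh, 17, 1)
    sim <- simulate_static(mesh, list(EEG = lf), patch,
                           noise = list(scale = list(EEG = 1e-7)),
                           seed = 8)
    compute_snr(sim$M$EEG, sim$E$EEG,
                peak_index = sim$spikes[[1]]$peak_index)
  }, numeric(1))
  expect_true(all(diff(snrs) < 0))
})

test_that("propagation delays the second source and enforces geometry", {
  geo <- tiny_cortex(3)
  mesh <- geo$mesh
  lfs <- list(MEG = meg_leadfield_sphere(mesh, geo$head, geo$meg))
  s1 <- which.max(mesh$vertices[, 1])
  ring <- which(memfusion:::graph_bfs_dist(mesh$adjacency, s1, 11) == 10)
  ring <- ring[sign(mesh$vertices[ring, 1]) ==
                 sign(mesh$vertices[s1, 1])]
  s2 <- ring[1]
  p1 <- grow_patch(mesh, s1, 2)
  p2 <- grow_patch(mesh, s2, 2)
  sim <- simulate_propagation(mesh, lfs, p1, p2, delay_ms = 15,
                              noise = list(target_ratio = Inf), seed = 3)
  # the second spike peaks 15 ms (9 samples at 600 Hz) later
  expect_equal(sim$spikes[[2]]$peak_index - sim$spikes[[1]]$peak_index, 9)
  # at source-1's peak, source 2's sensor contribution is the weaker one
  pk <- sim$spikes[[1]]$peak_index
  c1 <- lfs$MEG$G[, p1$vertices] %*% (sim$Jth_patch[[1]][, pk] * 1e-9)
  c2 <- lfs$MEG$G[, p2$vertices] %*% (sim$Jth_patch[[2]][, pk] * 1e-9)
  expect_lt(sqrt(sum(c2^2)), sqrt(sum(c1^2)))
  # delay 0 equals a two-patch static source
  sim0 <- simulate_propagation(mesh, lfs, p1, p2, delay_ms = 0,
                               noise = list(target_ratio = Inf), seed = 3)
  two_static <- simulate_patches_ref(mesh, lfs, p1, p2)
  expect_equal(sim0$M$MEG, two_static, tolerance = 1e-12)
  # overlapping patches rejected
  expect_error(simulate_propagation(mesh, lfs, p1,
                                    grow_patch(mesh, s1, 3),
                                    noise = list(target_ratio = Inf)),
               "overlap")
  # wrong separation rejected
  expect_error(simulate_propagation(mesh, lfs, p1, p2,
                                    separation_order = 5,
                                    noise = list(target_ratio = Inf)),
               "distance")
})

test_that("perturb_rbs draws a truncated normal on [15, 25]", {
  hd <- head_model()
  h0 <- perturb_rbs(hd, sd = 0, seed = 1)
  expect_equal(h0$rbs, 20, tolerance = 1e-12)
  draws <- vapply(1:2000, function(i) perturb_rbs(hd, seed = i)$rbs,
                  numeric(1))
  expect_true(all(draws >= 15 & draws <= 25))
  expect_equal(mean(draws), 20, tolerance = 0.15)
  expect_equal(perturb_rbs(hd, seed = 42)$rbs,
               perturb_rbs(hd, seed = 42)$rbs)
  expect_error(perturb_rbs(hd, sd = -1), "degenerate")
})
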