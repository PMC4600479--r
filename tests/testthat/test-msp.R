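test_that("MSP scores are projections onto the retained data subspace", {
  set.seed(3)
  q <- 12
  G <- qr.Q(qr(matrix(rnorm(q * q), q)))      # orthonormal columns
  w <- rnorm(8)
  M <- G[, 1, drop = FALSE] %*% rbind(w)
  msp <- msp_scores(M, G, l = 1)
  expect_equal(msp$scores[1], 1, tolerance = 1e-12)
  expect_lt(max(msp$scores[-1]), 1e-20)
  # a column orthogonal to the retained subspace scores zero
  expect_equal(msp$l, 1)
})

test_that("MSP scores stay within [0, 1] on random instances", {
  set.seed(4)
  for (r in 1:100) {
    q <- sample(3:10, 1)
    p <- sample(3:20, 1)
    tau <- sample(2:8, 1)
    G <- matrix(rnorm(q * p), q, p)
    M <- matrix(rnorm(q * tau), q, tau)
    sc <- msp_scores(M, G)$scores
    expect_true(all(sc >= 0 & sc <= 1))
  }
  expect_error(msp_scores(matrix(0, 3, 2), matrix(1, 3, 2)), "zero data")
  expect_error(msp_scores(matrix(1, 3, 2), cbind(c(1, 1, 1), 0)),
               "zero-norm")
})

test_that("baseline component rule keeps directions above background", {
  set.seed(5)
  q <- 20; tau <- 40
  base <- matrix(rnorm(q * tau), q, tau)
  topo <- rnorm(q) * 4
  M <- outer(topo, sin(seq_len(tau) / 3)) * 3 + matrix(rnorm(q * tau), q, tau)
  G <- matrix(rnorm(q * 15), q, 15)
  msp <- msp_scores(M, G, baseline = base)
  expect_gte(msp$l, 1)
  expect_lt(msp$l, 5)
  # pure noise data falls back to a single component
  msp0 <- msp_scores(matrix(rnorm(q * tau), q, tau), G, baseline = base)
  expect_equal(msp0$l, 1)
})

test_that("probabilistic OR fusion dominates both inputs", {
  a <- c(0, 1, 0.5, 0.2)
  b <- c(0.3, 1, 0.5, 0.9)
  f <- fuse_msp(a, b)$scores
  expect_equal(f, c(0.3, 1, 0.75, 0.92))
  expect_equal(fuse_msp(rep(0, 4), b)$scores, b)
  set.seed(6)
  for (r in 1:50) {
    x <- runif(10); y <- runif(10)
    z <- fuse_msp(x, y)$scores
    expect_true(all(z >= pmax(x, y) - 1e-12 & z <= 1))
  }
  expect_error(fuse_msp(a, b[1:3]), "lengths")
})

test_that("DDP tiles the surface with connected parcels", {
  geo <- tiny_cortex(2)
  set.seed(7)
  scores <- runif(nrow(geo$mesh$vertices))
  parc <- ddp_parcellate(scores, geo$mesh, scale = 2)
  expect_parcellation_valid(parc, geo$mesh)
  expect_lt(parc$K, nrow(geo$mesh$vertices))
  # deterministic
  parc2 <- ddp_parcellate(scores, geo$mesh, scale = 2)
  expect_identical(parc$parcel, parc2$parcel)
})

test_that("a unimodal score map on a small mesh yields one parcel", {
  geo <- tiny_cortex(1)
  mesh <- geo$mesh
  d <- memfusion:::graph_bfs_dist(mesh$adjacency, 1)
  scores <- 1 - d / (max(d) + 1)       # strictly decreasing from vertex 1
  parc <- ddp_parcellate(scores, mesh, scale = max(d))
  expect_equal(parc$K, 1L)
  expect_equal(parc$seeds, 1L)
})

test_that("uniform scores still produce a deterministic full partition", {
  geo <- tiny_cortex(1)
  parc <- ddp_parcellate(rep(0.5, nrow(geo$mesh$vertices)), geo$mesh,
                         scale = 1)
  expect_parcellation_valid(parc, geo$mesh)
  # lowest-index tie-break: vertex 1 seeds the first parcel
  expect_equal(parc$seeds[1], 1L)
})

test_that("two well-separated score bumps give two leading parcels", {
  geo <- tiny_cortex(2)
  mesh <- geo$mesh
  v1 <- 1
  v2 <- which.max(memfusion:::graph_bfs_dist(mesh$adjacency, v1))
  d1 <- memfusion:::graph_bfs_dist(mesh$adjacency, v1)
  d2 <- memfusion:::graph_bfs_dist(mesh$adjacency, v2)
  scores <- pmax(1 - d1 / 4, 1 - d2 / 4, 0)
  parc <- ddp_parcellate(scores, mesh, scale = 4)
  expect_true(all(c(v1, v2) %in% parc$seeds[1:2]))
  expect_true(parc$parcel[v1] != parc$parcel[v2])
  expect_parcellation_valid(parc, mesh)
})

test_that("scale-4 parcel counts land in the low hundreds at 4-mm scale", {
  # ~3 mm mesh, comparable to a clinical-resolution cortical surface
  geo <- build_synthetic_cortex(5, folding = list(amplitude = 0),
                                radius = 80, seed = 2)
  set.seed(8)
  d <- memfusion:::graph_bfs_dist(geo$mesh$adjacency, 17)
  scores <- 0.5 + 0.5 * cos(d / 6) * exp(-d / 40)   # smooth bumpy map
  parc <- ddp_parcellate(scores, geo$mesh, scale = 4)
  expect_gt(parc$K, 100)
  expect_lt(parc$K, 1000)
})

test_that("alpha initialization is the clipped per-parcel median", {
  parc <- structure(list(parcel = c(1L, 1L, 1L, 2L, 2L), K = 2L,
                         seeds = c(1L, 4L), scale = 1),
                    class = "parcellation")
  alpha <- init_alpha(parc, c(0.2, 0.4, 0.9, 0.7, 0.7))
  expect_equal(alpha, c(0.4, 0.7))
  expect_equal(init_alpha(parc, rep(0.3, 5)), c(0.3, 0.3))
  expect_equal(init_alpha(parc, rep(1, 5)), c(1 - 1e-3, 1 - 1e-3))
  expect_equal(init_alpha(parc, rep(0, 5), eps = 0.01), c(0.01, 0.01))
})
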