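# Independent oracles and shared fixtures for the test suite.

# Closed-form surface potential of a current monopole inside an
# insulated homogeneous sphere (generating-function form of the
# spherical-harmonic series). x = source radius / sphere radius,
# c = cos(angle between source and surface point).
oracle_mono_surface <- function(x, c, sigma, R) {
  g <- 1 / sqrt(1 - 2 * x * c + x^2)
  S <- 2 * (g - 1) - log((1 - x * c + 1 / g) / 2)
  S / (4 * pi * sigma * R)
}

# Dipole potential as a two-monopole finite difference of the closed
# form; positions in metres, moment unit vector times 1 A.m.
oracle_dipole_homog <- function(ele_dir, r0, m, sigma, R,
                                delta = 1e-4 * R) {
  mhat <- m / sqrt(sum(m^2))
  mom <- sqrt(sum(m^2))
  val <- 0
  for (s in c(1, -1)) {
    pos <- r0 + s * delta / 2 * mhat
    b <- sqrt(sum(pos^2))
    cc <- sum(ele_dir * pos) / b
    val <- val + s * oracle_mono_surface(b / R, cc, sigma, R)
  }
  val * mom / delta
}

# Radial component of the free-space (primary) dipole field: outside a
# spherically symmetric conductor the volume currents contribute
# nothing to B_r, so this equals the full field projected radially.
oracle_meg_radial <- function(r, r0, Q) {
  d <- r - r0
  cr <- c(Q[2] * d[3] - Q[3] * d[2],
          Q[3] * d[1] - Q[1] * d[3],
          Q[1] * d[2] - Q[2] * d[1])
  1e-7 * sum(cr * r) / (sum(d^2)^1.5 * sqrt(sum(r^2)))
}

# Brute-force pairwise AUC (independent of the package implementation).
oracle_auc <- function(pos, neg) {
  wins <- 0
  for (a in pos) for (b in neg) {
    wins <- wins + (a > b) + 0.5 * (a == b)
  }
  wins / (length(pos) * length(neg))
}

# Small shared geometries, built once per test run.
.fixture_env <- new.env(parent = emptyenv())

tiny_cortex <- function(n_subdivisions = 2, seed = 11) {
  key <- paste0("geo", n_subdivisions, "_", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- build_synthetic_cortex(n_subdivisions,
                                                  seed = seed)
  }
  .fixture_env[[key]]
}

# A fake "mesh" carrying only an adjacency list (for pure graph tests).
path_mesh <- function(n) {
  adj <- lapply(seq_len(n), function(i) {
    c(if (i > 1) i - 1L, if (i < n) i + 1L)
  })
  structure(list(adjacency = adj, cache = new.env()), class = "cortical_mesh")
}

# One-parcel scalar reference model on a 1-vertex "mesh".
scalar_model <- function(alpha, eta) {
  parc <- structure(list(parcel = 1L, K = 1L, seeds = 1L, scale = 1),
                    class = "parcellation")
  mesh1 <- list(adjacency = list(integer(0)))
  build_reference_model(parc, alpha, mesh1, eta = eta,
                        smoothing_order = 0)
}

# Independent noiseless forward projection of two simultaneous patches.
simulate_patches_ref <- function(mesh, lfs, p1, p2) {
  spike <- gamma_spike()
  G <- lfs[[1]]$G
  topo <- rowSums(G[, p1$vertices, drop = FALSE]) * p1$amplitude +
    rowSums(G[, p2$vertices, drop = FALSE]) * p2$amplitude
  outer(topo, spike$w) * 1e-9
}

expect_parcellation_valid <- function(parc, mesh) {
  p <- length(mesh$adjacency)
  expect_length(parc$parcel, p)
  expect_true(all(parc$parcel >= 1 & parc$parcel <= parc$K))
  expect_setequal(unique(parc$parcel), seq_len(parc$K))
  # each parcel connected on the mesh graph
  for (k in seq_len(parc$K)) {
    members <- which(parc$parcel == k)
    reached <- members[1]
    frontier <- reached
    while (length(frontier) > 0) {
      nxt <- intersect(unique(unlist(mesh$adjacency[frontier])), members)
      nxt <- setdiff(nxt, reached)
      reached <- c(reached, nxt)
      frontier <- nxt
    }
    expect_setequal(reached, members)
  }
}
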