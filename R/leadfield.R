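#' Lead-field container
#'
#' `G` maps dipole amplitudes (A.m) at the mesh vertices, oriented along
#' the outward vertex normals, to sensor measurements (EEG: volts, with
#' average reference; MEG: tesla).
#'
#' @param G q x p gain matrix.
#' @param modality `"EEG"` or `"MEG"`.
#' @param provenance `"analytic"` or `"file"`.
#' @param labels channel labels.
#' @return A `leadfield` object.
#' @export
leadfield <- function(G, modality, provenance = "analytic", labels = NULL) {
  G <- as.matrix(G)
  if (!all(is.finite(G))) stop("lead field has non-finite entries")
  structure(list(G = G, modality = modality, provenance = provenance,
                 labels = labels),
            class = "leadfield")
}

#' @export
print.leadfield <- function(x, ...) {
  cat(sprintf("<leadfield> %s, %d channels x %d sources (%s)\n",
              x$modality, nrow(x$G), ncol(x$G), x$provenance))
  invisible(x)
}

## ---- EEG: multilayer concentric-sphere series ----

# Per-harmonic surface factors f_n for a dipole in the innermost region of
# a 3-shell concentric sphere, insulated outside. Radii are scaled by the
# scalp radius so all powers stay bounded. With f_n = 1 the series is the
# infinite homogeneous medium evaluated at the scalp radius.
sphere_shell_factors <- function(radii, conductivities, n_terms) {
  u <- radii / radii[3]
  s <- conductivities
  vapply(seq_len(n_terms), function(n) {
    np1 <- n + 1
    # unknowns: a1, A2, B2, A3, B3 (potential r^n / r^-(n+1) coefficients)
    A <- matrix(0, 5, 5)
    b <- numeric(5)
    u1 <- u[1]; u2 <- u[2]
    # continuity of V at r1:  u1^-(n+1) + a1 u1^n = A2 u1^n + B2 u1^-(n+1)
    A[1, ] <- c(u1^n, -u1^n, -u1^(-np1), 0, 0)
    b[1] <- -u1^(-np1)
    # continuity of sigma dV/dr at r1
    A[2, ] <- c(s[1] * n * u1^(n - 1),
                -s[2] * n * u1^(n - 1),
                s[2] * np1 * u1^(-(n + 2)), 0, 0)
    b[2] <- s[1] * np1 * u1^(-(n + 2))
    # continuity of V at r2
    A[3, ] <- c(0, u2^n, u2^(-np1), -u2^n, -u2^(-np1))
    # continuity of sigma dV/dr at r2
    A[4, ] <- c(0, s[2] * n * u2^(n - 1), -s[2] * np1 * u2^(-(n + 2)),
                -s[3] * n * u2^(n - 1), s[3] * np1 * u2^(-(n + 2)))
    # insulated scalp: dV/dr = 0 at r3 (= 1 in scaled units)
    A[5, ] <- c(0, 0, 0, n, -np1)
    x <- solve(A, b)
    x[4] + x[5]                     # scalp-surface factor A3 + B3
  }, numeric(1))
}

# Legendre P_n(c) and P_n'(c) for n = 1..L, vectorized over c.
legendre_terms <- function(c_vals, L) {
  m <- length(c_vals)
  P <- matrix(0, m, L + 1)          # columns: n = 0..L
  P[, 1] <- 1
  P[, 2] <- c_vals
  for (n in 1:(L - 1)) {
    P[, n + 2] <- ((2 * n + 1) * c_vals * P[, n + 1] - n * P[, n]) / (n + 1)
  }
  dP <- matrix(0, m, L + 1)
  s2 <- 1 - c_vals^2
  ok <- s2 > 1e-12
  for (n in 1:L) {
    dP[ok, n + 1] <- n * (P[ok, n] - c_vals[ok] * P[ok, n + 1]) / s2[ok]
    # poles: P_n'(±1) = (±1)^(n+1) n(n+1)/2
    dP[!ok, n + 1] <- sign(c_vals[!ok])^(n + 1) * n * (n + 1) / 2
  }
  list(P = P[, -1, drop = FALSE], dP = dP[, -1, drop = FALSE])
}

#' Analytic EEG lead field in a three-shell sphere
#'
#' Scalp potentials of the fixed-orientation cortical dipoles from the
#' standard multilayer concentric-sphere series expansion (Legendre
#' recurrences, truncated at `n_terms`), average-referenced over the
#' electrodes.
#'
#' @param mesh a [cortical_mesh()] (dipoles strictly inside inner skull).
#' @param head a [head_model()].
#' @param eeg an EEG [sensor_array()]; positions are projected radially
#'   onto the scalp sphere.
#' @param n_terms series truncation (default 60).
#' @param average_reference subtract the mean over electrodes per source.
#' @return A `leadfield` (V per A.m).
#' @export
eeg_leadfield_sphere <- function(mesh, head, eeg, n_terms = 60,
                                 average_reference = TRUE) {
  center <- head$center
  rad_m <- head$radii / 1000
  R <- rad_m[3]
  dip_pos <- sweep(mesh$vertices, 2, center) / 1000    # m
  dip_r <- row_norms(dip_pos)
  if (any(dip_r >= rad_m[1])) {
    stop("dipoles must lie strictly inside the inner skull")
  }
  ele <- sweep(eeg$positions, 2, center) / 1000
  ele <- ele / row_norms(ele)                           # unit directions
  f_n <- sphere_shell_factors(head$radii, head$conductivities, n_terms)
  q <- nrow(ele)
  p <- nrow(dip_pos)
  G <- matrix(0, q, p)
  sig1 <- head$conductivities[1]
  n_seq <- seq_len(n_terms)
  for (j in seq_len(p)) {
    b <- dip_r[j]
    if (b < 1e-12) next                                 # central dipole: 0
    bh <- dip_pos[j, ] / b
    m <- mesh$normals[j, ]                              # unit moment
    cosg <- pmin(pmax(ele %*% bh, -1), 1)[, 1]
    leg <- legendre_terms(cosg, n_terms)
    m_r <- sum(m * bh)
    m_perp <- (ele %*% m)[, 1] - cosg * m_r             # m.(rhat - c bhat)
    x <- b / R
    coef <- f_n * x^(n_seq - 1)
    ang <- leg$P %*% (n_seq * coef) * m_r + leg$dP %*% coef * m_perp
    G[, j] <- ang / (4 * pi * sig1 * R^2)
  }
  if (average_reference) G <- sweep(G, 2, colMeans(G))
  leadfield(G, "EEG", labels = eeg$labels)
}

## ---- MEG: Sarvas formula ----

# Magnetic field (T) at sensor position r (m) of a dipole Q (A.m) at r0
# (m) inside a spherically symmetric conductor centred at the origin.
sarvas_field <- function(r, r0, Q) {
  a_vec <- r - r0
  a <- vec_norm(a_vec)
  rn <- vec_norm(r)
  F_s <- a * (rn * a + rn^2 - sum(r0 * r))
  if (abs(F_s) < 1e-30) return(c(0, 0, 0))
  gF <- (a^2 / rn + sum(a_vec * r) / a + 2 * a + 2 * rn) * r -
    (a + 2 * rn + sum(a_vec * r) / a) * r0
  Qxr0 <- cross3(Q, r0)
  1e-7 * (F_s * Qxr0 - sum(Qxr0 * r) * gF) / F_s^2
}

#' Analytic MEG lead field in a spherical conductor
#'
#' Magnetic field of the fixed-orientation cortical dipoles in a
#' spherically symmetric volume conductor (Sarvas formula), projected on
#' the sensor orientations. Radial dipoles and a dipole at the sphere
#' centre are magnetically silent.
#'
#' @param mesh a [cortical_mesh()].
#' @param head a [head_model()]; only the centre is used (spherical
#'   symmetry makes the field independent of the conductivity profile).
#' @param meg an MEG [sensor_array()] (point magnetometers outside the
#'   scalp sphere).
#' @return A `leadfield` (T per A.m).
#' @export
meg_leadfield_sphere <- function(mesh, head, meg) {
  center <- head$center
  sens <- sweep(meg$positions, 2, center) / 1000
  if (any(row_norms(sens) <= head$radii[3] / 1000)) {
    stop("MEG sensors must lie outside the scalp sphere")
  }
  dip_pos <- sweep(mesh$vertices, 2, center) / 1000
  q <- nrow(sens)
  p <- nrow(dip_pos)
  G <- matrix(0, q, p)
  rn <- row_norms(sens)
  ori <- meg$orientations
  for (j in seq_len(p)) {
    r0 <- dip_pos[j, ]
    Q <- mesh$normals[j, ]
    a_vec <- sweep(sens, 2, r0)
    a <- row_norms(a_vec)
    F_s <- a * (rn * a + rn^2 - as.numeric(sens %*% r0))
    ar <- rowSums(a_vec * sens)
    c1 <- a^2 / rn + ar / a + 2 * a + 2 * rn
    c2 <- a + 2 * rn + ar / a
    gF <- sens * c1 - tcrossprod(c2, r0)
    Qxr0 <- cross3(Q, r0)
    B <- 1e-7 * (tcrossprod(F_s, Qxr0) -
                   as.numeric(sens %*% Qxr0) * gF) / F_s^2
    G[, j] <- rowSums(B * ori)
  }
  leadfield(G, "MEG", labels = meg$labels)
}
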