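#' Spatial whitening
#'
#' Scales each channel by the inverse square root of its noise variance
#' so the whitened baseline has unit variance per channel.
#'
#' @param M data (q x tau); `G` gain (q x p).
#' @param sigma_d diagonal noise covariance (vector of variances).
#' @return List with `M_w`, `G_w`.
#' @export
whiten <- function(M, G, sigma_d) {
  if (any(sigma_d <= 0)) stop("noise variances must be > 0")
  w <- 1 / sqrt(sigma_d)
  list(M_w = M * w, G_w = G * w)
}

#' L-curve choice of the regularization parameter
#'
#' Evaluates the Tikhonov residual norm and solution norm over a grid of
#' candidate lambdas (via the SVD of the whitened gain) and returns the
#' lambda at the corner — the point of maximum curvature of the
#' log-log L-curve (three-point finite differences).
#'
#' @param M_w whitened data; `G_w` whitened gain.
#' @param grid positive candidate lambdas; the default is 60 log-spaced
#'   points spanning \[1e-6, 1e3\] times `trace(G_w G_w') / q`.
#' @param min_residual2 optional lower bound on the squared residual
#'   norm at the accepted corner. In whitened units the noise floor is
#'   known (about q x tau), and a gain matrix with rapidly decaying
#'   effective rank can leave the L-curve without a vertical branch, in
#'   which case the raw curvature maximum sits at the under-regularized
#'   end of the grid and fits noise; candidates whose residual falls
#'   below this bound are excluded from the corner search.
#' @return List with `lambda`, and the `grid`, `residual_norm`,
#'   `solution_norm`, `curvature` vectors.
#' @export
lcurve_lambda <- function(M_w, G_w, grid = NULL, min_residual2 = NULL) {
  M_w <- as.matrix(M_w)
  if (is.null(grid)) {
    s0 <- sum(G_w^2) / nrow(G_w)
    grid <- s0 * 10^seq(-6, 3, length.out = 60)
  }
  if (any(grid <= 0)) stop("lambdas must be > 0")
  if (length(grid) == 1) {
    return(list(lambda = grid, grid = grid, residual_norm = NA_real_,
                solution_norm = NA_real_, curvature = NA_real_))
  }
  sv <- svd(G_w)
  d <- sv$d
  UtM <- crossprod(sv$u, M_w)          # q x tau (rank rows relevant)
  # residual component orthogonal to the column space of G
  res0 <- sum(M_w^2) - sum(UtM^2)
  rho <- eta_n <- numeric(length(grid))
  for (i in seq_along(grid)) {
    lam <- grid[i]
    f <- d / (d^2 + lam)               # filter factors applied to UtM
    coefs <- UtM * f
    eta_n[i] <- sqrt(sum(coefs^2))
    r <- UtM * (lam / (d^2 + lam))
    rho[i] <- sqrt(max(res0, 0) + sum(r^2))
  }
  x <- log(pmax(rho, 1e-300))
  y <- log(pmax(eta_n, 1e-300))
  if (max(abs(diff(x))) < 1e-12 && max(abs(diff(y))) < 1e-12) {
    stop("degenerate L-curve: all points identical")
  }
  n <- length(grid)
  kappa <- rep(NA_real_, n)
  for (i in 2:(n - 1)) {
    x1 <- (x[i + 1] - x[i - 1]) / 2
    y1 <- (y[i + 1] - y[i - 1]) / 2
    x2 <- x[i + 1] - 2 * x[i] + x[i - 1]
    y2 <- y[i + 1] - 2 * y[i] + y[i - 1]
    den <- (x1^2 + y1^2)^1.5
    if (den > 0) kappa[i] <- (x1 * y2 - y1 * x2) / den
  }
  admissible <- if (!is.null(min_residual2)) {
    rho^2 >= min_residual2
  } else rep(TRUE, n)
  kap_adm <- ifelse(admissible, kappa, -Inf)
  best <- if (any(is.finite(kap_adm) & admissible)) {
    which.max(kap_adm)
  } else if (any(admissible)) {
    which(admissible)[1]
  } else {
    which.max(kappa)
  }
  list(lambda = grid[best], grid = grid, residual_norm = rho,
       solution_norm = eta_n, curvature = kappa)
}

#' Minimum-norm estimate (MNE)
#'
#' `J = G_w' (G_w G_w' + lambda I)^-1 M_w` — the Tikhonov solution with
#' identity source covariance on whitened data.
#'
#' @param M_w whitened data; `G_w` whitened gain; `lambda` > 0.
#' @return A `source_estimate` with the `W` (p x q inverse operator) and
#'   `lambda` kept for the noise-normalized variants.
#' @export
mne_solve <- function(M_w, G_w, lambda) {
  if (lambda <= 0) stop("`lambda` must be > 0")
  q <- nrow(G_w)
  K <- tcrossprod(G_w) + diag(lambda, q)
  W <- t(solve(K, G_w))                # p x q
  structure(list(J = W %*% as.matrix(M_w), W = W, lambda = lambda,
                 method = "MNE", diagnostics = NULL),
            class = "source_estimate")
}

#' Dynamic statistical parametric mapping (dSPM)
#'
#' Noise-normalized MNE: each row of the inverse operator is divided by
#' the estimated noise standard deviation at that source,
#' `sqrt(diag(W Sigma_d W'))` (identity noise covariance after
#' whitening).
#'
#' @param M_w whitened data; `G_w` whitened gain; `lambda` > 0.
#' @param sigma_d noise variances of the whitened channels (default 1).
#' @return A `source_estimate` (unitless statistical map).
#' @export
dspm_solve <- function(M_w, G_w, lambda, sigma_d = NULL) {
  mne <- mne_solve(M_w, G_w, lambda)
  W <- mne$W
  if (is.null(sigma_d)) sigma_d <- rep(1, ncol(W))
  nrm <- sqrt(rowSums(sweep(W^2, 2, sigma_d, `*`)))
  if (any(nrm == 0)) stop("zero-noise row in the inverse operator")
  structure(list(J = (W / nrm) %*% as.matrix(M_w), W = W / nrm,
                 lambda = mne$lambda, method = "dSPM",
                 diagnostics = NULL),
            class = "source_estimate")
}

#' Standardized low-resolution tomography (sLORETA)
#'
#' Rows of the MNE operator standardized by the variance of the
#' estimated sources, `sqrt(diag(W (G_w G_w' + lambda Sigma_d) W'))` =
#' `sqrt(diag(W G_w))` — yielding zero localization error for noiseless
#' single dipoles.
#'
#' @inheritParams dspm_solve
#' @return A `source_estimate` (unitless statistical map).
#' @export
sloreta_solve <- function(M_w, G_w, lambda, sigma_d = NULL) {
  mne <- mne_solve(M_w, G_w, lambda)
  W <- mne$W
  nrm2 <- rowSums(W * t(G_w))          # diag(W G_w) = diag(W (GG'+lam I) W')
  if (any(nrm2 <= 0)) stop("non-positive sLORETA normalizer")
  nrm <- sqrt(nrm2)
  structure(list(J = (W / nrm) %*% as.matrix(M_w), W = W / nrm,
                 lambda = mne$lambda, method = "sLORETA",
                 diagnostics = NULL),
            class = "source_estimate")
}
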