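#' Multivariate source pre-localization (MSP) scores
#'
#' Probability-like coefficient in \[0, 1\] per dipole quantifying its
#' contribution to the data: the squared projection of each unit-norm
#' gain column onto the subspace spanned by the `l` leading left singular
#' vectors of the scaled data.
#'
#' @param M_s scaled data (q x tau).
#' @param G_s scaled gain (q x p).
#' @param energy fraction of data energy (sum of squared singular
#'   values) the retained components must capture; the smallest such `l`
#'   is used when no baseline is available.
#' @param l optional fixed number of components (overrides the rules).
#' @param baseline optional scaled spike-free segment: when given, the
#'   retained components are those whose singular values exceed
#'   `noise_factor` times the largest singular value of an equal-length
#'   baseline block (at least one component is always kept). This keeps
#'   only directions that stand above the background and is the rule
#'   used by the study pipeline.
#' @param noise_factor multiplier on the baseline singular value.
#' @return An `msp_result`: `scores` (length p), `l`, `singular_values`.
#' @export
msp_scores <- function(M_s, G_s, energy = 0.95, l = NULL,
                       baseline = NULL, noise_factor = 1.0) {
  M_s <- as.matrix(M_s)
  if (all(M_s == 0)) stop("zero data matrix")
  sv <- svd(M_s)
  if (is.null(l) && !is.null(baseline)) {
    nb <- as.matrix(baseline)
    nb <- nb[, seq_len(min(ncol(nb), ncol(M_s))), drop = FALSE]
    d_noise <- svd(nb, nu = 0, nv = 0)$d[1]
    l <- max(1L, sum(sv$d > noise_factor * d_noise))
  }
  if (is.null(l)) {
    frac <- cumsum(sv$d^2) / sum(sv$d^2)
    l <- which(frac >= energy)[1]
  }
  l <- min(l, ncol(sv$u))
  U <- sv$u[, seq_len(l), drop = FALSE]
  cn <- col_norms(G_s)
  if (any(cn == 0)) stop("zero-norm gain column")
  Gbar <- sweep(G_s, 2, cn, `/`)
  scores <- colSums((crossprod(U, Gbar))^2)
  scores <- pmin(pmax(scores, 0), 1)
  structure(list(scores = scores, l = l,
                 singular_values = sv$d[seq_len(l)]),
            class = "msp_result")
}

#' @export
print.msp_result <- function(x, ...) {
  cat(sprintf("<msp_result> %d sources, l = %d components\n",
              length(x$scores), x$l))
  invisible(x)
}

#' Probabilistic OR fusion of MSP score maps
#'
#' Elementwise `a + b - a*b`, retaining a dipole that contributes to
#' either modality.
#'
#' @param msp_a,msp_b `msp_result`s (or bare score vectors) of equal
#'   length.
#' @return An `msp_result` with the fused scores.
#' @export
fuse_msp <- function(msp_a, msp_b) {
  a <- if (inherits(msp_a, "msp_result")) msp_a$scores else msp_a
  b <- if (inherits(msp_b, "msp_result")) msp_b$scores else msp_b
  if (length(a) != length(b)) stop("score maps have different lengths")
  structure(list(scores = a + b - a * b,
                 l = max(if (inherits(msp_a, "msp_result")) msp_a$l else 0,
                         if (inherits(msp_b, "msp_result")) msp_b$l else 0),
                 singular_values = NULL),
            class = "msp_result")
}

#' Data-driven parcellation (DDP)
#'
#' Tiles the cortical surface with connected parcels by region growing
#' from the local maxima of an MSP score map: seeds are vertices whose
#' score is >= every score within their order-`scale` neighbourhood;
#' parcels grow breadth-first from the seeds (descending seed score,
#' ties to the lowest index) up to the scale order; the procedure is
#' repeated on the not-yet-assigned remainder of the surface until every
#' vertex belongs to a parcel, so parcel diameters never exceed twice
#' the scale order (about 2.5 cm^2 at scale 4 on a 4-mm mesh).
#'
#' @param scores an `msp_result` or numeric score vector (length p).
#' @param mesh a [cortical_mesh()].
#' @param scale neighbourhood order of the parcels (default 4).
#' @return A `parcellation`: `parcel` (id per vertex), `K`, `seeds`,
#'   `scale`.
#' @export
ddp_parcellate <- function(scores, mesh, scale = 4) {
  s <- if (inherits(scores, "msp_result")) scores$scores else scores
  p <- length(mesh$adjacency)
  if (p == 0) stop("empty mesh")
  if (length(s) != p) stop("score length does not match mesh size")
  if (scale < 1) stop("`scale` must be >= 1")
  nb <- mesh_neighborhoods(mesh, scale)
  parcel <- integer(p)
  k <- 0L
  kept_seeds <- integer(0)
  # successive passes: local maxima of the score map among the vertices
  # not yet assigned become seeds; parcels grow breadth-first through
  # unassigned vertices up to the scale order; repeat until the surface
  # is tiled. Every pass assigns at least the global maximum of the
  # remaining set, so the loop terminates.
  while (any(parcel == 0L)) {
    free <- which(parcel == 0L)
    is_seed <- vapply(free, function(v) {
      nbr <- nb[[v]]
      s[v] >= max(s[nbr[parcel[nbr] == 0L]])
    }, logical(1))
    seeds <- free[is_seed]
    seeds <- seeds[order(-s[seeds], seeds)]
    for (sd_v in seeds) {
      if (parcel[sd_v] != 0L) next
      k <- k + 1L
      kept_seeds <- c(kept_seeds, sd_v)
      frontier <- sd_v
      parcel[sd_v] <- k
      d <- 0
      while (length(frontier) > 0 && d < scale) {
        d <- d + 1
        nxt <- unique(unlist(mesh$adjacency[frontier], use.names = FALSE))
        nxt <- nxt[parcel[nxt] == 0L]
        parcel[nxt] <- k
        frontier <- nxt
      }
    }
  }
  structure(list(parcel = parcel, K = k, seeds = kept_seeds,
                 scale = scale),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("<parcellation> %d parcels over %d vertices (scale %d)\n",
              x$K, length(x$parcel), x$scale))
  invisible(x)
}

#' Initial parcel activation probabilities
#'
#' The probability of each parcel to be active is initialized as the
#' median of the fused MSP scores of its dipoles, clipped away from the
#' degenerate values 0 and 1.
#'
#' @param parcellation a [ddp_parcellate()] result.
#' @param scores an `msp_result` or score vector.
#' @param eps clipping margin (default 1e-3).
#' @return Numeric vector alpha of length K, values in (eps, 1 - eps).
#' @export
init_alpha <- function(parcellation, scores, eps = 1e-3) {
  s <- if (inherits(scores, "msp_result")) scores$scores else scores
  alpha <- vapply(seq_len(parcellation$K), function(k) {
    idx <- which(parcellation$parcel == k)
    if (length(idx) == 0) stop(sprintf("parcel %d is empty", k))
    median(s[idx])
  }, numeric(1))
  pmin(pmax(alpha, eps), 1 - eps)
}
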