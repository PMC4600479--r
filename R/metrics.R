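#' ROC detection accuracy (AUC)
#'
#' Detection ability of a source map against the simulated patch,
#' obtained by thresholding the absolute current density at the spike
#' peak. To keep sensitivity to both near-field leakage and distant
#' spurious sources, the inactive set is balanced: one AUC uses
#' negatives drawn from the patch surround (within `surround_order`
#' graph rings), one uses negatives drawn from the remaining cortex,
#' and the two are averaged over `n_reps` seeded draws. Tie-corrected
#' pairwise (Mann-Whitney) computation.
#'
#' @param energy non-negative length-p map (e.g. `abs(J[, peak])`).
#' @param patch a [grow_patch()] or integer vertex set (ground truth).
#' @param mesh a [cortical_mesh()].
#' @param exclude vertices removed from the evaluation altogether (the
#'   other source of a two-source simulation).
#' @param balanced use the balanced near/far negative sampling; when
#'   FALSE all non-patch vertices are the negatives (deterministic).
#' @param surround_order graph order delimiting the surround (default 10).
#' @param n_reps number of sampling repetitions (default 10).
#' @param seed integer seed for the draws.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(energy, patch, mesh, exclude = integer(0),
                    balanced = TRUE, surround_order = 10, n_reps = 10,
                    seed = 1) {
  idx <- if (inherits(patch, "source_patch")) patch$vertices else patch
  if (length(idx) == 0) stop("empty patch")
  p <- length(energy)
  if (any(energy < 0)) stop("energy map must be non-negative")
  keep <- setdiff(seq_len(p), exclude)
  negatives <- setdiff(keep, idx)
  if (length(negatives) == 0) stop("patch covers all evaluable vertices")
  pos <- energy[idx]
  if (!balanced) return(pairwise_auc(pos, energy[negatives]))
  ring <- setdiff(graph_kring_set(mesh$adjacency, idx, surround_order), idx)
  close_set <- intersect(ring, keep)
  far_set <- setdiff(negatives, close_set)
  if (length(close_set) == 0) close_set <- negatives
  if (length(far_set) == 0) far_set <- negatives
  n_neg <- length(idx)
  with_seed(seed, {
    reps <- vapply(seq_len(n_reps), function(r) {
      cl <- sample(close_set, min(n_neg, length(close_set)))
      fa <- sample(far_set, min(n_neg, length(far_set)))
      (pairwise_auc(pos, energy[cl]) + pairwise_auc(pos, energy[fa])) / 2
    }, numeric(1))
    mean(reps)
  })
}

# all vertices within `order` rings of a vertex set (including the set)
graph_kring_set <- function(adjacency, sources, order) {
  dist <- graph_bfs_dist(adjacency, sources, max_order = order)
  which(dist <= order)
}

# tie-corrected probability that a positive exceeds a negative
pairwise_auc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  n1 <- length(pos)
  n2 <- length(neg)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Spatial dispersion (SD)
#'
#' Energy-weighted RMS of the minimum Euclidean distance from each
#' vertex to the simulated patch:
#' `SD = sqrt( sum_i d_i^2 J_i^2 / sum_i J_i^2 )` with `d_i = 0` inside
#' the patch. Close to zero when all reconstructed energy stays within
#' the patch; inflated by spatial spread or distant spurious sources.
#'
#' @param j_peak length-p current density at the spike peak.
#' @param patch ground-truth vertex set (or `source_patch`).
#' @param mesh a [cortical_mesh()].
#' @return SD in mm.
#' @export
spatial_dispersion <- function(j_peak, patch, mesh) {
  idx <- if (inherits(patch, "source_patch")) patch$vertices else patch
  if (all(j_peak == 0)) stop("all-zero estimate")
  e2 <- j_peak^2
  V <- mesh$vertices
  pv <- V[idx, , drop = FALSE]
  # min distance from every vertex to the patch
  d2min <- rep(Inf, nrow(V))
  for (j in seq_len(nrow(pv))) {
    d2 <- (V[, 1] - pv[j, 1])^2 + (V[, 2] - pv[j, 2])^2 +
      (V[, 3] - pv[j, 3])^2
    d2min <- pmin(d2min, d2)
  }
  d2min[idx] <- 0
  sqrt(sum(d2min * e2) / sum(e2))
}

#' Shape error (SE) of the reconstructed time course
#'
#' RMS difference between the peak-normalized patch-mean time courses of
#' the absolute true and estimated currents over the analysis window.
#' Zero when the estimate reproduces the true time course up to a
#' positive scale.
#'
#' @param Jth true current (p x tau or patch x tau).
#' @param Jhat estimated current (same number of columns).
#' @param patch ground-truth vertex set; row indices into `Jth`/`Jhat`
#'   when they are full p x tau matrices.
#' @param window columns to evaluate (default all).
#' @return SE >= 0 (at most 2 for peak-normalized non-negative means).
#' @export
shape_error <- function(Jth, Jhat, patch, window = NULL) {
  idx <- if (inherits(patch, "source_patch")) patch$vertices else patch
  if (length(idx) == 0) stop("empty patch")
  Jth <- as.matrix(Jth)
  Jhat <- as.matrix(Jhat)
  if (is.null(window)) window <- seq_len(ncol(Jth))
  sub_th <- abs(Jth[idx, window, drop = FALSE])
  sub_ht <- abs(Jhat[idx, window, drop = FALSE])
  m_th <- colMeans(sub_th)
  m_ht <- colMeans(sub_ht)
  if (max(m_ht) == 0) stop("all-zero estimate within the patch")
  a <- m_th / max(m_th)
  b <- m_ht / max(m_ht)
  sqrt(mean((a - b)^2))
}
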