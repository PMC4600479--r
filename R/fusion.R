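#' Baseline channel statistics
#'
#' Unbiased per-channel standard deviation of a spike-free baseline
#' segment and its mean over channels — the normalizer of the SNR
#' transformation that puts EEG (volts) and MEG (tesla) on a common
#' dimensionless scale.
#'
#' @param E q x tau baseline matrix.
#' @return A `baseline_stats` list: `sigma` (per channel), `sigma_bar`
#'   (mean over channels), `q`.
#' @export
baseline_std <- function(E) {
  E <- as.matrix(E)
  if (ncol(E) < 2) stop("baseline needs at least 2 samples")
  sigma <- apply(E, 1, sd)
  sigma_bar <- mean(sigma)
  if (sigma_bar == 0) stop("all-zero baseline: cannot normalize")
  structure(list(sigma = sigma, sigma_bar = sigma_bar, q = nrow(E)),
            class = "baseline_stats")
}

#' SNR transformation of data and lead field
#'
#' Divides the data and the gain matrix of one modality by the mean
#' baseline standard deviation, producing dimensionless quantities while
#' preserving the forward relation M = GJ.
#'
#' @param M q x tau data; `G` q x p gain; `stats` a [baseline_std()].
#' @param channelwise divide each channel by its own baseline sd instead
#'   of the modality mean.
#' @return List with `M_s`, `G_s` and the stats used.
#' @export
snr_transform <- function(M, G, stats, channelwise = FALSE) {
  if (stats$sigma_bar <= 0) stop("non-positive baseline scale")
  if (channelwise) {
    s <- stats$sigma
    if (any(s == 0)) stop("zero-variance channel in channel-wise transform")
    list(M_s = M / s, G_s = G / s, stats = stats)
  } else {
    list(M_s = M / stats$sigma_bar, G_s = G / stats$sigma_bar,
         stats = stats)
  }
}

#' Row-concatenation of scaled modalities
#'
#' Stacks the SNR-transformed EEG block on top of the MEG block (data,
#' gain and baseline), recording a modality mask so the blocks can be
#' recovered exactly. Either modality may be absent (`NULL`), in which
#' case the result degenerates to the monomodal pipeline.
#'
#' @param eeg,meg lists with `M_s`, `G_s` and optionally `E_s`.
#' @return A `fused_recording` with `M`, `G`, `E`, `modality` (character
#'   mask per row) and `noise_var` slot (filled by
#'   [estimate_noise_cov()]).
#' @export
concatenate_modalities <- function(eeg = NULL, meg = NULL) {
  blocks <- list(EEG = eeg, MEG = meg)
  blocks <- blocks[!vapply(blocks, is.null, logical(1))]
  if (length(blocks) == 0) stop("no modality supplied")
  taus <- vapply(blocks, function(b) ncol(b$M_s), numeric(1))
  ps <- vapply(blocks, function(b) ncol(b$G_s), numeric(1))
  if (length(unique(taus)) != 1) stop("mismatched number of time samples")
  if (length(unique(ps)) != 1) stop("mismatched number of sources")
  M <- do.call(rbind, lapply(blocks, `[[`, "M_s"))
  G <- do.call(rbind, lapply(blocks, `[[`, "G_s"))
  E <- if (all(vapply(blocks, function(b) !is.null(b$E_s), logical(1)))) {
    do.call(rbind, lapply(blocks, `[[`, "E_s"))
  } else NULL
  modality <- rep(names(blocks),
                  vapply(blocks, function(b) nrow(b$M_s), numeric(1)))
  structure(list(M = M, G = G, E = E, modality = modality,
                 noise_var = NULL),
            class = "fused_recording")
}

#' @export
print.fused_recording <- function(x, ...) {
  cat(sprintf("<fused_recording> %s channels, %d x %d\n",
              paste(sprintf("%d %s", table(x$modality)[unique(x$modality)],
                            unique(x$modality)), collapse = " + "),
              nrow(x$M), ncol(x$M)))
  invisible(x)
}

#' Extract one modality block from a fused recording
#'
#' @param fused a `fused_recording`.
#' @param modality `"EEG"` or `"MEG"`.
#' @return List with `M_s`, `G_s`, `E_s` for that block.
#' @export
extract_modality <- function(fused, modality) {
  rows <- fused$modality == modality
  if (!any(rows)) stop(sprintf("no %s rows in fused recording", modality))
  list(M_s = fused$M[rows, , drop = FALSE],
       G_s = fused$G[rows, , drop = FALSE],
       E_s = if (!is.null(fused$E)) fused$E[rows, , drop = FALSE] else NULL)
}

#' Diagonal noise covariance from a scaled baseline
#'
#' Per-channel variance of the (SNR-transformed) baseline; off-diagonal
#' terms are assumed zero. Used by the MEM data-fit term and by the
#' whitening step of the linear inverses.
#'
#' @param E_s scaled baseline matrix.
#' @param labels optional channel labels for error reporting.
#' @return Numeric vector of per-channel variances (the diagonal).
#' @export
estimate_noise_cov <- function(E_s, labels = NULL) {
  E_s <- as.matrix(E_s)
  if (ncol(E_s) < 2) stop("baseline needs at least 2 samples")
  v <- apply(E_s, 1, var)
  if (any(v == 0)) {
    bad <- which(v == 0)
    lab <- if (!is.null(labels)) paste(labels[bad], collapse = ", ") else
      paste(bad, collapse = ", ")
    stop(sprintf("zero-variance channel(s): %s", lab))
  }
  v
}
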