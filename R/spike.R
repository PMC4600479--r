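#' Three-Gamma interictal spike waveform
#'
#' Sum of three Gamma-density components (sharp spike, undershoot, slow
#' wave), renormalized to unit peak amplitude. Each component is
#' `amplitude * dgamma(t - delay, shape, scale)`; a component with shape
#' k and scale theta peaks at `delay + (k - 1) * theta`.
#'
#' @param t time grid in seconds.
#' @param components data frame / list of lists with `amplitude`,
#'   `shape`, `scale`, `delay` per component.
#' @return A `spike_timecourse` with fields `t`, `w` (unit peak) and
#'   `peak_index`.
#' @export
gamma_spike <- function(t = seq(0, 0.35, by = 1 / 600),
                        components = spike_components()) {
  comp <- lapply(components, as.list)
  if (all(vapply(comp, function(x) x$amplitude == 0, logical(1)))) {
    stop("all component amplitudes are zero: no peak")
  }
  w <- rep(0, length(t))
  for (cmp in comp) {
    if (cmp$shape <= 0 || cmp$scale <= 0) stop("shapes and scales must be > 0")
    w <- w + cmp$amplitude *
      dgamma(t - cmp$delay, shape = cmp$shape, scale = cmp$scale)
  }
  peak <- which.max(abs(w))
  w <- w / abs(w[peak])
  structure(list(t = t, w = w, peak_index = peak),
            class = "spike_timecourse")
}

#' @rdname gamma_spike
#' @export
spike_components <- function() {
  list(
    list(amplitude = 1.00, shape = 5, scale = 0.008, delay = 0.040),
    list(amplitude = -0.30, shape = 5, scale = 0.015, delay = 0.085),
    list(amplitude = 0.55, shape = 5, scale = 0.030, delay = 0.095))
}

#' @export
print.spike_timecourse <- function(x, ...) {
  cat(sprintf("<spike_timecourse> %d samples, peak at %.1f ms\n",
              length(x$t), 1000 * x$t[x$peak_index]))
  invisible(x)
}

#' Grow an extended cortical patch
#'
#' Region growing around a seed vertex following the cortical surface:
#' the patch is the order-`s_e` graph neighbourhood of the seed. The
#' patch area is the sum of the per-vertex areas (one third of the
#' incident triangle areas).
#'
#' @param mesh a [cortical_mesh()].
#' @param seed_vertex seed index.
#' @param s_e spatial neighbourhood order (default 3).
#' @param amplitude dipole amplitude in nA.m (default 9.5).
#' @return A `source_patch` with fields `seed`, `vertices`, `s_e`,
#'   `area_cm2`, `amplitude`.
#' @export
grow_patch <- function(mesh, seed_vertex, s_e = 3, amplitude = 9.5) {
  verts <- kring_neighborhood(mesh, seed_vertex, s_e)
  area <- sum(mesh_vertex_areas(mesh)[verts]) / 100  # mm^2 -> cm^2
  structure(list(seed = seed_vertex, vertices = verts, s_e = s_e,
                 area_cm2 = area, amplitude = amplitude),
            class = "source_patch")
}

#' @export
print.source_patch <- function(x, ...) {
  cat(sprintf("<source_patch> seed %d, %d vertices, %.1f cm^2, %.1f nA.m\n",
              x$seed, length(x$vertices), x$area_cm2, x$amplitude))
  invisible(x)
}

#' Cancellation index of a patch
#'
#' Degree to which the sensor signatures of the dipoles within a patch
#' cancel each other (opposing sulcal walls): `Ic = 1 - ||sum_l g_l|| /
#' sum_l ||g_l||` over the patch columns `g_l` of the lead field. 0 means
#' no cancellation (a single dipole), 1 full cancellation (equal and
#' opposite columns).
#'
#' @param lf a [leadfield()] or a plain gain matrix.
#' @param patch a [grow_patch()] result or integer vertex indices.
#' @return Ic in \[0, 1\].
#' @export
cancellation_index <- function(lf, patch) {
  G <- if (inherits(lf, "leadfield")) lf$G else as.matrix(lf)
  idx <- if (inherits(patch, "source_patch")) patch$vertices else patch
  if (length(idx) == 0) stop("empty patch")
  cols <- G[, idx, drop = FALSE]
  norms <- col_norms(cols)
  if (any(norms == 0)) stop("patch contains an all-zero lead-field column")
  1 - vec_norm(rowSums(cols)) / sum(norms)
}

#' Signal-to-noise ratio of a spike recording
#'
#' Ratio between the maximum absolute signal over all channels at the
#' spike peak and the pooled standard deviation of the baseline.
#'
#' @param M q x tau data matrix.
#' @param baseline q x tau_b spike-free segment.
#' @param peak_index column of `M` at which the spike peaks; defaults to
#'   the column with the largest absolute value.
#' @return Scalar SNR.
#' @export
compute_snr <- function(M, baseline, peak_index = NULL) {
  M <- as.matrix(M)
  baseline <- as.matrix(baseline)
  s <- sqrt(mean((baseline - rowMeans(baseline))^2) *
              ncol(baseline) / (ncol(baseline) - 1))
  if (s == 0) stop("baseline is constant: zero standard deviation")
  if (is.null(peak_index)) {
    peak_index <- which.max(apply(abs(M), 2, max))
  }
  max(abs(M[, peak_index])) / s
}

#' Synthetic background activity
#'
#' Coloured (1/f plus alpha-band) noise with optional smooth spatial
#' correlation across channels, standing in for spike-free EEG/MEG
#' background segments. Channels are zero-mean; with `spectral_slope = 0`,
#' `alpha_power = 0` and no mixing the output is white noise with the
#' requested standard deviation.
#'
#' @param q channels; `tau` samples; `fs` sampling rate (Hz).
#' @param target_sd per-channel standard deviation.
#' @param spectral_slope exponent of the 1/f^slope amplitude envelope.
#' @param alpha_power relative amplitude of a 10 Hz spectral bump.
#' @param positions optional q x 3 sensor positions used to build a
#'   smooth spatial correlation (Gaussian kernel, length `mixing_rho` mm);
#'   `NULL` disables mixing.
#' @param mixing_rho spatial correlation length (mm).
#' @param white_fraction fraction of the per-channel variance
#'   contributed by spatially and temporally white sensor noise
#'   (instrument/electrode noise on top of the coloured physiological
#'   background).
#' @param seed integer seed.
#' @return q x tau noise matrix.
#' @export
generate_background <- function(q, tau, fs = 600, target_sd = 1,
                                spectral_slope = 1, alpha_power = 1,
                                positions = NULL, mixing_rho = 40,
                                white_fraction = 0.4, seed = 1) {
  if (q < 1 || tau < 1) stop("q and tau must be >= 1")
  with_seed(seed, {
    x <- matrix(rnorm(q * tau), q, tau)
    if (spectral_slope != 0 || alpha_power != 0) {
      freqs <- (seq_len(tau) - 1) / tau * fs
      freqs <- pmin(freqs, fs - freqs)          # two-sided
      env <- (pmax(freqs, 1))^(-spectral_slope / 2)
      if (alpha_power != 0) {
        env <- env + alpha_power * exp(-((freqs - 10)^2) / (2 * 2^2)) *
          max(env[freqs >= 1])
      }
      env[1] <- 0                               # remove DC
      x <- t(Re(mvfft(mvfft(t(x)) * env, inverse = TRUE))) / tau
    }
    if (!is.null(positions)) {
      D2 <- as.matrix(dist(positions))^2
      C <- exp(-D2 / (2 * mixing_rho^2)) + diag(1e-6, q)
      x <- t(chol(C)) %*% x
    }
    if (white_fraction > 0 &&
        (spectral_slope != 0 || alpha_power != 0 || !is.null(positions))) {
      sds <- sqrt(pmax(rowSums(x^2), 1e-300) / (tau - 1))
      x <- sqrt(1 - white_fraction) * (x / sds) +
        sqrt(white_fraction) * matrix(rnorm(q * tau), q, tau)
    }
    x <- x - rowMeans(x)
    sds <- sqrt(rowSums(x^2) / (tau - 1))
    x * (target_sd / pmax(sds, 1e-300))
  })
}

#' Brain-like background generator
#'
#' Returns a generator closure producing spike-free background activity
#' as diffuse random cortical sources seen through the modality's own
#' lead field, plus a white sensor-noise floor. Because the latent
#' source processes are drawn from the seed alone, EEG and MEG
#' backgrounds generated with the same seed share the same underlying
#' brain activity, as simultaneously recorded modalities do.
#'
#' @param leadfields named list of [leadfield()]s.
#' @param n_latent number of randomly placed background source patches.
#' @param fs sampling rate (Hz); `spectral_slope`, `alpha_power` as in
#'   [generate_background()].
#' @param white_fraction fraction of each channel's variance from white
#'   sensor noise.
#' @return A function `(modality, q, tau, seed)` returning a q x tau
#'   noise matrix with mean channel standard deviation 1.
#' @export
brain_noise_generator <- function(leadfields, n_latent = 250, fs = 600,
                                  spectral_slope = 1, alpha_power = 1,
                                  white_fraction = 0.4) {
  p <- ncol(leadfields[[1]]$G)
  n_latent <- min(n_latent, p)
  function(modality, q, tau, seed) {
    latent <- with_seed(derive_seed(seed, 77), {
      idx <- sample.int(p, n_latent)
      amp <- abs(rnorm(n_latent, 1, 0.3))
      S <- generate_background(n_latent, tau, fs = fs,
                               spectral_slope = spectral_slope,
                               alpha_power = alpha_power,
                               positions = NULL, white_fraction = 0,
                               seed = derive_seed(seed, 78))
      list(idx = idx, S = amp * S)
    })
    G <- leadfields[[modality]]$G
    N <- G[, latent$idx, drop = FALSE] %*% latent$S
    s <- mean(sqrt(rowSums((N - rowMeans(N))^2) / (tau - 1)))
    N <- N / s
    white <- with_seed(derive_seed(seed, 79, match(modality,
                                                   names(leadfields))),
                       matrix(rnorm(q * tau), q, tau))
    out <- sqrt(1 - white_fraction) * N + sqrt(white_fraction) * white
    out <- out - rowMeans(out)
    out / mean(sqrt(rowSums(out^2) / (tau - 1)))
  }
}

#' Scale background noise to a target signal-to-background ratio
#'
#' Returns `c * N` with the scalar c chosen so that the spike recording
#' `M0 + c * N` has [compute_snr()] equal to `target_ratio` when the
#' baseline is scaled by the same factor: `c = peak(M0) /
#' (target_ratio * pooled_sd(N))`.
#'
#' @param M0 noiseless signal matrix (defines the spike peak).
#' @param N noise matrix (same number of channels).
#' @param target_ratio desired ratio (1 = 0 dB).
#' @param peak_index optional peak column of `M0`.
#' @return List with `scaled` (c * N) and `scale` (c).
#' @export
scale_background <- function(M0, N, target_ratio = 1, peak_index = NULL) {
  s <- sqrt(mean((N - rowMeans(N))^2) * ncol(N) / (ncol(N) - 1))
  if (s == 0) stop("noise matrix is zero")
  if (is.null(peak_index)) peak_index <- which.max(apply(abs(M0), 2, max))
  peak <- max(abs(M0[, peak_index]))
  cc <- peak / (target_ratio * s)
  list(scaled = cc * N, scale = cc)
}
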