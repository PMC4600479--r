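#' Simulate a static extended-source spike dataset
#'
#' Builds the theoretical current distribution `Jth` (uniform
#' `amplitude` times the spike waveform on the patch, zero elsewhere),
#' applies the lead fields per modality and adds scaled background
#' noise. A baseline segment of the same duration, drawn from the same
#' background process and scaled by the same factor, is stored per
#' modality.
#'
#' @param mesh a [cortical_mesh()].
#' @param leadfields named list of [leadfield()]s (e.g. `list(EEG = ,
#'   MEG = )`).
#' @param patch a [grow_patch()] result.
#' @param spike a [gamma_spike()] timecourse.
#' @param noise list with `target_ratio` (signal-to-background ratio used
#'   when `scale` is NULL), `scale` (optional named per-modality scaling
#'   factors from a reference configuration), and optional
#'   `generator` arguments (`spectral_slope`, `alpha_power`,
#'   `mixing_rho`). `target_ratio = Inf` or `scale = 0` gives noiseless
#'   data.
#' @param seed integer seed.
#' @return A `simulated_dataset`: recordings `M`, baselines `E`,
#'   ground-truth `Jth` (patch rows only, as `Jth_patch` plus indices),
#'   achieved per-modality SNR, the patch, spike and seed.
#' @export
simulate_static <- function(mesh, leadfields, patch, spike = gamma_spike(),
                            noise = list(target_ratio = 1), seed = 1) {
  simulate_patches(mesh, leadfields, list(patch), list(spike), noise, seed)
}

#' Simulate two propagating extended sources
#'
#' Two patches in the same hemisphere (same sign of the first
#' coordinate), with seed-to-seed graph distance `separation_order`, the
#' second following the first with a `delay_ms` lag. Patches must not
#' overlap.
#'
#' @inheritParams simulate_static
#' @param patch1,patch2 two [grow_patch()] results.
#' @param delay_ms propagation delay (default 15 ms).
#' @param separation_order required seed-to-seed graph distance
#'   (checked; NULL skips the check).
#' @export
simulate_propagation <- function(mesh, leadfields, patch1, patch2,
                                 spike = gamma_spike(), delay_ms = 15,
                                 separation_order = 10,
                                 noise = list(target_ratio = 3), seed = 1) {
  if (length(intersect(patch1$vertices, patch2$vertices)) > 0) {
    stop("patches overlap")
  }
  x1 <- mesh$vertices[patch1$seed, 1]
  x2 <- mesh$vertices[patch2$seed, 1]
  if (sign(x1) != sign(x2)) stop("seeds must lie in the same hemisphere")
  if (!is.null(separation_order)) {
    d <- graph_bfs_dist(mesh$adjacency, patch1$seed,
                        max_order = separation_order + 1)[patch2$seed]
    if (d != separation_order) {
      stop(sprintf("seed-to-seed graph distance is %s, not %d",
                   format(d), separation_order))
    }
  }
  fs <- 1 / diff(spike$t[1:2])
  shift <- round(delay_ms / 1000 * fs)
  w2 <- c(rep(0, shift), head(spike$w, length(spike$w) - shift))
  spike2 <- structure(list(t = spike$t, w = w2,
                           peak_index = as.integer(spike$peak_index +
                                                     shift)),
                      class = "spike_timecourse")
  simulate_patches(mesh, leadfields, list(patch1, patch2),
                   list(spike, spike2), noise, seed)
}

simulate_patches <- function(mesh, leadfields, patches, spikes, noise,
                             seed) {
  modalities <- names(leadfields)
  if (is.null(modalities)) stop("`leadfields` must be a named list")
  tau <- length(spikes[[1]]$w)
  p <- nrow(mesh$vertices)
  # ground truth on the union of patches, nA.m
  Jth_rows <- list()
  for (k in seq_along(patches)) {
    amp <- patches[[k]]$amplitude
    Jth_rows[[k]] <- outer(rep(amp, length(patches[[k]]$vertices)),
                           spikes[[k]]$w)
  }
  M <- list(); E <- list(); snr <- list(); scales <- list()
  target <- if (is.null(noise$target_ratio)) 1 else noise$target_ratio
  gen_args <- noise[intersect(names(noise),
                              c("spectral_slope", "alpha_power",
                                "mixing_rho", "white_fraction", "fs"))]
  for (mod in modalities) {
    G <- leadfields[[mod]]$G
    M0 <- matrix(0, nrow(G), tau)
    for (k in seq_along(patches)) {
      idx <- patches[[k]]$vertices
      M0 <- M0 + G[, idx, drop = FALSE] %*% (Jth_rows[[k]] * 1e-9)
    }
    cc_spec <- if (is.list(noise$scale)) noise$scale[[mod]] else noise$scale
    noiseless <- (is.null(cc_spec) && is.infinite(target)) ||
      (!is.null(cc_spec) && cc_spec == 0)
    if (noiseless) {
      N_sig <- matrix(0, nrow(G), tau)
      N_base <- matrix(0, nrow(G), tau)
      cc <- 0
    } else {
      raw <- if (is.function(noise$generator)) {
        # shared seed across modalities: simultaneously recorded
        # backgrounds reflect the same underlying brain activity
        noise$generator(mod, nrow(G), 2L * tau, derive_seed(seed, 5))
      } else {
        do.call(generate_background,
                c(list(q = nrow(G), tau = 2L * tau,
                       positions = if (is.list(noise$positions))
                         noise$positions[[mod]] else NULL,
                       seed = derive_seed(seed, match(mod, modalities))),
                  gen_args))
      }
      if (!is.null(cc_spec)) {
        cc <- cc_spec
      } else {
        cc <- scale_background(M0, raw[, seq_len(tau), drop = FALSE],
                               target_ratio = target,
                               peak_index = spikes[[1]]$peak_index)$scale
      }
      N_sig <- cc * raw[, seq_len(tau), drop = FALSE]
      N_base <- cc * raw[, tau + seq_len(tau), drop = FALSE]
    }
    M[[mod]] <- M0 + N_sig
    E[[mod]] <- N_base
    scales[[mod]] <- cc
    snr[[mod]] <- if (cc == 0) Inf else {
      compute_snr(M[[mod]], E[[mod]],
                  peak_index = spikes[[1]]$peak_index)
    }
  }
  structure(
    list(M = M, E = E, Jth_patch = Jth_rows, patches = patches,
         spikes = spikes, snr = snr, noise_scale = scales,
         p = p, seed = seed),
    class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("<simulated_dataset> %d source(s), modalities: %s\n",
              length(x$patches), paste(names(x$M), collapse = ", ")))
  for (mod in names(x$snr)) {
    cat(sprintf("  %s: %d x %d, SNR %.2f\n", mod, nrow(x$M[[mod]]),
                ncol(x$M[[mod]]), x$snr[[mod]]))
  }
  invisible(x)
}

#' Dense ground-truth current matrix
#'
#' @param sim a `simulated_dataset`.
#' @return p x tau matrix in nA.m (zero outside the simulated patches).
#' @export
ground_truth_current <- function(sim) {
  tau <- ncol(sim$Jth_patch[[1]])
  J <- matrix(0, sim$p, tau)
  for (k in seq_along(sim$patches)) {
    J[sim$patches[[k]]$vertices, ] <- J[sim$patches[[k]]$vertices, ] +
      sim$Jth_patch[[k]]
  }
  J
}

#' Perturb the brain-to-skull conductivity ratio
#'
#' Draws Rbs from a truncated normal distribution (default mean 20,
#' sd 3.3, truncated to \[15, 25\]) and returns a head model whose skull
#' conductivity realizes the drawn ratio.
#'
#' @param head a [head_model()].
#' @param mean,sd,lower,upper truncated-normal parameters on the
#'   denominator scale of 1:Rbs.
#' @param seed integer seed.
#' @return A `head_model` with updated skull conductivity and `rbs`.
#' @export
perturb_rbs <- function(head, mean = 20, sd = 3.3, lower = 15, upper = 25,
                        seed = 1) {
  if (sd < 0 || upper <= lower) stop("degenerate distribution parameters")
  rbs <- with_seed(seed, {
    if (sd == 0) mean else {
      repeat {
        x <- rnorm(1, mean, sd)
        if (x >= lower && x <= upper) break
      }
      x
    }
  })
  cond <- head$conductivities
  cond[2] <- cond[1] / rbs
  head_model(center = head$center, radii = head$radii,
             conductivities = cond)
}
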