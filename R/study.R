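#' Configuration of a simulation study
#'
#' Collects the geometry, simulation, localization and evaluation
#' parameters of an end-to-end study into one validated object. The
#' defaults reproduce the reference static-source conditions: extended
#' patches grown to neighbourhood order 3 at 9.5 nA.m per dipole,
#' background scaled to a signal-to-background ratio of 1 (0 dB) for the
#' most superficial reference source, 54 EEG channels fused with 272
#' MEG channels.
#'
#' @param n_simulations number of simulated source configurations.
#' @param n_subdivisions icosphere subdivision of the cortex (4 gives
#'   2562 vertices).
#' @param folding folding-field parameters passed to
#'   [build_synthetic_cortex()].
#' @param cortex_radius mean cortical radius in mm.
#' @param s_e patch spatial-extent order.
#' @param amplitude dipole amplitude (nA.m).
#' @param target_ratio signal-to-background ratio of the reference
#'   configuration (1 = 0 dB).
#' @param montage EEG montage size (54, 32 or 20).
#' @param methods subset of `c("cMEM", "MNE", "dSPM", "sLORETA")`.
#' @param modalities subset of `c("EEG", "MEG", "MEEG")`.
#' @param simulation_type `"static"` (one patch) or `"propagation"`
#'   (two delayed patches).
#' @param delay_ms,separation_order propagation parameters.
#' @param window_halfwidth half-width (samples) of the analysis window
#'   around the spike peak.
#' @param msp_halfwidth half-width (samples) of the wider window used
#'   for the MSP scores (the pre-localization benefits from seeing the
#'   whole main spike deflection).
#' @param parcel_scale DDP neighbourhood order.
#' @param seed_zmin seeds are drawn from vertices with z >=
#'   `seed_zmin` times the mean cortical radius: the bottom cap of the
#'   closed synthetic surface has no anatomical counterpart (a head has
#'   no cortex below the skull base) and no sensor coverage.
#' @param msp_energy energy fraction of the MSP component rule.
#' @param noise background-generator parameters (list).
#' @param anatomy_seed seed of the synthetic folded anatomy. The
#'   anatomy plays the role of the single subject on which every
#'   simulation of a study is run, so it is fixed independently of the
#'   master seed; sources, noise and metric sampling all derive from
#'   `seed`.
#' @param seed master seed; every random draw in the study other than
#'   the anatomy derives from it.
#' @return A `study_config` list.
#' @export
study_config <- function(n_simulations = 30,
                         n_subdivisions = 4,
                         folding = list(amplitude = 9, n_waves = 12,
                                        frequency = 6),
                         cortex_radius = 80,
                         s_e = 3,
                         amplitude = 9.5,
                         target_ratio = 1,
                         montage = 54,
                         methods = c("cMEM", "MNE", "dSPM", "sLORETA"),
                         modalities = c("EEG", "MEG", "MEEG"),
                         simulation_type = c("static", "propagation"),
                         delay_ms = 15,
                         separation_order = 10,
                         window_halfwidth = 1,
                         msp_halfwidth = 15,
                         parcel_scale = 4,
                         seed_zmin = -0.25,
                         msp_energy = 0.95,
                         noise = list(type = "brain", spectral_slope = 1,
                                      alpha_power = 1, n_latent = 250,
                                      white_fraction = 0.4,
                                      mixing_rho = 40),
                         anatomy_seed = 193197,
                         seed = 1) {
  simulation_type <- match.arg(simulation_type)
  if (n_simulations < 1) stop("`n_simulations` must be >= 1")
  methods <- match.arg(methods, several.ok = TRUE)
  modalities <- match.arg(modalities, several.ok = TRUE)
  structure(as.list(environment()), class = "study_config")
}

#' Precompute the fixed study environment
#'
#' Geometry, lead fields (EEG unreferenced, referenced per montage) and
#' the reference noise scaling shared by every simulation of a study.
#'
#' @param config a [study_config()].
#' @param head optional [head_model()] (default [head_model()]).
#' @return List used by [run_study()]; reusable across configs that
#'   share geometry.
#' @export
prepare_study <- function(config, head = head_model()) {
  geo <- build_synthetic_cortex(config$n_subdivisions,
                                folding = config$folding %||%
                                  list(amplitude = 9, n_waves = 12,
                                       frequency = 6),
                                radius = config$cortex_radius %||% 80,
                                seed = config$anatomy_seed %||%
                                  derive_seed(config$seed, 101),
                                head = head)
  lf_eeg_raw <- eeg_leadfield_sphere(geo$mesh, head, geo$eeg,
                                     average_reference = FALSE)
  lf_meg <- meg_leadfield_sphere(geo$mesh, head, geo$meg)
  keep <- if (config$montage < nrow(geo$eeg$positions)) {
    montage_subset(geo$eeg, config$montage)
  } else {
    seq_len(nrow(geo$eeg$positions))
  }
  G_eeg <- apply_average_reference(lf_eeg_raw$G[keep, , drop = FALSE])
  lf_eeg <- leadfield(G_eeg, "EEG", labels = lf_eeg_raw$labels[keep])
  # reference scaling: most superficial seed, patch grown to the order
  # whose area is closest to the 6 cm^2 reference extent
  ref_seed <- which.max(row_norms(sweep(geo$mesh$vertices, 2, head$center)))
  cand <- lapply(0:4, function(o) grow_patch(geo$mesh, ref_seed, o,
                                             amplitude = config$amplitude))
  ref_patch <- cand[[which.min(vapply(cand, function(pt)
    abs(pt$area_cm2 - 6), numeric(1)))]]
  spike <- gamma_spike()
  positions <- list(EEG = geo$eeg$positions[keep, , drop = FALSE],
                    MEG = geo$meg$positions)
  lfs <- list(EEG = lf_eeg, MEG = lf_meg)
  generator <- if (identical(config$noise$type %||% "brain", "brain")) {
    brain_noise_generator(
      lfs,
      n_latent = config$noise$n_latent %||% 250,
      spectral_slope = config$noise$spectral_slope %||% 1,
      alpha_power = config$noise$alpha_power %||% 1,
      white_fraction = config$noise$white_fraction %||% 0.4)
  } else NULL
  scales <- list()
  for (mod in c("EEG", "MEG")) {
    G <- lfs[[mod]]$G
    M0 <- G[, ref_patch$vertices, drop = FALSE] %*%
      (outer(rep(config$amplitude, length(ref_patch$vertices)),
             spike$w) * 1e-9)
    raw <- if (!is.null(generator)) {
      generator(mod, nrow(G), length(spike$w),
                derive_seed(config$seed, 150))
    } else {
      do.call(generate_background,
              c(list(q = nrow(G), tau = length(spike$w),
                     positions = positions[[mod]],
                     seed = derive_seed(config$seed, 150,
                                        match(mod, c("EEG", "MEG")))),
                config$noise[intersect(names(config$noise),
                                       c("spectral_slope", "alpha_power",
                                         "mixing_rho", "white_fraction",
                                         "fs"))]))
    }
    scales[[mod]] <- scale_background(M0, raw, config$target_ratio,
                                      peak_index = spike$peak_index)$scale
  }
  list(geo = geo, head = head, lf = lfs,
       eeg_keep = keep, spike = spike, noise_scale = scales,
       positions = positions, generator = generator,
       ref_patch = ref_patch)
}

apply_average_reference <- function(X) sweep(X, 2, colMeans(X))

#' Run a simulation study
#'
#' For every simulated source configuration and every (method, modality)
#' arm: simulate spike data with scaled background, localize over a
#' short window around the spike peak, and score the estimate against
#' the ground truth (AUC at the peak, spatial dispersion, shape error).
#' Fully deterministic given the config's master seed.
#'
#' @param config a [study_config()].
#' @param env optional [prepare_study()] result to reuse geometry and
#'   lead fields.
#' @return A tibble with one row per (simulation, source, method,
#'   modality).
#' @export
run_study <- function(config, env = NULL) {
  if (is.null(env)) env <- prepare_study(config)
  mesh <- env$geo$mesh
  p <- nrow(mesh$vertices)
  rows <- list()
  for (i in seq_len(config$n_simulations)) {
    sim_seed <- derive_seed(config$seed, 200, i)
    sim <- simulate_study_case(config, env, sim_seed)
    arms <- localize_and_score(config, env, sim, sim_seed, i)
    rows[[i]] <- arms
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("memfusion_study", class(out))
  out
}

simulate_study_case <- function(config, env, sim_seed) {
  mesh <- env$geo$mesh
  p <- nrow(mesh$vertices)
  zmin <- (config$seed_zmin %||% -0.25) *
    mean(row_norms(sweep(mesh$vertices, 2, env$head$center)))
  eligible <- which(mesh$vertices[, 3] - env$head$center[3] >= zmin)
  lfs <- list(EEG = env$lf$EEG, MEG = env$lf$MEG)
  noise <- c(list(scale = env$noise_scale, positions = env$positions,
                  generator = env$generator),
             config$noise)
  if (config$simulation_type == "static") {
    seed_v <- with_seed(derive_seed(sim_seed, 1),
                        eligible[sample.int(length(eligible), 1)])
    patch <- grow_patch(mesh, seed_v, config$s_e, config$amplitude)
    simulate_static(mesh, lfs, patch, env$spike, noise = noise,
                    seed = derive_seed(sim_seed, 2))
  } else {
    pair <- with_seed(derive_seed(sim_seed, 1), {
      tries <- 0
      repeat {
        tries <- tries + 1
        if (tries > 500) {
          stop("no non-overlapping patch pair at this separation order ",
               "and extent; reduce `s_e` or increase `separation_order`")
        }
        s1 <- eligible[sample.int(length(eligible), 1)]
        ring <- which(graph_bfs_dist(mesh$adjacency, s1,
                                     config$separation_order) ==
                        config$separation_order)
        ring <- intersect(ring, eligible)
        ring <- ring[sign(mesh$vertices[ring, 1]) ==
                       sign(mesh$vertices[s1, 1])]
        if (length(ring) > 0) {
          s2 <- ring[sample.int(length(ring), 1)]
          p1 <- grow_patch(mesh, s1, config$s_e, config$amplitude)
          p2 <- grow_patch(mesh, s2, config$s_e, config$amplitude)
          if (length(intersect(p1$vertices, p2$vertices)) == 0) {
            break
          }
        }
      }
      list(p1 = p1, p2 = p2)
    })
    simulate_propagation(mesh, lfs, pair$p1, pair$p2, env$spike,
                         delay_ms = config$delay_ms,
                         separation_order = config$separation_order,
                         noise = noise, seed = derive_seed(sim_seed, 2))
  }
}

# scaled (SNR-transformed) blocks + noise variances for one modality
scale_modality <- function(sim, env, mod) {
  M <- sim$M[[mod]]
  E <- sim$E[[mod]]
  G <- env$lf[[mod]]$G
  stats <- baseline_std(E)
  tr <- snr_transform(M, G, stats)
  E_s <- E / stats$sigma_bar
  list(M_s = tr$M_s, G_s = tr$G_s, E_s = E_s,
       sigma_d = estimate_noise_cov(E_s, labels = env$lf[[mod]]$labels))
}

localize_and_score <- function(config, env, sim, sim_seed, sim_id) {
  mesh <- env$geo$mesh
  Jth <- ground_truth_current(sim)
  peaks <- vapply(sim$spikes, function(s) s$peak_index, integer(1))
  h <- config$window_halfwidth
  window <- sort(unique(unlist(lapply(peaks, function(pk) {
    pmax(1, pmin(ncol(Jth), (pk - h):(pk + h)))
  }))))
  peak_pos <- match(peaks, window)
  hm <- config$msp_halfwidth %||% 15
  msp_window <- sort(unique(unlist(lapply(peaks, function(pk) {
    pmax(1, pmin(ncol(Jth), (pk - hm):(pk + hm)))
  }))))
  blocks <- list()
  for (mod in c("EEG", "MEG")) blocks[[mod]] <- scale_modality(sim, env, mod)
  ic <- list(EEG = NA_real_, MEG = NA_real_)
  for (mod in c("EEG", "MEG")) {
    ic[[mod]] <- cancellation_index(env$lf[[mod]]$G, sim$patches[[1]])
  }
  ecc <- eccentricity(sim$patches[[1]]$vertices, mesh, env$head)
  out <- list()
  row_id <- 0
  for (method in config$methods) {
    for (modality in config$modalities) {
      est <- tryCatch(
        localize_window(method, modality, blocks, window, config, mesh,
                        msp_window = msp_window),
        error = function(e) e)
      for (src in seq_along(sim$patches)) {
        row_id <- row_id + 1
        patch <- sim$patches[[src]]
        other <- if (length(sim$patches) > 1) {
          unlist(lapply(sim$patches[-src], `[[`, "vertices"))
        } else integer(0)
        if (inherits(est, "error")) {
          out[[row_id]] <- tibble::tibble(
            simulation = sim_id, source = src, method = method,
            modality = modality, auc = NA_real_, sd_mm = NA_real_,
            se = NA_real_, error = conditionMessage(est))
          next
        }
        jpk <- abs(est$J[, peak_pos[src]])
        auc <- roc_auc(jpk, patch, mesh, exclude = setdiff(other,
                                                           patch$vertices),
                       seed = derive_seed(sim_seed, 3, row_id))
        sd_mm <- if (all(jpk == 0)) NA_real_ else
          spatial_dispersion(jpk, patch, mesh)
        se <- tryCatch(
          shape_error(Jth[, window, drop = FALSE], est$J, patch),
          error = function(e) NA_real_)
        out[[row_id]] <- tibble::tibble(
          simulation = sim_id, source = src, method = method,
          modality = modality, auc = auc, sd_mm = sd_mm, se = se,
          error = NA_character_)
      }
    }
  }
  res <- dplyr::bind_rows(out)
  res$snr_eeg <- sim$snr$EEG
  res$snr_meg <- sim$snr$MEG
  res$ic_eeg <- ic$EEG
  res$ic_meg <- ic$MEG
  res$eccentricity <- ecc
  res$ecc_class <- eccentricity_class(ecc)
  res$area_cm2 <- sim$patches[[1]]$area_cm2
  res$seed <- sim_seed
  res
}

# Localize one (method, modality) arm over the window columns.
localize_window <- function(method, modality, blocks, window, config,
                            mesh, msp_window = window) {
  mods <- if (modality == "MEEG") c("EEG", "MEG") else modality
  use <- blocks[mods]
  Mw_list <- lapply(use, function(b) b$M_s[, window, drop = FALSE])
  if (method == "cMEM") {
    fused <- concatenate_modalities(
      eeg = if ("EEG" %in% mods)
        list(M_s = Mw_list[["EEG"]], G_s = use$EEG$G_s,
             E_s = use$EEG$E_s) else NULL,
      meg = if ("MEG" %in% mods)
        list(M_s = Mw_list[["MEG"]], G_s = use$MEG$G_s,
             E_s = use$MEG$E_s) else NULL)
    sigma_d <- unlist(lapply(use, `[[`, "sigma_d"), use.names = FALSE)
    msp <- lapply(mods, function(mod)
      msp_scores(use[[mod]]$M_s[, msp_window, drop = FALSE],
                 use[[mod]]$G_s, energy = config$msp_energy,
                 baseline = use[[mod]]$E_s))
    fused_scores <- if (length(msp) == 2) fuse_msp(msp[[1]], msp[[2]])
      else msp[[1]]
    parc <- ddp_parcellate(fused_scores, mesh,
                           scale = config$parcel_scale)
    alpha <- init_alpha(parc, fused_scores)
    model <- build_reference_model(parc, alpha, mesh)
    solve_mem(fused, model = model, sigma_d = sigma_d)
  } else {
    wh <- lapply(mods, function(mod)
      whiten(Mw_list[[mod]], use[[mod]]$G_s, use[[mod]]$sigma_d))
    M_w <- do.call(rbind, lapply(wh, `[[`, "M_w"))
    G_w <- do.call(rbind, lapply(wh, `[[`, "G_w"))
    # whitened units: exclude corner candidates fitting below the known
    # noise floor (half of E||noise||^2 = q * tau)
    lam <- lcurve_lambda(M_w, G_w,
                         min_residual2 = 0.5 * nrow(M_w) * ncol(M_w))$lambda
    switch(method,
           MNE = mne_solve(M_w, G_w, lam),
           dSPM = dspm_solve(M_w, G_w, lam),
           sLORETA = sloreta_solve(M_w, G_w, lam))
  }
}

#' Summarize a study by arm
#'
#' Median AUC, spatial dispersion and shape error per (method, modality,
#' source).
#'
#' @param results the tibble returned by [run_study()].
#' @return A tibble of medians and counts per arm.
#' @export
summarize_study <- function(results) {
  results |>
    dplyr::group_by(.data$method, .data$modality, .data$source) |>
    dplyr::summarise(
      n = dplyr::n(),
      median_auc = median(.data$auc, na.rm = TRUE),
      median_sd_mm = median(.data$sd_mm, na.rm = TRUE),
      median_se = median(.data$se, na.rm = TRUE),
      failed = sum(!is.na(.data$error)),
      .groups = "drop")
}

#' Brain-to-skull conductivity-ratio robustness experiment
#'
#' Simulates EEG data with a randomized Rbs per source (truncated normal
#' on \[15, 25\], mean 20) while localizing with the head model fixed at
#' the reference Rbs, and pairs each AUC with the one from a matched
#' simulation at the reference Rbs, for cMEM on EEG and on fused MEEG.
#'
#' @param config a [study_config()]; `n_simulations` sources are drawn.
#' @param env optional [prepare_study()] result.
#' @param modalities arms to run (default EEG and MEEG).
#' @return Tibble with one row per (source, modality): `rbs_sim`,
#'   `auc_incorrect` (perturbed simulation), `auc_correct` (matched).
#' @export
run_rbs_experiment <- function(config, env = NULL,
                               modalities = c("EEG", "MEEG")) {
  if (is.null(env)) env <- prepare_study(config)
  mesh <- env$geo$mesh
  p <- nrow(mesh$vertices)
  rows <- list()
  for (i in seq_len(config$n_simulations)) {
    sim_seed <- derive_seed(config$seed, 400, i)
    head_i <- perturb_rbs(env$head, seed = derive_seed(sim_seed, 9))
    lf_eeg_i <- eeg_leadfield_sphere(mesh, head_i, env$geo$eeg,
                                     average_reference = FALSE)
    G_i <- apply_average_reference(lf_eeg_i$G[env$eeg_keep, ,
                                              drop = FALSE])
    env_i <- env
    env_i$lf$EEG <- leadfield(G_i, "EEG")
    zmin <- (config$seed_zmin %||% -0.25) *
      mean(row_norms(sweep(mesh$vertices, 2, env$head$center)))
    eligible <- which(mesh$vertices[, 3] - env$head$center[3] >= zmin)
    seed_v <- with_seed(derive_seed(sim_seed, 1),
                        eligible[sample.int(length(eligible), 1)])
    patch <- grow_patch(mesh, seed_v, config$s_e, config$amplitude)
    cfg <- config
    cfg$methods <- "cMEM"
    cfg$modalities <- modalities
    for (arm in c("incorrect", "correct")) {
      sim_env <- if (arm == "incorrect") env_i else env
      sim <- simulate_static(mesh, list(EEG = sim_env$lf$EEG,
                                        MEG = env$lf$MEG),
                             patch, env$spike,
                             noise = c(list(scale = env$noise_scale,
                                            positions = env$positions,
                                            generator = env$generator),
                                       config$noise),
                             seed = derive_seed(sim_seed, 2))
      # localization always uses the reference-Rbs lead field
      scored <- localize_and_score(cfg, env, sim, sim_seed, i)
      scored$arm <- arm
      scored$rbs_sim <- head_i$rbs
      rows[[length(rows) + 1]] <- scored
    }
  }
  dplyr::bind_rows(rows) |>
    dplyr::select(dplyr::all_of(c("simulation", "modality", "arm",
                                  "rbs_sim", "auc"))) |>
    tidyr::pivot_wider(names_from = "arm", values_from = "auc",
                       names_prefix = "auc_")
}
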