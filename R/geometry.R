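#' Three-shell spherical head model
#'
#' Concentric-sphere volume conductor with inner-skull, outer-skull and
#' scalp interfaces. The brain-to-skull conductivity ratio Rbs
#' (conductivity(brain) / conductivity(skull)) is the parameter the EEG
#' forward model is most sensitive to; the default 0.33:0.0165:0.33 S/m
#' gives Rbs = 20.
#'
#' @param center 3-vector, head centre in mm.
#' @param radii increasing radii (mm) of inner skull, outer skull, scalp.
#' @param conductivities conductivities (S/m) of brain, skull, scalp.
#' @return A `head_model` object; field `rbs` holds the conductivity ratio.
#' @export
head_model <- function(center = c(0, 0, 0),
                       radii = c(90, 95, 102),
                       conductivities = c(0.33, 0.0165, 0.33)) {
  if (length(radii) != 3 || any(diff(radii) <= 0)) {
    stop("`radii` must be three strictly increasing values")
  }
  if (any(conductivities <= 0)) stop("conductivities must be > 0")
  structure(
    list(center = as.numeric(center), radii = as.numeric(radii),
         conductivities = as.numeric(conductivities),
         rbs = conductivities[1] / conductivities[2]),
    class = "head_model")
}

#' @export
print.head_model <- function(x, ...) {
  cat(sprintf("<head_model> radii %s mm, Rbs = %.2f\n",
              paste(x$radii, collapse = "/"), x$rbs))
  invisible(x)
}

#' Sensor arrays
#'
#' @param modality `"EEG"` or `"MEG"`.
#' @param positions q x 3 matrix of sensor positions (mm).
#' @param orientations q x 3 unit sensing directions (MEG only).
#' @param labels channel names.
#' @return A `sensor_array` object.
#' @export
sensor_array <- function(modality, positions, orientations = NULL,
                         labels = NULL) {
  modality <- match.arg(modality, c("EEG", "MEG"))
  positions <- as.matrix(positions)
  q <- nrow(positions)
  if (q < 1) stop("need at least one sensor")
  if (modality == "MEG") {
    if (is.null(orientations)) stop("MEG sensors need orientations")
    orientations <- as.matrix(orientations)
    orientations <- orientations / row_norms(orientations)
  }
  if (is.null(labels)) {
    labels <- sprintf("%s%03d", ifelse(modality == "EEG", "E", "M"),
                      seq_len(q))
  }
  structure(list(modality = modality, positions = positions,
                 orientations = orientations, labels = labels),
            class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf("<sensor_array> %s, %d channels\n", x$modality,
              nrow(x$positions)))
  invisible(x)
}

# Quasi-uniform points on a spherical cap (z/r in [z_min, 1]) using the
# Fibonacci lattice; deterministic.
fibonacci_cap <- function(n, radius, z_min) {
  i <- seq_len(n)
  z <- z_min + (1 - z_min) * (1 - (i - 0.5) / n)
  th <- pi * (3 - sqrt(5)) * (i - 1)
  r <- sqrt(pmax(0, 1 - z^2))
  radius * cbind(r * cos(th), r * sin(th), z)
}

#' Synthetic folded cortex with matching head model and sensor arrays
#'
#' Builds an icosphere-based cortical surface whose radius is perturbed by
#' a band-limited random "folding" field, emulating the alternation of
#' gyral (radial) and sulcal (tangential) dipole orientations that drives
#' the complementary EEG/MEG sensitivity. EEG electrodes are placed
#' quasi-uniformly on the scalp sphere with extended inferior coverage;
#' MEG sensors are radial point magnetometers on a helmet sphere.
#'
#' @param n_subdivisions icosphere subdivision level; the mesh has
#'   `10 * 4^n + 2` vertices.
#' @param folding list with `amplitude` (mm, 0 disables folding),
#'   `n_waves` (number of random plane-wave components) and `frequency`
#'   (radians per unit of the direction cosine; higher = finer folds).
#' @param radius mean cortical radius in mm.
#' @param head a [head_model()].
#' @param n_eeg,n_meg channel counts.
#' @param meg_radius MEG helmet radius (mm).
#' @param seed integer seed controlling the folding field.
#' @return List with `mesh`, `head`, `eeg`, `meg`.
#' @export
build_synthetic_cortex <- function(n_subdivisions = 4,
                                   folding = list(amplitude = 9,
                                                  n_waves = 12,
                                                  frequency = 6),
                                   radius = 80,
                                   head = head_model(),
                                   n_eeg = 54, n_meg = 272,
                                   meg_radius = 120,
                                   seed = 1) {
  if (n_subdivisions < 0) stop("`n_subdivisions` must be >= 0")
  amplitude <- if (is.null(folding$amplitude)) 0 else folding$amplitude
  wrinkle <- if (is.null(folding$wrinkle_amplitude)) 0 else
    folding$wrinkle_amplitude
  if (radius + amplitude + wrinkle >= head$radii[1]) {
    stop("folding amplitude pushes vertices outside the inner skull")
  }
  ico <- icosphere(n_subdivisions)
  dirs <- ico$vertices                       # unit directions
  r <- rep(radius, nrow(dirs))
  wave_field <- function(nw, freq, dirs) {
    u <- matrix(rnorm(3 * nw), nw, 3)
    u <- u / row_norms(u)
    cf <- rnorm(nw)
    ph <- runif(nw, 0, 2 * pi)
    field <- rep(0, nrow(dirs))
    for (j in seq_len(nw)) {
      field <- field + cf[j] * sin(freq * (dirs %*% u[j, ])[, 1] + ph[j])
    }
    field / max(abs(field))
  }
  if (amplitude > 0 || wrinkle > 0) {
    r <- with_seed(derive_seed(seed, 1), {
      out <- rep(radius, nrow(dirs))
      if (amplitude > 0) {
        out <- out + amplitude * wave_field(folding$n_waves,
                                            folding$frequency, dirs)
      }
      if (wrinkle > 0) {
        out <- out + wrinkle *
          wave_field(folding$n_waves,
                     folding$wrinkle_frequency %||% 40, dirs)
      }
      out
    })
  }
  vertices <- dirs * r
  mesh <- cortical_mesh(sweep(vertices, 2, head$center, `+`), ico$faces)
  eeg <- sensor_array("EEG",
                      sweep(fibonacci_cap(n_eeg, head$radii[3], -0.30),
                            2, head$center, `+`))
  meg_pos <- fibonacci_cap(n_meg, meg_radius, -0.35)
  meg <- sensor_array("MEG", sweep(meg_pos, 2, head$center, `+`),
                      orientations = meg_pos / row_norms(meg_pos))
  list(mesh = mesh, head = head, eeg = eeg, meg = meg)
}

#' Reduced EEG montages
#'
#' Deterministically subsamples an EEG array to a quasi-uniform reduced
#' montage (greedy farthest-point selection starting from the vertex
#' electrode), mimicking clinical 32- and 20-electrode systems.
#'
#' @param eeg an EEG [sensor_array()].
#' @param n_keep montage size (e.g. 32 or 20).
#' @return Integer indices of the retained channels.
#' @export
montage_subset <- function(eeg, n_keep) {
  q <- nrow(eeg$positions)
  if (n_keep > q) stop("montage larger than the array")
  pos <- eeg$positions
  picked <- which.max(pos[, 3])
  d2 <- colSums((t(pos) - pos[picked, ])^2)
  while (length(picked) < n_keep) {
    nxt <- which.max(d2)
    picked <- c(picked, nxt)
    d2 <- pmin(d2, colSums((t(pos) - pos[nxt, ])^2))
  }
  sort(picked)
}

#' Patch eccentricity
#'
#' Mean Euclidean distance (mm) between the patch vertices and the head
#' centre; a proxy for source depth. Sources above 80 mm are labelled
#' superficial, 60-80 mm mesial, below 60 mm deep.
#'
#' @param patch integer vertex indices.
#' @param mesh a [cortical_mesh()].
#' @param head a [head_model()].
#' @return Eccentricity in mm.
#' @export
eccentricity <- function(patch, mesh, head) {
  if (length(patch) == 0) stop("empty patch")
  d <- sqrt(colSums((t(mesh$vertices[patch, , drop = FALSE]) -
                       head$center)^2))
  mean(d)
}

#' @rdname eccentricity
#' @param ecc eccentricity value (mm).
#' @export
eccentricity_class <- function(ecc) {
  cut(ecc, breaks = c(-Inf, 60, 80, Inf),
      labels = c("deep", "mesial", "superficial"), right = FALSE) |>
    as.character()
}
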