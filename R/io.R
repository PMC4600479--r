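#' Wavefront OBJ mesh I/O
#'
#' @param mesh a [cortical_mesh()].
#' @param path file path.
#' @return `write_obj` returns `path` invisibly; `read_obj` a
#'   [cortical_mesh()].
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
  invisible(path)
}

#' @rdname write_obj
#' @export
read_obj <- function(path) {
  lines <- readLines(path)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  parse_rows <- function(x, prefix) {
    do.call(rbind, lapply(strsplit(sub(prefix, "", x), "\\s+"),
                          as.numeric))
  }
  vertices <- parse_rows(vl, "^v ")
  faces <- parse_rows(fl, "^f ")
  cortical_mesh(vertices, faces)
}

#' Export a lead field, sensor array or parcellation as TSV
#'
#' Plain-text serialization used for interchange with other tools.
#'
#' @param x the object to export.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_tsv_matrix <- function(x, path) {
  m <- if (inherits(x, "leadfield")) x$G else as.matrix(x)
  utils::write.table(m, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_matrix
#' @export
read_tsv_matrix <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
}

#' Serialize a simulated dataset to a plain-text directory
#'
#' Writes per-modality data and baseline matrices (TSV), the sparse
#' ground-truth current (triplets), patch membership and the seed/config
#' echo (JSON) under `dir`.
#'
#' @param sim a `simulated_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (mod in names(sim$M)) {
    write_tsv_matrix(sim$M[[mod]], file.path(dir, paste0("M_", mod, ".tsv")))
    write_tsv_matrix(sim$E[[mod]], file.path(dir, paste0("E_", mod, ".tsv")))
  }
  tau <- ncol(sim$Jth_patch[[1]])
  trip <- list()
  for (k in seq_along(sim$patches)) {
    idx <- sim$patches[[k]]$vertices
    Jk <- sim$Jth_patch[[k]]
    trip[[k]] <- data.frame(
      vertex = rep(idx, times = tau),
      sample = rep(seq_len(tau), each = length(idx)),
      current = as.numeric(Jk))
  }
  trip <- do.call(rbind, trip)
  trip <- trip[trip$current != 0, , drop = FALSE]
  utils::write.table(trip, file.path(dir, "Jth_triplets.tsv"), sep = "\t",
                     row.names = FALSE)
  meta <- list(
    modalities = names(sim$M), p = sim$p, tau = tau, seed = sim$seed,
    snr = sim$snr, noise_scale = sim$noise_scale,
    patches = lapply(sim$patches, function(pt)
      list(seed = pt$seed, vertices = pt$vertices, s_e = pt$s_e,
           area_cm2 = pt$area_cm2, amplitude = pt$amplitude)),
    peak_index = vapply(sim$spikes, function(s) s$peak_index, integer(1)))
  writeLines(jsonlite_json(meta), file.path(dir, "dataset.json"))
  invisible(dir)
}

jsonlite_json <- function(x) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("the jsonlite package is required for JSON serialization")
  }
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("the jsonlite package is required for JSON serialization")
  }
  meta <- jsonlite::fromJSON(file.path(dir, "dataset.json"),
                             simplifyVector = TRUE)
  M <- list(); E <- list()
  for (mod in meta$modalities) {
    M[[mod]] <- read_tsv_matrix(file.path(dir, paste0("M_", mod, ".tsv")))
    E[[mod]] <- read_tsv_matrix(file.path(dir, paste0("E_", mod, ".tsv")))
  }
  trip <- utils::read.table(file.path(dir, "Jth_triplets.tsv"),
                            sep = "\t", header = TRUE)
  patches <- lapply(seq_len(nrow(meta$patches)), function(k) {
    structure(list(seed = meta$patches$seed[k],
                   vertices = meta$patches$vertices[[k]],
                   s_e = meta$patches$s_e[k],
                   area_cm2 = meta$patches$area_cm2[k],
                   amplitude = meta$patches$amplitude[k]),
              class = "source_patch")
  })
  Jth_patch <- lapply(patches, function(pt) {
    Jk <- matrix(0, length(pt$vertices), meta$tau)
    rows <- trip[trip$vertex %in% pt$vertices, , drop = FALSE]
    Jk[cbind(match(rows$vertex, pt$vertices), rows$sample)] <- rows$current
    Jk
  })
  structure(list(M = M, E = E, Jth_patch = Jth_patch, patches = patches,
                 spikes = NULL, snr = as.list(meta$snr),
                 noise_scale = as.list(meta$noise_scale), p = meta$p,
                 seed = meta$seed, peak_index = meta$peak_index),
            class = "simulated_dataset")
}

#' Export per-vertex parcel labels
#'
#' @param parcellation a [ddp_parcellate()] result.
#' @param path TSV file path.
#' @return `path`, invisibly.
#' @export
write_parcellation_tsv <- function(parcellation, path) {
  utils::write.table(
    data.frame(vertex = seq_along(parcellation$parcel),
               parcel = parcellation$parcel),
    path, sep = "\t", row.names = FALSE)
  invisible(path)
}
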