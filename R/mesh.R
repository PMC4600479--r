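#' Cortical surface meshes
#'
#' A `cortical_mesh` is a triangulated closed surface carrying the source
#' space: one current dipole per vertex, oriented along the outward vertex
#' normal. Vertex coordinates are in millimetres.
#'
#' @param vertices numeric p x 3 matrix of vertex coordinates (mm).
#' @param faces integer f x 3 matrix of 1-based triangle vertex indices.
#' @return An object of class `cortical_mesh` with fields `vertices`,
#'   `faces`, `normals` (unit outward vertex normals), `adjacency`
#'   (edge-graph neighbour list) and a private cache environment.
#' @export
cortical_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(faces), ncol = 3)
  p <- nrow(vertices)
  if (ncol(vertices) != 3) stop("`vertices` must be p x 3")
  if (any(faces < 1L) || any(faces > p)) stop("face indices out of range")
  centroid <- colMeans(vertices)
  faces <- orient_faces_outward(vertices, faces, centroid)
  normals <- vertex_normals(vertices, faces)
  adjacency <- adjacency_from_faces(p, faces)
  structure(
    list(vertices = vertices, faces = faces, normals = normals,
         adjacency = adjacency, cache = new.env(parent = emptyenv())),
    class = "cortical_mesh")
}

#' @export
print.cortical_mesh <- function(x, ...) {
  cat(sprintf("<cortical_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# flip faces whose normal points towards the interior
orient_faces_outward <- function(vertices, faces, centroid) {
  v1 <- vertices[faces[, 1], , drop = FALSE]
  v2 <- vertices[faces[, 2], , drop = FALSE]
  v3 <- vertices[faces[, 3], , drop = FALSE]
  e1 <- v2 - v1
  e2 <- v3 - v1
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  fc <- (v1 + v2 + v3) / 3
  outward <- rowSums(n * sweep(fc, 2, centroid)) >= 0
  faces[!outward, c(2, 3)] <- faces[!outward, c(3, 2)]
  faces
}

face_normals_areas <- function(vertices, faces) {
  v1 <- vertices[faces[, 1], , drop = FALSE]
  v2 <- vertices[faces[, 2], , drop = FALSE]
  v3 <- vertices[faces[, 3], , drop = FALSE]
  e1 <- v2 - v1
  e2 <- v3 - v1
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  a2 <- sqrt(rowSums(n^2))            # twice the triangle area
  list(normals = n / a2, areas = a2 / 2)
}

vertex_normals <- function(vertices, faces) {
  fn <- face_normals_areas(vertices, faces)
  p <- nrow(vertices)
  acc <- matrix(0, p, 3)
  w <- fn$normals * fn$areas          # area-weighted face normals
  for (j in 1:3) {
    idx <- faces[, j]
    acc[, 1] <- acc[, 1] + tabulate_sum(idx, w[, 1], p)
    acc[, 2] <- acc[, 2] + tabulate_sum(idx, w[, 2], p)
    acc[, 3] <- acc[, 3] + tabulate_sum(idx, w[, 3], p)
  }
  acc / row_norms(acc)
}

tabulate_sum <- function(idx, values, n) {
  out <- numeric(n)
  agg <- rowsum(values, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

adjacency_from_faces <- function(p, faces) {
  edges <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  edges <- rbind(edges, edges[, c(2, 1)])
  key <- (edges[, 1] - 1) * p + edges[, 2]
  keep <- !duplicated(key) & edges[, 1] != edges[, 2]
  edges <- edges[keep, , drop = FALSE]
  ord <- order(edges[, 1], edges[, 2])
  edges <- edges[ord, , drop = FALSE]
  unname(split(edges[, 2], factor(edges[, 1], levels = seq_len(p))))
}

#' Vertices within a graph neighbourhood order
#'
#' Returns all vertices whose edge-graph distance from `seed` is at most
#' `order` (the "k-ring"), including the seed itself. The neighbourhood
#' order is the spatial-extent unit used both to grow simulated patches
#' and to set the parcel scale.
#'
#' @param mesh a [cortical_mesh()].
#' @param seed integer vertex index (1-based).
#' @param order integer neighbourhood order, >= 0.
#' @return Sorted integer vector of vertex indices.
#' @export
kring_neighborhood <- function(mesh, seed, order) {
  graph_kring(mesh$adjacency, seed, order)
}

graph_kring <- function(adjacency, seed, order) {
  p <- length(adjacency)
  if (length(seed) != 1L || is.na(seed) || seed < 1L || seed > p) {
    stop("invalid seed vertex index")
  }
  if (order < 0) stop("`order` must be >= 0")
  dist <- graph_bfs_dist(adjacency, seed, max_order = order)
  sort(which(dist <= order))
}

# BFS distances from (possibly multiple) sources; Inf beyond max_order
graph_bfs_dist <- function(adjacency, sources, max_order = Inf) {
  p <- length(adjacency)
  dist <- rep(Inf, p)
  dist[sources] <- 0
  frontier <- sources
  d <- 0
  while (length(frontier) > 0 && d < max_order) {
    d <- d + 1
    nxt <- unique(unlist(adjacency[frontier], use.names = FALSE))
    nxt <- nxt[dist[nxt] > d]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

# Per-vertex area: one third of the area of the incident triangles.
mesh_vertex_areas <- function(mesh) {
  cache <- mesh$cache
  if (!is.null(cache$vertex_areas)) return(cache$vertex_areas)
  fa <- face_normals_areas(mesh$vertices, mesh$faces)$areas
  p <- nrow(mesh$vertices)
  acc <- numeric(p)
  for (j in 1:3) acc <- acc + tabulate_sum(mesh$faces[, j], fa, p)
  cache$vertex_areas <- acc / 3
  cache$vertex_areas
}

# Precomputed k-ring membership for every vertex at a fixed order.
mesh_neighborhoods <- function(mesh, order) {
  cache <- mesh$cache
  key <- paste0("nb", order)
  if (!is.null(cache[[key]])) return(cache[[key]])
  adj <- mesh$adjacency
  p <- length(adj)
  out <- vector("list", p)
  for (v in seq_len(p)) out[[v]] <- graph_kring(adj, v, order)
  cache[[key]] <- out
  out
}

## ---- icosphere construction ----

icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, faces = f)
}

icosphere <- function(n_subdivisions) {
  base <- icosahedron()
  v <- base$vertices
  f <- base$faces
  if (n_subdivisions > 0) {
    for (s in seq_len(n_subdivisions)) {
      midpoint <- new.env(parent = emptyenv())
      nv <- nrow(v)
      vlist <- list(v)
      get_mid <- function(a, b) {
        key <- paste(min(a, b), max(a, b))
        hit <- midpoint[[key]]
        if (!is.null(hit)) return(hit)
        m <- (vlist[[1]][a, ] + vlist[[1]][b, ]) / 2
        m <- m / vec_norm(m)
        vlist[[1]] <<- rbind(vlist[[1]], m)
        idx <- nrow(vlist[[1]])
        midpoint[[key]] <- idx
        idx
      }
      nf <- matrix(0L, nrow(f) * 4, 3)
      for (i in seq_len(nrow(f))) {
        a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
        ab <- get_mid(a, b); bc <- get_mid(b, cc); ca <- get_mid(cc, a)
        nf[(i - 1) * 4 + 1, ] <- c(a, ab, ca)
        nf[(i - 1) * 4 + 2, ] <- c(b, bc, ab)
        nf[(i - 1) * 4 + 3, ] <- c(cc, ca, bc)
        nf[(i - 1) * 4 + 4, ] <- c(ab, bc, ca)
      }
      v <- vlist[[1]]
      f <- nf
    }
  }
  list(vertices = v, faces = f)
}
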