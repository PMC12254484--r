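#' Triangulated surface mesh
#'
#' Lightweight container for a closed triangulated surface: an n x 3 vertex
#' matrix (mm), an f x 3 face index matrix (1-based, counter-clockwise seen
#' from outside) and a per-vertex adjacency list derived from the edges.
#'
#' @param vertices numeric n x 3 matrix of vertex positions in mm.
#' @param faces integer f x 3 matrix of vertex indices.
#' @return An object of class `trimesh` with components `vertices`, `faces`,
#'   `adjacency` (list of integer neighbour vectors).
#' @export
trimesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  n <- nrow(vertices)
  if (any(faces < 1L) || any(faces > n)) {
    stop("face indices out of range [1, ", n, "]")
  }
  adj <- vector("list", n)
  e <- mesh_edge_pairs(faces)
  for (k in seq_len(nrow(e))) {
    i <- e[k, 1L]; j <- e[k, 2L]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj <- lapply(adj, function(v) sort(unique(v)))
  structure(list(vertices = vertices, faces = faces, adjacency = adj),
            class = "trimesh")
}

#' @export
print.trimesh <- function(x, ...) {
  cat("trimesh:", nrow(x$vertices), "vertices,", nrow(x$faces), "faces\n")
  invisible(x)
}

# unique undirected edges of a face matrix, rows sorted lexicographically
mesh_edge_pairs <- function(faces) {
  e <- rbind(faces[, c(1L, 2L)], faces[, c(2L, 3L)], faces[, c(3L, 1L)])
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  e <- unique(e)
  e[order(e[, 1L], e[, 2L]), , drop = FALSE]
}

#' Edges of a triangulated mesh
#'
#' @param mesh a [trimesh()].
#' @return Integer matrix with one row per undirected edge (smaller index
#'   first), sorted lexicographically.
#' @export
mesh_edges <- function(mesh) {
  stopifnot(inherits(mesh, "trimesh"))
  mesh_edge_pairs(mesh$faces)
}

#' Build an ellipsoidal heart surface mesh
#'
#' Generates a closed, orientable UV-sphere style triangulation mapped onto an
#' ellipsoid. Vertices lie exactly on the ellipsoid; the azimuthal placement of
#' each latitude ring is jittered deterministically from `seed` so that
#' distinct seeds give distinct (but reproducible) node layouts.
#'
#' @param n_nodes requested number of vertices (>= 12); the actual count is
#'   the closest achievable ring layout.
#' @param radii semi-axes in mm, length 3.
#' @param center ellipsoid centre in mm, length 3.
#' @param seed integer seed controlling the ring jitter.
#' @return A [trimesh()] with approximately `n_nodes` vertices.
#' @export
build_heart_surface <- function(n_nodes, radii = c(50, 40, 35),
                                center = c(0, 0, -60), seed = 1L) {
  if (length(n_nodes) != 1L || n_nodes < 12) {
    stop("n_nodes must be a single integer >= 12")
  }
  if (length(radii) != 3L || any(radii <= 0)) stop("radii must be 3 positive values")
  n_lon <- max(4L, as.integer(ceiling(sqrt(2 * (n_nodes - 2)))))
  n_lat <- max(3L, as.integer(round((n_nodes - 2) / n_lon)))
  offsets <- with_preserved_rng(seed, stats::runif(n_lat, 0, 2 * pi / n_lon))
  theta <- pi * seq_len(n_lat) / (n_lat + 1)
  verts <- matrix(0, nrow = 2L + n_lat * n_lon, ncol = 3L)
  verts[1L, ] <- c(0, 0, 1)
  verts[2L, ] <- c(0, 0, -1)
  idx <- 3L
  for (i in seq_len(n_lat)) {
    phi <- 2 * pi * (seq_len(n_lon) - 1L) / n_lon + offsets[i]
    verts[idx:(idx + n_lon - 1L), ] <- cbind(sin(theta[i]) * cos(phi),
                                             sin(theta[i]) * sin(phi),
                                             cos(theta[i]))
    idx <- idx + n_lon
  }
  verts <- sweep(verts, 2L, radii, `*`)
  verts <- sweep(verts, 2L, center, `+`)

  ring <- function(i) 2L + (i - 1L) * n_lon + seq_len(n_lon)  # ring i indices
  faces <- list()
  r1 <- ring(1L)
  faces[[length(faces) + 1L]] <- cbind(1L, r1, c(r1[-1L], r1[1L]))
  for (i in seq_len(n_lat - 1L)) {
    a <- ring(i); b <- ring(i + 1L)
    a2 <- c(a[-1L], a[1L]); b2 <- c(b[-1L], b[1L])
    faces[[length(faces) + 1L]] <- cbind(a, b, b2)
    faces[[length(faces) + 1L]] <- cbind(a, b2, a2)
  }
  rl <- ring(n_lat)
  faces[[length(faces) + 1L]] <- cbind(2L, c(rl[-1L], rl[1L]), rl)
  trimesh(verts, do.call(rbind, faces))
}

#' Build a planar rectangular detector grid
#'
#' Constructs a `rows x cols` coplanar grid of sensing positions with the
#' given inter-sensor spacing, centred on `origin`, lying in the plane with
#' the given normal.
#'
#' @param rows,cols grid dimensions (>= 1).
#' @param spacing inter-sensor distance in mm (> 0).
#' @param origin grid centre, mm.
#' @param normal sensing-plane normal (non-zero; normalised internally).
#' @return An object of class `detector_array` with `positions` (M x 3, mm),
#'   `normal` (unit), `rows`, `cols`, `spacing`.
#' @export
build_detector_grid <- function(rows = 9L, cols = 9L, spacing = 30,
                                origin = c(0, 0, 0), normal = c(0, 0, 1)) {
  if (rows < 1 || cols < 1) stop("rows and cols must be >= 1")
  if (spacing <= 0) stop("spacing must be positive")
  nn <- sqrt(sum(normal^2))
  if (nn == 0) stop("normal must be a non-zero vector")
  normal <- normal / nn
  a <- if (abs(normal[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- cross3(normal, a); u <- u / sqrt(sum(u^2))
  v <- cross3(normal, u)
  ri <- (seq_len(rows) - (rows + 1) / 2) * spacing
  ci <- (seq_len(cols) - (cols + 1) / 2) * spacing
  g <- expand.grid(row = seq_len(rows), col = seq_len(cols))
  pos <- matrix(rep(origin, each = nrow(g)), ncol = 3L) +
    outer(ri[g$row], u) + outer(ci[g$col], v)
  structure(list(positions = pos, normal = normal, rows = as.integer(rows),
                 cols = as.integer(cols), spacing = spacing, grid = g),
            class = "detector_array")
}

#' @export
print.detector_array <- function(x, ...) {
  cat("detector_array:", x$rows, "x", x$cols, "grid, spacing", x$spacing, "mm\n")
  invisible(x)
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Select mesh nodes within a Euclidean radius of a centre node
#'
#' Region query used for infarct placement and for the region-of-spread
#' statistic: all vertices within `radius_cm` (Euclidean, 3-D) of the centre
#' vertex, plus the subset of members that have at least one mesh neighbour
#' outside the region (the border).
#'
#' @param mesh a [trimesh()].
#' @param center_node vertex index.
#' @param radius_cm region radius in cm (vertices are in mm).
#' @return A list of class `region_spec` with `center_node`, `radius_cm`,
#'   `member_nodes`, `border_nodes`.
#' @export
nodes_within_radius <- function(mesh, center_node, radius_cm) {
  stopifnot(inherits(mesh, "trimesh"))
  n <- nrow(mesh$vertices)
  if (length(center_node) != 1L || center_node < 1 || center_node > n) {
    stop("center_node index out of range")
  }
  if (radius_cm < 0) stop("radius_cm must be >= 0")
  d <- sqrt(colSums((t(mesh$vertices) - mesh$vertices[center_node, ])^2))
  member <- which(d <= radius_cm * 10 + 1e-12)
  border <- member[vapply(member, function(i) {
    any(!(mesh$adjacency[[i]] %in% member))
  }, logical(1L))]
  structure(list(center_node = as.integer(center_node), radius_cm = radius_cm,
                 member_nodes = as.integer(member),
                 border_nodes = as.integer(border)),
            class = "region_spec")
}

#' Synthetic torso dimensions
#'
#' Elliptic-cylinder stand-in for the thorax: cross-section semi-axes in x
#' (left-right) and z (antero-posterior), extent along y (cranio-caudal).
#' The anterior surface touches the detector plane z = 0; the cylinder axis
#' runs along y through (0, 0, -half_depth).
#'
#' @param half_width,half_depth cross-section semi-axes, mm.
#' @param height cranio-caudal extent, mm.
#' @export
torso_params <- function(half_width = 150, half_depth = 120, height = 500) {
  if (half_width <= 0 || half_depth <= 0 || height <= 0) {
    stop("torso dimensions must be positive")
  }
  list(half_width = half_width, half_depth = half_depth, height = height)
}

# fixed fractional electrode placement: azimuth (deg from anterior +z
# direction towards the left, i.e. +x) and height fraction of the torso
.electrode_fractions <- data.frame(
  label = c("V1", "V2", "V3", "V4", "V5", "V6", "I", "II"),
  psi_deg = c(-15, -5, 5, 15, 30, 45, 75, 20),
  y_frac = c(0.05, 0.05, 0.02, 0, 0, 0, 0.10, -0.35),
  stringsAsFactors = FALSE
)

#' Place the eight ECG sensing sites on the synthetic torso
#'
#' Positions V1-V6 and the lead I / lead II derivation sites at fixed
#' fractional coordinates (azimuth from the anterior midline, height fraction)
#' on the elliptic-cylinder torso surface. Placement is linear in the torso
#' dimensions, so scaling the torso scales the electrode positions.
#'
#' @param torso a [torso_params()] list.
#' @return Object of class `electrode_set`: `names` (8 labels), `positions`
#'   (8 x 3 matrix, mm).
#' @export
place_precordial_electrodes <- function(torso = torso_params()) {
  psi <- .electrode_fractions$psi_deg * pi / 180
  pos <- cbind(torso$half_width * sin(psi),
               torso$height * .electrode_fractions$y_frac,
               torso$half_depth * (cos(psi) - 1))
  rownames(pos) <- .electrode_fractions$label
  structure(list(names = .electrode_fractions$label, positions = pos,
                 torso = torso),
            class = "electrode_set")
}

#' @export
print.electrode_set <- function(x, ...) {
  cat("electrode_set:", paste(x$names, collapse = " "), "\n")
  invisible(x)
}

#' Default reference node of a heart mesh
#'
#' The vertex closest to the detector plane (largest z), used as the default
#' infarct centre and calibration site.
#'
#' @param mesh a [trimesh()].
#' @export
default_reference_node <- function(mesh) {
  stopifnot(inherits(mesh, "trimesh"))
  which.max(mesh$vertices[, 3L])
}

# run code under a temporary RNG state, restoring the caller's stream
with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
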