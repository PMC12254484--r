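#' Write a mesh in OFF format
#'
#' Plain-text OFF (Object File Format): header line `OFF`, a counts line
#' `n_vertices n_faces 0`, the vertex coordinates and the faces as
#' `3 i j k` with 0-based indices. Vertex order is preserved round-trip.
#'
#' @param mesh a [trimesh()].
#' @param path output file.
#' @export
write_mesh_off <- function(mesh, path) {
  stopifnot(inherits(mesh, "trimesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$faces)), con)
  writeLines(apply(mesh$vertices, 1L, function(v) {
    paste(format(v, digits = 17, scientific = FALSE, trim = TRUE), collapse = " ")
  }), con)
  writeLines(apply(mesh$faces - 1L, 1L, function(f) {
    paste(c(3L, f), collapse = " ")
  }), con)
  invisible(path)
}

#' Read a mesh in OFF format
#'
#' @param path OFF file written by [write_mesh_off()] or any triangles-only
#'   ASCII OFF file.
#' @return A [trimesh()].
#' @export
read_mesh_off <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!grepl("^OFF", lines[1L])) stop("not an OFF file: ", path)
  counts <- scan(text = lines[2L], what = integer(), quiet = TRUE)
  nv <- counts[1L]; nf <- counts[2L]
  verts <- matrix(scan(text = paste(lines[3:(2 + nv)], collapse = "\n"),
                       what = double(), quiet = TRUE), ncol = 3L, byrow = TRUE)
  fl <- lapply(lines[(3 + nv):(2 + nv + nf)], function(l) {
    v <- scan(text = l, what = integer(), quiet = TRUE)
    if (v[1L] != 3L) stop("only triangular faces are supported")
    v[2:4] + 1L
  })
  trimesh(verts, do.call(rbind, fl))
}

#' Write labelled 3-D positions as delimited text
#'
#' Comma-separated `label,x,y,z` table (mm) with a header line, used for
#' detector and electrode sets.
#'
#' @param labels character vector.
#' @param positions matrix with one row per label, columns x, y, z in mm.
#' @param path output file.
#' @export
write_positions_csv <- function(labels, positions, path) {
  stopifnot(length(labels) == nrow(positions))
  df <- data.frame(label = labels, x = positions[, 1L], y = positions[, 2L],
                   z = positions[, 3L])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read labelled 3-D positions from delimited text
#'
#' @param path file written by [write_positions_csv()].
#' @return List with `labels` and `positions` (matrix, mm).
#' @export
read_positions_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("label", "x", "y", "z") %in% names(df))) {
    stop("expected header label,x,y,z in ", path)
  }
  list(labels = as.character(df$label),
       positions = as.matrix(df[, c("x", "y", "z")]))
}

#' Write a channels-by-time signal matrix as delimited text
#'
#' Rows are channels/nodes, columns time samples. A sidecar `<path>.meta`
#' file records the metadata fields as `key: value` lines.
#'
#' @param values numeric matrix.
#' @param path output file (CSV, no header).
#' @param meta named list of scalar metadata written to the sidecar.
#' @export
write_signal_csv <- function(values, path, meta = list()) {
  utils::write.table(values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  if (length(meta)) {
    writeLines(sprintf("%s: %s", names(meta),
                       vapply(meta, function(x) paste(x, collapse = " "),
                              character(1L))),
               paste0(path, ".meta"))
  }
  invisible(path)
}

#' Read a channels-by-time signal matrix written by [write_signal_csv()]
#'
#' @param path CSV file.
#' @return Numeric matrix.
#' @export
read_signal_csv <- function(path) {
  as.matrix(utils::read.table(path, sep = ",", header = FALSE))
}
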