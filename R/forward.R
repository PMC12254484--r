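#' Forward-model configuration
#'
#' @param mu0_over_4pi magnetic constant over 4 pi, T m / A.
#' @param dipole_strength unit dipole strength P0 used per unit (mV) source,
#'   A m.
#' @param sensing_mode `"normal_component"` (field projected onto the
#'   detector-plane normal, one row per sensor) or `"full_vector"` (three
#'   stacked rows per sensor).
#' @export
forward_config <- function(mu0_over_4pi = 1e-7, dipole_strength = 1,
                           sensing_mode = c("normal_component",
                                            "full_vector")) {
  if (dipole_strength <= 0) stop("dipole_strength must be positive")
  list(mu0_over_4pi = mu0_over_4pi, dipole_strength = dipole_strength,
       sensing_mode = match.arg(sensing_mode))
}

#' Magnetic field of a current dipole (primary-current Biot-Savart kernel)
#'
#' `B = (mu0 / 4 pi) m x (r_s - r_q) / ||r_s - r_q||^3`, the primary-current
#' term only (no volume currents). All positions in metres, moment in A m.
#'
#' @param source_pos,sensor_pos 3-vectors, m.
#' @param moment dipole moment, A m.
#' @param mu0_over_4pi constant, T m / A.
#' @return Field 3-vector, T.
#' @export
dipole_field_kernel <- function(source_pos, moment, sensor_pos,
                                mu0_over_4pi = 1e-7) {
  d <- sensor_pos - source_pos
  r3 <- sum(d^2)^1.5
  if (r3 < 1e-30) stop("sensor coincides with the source position")
  mu0_over_4pi * cross3(moment, d) / r3
}

#' Geometry kernel mapping dipole moments to sensed field values
#'
#' Precomputes, for every (sensor m, source q) pair, the 3-vector `C[m,q,]`
#' such that the sensed (normal-component) field of a dipole with moment `p`
#' at source q is `C[m,q,] . p`. Positions are taken in mm and converted to
#' SI metres internally. All lead fields in the package are contractions of
#' this kernel with an orientation vector.
#'
#' @param source_positions_mm Q x 3 matrix or a [trimesh()] (its vertices).
#' @param detectors a [build_detector_grid()] array.
#' @param cfg a [forward_config()].
#' @return Object of class `forward_kernel`: `C` (M x Q x 3 array, T per
#'   A m), `source_positions_mm`, `detectors`, `cfg`.
#' @export
forward_kernel <- function(source_positions_mm, detectors,
                           cfg = forward_config()) {
  if (inherits(source_positions_mm, "trimesh")) {
    source_positions_mm <- source_positions_mm$vertices
  }
  stopifnot(inherits(detectors, "detector_array"))
  rq <- as.matrix(source_positions_mm) * 1e-3
  rm_ <- detectors$positions * 1e-3
  m <- nrow(rm_); q <- nrow(rq)
  nrm <- detectors$normal
  k <- cfg$mu0_over_4pi * cfg$dipole_strength
  if (cfg$sensing_mode == "normal_component") {
    C <- array(0, dim = c(m, q, 3L))
    for (i in seq_len(m)) {
      d <- sweep(-rq, 2L, rm_[i, ], `+`)          # r_m - r_q
      r3 <- rowSums(d^2)^1.5
      if (any(r3 < 1e-30)) stop("a source coincides with sensor ", i)
      # n . (p x d) = p . (d x n)
      C[i, , 1L] <- k * (d[, 2L] * nrm[3L] - d[, 3L] * nrm[2L]) / r3
      C[i, , 2L] <- k * (d[, 3L] * nrm[1L] - d[, 1L] * nrm[3L]) / r3
      C[i, , 3L] <- k * (d[, 1L] * nrm[2L] - d[, 2L] * nrm[1L]) / r3
    }
  } else {
    # full_vector: 3 stacked rows (Bx, By, Bz) per sensor
    C <- array(0, dim = c(3L * m, q, 3L))
    for (i in seq_len(m)) {
      d <- sweep(-rq, 2L, rm_[i, ], `+`)
      r3 <- rowSums(d^2)^1.5
      if (any(r3 < 1e-30)) stop("a source coincides with sensor ", i)
      rows <- 3L * (i - 1L) + 1:3
      # B = k p x d / r3, written as coefficients on p
      C[rows[1L], , 2L] <- k * d[, 3L] / r3
      C[rows[1L], , 3L] <- -k * d[, 2L] / r3
      C[rows[2L], , 1L] <- -k * d[, 3L] / r3
      C[rows[2L], , 3L] <- k * d[, 1L] / r3
      C[rows[3L], , 1L] <- k * d[, 2L] / r3
      C[rows[3L], , 2L] <- -k * d[, 1L] / r3
    }
  }
  structure(list(C = C, source_positions_mm = as.matrix(source_positions_mm),
                 detectors = detectors, cfg = cfg),
            class = "forward_kernel")
}

# contract the kernel with per-source orientations (3-vector or Q x 3)
kernel_contract <- function(kernel, orientations) {
  C <- kernel$C
  if (is.null(dim(orientations))) {
    C[, , 1L] * orientations[1L] + C[, , 2L] * orientations[2L] +
      C[, , 3L] * orientations[3L]
  } else {
    sweep(C[, , 1L], 2L, orientations[, 1L], `*`) +
      sweep(C[, , 2L], 2L, orientations[, 2L], `*`) +
      sweep(C[, , 3L], 2L, orientations[, 3L], `*`)
  }
}

new_lead_field <- function(matrix, orientations, provenance,
                           time_index = NULL) {
  structure(list(matrix = matrix, orientations = orientations,
                 provenance = provenance, time_index = time_index),
            class = "lead_field")
}

#' @export
print.lead_field <- function(x, ...) {
  cat("lead_field (", x$provenance, "): ", nrow(x$matrix), " x ",
      ncol(x$matrix), "\n", sep = "")
  invisible(x)
}

#' Conventional radial-orientation lead field
#'
#' Each source carries a unit dipole of strength P0 oriented along the radial
#' unit vector from the heart-mesh centroid through the node; column q of the
#' lead field is the sensed field of that dipole at every detector.
#'
#' @param source_positions_mm Q x 3 matrix, a [trimesh()], or a
#'   [forward_kernel()] (reused directly).
#' @param detectors a [build_detector_grid()] array (ignored when a kernel is
#'   supplied).
#' @param cfg a [forward_config()].
#' @return A `lead_field` object (`matrix` is M x Q; `provenance` "radial").
#' @export
lead_field_radial <- function(source_positions_mm, detectors = NULL,
                              cfg = forward_config()) {
  kernel <- if (inherits(source_positions_mm, "forward_kernel")) {
    source_positions_mm
  } else {
    forward_kernel(source_positions_mm, detectors, cfg)
  }
  pos <- kernel$source_positions_mm
  ctr <- colMeans(pos)
  orient <- sweep(pos, 2L, ctr)
  nn <- sqrt(rowSums(orient^2))
  bad <- which(nn < 1e-9)
  if (length(bad)) {
    stop("radial orientation undefined: node(s) ",
         paste(bad, collapse = ", "), " coincide with the mesh centroid")
  }
  orient <- orient / nn
  new_lead_field(kernel_contract(kernel, orient), orient, "radial")
}

#' VCG-constrained lead field for one time instant
#'
#' As [lead_field_radial()], but every source dipole carries the same unit
#' orientation `orient` (the unit VCG vector of the instant).
#'
#' @param source_positions_mm Q x 3 matrix, [trimesh()] or [forward_kernel()].
#' @param detectors detector array (ignored when a kernel is supplied).
#' @param orient unit 3-vector.
#' @param cfg a [forward_config()].
#' @param time_index optional sample index recorded on the result.
#' @return A `lead_field` (`provenance` "uVCG").
#' @export
lead_field_uvcg <- function(source_positions_mm, detectors = NULL, orient,
                            cfg = forward_config(), time_index = NULL) {
  if (abs(sqrt(sum(orient^2)) - 1) > 1e-6) {
    stop("orient must be a unit vector")
  }
  kernel <- if (inherits(source_positions_mm, "forward_kernel")) {
    source_positions_mm
  } else {
    forward_kernel(source_positions_mm, detectors, cfg)
  }
  q <- nrow(kernel$source_positions_mm)
  new_lead_field(kernel_contract(kernel, orient),
                 matrix(orient, q, 3L, byrow = TRUE), "uVCG", time_index)
}

#' Time-varying lead-field sequence from an orientation series
#'
#' Compact representation of the per-instant VCG-constrained lead fields:
#' the geometry kernel plus the orientation series, contracted on demand.
#'
#' @param kernel a [forward_kernel()].
#' @param orientations an [unit_vcg_series()] result or 3 x T matrix of unit
#'   columns.
#' @return Object of class `dynamic_lead_field`.
#' @export
dynamic_lead_field <- function(kernel, orientations) {
  stopifnot(inherits(kernel, "forward_kernel"))
  v <- if (inherits(orientations, "orientation_series")) {
    orientations$vectors
  } else {
    as.matrix(orientations)
  }
  if (nrow(v) != 3L) stop("orientations must be 3 x T")
  structure(list(kernel = kernel, orientations = v),
            class = "dynamic_lead_field")
}

#' Lead-field matrix of a dynamic lead field at one instant
#'
#' @param dlf a [dynamic_lead_field()].
#' @param t sample index.
#' @return M x Q matrix.
#' @export
lead_field_at <- function(dlf, t) {
  stopifnot(inherits(dlf, "dynamic_lead_field"))
  if (t < 1L || t > ncol(dlf$orientations)) stop("time index out of range")
  kernel_contract(dlf$kernel, dlf$orientations[, t])
}

#' Synthesize MCG observations from epicardial sources
#'
#' `B(:, t) = L(t) s(:, t)` with a static [lead_field_radial()] /
#' [lead_field_uvcg()] matrix or a [dynamic_lead_field()] sequence. Linear in
#' the sources.
#'
#' @param leadfield a `lead_field`, a plain M x Q matrix, or a
#'   `dynamic_lead_field`.
#' @param sources an `epicardial_sources` object or Q x T matrix (mV).
#' @return Object of class `mcg_recording`: `values` (M x T), `snr_db`
#'   (`NA` until noise is added), `seed`.
#' @export
synthesize_mcg <- function(leadfield, sources) {
  s <- if (inherits(sources, "epicardial_sources")) sources$values else
    as.matrix(sources)
  if (inherits(leadfield, "dynamic_lead_field")) {
    if (ncol(dlf_or <- leadfield$orientations) < ncol(s)) {
      stop("orientation series shorter than the source duration")
    }
    m <- dim(leadfield$kernel$C)[1L]
    q <- dim(leadfield$kernel$C)[2L]
    if (nrow(s) != q) stop("source count does not match the kernel")
    C <- leadfield$kernel$C
    # B[,t] = sum_k (C_k s_t) e_k(t): precompute the three M x T products
    p1 <- C[, , 1L] %*% s; p2 <- C[, , 2L] %*% s; p3 <- C[, , 3L] %*% s
    tt <- seq_len(ncol(s))
    b <- p1 * rep(dlf_or[1L, tt], each = m) +
      p2 * rep(dlf_or[2L, tt], each = m) +
      p3 * rep(dlf_or[3L, tt], each = m)
  } else {
    L <- if (inherits(leadfield, "lead_field")) leadfield$matrix else
      as.matrix(leadfield)
    if (ncol(L) != nrow(s)) {
      stop("lead field has ", ncol(L), " columns but sources have ",
           nrow(s), " nodes")
    }
    b <- L %*% s
  }
  structure(list(values = b, snr_db = NA_real_, seed = NA_integer_),
            class = "mcg_recording")
}

#' @export
print.mcg_recording <- function(x, ...) {
  cat("mcg_recording:", nrow(x$values), "sensors x", ncol(x$values),
      "samples", if (!is.na(x$snr_db)) paste0("(SNR ", x$snr_db, " dB)"),
      "\n")
  invisible(x)
}
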