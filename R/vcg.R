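#' Inverse Dower transform matrix
#'
#' The published 3 x 8 inverse Dower coefficient matrix converting the eight
#' leads V1-V6, I, II to the orthogonal vectorcardiogram components
#' (x, y, z). These are the least-squares inverse coefficients of the Dower
#' lead matrix (Edenbrandt & Pahlm, J Electrocardiol 1988). Any alternative
#' 3 x 8 matrix with the same lead order can be supplied to
#' [inverse_dower()] instead.
#'
#' @return 3 x 8 numeric matrix with rownames x, y, z and colnames
#'   V1..V6, I, II.
#' @export
dower_inverse_matrix <- function() {
  m <- rbind(
    x = c(-0.172, -0.074,  0.122,  0.231,  0.239,  0.194,  0.156, -0.010),
    y = c( 0.057, -0.019, -0.106, -0.022,  0.041,  0.048, -0.227,  0.887),
    z = c(-0.229, -0.310, -0.246, -0.063,  0.055,  0.108,  0.022,  0.102))
  colnames(m) <- c("V1", "V2", "V3", "V4", "V5", "V6", "I", "II")
  m
}

#' Derive the 3-lead VCG from an 8-lead ECG
#'
#' Applies a 3 x 8 transform (by default the inverse Dower matrix) sample by
#' sample: `VCG(t) = T ECG(t)`. Exactly linear in the ECG.
#'
#' @param ecg 8 x T numeric matrix, rows ordered as the transform's columns
#'   (V1..V6, I, II for the default transform).
#' @param transform 3 x 8 coefficient matrix.
#' @param sample_period_ms sampling period carried through to the output.
#' @return Object of class `vcg_signal` with `vectors` (3 x T matrix, rows
#'   x/y/z) and `sample_period_ms`.
#' @export
inverse_dower <- function(ecg, transform = dower_inverse_matrix(),
                          sample_period_ms = 1) {
  ecg <- as.matrix(ecg)
  if (nrow(ecg) != 8L) stop("ecg must have exactly 8 rows (leads)")
  if (!all(dim(transform) == c(3L, 8L))) stop("transform must be 3 x 8")
  v <- transform %*% ecg
  rownames(v) <- c("x", "y", "z")
  structure(list(vectors = v, sample_period_ms = sample_period_ms),
            class = "vcg_signal")
}

#' @export
print.vcg_signal <- function(x, ...) {
  cat("vcg_signal:", ncol(x$vectors), "samples\n")
  invisible(x)
}

#' Unit orientation series from a VCG loop
#'
#' Normalises the VCG vector at every instant to unit length. Instants whose
#' magnitude falls below `magnitude_floor` are masked and carry forward the
#' last unmasked orientation (+z if no unmasked instant has occurred yet).
#'
#' @param vcg a [inverse_dower()] result or a 3 x T matrix.
#' @param magnitude_floor smallest usable VCG magnitude, mV.
#' @return Object of class `orientation_series` with `vectors` (3 x T unit
#'   columns) and `mask` (logical, `TRUE` where carried forward).
#' @export
unit_vcg_series <- function(vcg, magnitude_floor = 1e-6) {
  if (magnitude_floor < 0) stop("magnitude_floor must be >= 0")
  v <- if (inherits(vcg, "vcg_signal")) vcg$vectors else as.matrix(vcg)
  if (nrow(v) != 3L) stop("VCG must have 3 rows")
  n <- ncol(v)
  mag <- sqrt(colSums(v^2))
  out <- matrix(0, 3L, n)
  mask <- logical(n)
  last <- c(0, 0, 1)
  for (t in seq_len(n)) {
    if (mag[t] < magnitude_floor || !is.finite(mag[t])) {
      out[, t] <- last
      mask[t] <- TRUE
    } else {
      last <- v[, t] / mag[t]
      out[, t] <- last
    }
  }
  rownames(out) <- c("x", "y", "z")
  structure(list(vectors = out, mask = mask), class = "orientation_series")
}

#' @export
print.orientation_series <- function(x, ...) {
  cat("orientation_series:", ncol(x$vectors), "instants,",
      sum(x$mask), "masked\n")
  invisible(x)
}

#' Orientations at the QRST fiducial instants
#'
#' @param orients an [unit_vcg_series()] result.
#' @param fiducials named list or vector with sample indices `q`, `r`, `s`,
#'   `t` (the `st` entry of a sources object is ignored).
#' @return List with `vectors` (3 x 4 matrix, columns Q, R, S, T) and
#'   `masked` (logical of length 4).
#' @export
fiducial_orientations <- function(orients, fiducials) {
  stopifnot(inherits(orients, "orientation_series"))
  idx <- unlist(fiducials[c("q", "r", "s", "t")])
  n <- ncol(orients$vectors)
  if (any(is.na(idx)) || any(idx < 1L) || any(idx > n)) {
    stop("fiducial index out of range [1, ", n, "]")
  }
  v <- orients$vectors[, idx, drop = FALSE]
  colnames(v) <- c("Q", "R", "S", "T")
  list(vectors = v, masked = orients$mask[idx])
}
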