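#' VCG-prior solver configuration
#'
#' @param alpha_vcg relative precision of the Gaussian orientation prior:
#'   the weight on `||e - e_VCG||^2` in the orientation update, expressed as
#'   a fraction of the mean diagonal of the (scaled) normal-equation matrix
#'   so that its effect is independent of the lead-field magnitude.
#' @param max_outer_iterations cap on the orientation/source alternation.
#' @param orientation_tolerance_deg stop when the orientation moves less
#'   than this angle between outer iterations.
#' @param misfit_tolerance relative data-misfit change for convergence.
#' @export
vcg_prior_config <- function(alpha_vcg = 0.01, max_outer_iterations = 50L,
                             orientation_tolerance_deg = 0.1,
                             misfit_tolerance = 1e-6) {
  if (alpha_vcg <= 0 || max_outer_iterations < 1 ||
      orientation_tolerance_deg <= 0 || misfit_tolerance <= 0) {
    stop("all VCG prior configuration values must be positive")
  }
  list(alpha_vcg = alpha_vcg,
       max_outer_iterations = as.integer(max_outer_iterations),
       orientation_tolerance_deg = orientation_tolerance_deg,
       misfit_tolerance = misfit_tolerance)
}

#' Bayesian reconstruction with a dynamic VCG-constrained lead field
#'
#' For every time instant: (i) build the lead field from the current shared
#' orientation estimate; (ii) solve the inner Bayesian problem (Gaussian
#' evidence approximation or variational-Bayes TV, per `prior_kind`) for the
#' sources; (iii) update the orientation by solving the ridge-regularized
#' linear problem `min_e ||B(:, t) - G(s) e||^2 + alpha_vcg ||e - e_VCG||^2`
#' (the Gaussian orientation prior centred on the unit-VCG vector of the
#' instant), where `G(s)` contracts the geometry kernel with the current
#' source estimate, then renormalizing `e` to unit length. Centring the
#' prior on the VCG orientation matters physically: a planar array sensing
#' the normal field component is blind to the moment component along the
#' plane normal, and the VCG prior supplies exactly that unobservable
#' direction. The alternation stops when the orientation change and the
#' relative misfit change both fall below their tolerances.
#'
#' @param B an `mcg_recording` or M x T matrix of observations.
#' @param kernel a [forward_kernel()] for the source geometry and detectors.
#' @param vcg_init an [unit_vcg_series()] result or 3 x T matrix of unit
#'   initial orientations (typically from the inverse Dower transform of the
#'   measured ECG).
#' @param prior_kind `"gaussian"` (inner Algorithm: evidence approximation)
#'   or `"tv"` (inner Algorithm: variational-Bayes TV).
#' @param D gradient operator (required for `prior_kind = "tv"`).
#' @param cfg a [vcg_prior_config()].
#' @param instants sample indices to solve (default all columns of `B`).
#' @param inner named list of arguments passed to the inner solver.
#' @return `inverse_solution` with `s_hat` (Q x length(instants)),
#'   `orientations_hat` (3 x length(instants)), `instants`, per-instant
#'   `misfit_trace`, `n_outer`, `flagged` (instants where the source
#'   estimate vanished and the prior orientation was kept).
#' @export
solve_bayes_vcg <- function(B, kernel, vcg_init,
                            prior_kind = c("gaussian", "tv"), D = NULL,
                            cfg = vcg_prior_config(), instants = NULL,
                            inner = list()) {
  prior_kind <- match.arg(prior_kind)
  stopifnot(inherits(kernel, "forward_kernel"))
  bmat <- if (inherits(B, "mcg_recording")) B$values else as.matrix(B)
  v0 <- if (inherits(vcg_init, "orientation_series")) vcg_init$vectors else
    as.matrix(vcg_init)
  if (nrow(v0) != 3L) stop("vcg_init must be 3 x T")
  nrm <- sqrt(colSums(v0^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("vcg_init columns must be unit vectors")
  m <- dim(kernel$C)[1L]; q <- dim(kernel$C)[2L]
  if (nrow(bmat) != m) stop("observation rows do not match the kernel")
  if (prior_kind == "tv" && is.null(D)) {
    stop("prior_kind = 'tv' requires a gradient operator D")
  }
  if (is.null(instants)) instants <- seq_len(ncol(bmat))
  if (ncol(v0) < max(instants)) stop("vcg_init shorter than requested instants")

  inner_solve <- function(L, b) {
    if (prior_kind == "gaussian") {
      do.call(solve_bayes_gaussian, c(list(L = L, b = b), inner))
    } else {
      do.call(solve_bayes_tv, c(list(L = L, b = b, D = D), inner))
    }
  }

  s_hat <- matrix(0, q, length(instants))
  e_hat <- matrix(0, 3L, length(instants))
  misfits <- vector("list", length(instants))
  flagged <- logical(length(instants))
  n_outer <- integer(length(instants))

  for (j in seq_along(instants)) {
    t <- instants[j]
    bt <- bmat[, t]
    e <- v0[, t]
    misfit_prev <- Inf
    trace <- numeric(0)
    s <- rep(0, q)
    for (k in seq_len(cfg$max_outer_iterations)) {
      L <- kernel_contract(kernel, e)
      if (max(abs(L)) < 1e-300 || sqrt(sum(bt^2)) < 1e-300) {
        # sensors blind to this orientation (e along the array normal) or
        # no signal at this instant: keep the prior orientation
        flagged[j] <- TRUE
        break
      }
      s <- inner_solve(L, bt)$s_hat
      if (sqrt(sum(s^2)) < 1e-300) {
        flagged[j] <- TRUE
        break
      }
      G <- cbind(kernel$C[, , 1L] %*% s, kernel$C[, , 2L] %*% s,
                 kernel$C[, , 3L] %*% s)
      scale <- max(abs(G))
      e_new <- if (scale > 0) {
        Gs <- G / scale
        GtG <- crossprod(Gs)
        prior_w <- cfg$alpha_vcg * mean(diag(GtG))
        drop(solve(GtG + prior_w * diag(3L),
                   crossprod(Gs, bt / scale) + prior_w * v0[, t]))
      } else {
        e
      }
      en <- sqrt(sum(e_new^2))
      if (en < 1e-300) {
        flagged[j] <- TRUE
        e_new <- e
      } else {
        e_new <- e_new / en
      }
      # the orientation sign is absorbed by the source sign; keep the
      # hemisphere of the initial orientation for identifiability
      if (sum(e_new * v0[, t]) < 0) e_new <- -e_new
      misfit <- sum((bt - kernel_contract(kernel, e_new) %*% s)^2)
      trace <- c(trace, misfit)
      ang <- angle_of_deviation(e, e_new)
      dm <- abs(misfit_prev - misfit) / max(misfit, 1e-30)
      e <- e_new
      misfit_prev <- misfit
      n_outer[j] <- k
      if (ang < cfg$orientation_tolerance_deg && dm < cfg$misfit_tolerance) {
        break
      }
    }
    # final source estimate at the converged orientation
    if (!flagged[j]) {
      Lf <- kernel_contract(kernel, e)
      if (max(abs(Lf)) > 1e-300 && sqrt(sum(bt^2)) > 1e-300) {
        s <- inner_solve(Lf, bt)$s_hat
      }
    }
    s_hat[, j] <- s
    e_hat[, j] <- e
    misfits[[j]] <- trace
  }
  structure(list(s_hat = s_hat, orientations_hat = e_hat,
                 instants = instants, misfit_trace = misfits,
                 n_outer = n_outer, flagged = flagged,
                 converged = all(!flagged), n_iterations = sum(n_outer),
                 prior_kind = prior_kind),
            class = "inverse_solution")
}
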