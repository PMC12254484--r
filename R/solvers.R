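#' Discrete gradient operator of a surface mesh
#'
#' One row per mesh edge: `+1/l` and `-1/l` on the edge's endpoints, with
#' `l` the edge length in cm. `D s` approximates the normal derivative of a
#' nodal field along edges; its L1 norm is the total-variation penalty used
#' by the TV solvers. Edges are ordered deterministically (sorted index
#' pairs).
#'
#' @param mesh a [trimesh()].
#' @return Object of class `gradient_operator`: `D` (sparse E x Q
#'   [Matrix::sparseMatrix()]), `edges` (E x 2), `edge_lengths_cm`.
#' @export
mesh_gradient_operator <- function(mesh) {
  stopifnot(inherits(mesh, "trimesh"))
  e <- mesh_edges(mesh)
  if (nrow(e) < 1L) stop("mesh has no edges")
  len <- sqrt(rowSums((mesh$vertices[e[, 1L], , drop = FALSE] -
                       mesh$vertices[e[, 2L], , drop = FALSE])^2)) / 10
  if (any(len <= 1e-12)) {
    stop("degenerate zero-length edge(s): ",
         paste(which(len <= 1e-12), collapse = ", "))
  }
  ne <- nrow(e)
  D <- Matrix::sparseMatrix(
    i = c(seq_len(ne), seq_len(ne)),
    j = c(e[, 1L], e[, 2L]),
    x = c(1 / len, -1 / len),
    dims = c(ne, nrow(mesh$vertices)))
  structure(list(D = D, edges = e, edge_lengths_cm = len),
            class = "gradient_operator")
}

# accept lead_field objects, gradient_operator objects or plain matrices
as_lead_matrix <- function(L) {
  if (inherits(L, "lead_field")) L$matrix else as.matrix(L)
}

# generalized cross-validation choice of a ridge weight, via the dual
# eigendecomposition (cheap for M << Q); used to seed the Bayesian solvers
# at a noise-adaptive regularization level
gcv_ridge_lambda <- function(L, b, n_grid = 25L) {
  m <- nrow(L)
  scale <- mean(diag(crossprod(L)))
  if (scale <= 0) stop("lead field is identically zero")
  eg <- eigen(tcrossprod(L), symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  bt <- drop(crossprod(eg$vectors, b))
  grid <- scale * 10^seq(-8, 2, length.out = n_grid)
  gcv <- vapply(grid, function(lam) {
    r <- lam / (ev + lam)
    m * sum((r * bt)^2) / sum(r)^2
  }, numeric(1L))
  grid[which.min(gcv)]
}
as_gradient_matrix <- function(D) {
  if (inherits(D, "gradient_operator")) D$D else D
}

#' Tikhonov (L2) regularized solution
#'
#' `s = (L^T L + lambda I)^-1 L^T b`. For underdetermined systems with
#' `lambda > 0` the algebraically identical dual form
#' `L^T (L L^T + lambda I)^-1 b` is used for speed.
#'
#' @param L lead field (M x Q matrix or `lead_field`).
#' @param b observation M-vector.
#' @param lambda regularization weight (>= 0; 0 requires `L^T L` invertible).
#' @return Source Q-vector.
#' @export
solve_tikhonov <- function(L, b, lambda) {
  L <- as_lead_matrix(L)
  b <- as.numeric(b)
  if (lambda < 0) stop("lambda must be >= 0")
  m <- nrow(L); q <- ncol(L)
  if (lambda > 0 && m < q) {
    return(drop(crossprod(L, solve(tcrossprod(L) + lambda * diag(m), b))))
  }
  A <- crossprod(L) + lambda * diag(q)
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) stop("normal equations are singular at lambda = ", lambda)
  drop(backsolve(ch, forwardsolve(t(ch), crossprod(L, b))))
}

#' Deterministic L1 / total-variation solution by IRLS
#'
#' Minimizes `0.5 ||b - L s||^2 + lambda sum_e sqrt((D s)_e^2 + epsilon)` by
#' iteratively reweighted least squares (majorize-minimize on the smoothed
#' absolute value), so the objective is non-increasing across iterations.
#'
#' @param L lead field (M x Q or `lead_field`).
#' @param b observation M-vector.
#' @param lambda TV weight (> 0).
#' @param D gradient operator ([mesh_gradient_operator()] or E x Q matrix).
#' @param tol relative objective-change stopping tolerance.
#' @param max_iter iteration cap.
#' @param epsilon smoothing inside the square root.
#' @return List of class `inverse_solution`: `s_hat`, `converged`,
#'   `n_iterations`, `objective_trace`.
#' @export
solve_l1_tv <- function(L, b, lambda, D, tol = 1e-6, max_iter = 200L,
                        epsilon = 1e-8) {
  L <- as_lead_matrix(L)
  D <- as_gradient_matrix(D)
  b <- as.numeric(b)
  if (lambda <= 0) stop("lambda must be positive")
  q <- ncol(L)
  LtL <- crossprod(L)
  Ltb <- drop(crossprod(L, b))
  objective <- function(s) {
    0.5 * sum((b - L %*% s)^2) +
      lambda * sum(sqrt(as.numeric(D %*% s)^2 + epsilon))
  }
  s <- solve_tikhonov(L, b, lambda)
  trace <- objective(s)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    g <- as.numeric(D %*% s)
    w <- 1 / sqrt(g^2 + epsilon)
    Dw <- Matrix::Diagonal(x = sqrt(w)) %*% D
    A <- LtL + lambda * as.matrix(Matrix::crossprod(Dw))
    s_new <- drop(solve(A, Ltb))
    obj <- objective(s_new)
    trace <- c(trace, obj)
    delta <- abs(trace[it] - obj) / max(abs(obj), 1e-30)
    s <- s_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  structure(list(s_hat = s, converged = converged, n_iterations = it,
                 objective_trace = trace),
            class = "inverse_solution")
}

#' @export
print.inverse_solution <- function(x, ...) {
  cat("inverse_solution:",
      if (is.matrix(x$s_hat)) paste(dim(x$s_hat), collapse = " x ") else
        length(x$s_hat),
      "sources,", x$n_iterations, "iterations,",
      if (isTRUE(x$converged)) "converged" else "not converged", "\n")
  invisible(x)
}

#' Bayesian Gaussian regression with evidence-approximated hyperparameters
#'
#' Gaussian source prior (precision `alpha`) and Gaussian noise model
#' (precision `beta`). Iterates the MAP estimate
#' `s_MP = (L^T L + (alpha/beta) I)^-1 L^T b` with the evidence-maximising
#' updates `alpha = gamma / (2 E_s)`, `beta = (M - gamma) / (2 E_B)` where
#' `gamma = sum_i lambda_i / (lambda_i + alpha)` over the eigenvalues
#' `lambda_i` of `beta L^T L`, `E_s = ||s_MP||^2 / 2`,
#' `E_B = ||b - L s_MP||^2 / 2`, until the relative change of both
#' hyperparameters falls below `tol`. With `max_iter = 0` the
#' hyperparameters stay frozen at their initial values, which reproduces the
#' Tikhonov solution with `lambda = alpha/beta` exactly.
#'
#' @param L lead field (M x Q or `lead_field`).
#' @param b observation M-vector.
#' @param init_alpha,init_beta positive initial precisions; `NULL` (the
#'   default) initializes from the data scale: a pilot ridge solution at
#'   `lambda0 = 1e-2 mean(diag(L^T L))` sets `beta0 = M / ||b - L s0||^2`
#'   and `alpha0 = lambda0 beta0`.
#' @param tol relative hyperparameter-change stopping tolerance.
#' @param max_iter hyperparameter update cap.
#' @param hyper_cap ceiling on the growth of each precision relative to its
#'   initial value, applied when an energy underflows (exact data).
#' @return `inverse_solution` with `s_hat`, `converged`, `n_iterations`, and
#'   `state` (`alpha`, `beta`, `gamma`, `eigvals`, `trace` of
#'   (alpha, beta, E_s, E_B) per iteration).
#' @export
solve_bayes_gaussian <- function(L, b, init_alpha = NULL, init_beta = NULL,
                                 tol = 1e-6, max_iter = 200L,
                                 hyper_cap = 1e12) {
  L <- as_lead_matrix(L)
  b <- as.numeric(b)
  m <- nrow(L); q <- ncol(L)
  if (is.null(init_alpha) != is.null(init_beta)) {
    stop("supply both initial hyperparameters or neither")
  }
  if (is.null(init_alpha)) {
    lam0 <- gcv_ridge_lambda(L, b)
    s0 <- solve_tikhonov(L, b, lam0)
    e_b0 <- 0.5 * sum((b - L %*% s0)^2)
    init_beta <- if (e_b0 > 1e-300) m / (2 * e_b0) else hyper_cap
    init_alpha <- lam0 * init_beta
  }
  if (init_alpha <= 0 || init_beta <= 0) {
    stop("initial hyperparameters must be positive")
  }
  # nonzero eigenvalues of L^T L equal those of L L^T; zeros add 0 to gamma
  ev <- if (m <= q) {
    eigen(tcrossprod(L), symmetric = TRUE, only.values = TRUE)$values
  } else {
    eigen(crossprod(L), symmetric = TRUE, only.values = TRUE)$values
  }
  ev <- pmax(ev, 0)
  alpha <- init_alpha; beta <- init_beta
  alpha_cap <- hyper_cap * init_alpha
  beta_cap <- hyper_cap * init_beta
  # numerical floor on the effective regularization so the MAP solve stays
  # well-posed when beta runs to its ceiling on (near-)exact data
  lam_floor <- 1e-12 * mean(diag(crossprod(L)))
  map_est <- function(lam) solve_tikhonov(L, b, max(lam, lam_floor))
  s <- map_est(alpha / beta)
  trace <- NULL
  converged <- max_iter == 0L
  it <- 0L
  gamma <- NA_real_
  capped <- FALSE
  if (max_iter > 0L) {
    for (it in seq_len(max_iter)) {
      lam_i <- beta * ev
      gamma <- sum(lam_i / (lam_i + alpha))
      e_s <- 0.5 * sum(s^2)
      e_b <- 0.5 * sum((b - L %*% s)^2)
      alpha_new <- if (e_s > 1e-300) gamma / (2 * e_s) else alpha_cap
      beta_new <- if (e_b > 1e-300) max(m - gamma, 1e-12) / (2 * e_b) else
        beta_cap
      if (alpha_new > alpha_cap) { alpha_new <- alpha_cap; capped <- TRUE }
      if (beta_new > beta_cap) { beta_new <- beta_cap; capped <- TRUE }
      trace <- rbind(trace, c(alpha = alpha_new, beta = beta_new,
                              E_s = e_s, E_B = e_b))
      delta <- max(abs(alpha_new - alpha) / alpha,
                   abs(beta_new - beta) / beta)
      alpha <- alpha_new; beta <- beta_new
      s <- map_est(alpha / beta)
      if (delta < tol) {
        converged <- TRUE
        break
      }
    }
    if (capped) {
      warning("hyperparameter capped at ceiling (near-exact data)")
    }
  }
  state <- list(alpha = alpha, beta = beta, gamma = gamma, eigvals = ev,
                trace = trace, capped = capped)
  structure(list(s_hat = s, converged = converged, n_iterations = it,
                 state = state),
            class = "inverse_solution")
}

#' Hierarchical variational-Bayes solution with a total-variation prior
#'
#' TV prior on the mesh gradient with auxiliary variables `v` (one per
#' edge), Gamma hyperpriors on the source precision `alpha` and noise
#' precision `beta`. Coordinate ascent on the variational point-estimate
#' objective:
#' \enumerate{
#'   \item `s = (beta L^T L + alpha D^T W(v) D)^-1 beta L^T b`,
#'     `W(v) = diag(1/sqrt(v))`;
#'   \item `v_e = (D s)_e^2`, floored at `v_floor`;
#'   \item `alpha = (E/2 + a_alpha0) / (sum_e ((D s)_e^2 + v_e) /
#'     (2 sqrt(v_e)) + b_alpha0)`;
#'   \item `beta = (M/2 + a_beta0) / (||b - L s||^2 / 2 + b_beta0)`.
#' }
#' Each step maximizes the objective in one block, so the recorded bound
#' trace is non-decreasing. An optional covariance-trace term in the
#' `v`-update (`use_cov_trace = TRUE`) adds `diag(D Cov(s) D^T)`; it is off
#' by default.
#'
#' @param L lead field (M x Q or `lead_field`).
#' @param b observation M-vector.
#' @param D gradient operator.
#' @param hyperprior list with `a_alpha0`, `b_alpha0`, `a_beta0`, `b_beta0`
#'   (all >= 0; zeros give the flat hyperprior), or `NULL` (the default) for
#'   an empirical-Bayes anchor: `a_alpha0 = E/2` and
#'   `b_alpha0 = a_alpha0 / alpha0` with `alpha0` the TV precision matched
#'   to the GCV pilot (`alpha0 = beta0 lambda_GCV ||s0||^2 / TV(s0)`), and a
#'   flat hyperprior on `beta`. The anchor lets `alpha` adapt by the data
#'   while bounding it away from the degenerate flat solution
#'   (`TV(s) -> 0`, `alpha -> Inf`), which is an attractor of the fully
#'   flat hierarchy on strongly underdetermined problems.
#' @param tol relative change of `s` for convergence.
#' @param max_iter iteration cap.
#' @param v_floor positive floor on the auxiliary variables.
#' @param use_cov_trace include the posterior-covariance trace term in the
#'   `v`-update.
#' @return `inverse_solution` with `s_hat`, `state` (`v`, `alpha_hat`,
#'   `beta_hat`, `bound_trace`), `converged`, `n_iterations`.
#' @export
solve_bayes_tv <- function(L, b, D, hyperprior = NULL,
                           tol = 1e-6, max_iter = 200L, v_floor = 1e-8,
                           use_cov_trace = FALSE) {
  L <- as_lead_matrix(L)
  D <- as_gradient_matrix(D)
  b <- as.numeric(b)
  if (v_floor <= 0) stop("v_floor must be positive")
  m <- nrow(L); q <- ncol(L); ne <- nrow(D)
  LtL <- crossprod(L)
  Ltb <- drop(crossprod(L, b))
  bound <- function(s, v, alpha, beta) {
    g <- as.numeric(D %*% s)
    (ne / 2 + hp$a_alpha0) * log(alpha) -
      alpha * (0.5 * sum((g^2 + v) / sqrt(v)) + hp$b_alpha0) +
      (m / 2 + hp$a_beta0) * log(beta) -
      beta * (0.5 * sum((b - L %*% s)^2) + hp$b_beta0)
  }
  # noise-adaptive start: a GCV-selected ridge pilot seeds v, alpha and
  # beta so the first coordinate-ascent step operates at the data's
  # magnitude and regularization level
  lam0 <- gcv_ridge_lambda(L, b)
  s <- solve_tikhonov(L, b, lam0)
  g0 <- as.numeric(D %*% s)
  v <- pmax(g0^2, v_floor)
  resid0 <- 0.5 * sum((b - L %*% s)^2)
  beta0 <- if (resid0 > 1e-300) m / (2 * resid0) else 1
  if (is.null(hyperprior)) {
    tv0 <- sum(abs(g0))
    alpha0 <- if (tv0 > 1e-300) beta0 * lam0 * sum(s^2) / tv0 else 1
    hp <- list(a_alpha0 = ne / 2, b_alpha0 = (ne / 2) / alpha0,
               a_beta0 = 0, b_beta0 = 0)
  } else {
    hp <- hyperprior
  }
  if (any(unlist(hp) < 0)) stop("hyperprior parameters must be >= 0")
  alpha <- (ne / 2 + hp$a_alpha0) /
    (0.5 * sum((g0^2 + v) / sqrt(v)) + hp$b_alpha0)
  beta <- (m / 2 + hp$a_beta0) /
    (0.5 * sum((b - L %*% s)^2) + hp$b_beta0)
  if (!is.finite(alpha) || alpha <= 0) alpha <- 1
  if (!is.finite(beta) || beta <= 0) beta <- 1
  alpha_cap <- 1e12 * alpha
  # beta ceiling equals a 1e-12 relative residual floor: beyond it the
  # beta-weighted misfit term is pure rounding noise
  beta_cap <- (m / 2 + hp$a_beta0) /
    (0.5e-12 * sum(b^2) + hp$b_beta0 + 1e-300)
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    w <- 1 / sqrt(v)
    Dw <- Matrix::Diagonal(x = sqrt(w)) %*% D
    A <- beta * LtL + alpha * as.matrix(Matrix::crossprod(Dw))
    # the exact solve preserves coordinate ascent; only a genuinely
    # singular system (e.g. the TV weight vanished on an underdetermined
    # problem) receives an escalating tiny ridge
    s_new <- NULL
    ridge <- 0
    repeat {
      s_new <- tryCatch(drop(solve(A + diag(ridge, nrow(A)), beta * Ltb)),
                        error = function(e) NULL)
      if (!is.null(s_new)) break
      ridge <- max(ridge * 100, 1e-14 * mean(diag(A)))
    }
    g <- as.numeric(D %*% s_new)
    v <- g^2
    if (use_cov_trace) {
      cv <- solve(A)
      v <- v + rowSums(as.matrix(D %*% cv) * as.matrix(D))
    }
    v <- pmax(v, v_floor)
    # caps keep the updates finite on exact (zero-residual) data; the
    # capped value still increases the bound, which is monotone in each
    # hyperparameter up to its unconstrained maximizer
    alpha <- min((ne / 2 + hp$a_alpha0) /
                   (0.5 * sum((g^2 + v) / sqrt(v)) + hp$b_alpha0), alpha_cap)
    beta <- min((m / 2 + hp$a_beta0) /
                  (0.5 * sum((b - L %*% s_new)^2) + hp$b_beta0), beta_cap)
    trace <- c(trace, bound(s_new, v, alpha, beta))
    delta <- sqrt(sum((s_new - s)^2)) / max(sqrt(sum(s_new^2)), 1e-30)
    s <- s_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  state <- list(v = v, alpha_hat = alpha, beta_hat = beta,
                hyperprior = hp, bound_trace = trace)
  structure(list(s_hat = s, converged = converged, n_iterations = it,
                 state = state),
            class = "inverse_solution")
}
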