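#' Root-mean-square error between true and estimated epicardial potentials
#'
#' RMSE over all nodes and time instants, in mV (the root is taken so the
#' statistic carries the sources' mV units).
#'
#' @param true_s `epicardial_sources` or Q x T matrix (mV).
#' @param est_s Q x T matrix of the same shape.
#' @return Scalar RMSE, mV.
#' @export
mse_epicardial <- function(true_s, est_s) {
  a <- if (inherits(true_s, "epicardial_sources")) true_s$values else
    as.matrix(true_s)
  b <- if (inherits(est_s, "epicardial_sources")) est_s$values else
    as.matrix(est_s)
  if (!all(dim(a) == dim(b))) {
    stop("shape mismatch: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"))
  }
  sqrt(mean((a - b)^2))
}

#' Angle of deviation between two orientation vectors
#'
#' `theta = arccos(e1 . e2 / (||e1|| ||e2||))` in degrees, in [0, 180].
#' Symmetric and invariant to positive rescaling of either argument.
#'
#' @param e_true,e_est non-zero 3-vectors.
#' @return Angle in degrees.
#' @export
angle_of_deviation <- function(e_true, e_est) {
  n1 <- sqrt(sum(e_true^2)); n2 <- sqrt(sum(e_est^2))
  if (n1 == 0 || n2 == 0) stop("angle undefined for a zero vector")
  c_ <- sum(e_true * e_est) / (n1 * n2)
  acos(min(1, max(-1, c_))) * 180 / pi
}

#' Detect the abnormal region from reconstructed sources
#'
#' Flags the nodes whose deviation energy from the normal reference,
#' `||est(q, ) - normal_ref(q, )||` (root-sum-square over time), exceeds
#' `threshold_fraction` times the maximum per-node deviation.
#'
#' @param est_s Q x T estimated sources.
#' @param normal_ref Q x T normal-case reference (same solver, same
#'   conditions).
#' @param threshold_fraction fraction of the maximum deviation in (0, 1].
#' @return Integer vector of detected node indices (empty, with a warning,
#'   when the deviation is identically zero).
#' @export
detect_abnormal_region <- function(est_s, normal_ref,
                                   threshold_fraction = 0.5) {
  est_s <- as.matrix(est_s); normal_ref <- as.matrix(normal_ref)
  if (!all(dim(est_s) == dim(normal_ref))) stop("shape mismatch")
  if (threshold_fraction <= 0 || threshold_fraction > 1) {
    stop("threshold_fraction must be in (0, 1]")
  }
  dev <- sqrt(rowSums((est_s - normal_ref)^2))
  mx <- max(dev)
  if (mx == 0) {
    warning("deviation is identically zero; returning an empty set")
    return(integer(0))
  }
  which(dev > threshold_fraction * mx)
}

#' Connected component of a node set around a seed node
#'
#' Restricts a detected node set to the nodes reachable from `seed_node`
#' through mesh edges without leaving the set (the component "surrounding"
#' the target). When the seed itself is not in the set, the component grown
#' from the set node nearest to the seed is returned.
#'
#' @param mesh a [trimesh()].
#' @param nodes integer node set.
#' @param seed_node node around which the component is grown.
#' @return Integer subset of `nodes`.
#' @export
connected_component <- function(mesh, nodes, seed_node) {
  stopifnot(inherits(mesh, "trimesh"))
  nodes <- as.integer(nodes)
  if (length(nodes) == 0L) return(nodes)
  inset <- logical(nrow(mesh$vertices))
  inset[nodes] <- TRUE
  start <- if (inset[seed_node]) {
    seed_node
  } else {
    d <- sqrt(colSums((t(mesh$vertices[nodes, , drop = FALSE]) -
                         mesh$vertices[seed_node, ])^2))
    nodes[which.min(d)]
  }
  seen <- logical(nrow(mesh$vertices))
  queue <- as.integer(start)
  seen[start] <- TRUE
  while (length(queue)) {
    cur <- queue[1L]; queue <- queue[-1L]
    nb <- mesh$adjacency[[cur]]
    nb <- nb[inset[nb] & !seen[nb]]
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  sort(which(seen))
}

#' Region of spread of a reconstructed abnormality
#'
#' Border nodes are the abnormal nodes with at least one non-abnormal mesh
#' neighbour; the spread is the RMS distance from the centre node to the
#' border nodes, `ROS = sqrt(sum_i ||R_c - R_i||^2 / n)`, reported in cm.
#' `squared = TRUE` returns the raw mean of squared distances (cm^2)
#' instead.
#'
#' @param mesh a [trimesh()].
#' @param abnormal_nodes non-empty integer set of detected nodes.
#' @param center_node abnormality centre index.
#' @param squared return the mean squared distance instead of its root.
#' @return List of class `spread_result`: `ros_cm`, `center`,
#'   `border_points` (matrix, mm), `border_nodes`, `n`.
#' @export
region_of_spread <- function(mesh, abnormal_nodes, center_node,
                             squared = FALSE) {
  stopifnot(inherits(mesh, "trimesh"))
  abnormal_nodes <- as.integer(abnormal_nodes)
  if (length(abnormal_nodes) == 0L) stop("abnormal node set is empty")
  nv <- nrow(mesh$vertices)
  if (center_node < 1L || center_node > nv) stop("center_node out of range")
  if (any(abnormal_nodes < 1L | abnormal_nodes > nv)) {
    stop("abnormal node index out of range")
  }
  border <- abnormal_nodes[vapply(abnormal_nodes, function(i) {
    any(!(mesh$adjacency[[i]] %in% abnormal_nodes))
  }, logical(1L))]
  if (length(border) == 0L) border <- abnormal_nodes
  pts <- mesh$vertices[border, , drop = FALSE]
  d2_cm <- rowSums(sweep(pts, 2L, mesh$vertices[center_node, ])^2) / 100
  ros <- if (squared) mean(d2_cm) else sqrt(mean(d2_cm))
  structure(list(ros_cm = ros, center = mesh$vertices[center_node, ],
                 border_points = pts, border_nodes = border,
                 n = length(border)),
            class = "spread_result")
}

#' @export
print.spread_result <- function(x, ...) {
  cat("spread_result: ROS =", signif(x$ros_cm, 4), "cm over", x$n,
      "border nodes\n")
  invisible(x)
}
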