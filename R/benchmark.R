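#' Default benchmark configuration
#'
#' Desk-scale version of the full evaluation protocol: Q = 500 heart nodes,
#' one 300-sample beat, the three disease cases, noise-free plus 10/20/50 dB
#' SNR, and a configurable number of noise replicates per cell. All solver
#' iteration caps and tolerances live in the `solvers` block.
#'
#' @param n_nodes heart mesh size.
#' @param n_seeds noise replicates per (case, SNR) cell.
#' @param base_seed seed from which per-cell seeds are derived.
#' @param snr_db SNR levels in dB; `Inf` denotes the noise-free condition.
#' @param cases disease cases to run.
#' @return Nested configuration list of class `run_config`.
#' @export
default_run_config <- function(n_nodes = 500L, n_seeds = 5L, base_seed = 1L,
                               snr_db = c(Inf, 10, 20, 50),
                               cases = c("D1", "D2", "D3")) {
  structure(list(
    geometry = list(
      n_nodes = n_nodes, radii = c(50, 40, 35), center = c(0, 0, -60),
      mesh_seed = 1L,
      detector = list(rows = 9L, cols = 9L, spacing = 30,
                      origin = c(0, 0, 0), normal = c(0, 0, 1)),
      torso = torso_params()),
    simulation = list(
      tmp = tmp_params(), conduction_speed_mm_ms = 0.8, n_samples = 300L,
      sample_period_ms = 1, normal_pp_mv = 8, region_radius_cm = 2.5,
      reference_node = NULL, cases = cases, conductivity_s_m = 0.2),
    noise = list(snr_db = snr_db, n_seeds = n_seeds, base_seed = base_seed),
    solvers = list(
      lambda_grid = 10^seq(-6, 2),
      l1_lambda_grid = 10^seq(-4, 0, by = 1),
      l1_max_iter = 15L, l1_tol = 1e-4,
      evidence = list(tol = 1e-5, max_iter = 50L),
      tv = list(tol = 1e-4, max_iter = 30L),
      vcg = list(alpha_vcg = 0.01, max_outer_iterations = 4L,
                 orientation_tolerance_deg = 0.1, misfit_tolerance = 1e-4),
      detection_threshold = 0.5)),
    class = "run_config")
}

# deterministic per-cell seed below 2^31
cell_seed <- function(base_seed, case, snr_db, rep) {
  ci <- match(case, c("normal", "D1", "D2", "D3"))
  si <- if (is.infinite(snr_db)) 0L else as.integer(snr_db)
  (as.integer(base_seed) + ci * 1000003L + si * 7919L + rep * 104729L) %%
    2147483647L
}

# discrepancy-principle lambda pick for the Tikhonov baseline
pick_lambda_l2 <- function(L, b, grid, target) {
  res <- vapply(grid, function(lam) {
    s <- solve_tikhonov(L, b, lam)
    sum((b - L %*% s)^2)
  }, numeric(1L))
  grid[which.min(abs(res - target))]
}

pick_lambda_l1 <- function(L, b, D, grid, target, max_iter, tol) {
  res <- vapply(grid, function(lam) {
    s <- solve_l1_tv(L, b, lam, D, tol = tol, max_iter = max_iter)$s_hat
    sum((b - L %*% s)^2)
  }, numeric(1L))
  grid[which.min(abs(res - target))]
}

# per-instant reconstruction with one named algorithm; returns Q x K matrix
# (and 3 x K orientations for the VCG solvers)
reconstruct_instants <- function(algorithm, Bmat, ctx) {
  K <- length(ctx$instants)
  est <- matrix(0, ctx$q, K)
  orient <- NULL
  if (algorithm %in% c("Alg3", "Alg4")) {
    kind <- if (algorithm == "Alg3") "gaussian" else "tv"
    inner <- if (kind == "gaussian") ctx$cfg$solvers$evidence else
      c(ctx$cfg$solvers$tv, list(v_floor = 1e-8))
    sol <- solve_bayes_vcg(Bmat, ctx$kernel, ctx$vcg_init,
                           prior_kind = kind, D = ctx$D,
                           cfg = do.call(vcg_prior_config,
                                         ctx$cfg$solvers$vcg),
                           instants = ctx$instants, inner = inner)
    est <- sol$s_hat
    orient <- sol$orientations_hat
  } else {
    for (k in seq_len(K)) {
      b <- Bmat[, ctx$instants[k]]
      est[, k] <- switch(algorithm,
        L2 = solve_tikhonov(ctx$L_rad, b,
                            pick_lambda_l2(ctx$L_rad$matrix, b,
                                           ctx$lambda_grid_scaled,
                                           ctx$res_target)),
        L1 = solve_l1_tv(ctx$L_rad, b, ctx$lambda_l1, ctx$D,
                         tol = ctx$cfg$solvers$l1_tol,
                         max_iter = ctx$cfg$solvers$l1_max_iter)$s_hat,
        Alg1 = do.call(solve_bayes_gaussian,
                       c(list(L = ctx$L_rad, b = b),
                         ctx$cfg$solvers$evidence))$s_hat,
        Alg2 = do.call(solve_bayes_tv,
                       c(list(L = ctx$L_rad, b = b, D = ctx$D),
                         ctx$cfg$solvers$tv))$s_hat,
        stop("unknown algorithm ", algorithm))
    }
  }
  list(est = est, orient = orient)
}

#' Run the end-to-end benchmark protocol
#'
#' For every (case, SNR, replicate) cell: generate the epicardial sources,
#' synthesize MCG through the VCG-constrained dynamic lead field, add noise,
#' reconstruct with the six solvers (Tikhonov L2, IRLS L1/TV, evidence
#' Gaussian, VB-TV, and the two dynamic-lead-field VCG variants), and score
#' epicardial RMSE, the orientation angle of deviation at the Q/R/S/T
#' fiducials (VCG solvers), and the region of spread of the detected
#' abnormality. Reconstruction is performed at the five fiducial instants
#' (Q, R, S, ST, T) of the beat. A solver failure in one cell is recorded
#' and the sweep continues.
#'
#' @param config a [default_run_config()] list.
#' @param out_dir optional directory; when given, writes `results.csv`
#'   (tidy), `table_angles.csv`, `table_ros.csv` and `log.csv`.
#' @return List with `results` (tidy data frame: case, algorithm, snr_db,
#'   seed, metric, value), `table_angles`, `table_ros`, `errors`, `log`.
#' @export
run_benchmark <- function(config = default_run_config(), out_dir = NULL) {
  cfg <- config
  t0 <- proc.time()[["elapsed"]]
  log <- list()
  note <- function(stage, status = "ok") {
    log[[length(log) + 1L]] <<- data.frame(
      stage = stage, elapsed_s = round(proc.time()[["elapsed"]] - t0, 2),
      status = status)
  }

  g <- cfg$geometry
  mesh <- build_heart_surface(g$n_nodes, g$radii, g$center, g$mesh_seed)
  detectors <- do.call(build_detector_grid, g$detector)
  electrodes <- place_precordial_electrodes(g$torso)
  kernel <- forward_kernel(mesh, detectors)
  L_rad <- lead_field_radial(kernel)
  D <- mesh_gradient_operator(mesh)
  note("geometry")

  sim <- cfg$simulation
  ref <- if (is.null(sim$reference_node)) default_reference_node(mesh) else
    sim$reference_node
  region <- nodes_within_radius(mesh, ref, sim$region_radius_cm)
  normal <- build_epicardial_sources(
    mesh, sim$tmp, conduction_speed_mm_ms = sim$conduction_speed_mm_ms,
    n_samples = sim$n_samples, sample_period_ms = sim$sample_period_ms,
    normal_pp_mv = sim$normal_pp_mv, reference_node = ref)
  fid <- normal$fiducials
  instants <- unlist(fid)

  case_data <- list()
  for (cs in c("normal", sim$cases)) {
    src <- if (cs == "normal") normal else
      inject_abnormality(normal, cs, region)
    ecg <- surface_ecg(src, mesh, electrodes, sim$conductivity_s_m)
    orient <- unit_vcg_series(inverse_dower(ecg))
    Bclean <- synthesize_mcg(dynamic_lead_field(kernel, orient), src)$values
    case_data[[cs]] <- list(sources = src, orient = orient, Bclean = Bclean)
  }
  note("simulation")

  algorithms <- c("L2", "L1", "Alg1", "Alg2", "Alg3", "Alg4")
  lam_scale <- mean(diag(crossprod(L_rad$matrix)))
  rows <- list()
  errors <- list()
  K <- length(instants)
  M <- nrow(detectors$positions)

  lambda_l1_cache <- list()
  for (snr in cfg$noise$snr_db) {
    snr_lin <- if (is.infinite(snr)) Inf else 10^(snr / 10)
    for (rep_i in seq_len(cfg$noise$n_seeds)) {
      # normal-reference reconstructions, shared by all cases at this cell
      seed_n <- cell_seed(cfg$noise$base_seed, "normal", snr, rep_i)
      Bn <- if (is.infinite(snr)) case_data$normal$Bclean else
        add_noise(case_data$normal$Bclean, snr, seed_n)
      est_norm <- list()
      for (cs in c("normal", sim$cases)) {
        cd <- case_data[[cs]]
        seed_c <- cell_seed(cfg$noise$base_seed, cs, snr, rep_i)
        Bc <- if (cs == "normal") Bn else if (is.infinite(snr)) cd$Bclean
          else add_noise(cd$Bclean, snr, seed_c)
        p_noise <- if (is.infinite(snr)) 0 else
          mean(Bc^2) / (1 + snr_lin)
        ctx <- list(
          q = nrow(mesh$vertices), kernel = kernel, L_rad = L_rad, D = D,
          instants = instants, cfg = cfg,
          lambda_grid_scaled = cfg$solvers$lambda_grid * lam_scale,
          res_target = M * p_noise,
          vcg_init = cd$orient)
        # the grid scan for the L1 weight is calibrated once per
        # (case, SNR) condition, on the first replicate's R instant
        l1_key <- paste(cs, snr)
        if (is.null(lambda_l1_cache[[l1_key]])) {
          lambda_l1_cache[[l1_key]] <- pick_lambda_l1(
            L_rad$matrix, Bc[, fid$r], D$D,
            cfg$solvers$l1_lambda_grid * lam_scale, M * p_noise,
            cfg$solvers$l1_max_iter, cfg$solvers$l1_tol)
        }
        ctx$lambda_l1 <- lambda_l1_cache[[l1_key]]
        for (alg in algorithms) {
          res <- tryCatch(
            suppressWarnings(reconstruct_instants(alg, Bc, ctx)),
            error = function(e) e)
          if (inherits(res, "error")) {
            errors[[length(errors) + 1L]] <- data.frame(
              case = cs, algorithm = alg, snr_db = snr, seed = rep_i,
              message = conditionMessage(res))
            next
          }
          if (cs == "normal") {
            est_norm[[alg]] <- res$est
            next
          }
          true_sub <- cd$sources$values[, instants]
          add_row <- function(metric, value) {
            rows[[length(rows) + 1L]] <<- data.frame(
              case = cs, algorithm = alg, snr_db = snr, seed = rep_i,
              metric = metric, value = value)
          }
          add_row("mse_mv", sqrt(mean((true_sub - res$est)^2)))
          if (!is.null(est_norm[[alg]])) {
            det <- suppressWarnings(detect_abnormal_region(
              res$est, est_norm[[alg]], cfg$solvers$detection_threshold))
            # the spread statistic counts the abnormal points surrounding
            # the targeted node: keep the connected component at the target
            det <- connected_component(mesh, det, ref)
            if (length(det)) {
              add_row("ros_cm",
                      region_of_spread(mesh, det, ref)$ros_cm)
            }
          }
          if (!is.null(res$orient)) {
            fo_idx <- match(c("q", "r", "s", "t"), names(fid))
            for (nm in c("q", "r", "s", "t")) {
              k <- match(nm, names(fid))
              add_row(paste0("theta_", nm, "_deg"),
                      angle_of_deviation(
                        cd$orient$vectors[, fid[[nm]]],
                        res$orient[, k]))
            }
          }
        }
      }
      note(sprintf("cell snr=%s rep=%d", snr, rep_i))
    }
  }

  results <- if (length(rows)) do.call(rbind, rows) else
    data.frame(case = character(), algorithm = character(),
               snr_db = numeric(), seed = integer(), metric = character(),
               value = numeric())
  errors <- if (length(errors)) do.call(rbind, errors) else NULL

  table_angles <- pivot_angles(results)
  table_ros <- pivot_ros(results)
  log <- do.call(rbind, log)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(results, file.path(out_dir, "results.csv"),
                     row.names = FALSE)
    utils::write.csv(table_angles, file.path(out_dir, "table_angles.csv"),
                     row.names = FALSE)
    utils::write.csv(table_ros, file.path(out_dir, "table_ros.csv"),
                     row.names = FALSE)
    utils::write.csv(log, file.path(out_dir, "log.csv"), row.names = FALSE)
  }
  list(results = results, table_angles = table_angles,
       table_ros = table_ros, errors = errors, log = log,
       mesh = mesh, region = region, reference_node = ref)
}

# Table-1-shaped pivot: median angle by condition x fiducial x case for the
# two VCG solvers
pivot_angles <- function(results) {
  ang <- results[grepl("^theta_", results$metric), ]
  if (!nrow(ang)) return(data.frame())
  ang$fiducial <- toupper(sub("theta_(.)_deg", "\\1", ang$metric))
  stats::aggregate(value ~ snr_db + fiducial + algorithm + case, ang,
                   stats::median)
}

# Table-2-shaped pivot: median ROS by condition x case x algorithm
pivot_ros <- function(results) {
  ros <- results[results$metric == "ros_cm", ]
  if (!nrow(ros)) return(data.frame())
  wide <- stats::aggregate(value ~ snr_db + case + algorithm, ros,
                           stats::median)
  stats::reshape(wide, idvar = c("snr_db", "case"), timevar = "algorithm",
                 direction = "wide")
}

#' Export an MCG field map at one instant as a grid table
#'
#' @param recording an `mcg_recording` (or M x T matrix).
#' @param instant sample index.
#' @param detectors the [build_detector_grid()] array the recording was
#'   sampled on.
#' @return Data frame with `row`, `col`, `x`, `y`, `z` (mm) and `value`.
#' @export
export_field_map <- function(recording, instant, detectors) {
  stopifnot(inherits(detectors, "detector_array"))
  vals <- if (inherits(recording, "mcg_recording")) recording$values else
    as.matrix(recording)
  if (instant < 1L || instant > ncol(vals)) stop("instant out of range")
  data.frame(row = detectors$grid$row, col = detectors$grid$col,
             x = detectors$positions[, 1L], y = detectors$positions[, 2L],
             z = detectors$positions[, 3L], value = vals[, instant])
}
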