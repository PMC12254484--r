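#' Transmembrane potential template parameters
#'
#' Parameters of the piecewise-smooth action-potential template: resting
#' level, depolarisation amplitude, and the durations of the upstroke,
#' plateau and repolarisation phases. `activation_delay_ms` shifts the whole
#' template in time (per-node conduction delay).
#'
#' @param resting_mv resting potential, mV.
#' @param amplitude_mv depolarisation amplitude (peak minus resting), mV.
#' @param upstroke_ms,plateau_ms,repol_ms phase durations, ms (> 0).
#' @param activation_delay_ms onset delay, ms (>= 0).
#' @return List of class `tmp_params`.
#' @export
tmp_params <- function(resting_mv = -80, amplitude_mv = 100, upstroke_ms = 12,
                       plateau_ms = 100, repol_ms = 70,
                       activation_delay_ms = 0) {
  if (amplitude_mv <= 0) stop("amplitude_mv must be positive")
  if (upstroke_ms <= 0 || plateau_ms <= 0 || repol_ms <= 0) {
    stop("phase durations must be positive")
  }
  if (activation_delay_ms < 0) stop("activation_delay_ms must be >= 0")
  structure(list(resting_mv = resting_mv, amplitude_mv = amplitude_mv,
                 upstroke_ms = upstroke_ms, plateau_ms = plateau_ms,
                 repol_ms = repol_ms,
                 activation_delay_ms = activation_delay_ms),
            class = "tmp_params")
}

#' Evaluate the transmembrane potential template
#'
#' Piecewise-smooth action-potential curve: resting level, C1 smoothstep
#' upstroke, flat plateau, raised-cosine repolarisation, resting level. The
#' peak-to-peak excursion equals `amplitude_mv` exactly.
#'
#' @param params a [tmp_params()].
#' @param n_samples number of samples.
#' @param sample_period_ms sampling period, ms.
#' @return Numeric vector of length `n_samples`, mV.
#' @export
tmp_waveform <- function(params, n_samples, sample_period_ms = 1) {
  stopifnot(inherits(params, "tmp_params"))
  total <- params$activation_delay_ms + params$upstroke_ms +
    params$plateau_ms + params$repol_ms
  if (total > n_samples * sample_period_ms) {
    stop("template duration (", total, " ms) exceeds the sampled beat")
  }
  t <- (seq_len(n_samples) - 1L) * sample_period_ms - params$activation_delay_ms
  up <- params$upstroke_ms; pl <- params$plateau_ms; rp <- params$repol_ms
  w <- numeric(n_samples)
  x <- t / up
  seg <- t >= 0 & t < up
  w[seg] <- x[seg]^2 * (3 - 2 * x[seg])            # smoothstep ascent
  w[t >= up & t < up + pl] <- 1
  seg <- t >= up + pl & t < up + pl + rp
  y <- (t[seg] - up - pl) / rp
  w[seg] <- 0.5 * (1 + cos(pi * y))                # raised-cosine descent
  params$resting_mv + params$amplitude_mv * w
}

#' Disease-case descriptor
#'
#' The three simulated myocardial-infarction variants and the transmembrane
#' template modification each one applies:
#' * `D1` (increased R peak): slowed rate of ascent (`slow_upstroke`).
#' * `D2` (ST elevation): template magnitude lowered to 40% of normal with
#'   unchanged duration (`amplitude_40pct`).
#' * `D3` (increased T peak): shortened active duration (`shorten_duration`).
#'
#' @param label one of `"D1"`, `"D2"`, `"D3"`.
#' @return List of class `disease_case` with `label`, `tmp_modification` and
#'   the calibration targets applied at the epicardial level
#'   (`target_metrics`).
#' @export
disease_case <- function(label = c("D1", "D2", "D3")) {
  label <- match.arg(label)
  mod <- switch(label, D1 = "slow_upstroke", D2 = "amplitude_40pct",
                D3 = "shorten_duration")
  targets <- switch(label,
    D1 = list(min_mv = -10, max_mv = 19),
    D2 = list(st_increase_mv = 5, r_unchanged = TRUE),
    D3 = list(t_increase_mv = 6))
  structure(list(label = label, tmp_modification = mod,
                 target_metrics = targets),
            class = "disease_case")
}

#' Apply a disease-case modification to transmembrane template parameters
#'
#' @param params a [tmp_params()].
#' @param case a [disease_case()] or case label.
#' @param upstroke_factor slow-down factor for the D1 ascent.
#' @param duration_factor shortening factor for the D3 plateau/repolarisation.
#' @return Modified [tmp_params()].
#' @export
modify_tmp_params <- function(params, case, upstroke_factor = 2,
                              duration_factor = 0.7) {
  if (is.character(case)) case <- disease_case(case)
  stopifnot(inherits(params, "tmp_params"), inherits(case, "disease_case"))
  switch(case$tmp_modification,
    slow_upstroke = {
      params$upstroke_ms <- params$upstroke_ms * upstroke_factor
      params
    },
    amplitude_40pct = {
      params$amplitude_mv <- params$amplitude_mv * 0.4
      params
    },
    shorten_duration = {
      params$plateau_ms <- params$plateau_ms * duration_factor
      params$repol_ms <- params$repol_ms * duration_factor
      params
    })
}

#' Generate normal epicardial source waveforms on a heart mesh
#'
#' Emulates an ECGSIM-style beat: each node carries the transmembrane
#' template delayed by its conduction time from the activation origin; the
#' epicardial potential at a node is the local template minus the spatial
#' mean template (a surface-source construction), globally scaled so that
#' the reference node's peak-to-peak amplitude equals `normal_pp_mv`.
#'
#' Fiducial sample indices (Q, R, S, ST, T) are taken from template
#' landmarks: activation onset and upstroke completion at the reference node,
#' global depolarisation end, mid-repolarisation, and the ST midpoint.
#'
#' @param mesh a [trimesh()].
#' @param tmp a [tmp_params()] template.
#' @param activation_origin node index where activation starts (default: the
#'   reference node).
#' @param conduction_speed_mm_ms conduction speed, mm/ms (> 0; `Inf` gives
#'   simultaneous activation).
#' @param n_samples,sample_period_ms beat sampling.
#' @param normal_pp_mv calibration target for the reference-node
#'   peak-to-peak amplitude, mV.
#' @param reference_node calibration node (default [default_reference_node()]).
#' @param base_delay_ms quiescent interval before activation onset, ms.
#' @return Object of class `epicardial_sources`: `values` (Q x T, mV),
#'   `sample_period_ms`, `case_label`, `region`, `fiducials` (named list
#'   q, r, s, st, t of sample indices), plus the generator state needed by
#'   [inject_abnormality()].
#' @export
build_epicardial_sources <- function(mesh, tmp = tmp_params(),
                                     activation_origin = NULL,
                                     conduction_speed_mm_ms = 0.8,
                                     n_samples = 300L, sample_period_ms = 1,
                                     normal_pp_mv = 8,
                                     reference_node = NULL,
                                     base_delay_ms = 10) {
  stopifnot(inherits(mesh, "trimesh"), inherits(tmp, "tmp_params"))
  if (conduction_speed_mm_ms <= 0) stop("conduction speed must be positive")
  if (is.null(reference_node)) reference_node <- default_reference_node(mesh)
  if (is.null(activation_origin)) activation_origin <- reference_node
  q_n <- nrow(mesh$vertices)
  d <- sqrt(colSums((t(mesh$vertices) - mesh$vertices[activation_origin, ])^2))
  delays <- if (is.finite(conduction_speed_mm_ms)) {
    d / conduction_speed_mm_ms
  } else {
    rep(0, q_n)
  }

  tmps <- matrix(0, q_n, n_samples)
  for (q in seq_len(q_n)) {
    p <- tmp
    p$activation_delay_ms <- base_delay_ms + delays[q]
    tmps[q, ] <- tmp_waveform(p, n_samples, sample_period_ms)
  }
  mean_tmp <- colMeans(tmps)
  epi <- sweep(tmps, 2L, mean_tmp)
  pp_ref <- max(epi[reference_node, ]) - min(epi[reference_node, ])
  scale <- if (pp_ref > 1e-12) normal_pp_mv / pp_ref else 1
  values <- scale * epi

  per <- sample_period_ms
  d_ref <- delays[reference_node]
  fid <- list(
    q = 1L + round((base_delay_ms + d_ref) / per),
    r = 1L + round((base_delay_ms + d_ref + tmp$upstroke_ms) / per),
    s = 1L + round((base_delay_ms + max(delays) + tmp$upstroke_ms) / per),
    t = 1L + round((base_delay_ms + d_ref + tmp$upstroke_ms + tmp$plateau_ms +
                      tmp$repol_ms / 2) / per))
  fid$s <- max(fid$s, fid$r + 1L)
  fid$t <- max(fid$t, fid$s + 2L)
  fid$st <- as.integer(round((fid$s + fid$t) / 2))
  fid <- lapply(fid[c("q", "r", "s", "st", "t")], function(i) {
    as.integer(min(max(i, 1L), n_samples))
  })

  structure(list(values = values, sample_period_ms = sample_period_ms,
                 case_label = "normal", region = NULL, fiducials = fid,
                 reference_node = as.integer(reference_node),
                 activation_origin = as.integer(activation_origin),
                 tmp = tmp, delays = delays, base_delay_ms = base_delay_ms,
                 mean_tmp = mean_tmp, scale = scale),
            class = "epicardial_sources")
}

#' @export
print.epicardial_sources <- function(x, ...) {
  cat("epicardial_sources:", nrow(x$values), "nodes x", ncol(x$values),
      "samples, case", x$case_label, "\n")
  invisible(x)
}

# raised-cosine bump of unit height centred at sample `center`, zero for
# |i - center| >= halfwidth
cosine_bump <- function(n, center, halfwidth) {
  i <- seq_len(n)
  w <- (i - center) / halfwidth
  out <- numeric(n)
  inside <- abs(w) < 1
  out[inside] <- 0.5 * (1 + cos(pi * w[inside]))
  out
}

#' Inject a disease case into normal epicardial sources
#'
#' Replaces the waveforms at the region's member nodes by the case-modified
#' waveform, calibrated so the printed amplitude characteristics hold exactly
#' at the region centre: D1 spans -10 to 19 mV; D2 adds +5 mV at the ST
#' fiducial while leaving the R-peak value unchanged; D3 adds +6 mV at the T
#' fiducial. Nodes outside the region are bit-identical to the input.
#'
#' @param sources normal [build_epicardial_sources()] output.
#' @param case a [disease_case()] or label.
#' @param region a [nodes_within_radius()] region.
#' @return Modified `epicardial_sources` with `case_label` and `region` set.
#' @export
inject_abnormality <- function(sources, case, region) {
  stopifnot(inherits(sources, "epicardial_sources"),
            inherits(region, "region_spec"))
  if (is.character(case)) case <- disease_case(case)
  stopifnot(inherits(case, "disease_case"))
  if (sources$case_label != "normal") {
    stop("abnormalities can only be injected into normal sources")
  }
  if (!(region$center_node %in% region$member_nodes)) {
    stop("region centre is not a member of the region")
  }
  vals <- sources$values
  n <- ncol(vals)
  fid <- sources$fiducials
  member <- region$member_nodes
  out <- sources

  if (case$label == "D1") {
    p_mod <- modify_tmp_params(sources$tmp, case)
    emod <- matrix(0, length(member), n)
    for (k in seq_along(member)) {
      p <- p_mod
      p$activation_delay_ms <- sources$base_delay_ms +
        sources$delays[member[k]]
      emod[k, ] <- sources$scale *
        (tmp_waveform(p, n, sources$sample_period_ms) - sources$mean_tmp)
    }
    cw <- emod[match(region$center_node, member), ]
    rng <- max(cw) - min(cw)
    if (rng < 1e-12) stop("degenerate modified waveform at region centre")
    a <- (case$target_metrics$max_mv - case$target_metrics$min_mv) / rng
    b <- case$target_metrics$min_mv - a * min(cw)
    vals[member, ] <- a * emod + b
  } else if (case$label == "D2") {
    hw <- min(fid$st - fid$r, n - fid$st)
    bump <- case$target_metrics$st_increase_mv * cosine_bump(n, fid$st, hw)
    vals[member, ] <- sweep(vals[member, , drop = FALSE], 2L, bump, `+`)
  } else {
    hw <- min(fid$t - fid$st, n - fid$t)
    bump <- case$target_metrics$t_increase_mv * cosine_bump(n, fid$t, hw)
    vals[member, ] <- sweep(vals[member, , drop = FALSE], 2L, bump, `+`)
  }
  out$values <- vals
  out$case_label <- case$label
  out$region <- region
  out
}

#' Body-surface ECG from epicardial sources
#'
#' Evaluates the infinite-homogeneous-medium current-dipole potential at the
#' eight electrode sites, with each source node carrying a dipole oriented
#' along its radial direction from the mesh centroid:
#' `phi(r_k, r_q) = p_hat_q . (r_k - r_q) / (4 pi sigma ||r_k - r_q||^3)`.
#' Lead k at time t is the source-weighted sum, linear in the sources.
#'
#' @param sources an `epicardial_sources` object.
#' @param mesh the [trimesh()] the sources live on.
#' @param electrodes an [place_precordial_electrodes()] set (8 sites).
#' @param conductivity_s_m medium conductivity, S/m.
#' @param dipole_moment_scale equivalent dipole moment per mV of epicardial
#'   potential, A m / mV; the default puts the leads on a physiological mV
#'   scale (the derived VCG orientation is invariant to this factor).
#' @return 8 x T numeric matrix (mV scale), rows named by electrode label.
#' @export
surface_ecg <- function(sources, mesh, electrodes, conductivity_s_m = 0.2,
                        dipole_moment_scale = 1e-5) {
  stopifnot(inherits(sources, "epicardial_sources"),
            inherits(mesh, "trimesh"), inherits(electrodes, "electrode_set"))
  if (length(electrodes$names) != 8L) stop("exactly 8 electrodes required")
  rq <- mesh$vertices * 1e-3
  rk <- electrodes$positions * 1e-3
  ctr <- colMeans(rq)
  orient <- sweep(rq, 2L, ctr)
  on <- sqrt(rowSums(orient^2))
  if (any(on < 1e-12)) stop("source node at mesh centroid: orientation undefined")
  orient <- orient / on
  phi <- matrix(0, nrow(rk), nrow(rq))
  for (k in seq_len(nrow(rk))) {
    dvec <- sweep(-rq, 2L, rk[k, ], `+`)          # r_k - r_q
    dist3 <- rowSums(dvec^2)^1.5
    if (any(dist3 < 1e-30)) {
      stop("electrode coincides with a source node (k = ", k, ")")
    }
    phi[k, ] <- dipole_moment_scale * rowSums(orient * dvec) /
      (4 * pi * conductivity_s_m * dist3)
  }
  ecg <- phi %*% sources$values
  rownames(ecg) <- electrodes$names
  ecg
}

#' Add white Gaussian noise at a prescribed SNR
#'
#' Adds zero-mean i.i.d. Gaussian noise with variance equal to the mean
#' per-sample signal power divided by `10^(snr_db/10)`. Deterministic given
#' `seed`; the caller's RNG stream is left untouched.
#'
#' @param signal numeric matrix (channels x time) or vector with non-zero
#'   power.
#' @param snr_db target signal-to-noise ratio, dB.
#' @param seed integer seed.
#' @return Matrix of the same shape as `signal`.
#' @export
add_noise <- function(signal, snr_db, seed) {
  p <- mean(signal^2)
  if (!is.finite(p) || p <= 0) {
    stop("signal power is zero: SNR undefined")
  }
  sigma <- sqrt(p / 10^(snr_db / 10))
  noise <- with_preserved_rng(seed,
    matrix(stats::rnorm(length(signal), sd = sigma),
           nrow = NROW(signal), ncol = NCOL(signal)))
  signal + noise
}
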