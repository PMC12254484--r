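# Shared fixtures, built once per test run. Small meshes keep the suite
# fast; scale-sensitive behaviour is exercised explicitly where needed.

fix_mesh <- function(n = 60, seed = 2) build_heart_surface(n, seed = seed)

fix_pipeline <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    mesh <- fix_mesh()
    detectors <- build_detector_grid()
    kernel <- forward_kernel(mesh, detectors)
    sources <- build_epicardial_sources(mesh)
    electrodes <- place_precordial_electrodes()
    ecg <- surface_ecg(sources, mesh, electrodes)
    orient <- unit_vcg_series(inverse_dower(ecg))
    dlf <- dynamic_lead_field(kernel, orient)
    mcg <- synthesize_mcg(dlf, sources)
    cache <<- list(mesh = mesh, detectors = detectors, kernel = kernel,
                   sources = sources, electrodes = electrodes, ecg = ecg,
                   orient = orient, dlf = dlf, mcg = mcg,
                   D = mesh_gradient_operator(mesh),
                   L_rad = lead_field_radial(kernel))
    cache
  }
})

# published forward Dower lead matrix (V1..V6, I, II rows), used only as an
# independent oracle for the VCG loop-recovery check
dower_forward_matrix <- function() {
  m <- rbind(
    V1 = c(-0.515, 0.157, -0.917),
    V2 = c( 0.044, 0.164, -1.387),
    V3 = c( 0.882, 0.098, -1.277),
    V4 = c( 1.213, 0.127, -0.601),
    V5 = c( 1.125, 0.127, -0.086),
    V6 = c( 0.831, 0.076,  0.230),
    I  = c( 0.632, -0.235,  0.059),
    II = c( 0.235,  1.066, -0.132))
  colnames(m) <- c("x", "y", "z")
  m
}

rel_err <- function(est, truth) {
  sqrt(sum((est - truth)^2)) / sqrt(sum(truth^2))
}

bound_is_monotone <- function(trace, tol = 1e-8) {
  if (length(trace) < 2L) return(TRUE)
  all(diff(trace) >= -tol * pmax(abs(trace[-1]), 1))
}
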