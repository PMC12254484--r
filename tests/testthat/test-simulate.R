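test_that("tmp template has the configured amplitude and case modifications act as described", {
  p <- tmp_params()
  w <- tmp_waveform(p, 300)
  expect_equal(max(w) - min(w), p$amplitude_mv, tolerance = 0.01)
  expect_equal(min(w), p$resting_mv)
  expect_equal(max(w), p$resting_mv + p$amplitude_mv)

  # D2: magnitude lowered to 40% without altering duration
  p2 <- modify_tmp_params(p, "D2")
  w2 <- tmp_waveform(p2, 300)
  expect_equal(max(w2) - min(w2), 0.4 * p$amplitude_mv, tolerance = 1e-9)
  expect_equal(p2$upstroke_ms + p2$plateau_ms + p2$repol_ms,
               p$upstroke_ms + p$plateau_ms + p$repol_ms)

  # D3: active duration strictly shorter
  p3 <- modify_tmp_params(p, "D3")
  expect_lt(p3$plateau_ms + p3$repol_ms, p$plateau_ms + p$repol_ms)

  # D1: slower ascent
  p1 <- modify_tmp_params(p, "D1")
  expect_gt(p1$upstroke_ms, p$upstroke_ms)

  expect_error(tmp_waveform(p, 50), "duration")
  expect_error(tmp_params(amplitude_mv = -1), "amplitude")
})

test_that("epicardial generator calibrates the reference node and orders delays by distance", {
  fx <- fix_pipeline()
  src <- fx$sources
  ref <- src$reference_node
  w <- src$values[ref, ]
  expect_equal(max(w) - min(w), 8, tolerance = 0.01 * 8)

  # delays equal brute-force distance / speed; origin has the minimum
  d <- sqrt(colSums((t(fx$mesh$vertices) -
                       fx$mesh$vertices[src$activation_origin, ])^2))
  expect_equal(src$delays, d / 0.8, tolerance = 1e-12)
  expect_identical(which.min(src$delays), src$activation_origin)

  # fiducials strictly increasing and inside the beat
  f <- unlist(src$fiducials)
  expect_true(all(diff(f) > 0))
  expect_true(all(f >= 1 & f <= ncol(src$values)))

  # infinite conduction speed: all node waveforms identical
  inst <- build_epicardial_sources(fx$mesh, conduction_speed_mm_ms = Inf)
  expect_lt(max(abs(sweep(inst$values, 2, inst$values[1, ]))), 1e-12)

  expect_error(build_epicardial_sources(fx$mesh,
                                        conduction_speed_mm_ms = 0),
               "positive")
})

test_that("disease injection hits the printed amplitude targets and is local to the region", {
  fx <- fix_pipeline()
  src <- fx$sources
  ref <- src$reference_node
  region <- nodes_within_radius(fx$mesh, ref, 2.5)
  outside <- setdiff(seq_len(nrow(fx$mesh$vertices)), region$member_nodes)
  fid <- src$fiducials

  d1 <- inject_abnormality(src, "D1", region)
  expect_equal(min(d1$values[ref, ]), -10, tolerance = 0.02 * 10)
  expect_equal(max(d1$values[ref, ]), 19, tolerance = 0.02 * 19)

  d2 <- inject_abnormality(src, "D2", region)
  expect_equal(d2$values[ref, fid$st] - src$values[ref, fid$st], 5,
               tolerance = 0.02 * 5)
  expect_equal(d2$values[ref, fid$r], src$values[ref, fid$r],
               tolerance = 0.02 * max(abs(src$values[ref, fid$r]), 1))

  d3 <- inject_abnormality(src, "D3", region)
  expect_equal(d3$values[ref, fid$t] - src$values[ref, fid$t], 6,
               tolerance = 0.02 * 6)

  # locality: outside the region every case is bit-identical to normal
  for (ab in list(d1, d2, d3)) {
    expect_identical(ab$values[outside, ], src$values[outside, ])
    expect_identical(ab$region$member_nodes, region$member_nodes)
  }

  expect_error(inject_abnormality(d1, "D2", region), "normal")
})

test_that("surface ECG is linear in the sources and matches a hand-evaluated kernel", {
  fx <- fix_pipeline()
  src <- fx$sources

  zero <- src
  zero$values[] <- 0
  expect_true(all(surface_ecg(zero, fx$mesh, fx$electrodes) == 0))

  twice <- src
  twice$values <- 2 * src$values
  expect_equal(surface_ecg(twice, fx$mesh, fx$electrodes),
               2 * fx$ecg, tolerance = 1e-12)

  # single active node against a direct evaluation of the dipole potential
  single <- src
  single$values[] <- 0
  single$values[5, 10] <- 3
  ecg1 <- surface_ecg(single, fx$mesh, fx$electrodes)
  rq <- fx$mesh$vertices * 1e-3
  ctr <- colMeans(rq)
  o <- rq[5, ] - ctr; o <- o / sqrt(sum(o^2))
  rk <- fx$electrodes$positions[2, ] * 1e-3
  dvec <- rk - rq[5, ]
  phi <- 1e-5 * sum(o * dvec) / (4 * pi * 0.2 * sum(dvec^2)^1.5)
  expect_equal(unname(ecg1[2, 10]), 3 * phi, tolerance = 1e-12)
  expect_equal(unname(ecg1[2, 11]), 0)
})

test_that("noise injection achieves the requested SNR and is reproducible", {
  set.seed(77)
  x <- matrix(rnorm(10 * 10000), 10)
  y1 <- add_noise(x, 20, seed = 5)
  y2 <- add_noise(x, 20, seed = 5)
  expect_identical(y1, y2)
  expect_false(identical(y1, add_noise(x, 20, seed = 6)))

  # achieved SNR within 0.2 dB at N = 1e5
  achieved <- 10 * log10(mean(x^2) / mean((y1 - x)^2))
  expect_lt(abs(achieved - 20), 0.2)

  # definition of dB: noise power is a tenth of unit signal power at 10 dB
  n <- add_noise(x, 10, seed = 1) - x
  expect_equal(mean(n^2), mean(x^2) / 10, tolerance = 0.05)

  # caller's RNG stream untouched
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(add_noise(x, 10, seed = 2)); after <- rnorm(1)
  expect_identical(before, after)

  expect_error(add_noise(matrix(0, 2, 2), 10, 1), "zero")
})

test_that("signal matrices round-trip through delimited text with metadata", {
  x <- matrix(rnorm(12), 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_signal_csv(x, path, meta = list(case = "D1", fiducials = c(1, 2)))
  expect_equal(unname(read_signal_csv(path)), x, tolerance = 1e-12)
  expect_true(file.exists(paste0(path, ".meta")))
  expect_match(readLines(paste0(path, ".meta"))[1], "case: D1")
})
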