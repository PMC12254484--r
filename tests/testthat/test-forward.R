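test_that("dipole kernel matches hand evaluation, antisymmetry and inverse-square decay", {
  # literal cross-product evaluation: x-moment at origin, sensor on +z
  b <- dipole_field_kernel(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1))
  expect_equal(b, c(0, -1e-7, 0), tolerance = 1e-20)

  # moment parallel to the separation gives a zero field
  expect_equal(dipole_field_kernel(c(0, 0, 0), c(0, 0, 2), c(0, 0, 1)),
               c(0, 0, 0))

  # doubling the distance divides the magnitude by four
  b1 <- dipole_field_kernel(c(0, 0, 0), c(1, 2, 3), c(0, 0, 1))
  b2 <- dipole_field_kernel(c(0, 0, 0), c(1, 2, 3), c(0, 0, 2))
  expect_equal(sqrt(sum(b1^2)) / sqrt(sum(b2^2)), 4, tolerance = 1e-12)

  # sign antisymmetry in the moment
  expect_identical(dipole_field_kernel(c(0, 0, 0), -c(1, 2, 3), c(0, 1, 1)),
                   -dipole_field_kernel(c(0, 0, 0), c(1, 2, 3), c(0, 1, 1)))

  expect_error(dipole_field_kernel(c(0, 0, 0), c(1, 0, 0), c(0, 0, 0)),
               "coincides")
})

test_that("far-field decay follows inverse square along a fixed ray", {
  m <- c(0.3, -1, 2)
  r <- seq(0.5, 5, by = 0.5)
  mag <- vapply(r, function(ri) {
    sqrt(sum(dipole_field_kernel(c(0, 0, 0), m, ri * c(1, 1, 1) / sqrt(3))^2))
  }, numeric(1))
  expect_lt(max(abs(mag * r^2 / (mag[1] * r[1]^2) - 1)), 0.01)
})

test_that("radial lead field columns equal a brute-force sensor loop", {
  fx <- fix_pipeline()
  lf <- fx$L_rad
  pos <- fx$mesh$vertices
  ctr <- colMeans(pos)
  det <- fx$detectors
  for (q in c(1L, 17L, nrow(pos))) {
    o <- pos[q, ] - ctr; o <- o / sqrt(sum(o^2))
    col <- vapply(seq_len(nrow(det$positions)), function(i) {
      sum(dipole_field_kernel(pos[q, ] * 1e-3, o, det$positions[i, ] * 1e-3) *
            det$normal)
    }, numeric(1))
    expect_equal(lf$matrix[, q], col, tolerance = 1e-12)
  }
  # orientations are unit radial vectors
  expect_true(all(abs(sqrt(rowSums(lf$orientations^2)) - 1) < 1e-12))
})

test_that("uVCG lead field reduces to the radial one on centred rays and is odd in the orientation", {
  det <- build_detector_grid(3, 3, 30, origin = c(0, 0, 60))
  # sources placed on a single ray through the centroid... use a sphere
  # mesh centred at the origin so radial directions are r / |r|
  m <- build_heart_surface(40, radii = c(30, 30, 30), center = c(0, 0, 0),
                           seed = 1)
  kern <- forward_kernel(m, det)
  lr <- lead_field_radial(kern)
  # per source, a uVCG field with orient = that source's radial direction
  # must reproduce the radial column
  for (q in c(1L, 9L, 25L)) {
    o <- lr$orientations[q, ]
    lu <- lead_field_uvcg(kern, orient = o)
    expect_equal(lu$matrix[, q], lr$matrix[, q], tolerance = 1e-12)
  }
  # 180-degree rotation negates the matrix
  lu1 <- lead_field_uvcg(kern, orient = c(1, 0, 0))
  lu2 <- lead_field_uvcg(kern, orient = c(-1, 0, 0))
  expect_equal(lu2$matrix, -lu1$matrix, tolerance = 1e-15)

  expect_error(lead_field_uvcg(kern, orient = c(1, 1, 0)), "unit")
})

test_that("sensors directly above sources with a vertical moment read zero", {
  det <- build_detector_grid(2, 2, 10, origin = c(0, 0, 0),
                             normal = c(0, 0, 1))
  pos <- det$positions + matrix(rep(c(0, 0, -50), each = 4), ncol = 3)
  lu <- lead_field_uvcg(pos, det, orient = c(0, 0, 1))
  # each source sits below one sensor; for that pair d is parallel to z and
  # the moment is z, so the sensed normal component vanishes; for other
  # pairs the kernel is blind to a z moment altogether
  expect_lt(max(abs(lu$matrix)), 1e-25)
})

test_that("MCG synthesis is the per-instant matrix product and superposes", {
  fx <- fix_pipeline()
  src <- fx$sources
  # zero sources give zero field
  z <- src; z$values[] <- 0
  expect_true(all(synthesize_mcg(fx$dlf, z)$values == 0))

  # one active node reproduces the column of the instant's lead field
  one <- src; one$values[] <- 0; one$values[7, 25] <- 2.5
  b <- synthesize_mcg(fx$dlf, one)$values
  L25 <- lead_field_at(fx$dlf, 25)
  expect_equal(b[, 25], 2.5 * L25[, 7], tolerance = 1e-15)
  expect_true(all(b[, -25] == 0))

  # superposition against independently synthesized parts
  s1 <- src; s2 <- src
  set.seed(8)
  s1$values <- matrix(rnorm(length(src$values)), nrow(src$values))
  s2$values <- matrix(rnorm(length(src$values)), nrow(src$values))
  sum_ <- src; sum_$values <- s1$values + s2$values
  expect_equal(synthesize_mcg(fx$dlf, sum_)$values,
               synthesize_mcg(fx$dlf, s1)$values +
                 synthesize_mcg(fx$dlf, s2)$values,
               tolerance = 1e-12)

  # static lead field path agrees with plain matrix multiplication
  bs <- synthesize_mcg(fx$L_rad, src)$values
  expect_equal(bs, fx$L_rad$matrix %*% src$values, tolerance = 1e-15)

  expect_error(synthesize_mcg(fx$L_rad, src$values[-1, ]), "nodes")
})

test_that("field map export has the grid shape and locates the extremum sensor", {
  fx <- fix_pipeline()
  map <- export_field_map(fx$mcg, fx$sources$fiducials$r, fx$detectors)
  expect_identical(nrow(map), 81L)
  expect_identical(max(map$row), 9L)
  i_max <- which.max(abs(map$value))
  expect_equal(map$value[i_max],
               fx$mcg$values[i_max, fx$sources$fiducials$r])
  expect_error(export_field_map(fx$mcg, 10000, fx$detectors), "range")
})
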