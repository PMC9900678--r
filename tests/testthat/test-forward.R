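test_that("diffusion coefficient follows D = 1/(3(mu_a + mu_s'))", {
  op <- optical_properties(0.0059, 0.69)
  expect_equal(op$D, 1 / (3 * (0.0059 + 0.69)))
  expect_error(optical_properties(-0.01, 1), "mu_a")
  expect_error(optical_properties(0.01, 0), "mu_s")
})

test_that("assembled system is real s.p.d. at omega = 0 and matches P1 mass blocks", {
  spec <- phantom_spec(50, optical_properties(0.01, 1))
  acq <- acquisition_config(8, frequency_mhz = 0)
  mesh <- build_mesh(spec, 6)
  sys <- assemble_system(mesh, list(spec$background), acq)
  expect_equal(max(abs(sys$K_im)), 0)
  K <- as.matrix(sys$K_re)
  expect_equal(K, t(K), tolerance = 1e-12)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))

  # the mass contribution against the hand-integrated P1 block: applying K
  # to the constant field annihilates the stiffness part, so an interior
  # row n reduces to the mass term mu_a * sum(area/12 * [2 1 1]) summed
  # over the elements of the node patch = mu_a * patch_area / 3
  interior <- setdiff(seq_len(nrow(mesh$nodes)), mesh$boundary)
  areas <- dotrecon:::element_areas(mesh)
  Kone <- as.vector(K %*% rep(1, nrow(mesh$nodes)))
  for (n in interior[c(1L, 5L, 11L)]) {
    patch <- apply(mesh$elements, 1, function(v) n %in% v)
    expect_equal(Kone[n], 0.01 * sum(areas[patch]) / 3, tolerance = 1e-10)
  }
})

test_that("doubling absorption decreases the CW solution everywhere", {
  spec <- phantom_spec(50, optical_properties(0.01, 1))
  acq <- acquisition_config(8, frequency_mhz = 0)
  mesh <- build_mesh(spec, 4)
  s1 <- assemble_system(mesh, list(optical_properties(0.01, 1)), acq)
  s2 <- assemble_system(mesh, list(optical_properties(0.02, 1)), acq)
  f1 <- solve_forward(s1, 1L)
  f2 <- solve_forward(s2, 1L)
  expect_true(all(Re(f2) < Re(f1)))
})

test_that("homogeneous-disk solution matches the 2D infinite-medium kernel", {
  spec <- homog_phantom()  # mu_a = 0.0080, mu_s' = 0.5634
  mesh <- build_mesh(spec, 1.8)
  D <- spec$background$D
  r <- sqrt(rowSums(mesh$nodes^2))
  sel <- r > 10 & r < 20
  center_load <- dotrecon:::point_loads(mesh, matrix(c(0, 0), 1))

  for (f_mhz in c(0, 20)) {
    acq <- acquisition_config(16, f_mhz)
    sys <- assemble_system(mesh, list(spec$background), acq)
    phi <- dotrecon:::solve_system(sys, center_load)[sel, 1]
    k <- sqrt(complex(real = 0.0080,
                      imaginary = -acq$omega / acq$c_medium) / D)
    exact <- besselK0_complex(k * r[sel]) / (2 * pi * D)
    expect_lt(max(abs(Mod(phi) - Mod(exact)) / Mod(exact)), 0.05)
    if (f_mhz > 0)
      expect_lt(max(abs(Arg(phi) - Arg(exact))), 0.01)
    # amplitude decays monotonically with distance from the source
    ord <- order(r[sel])
    ring_mean <- tapply(Mod(phi)[ord], round(r[sel][ord], 1), mean)
    expect_true(all(diff(ring_mean) < 0))
  }
})

test_that("source-detector reciprocity holds to 1e-8 (symmetric system)", {
  spec <- phantom_spec(60, optical_properties(0.01, 1), list(
    list(center = c(8, 5), radius = 8,
         props = optical_properties(0.02, 1.5))), frequency_mhz = 50)
  acq <- acquisition_config(16, 50)
  mesh <- build_mesh(spec, 4)
  props <- c(list(spec$background), lapply(spec$inclusions, `[[`, "props"))
  sys <- assemble_system(mesh, props, acq)
  fields <- solve_forward(sys)
  loads <- dotrecon:::point_loads(
    mesh, dotrecon:::source_points(mesh, acq, spec$background$mu_s_prime))
  G <- t(loads) %*% Re(fields) + 1i * t(loads) %*% Im(fields)
  expect_lt(max(Mod(G - t(G)) / Mod(G)), 1e-8)
})

test_that("omega = 0 gives zero phase; omega > 0 gives distance-monotone lag", {
  spec_cw <- phantom_spec(80, optical_properties(0.0080, 0.5634),
                          frequency_mhz = 0)
  bd0 <- simulate_boundary(spec_cw, acquisition_config(16, 0),
                           target_edge_mm = 3)
  expect_equal(max(abs(bd0$phase)), 0, tolerance = 1e-10)

  bd <- simulate_boundary(homog_phantom(), acquisition_config(16, 20),
                          target_edge_mm = 3)
  lag <- abs(bd$phase[1, ] - bd$phase[1, 1])
  half <- floor(15 / 2)
  expect_true(all(diff(lag[seq_len(half + 1)]) > 0))
  # rows of a homogeneous phantom are symmetric about the diametric detector
  expect_equal(bd$amplitude[1, 1:7], rev(bd$amplitude[1, 9:15]),
               tolerance = 0.02)
})

test_that("boundary sampling yields m x (m-1) observations per channel", {
  spec <- homog_phantom()
  bd36 <- simulate_boundary(spec, acquisition_config(36, 20))
  expect_equal(dim(bd36$amplitude), c(36L, 35L))
  expect_equal(length(bd36$amplitude), 1260L)
  bd16 <- simulate_boundary(spec, acquisition_config(16, 20))
  expect_equal(length(bd16$amplitude), 240L)
  expect_equal(length(bd16$phase), 240L)
})

test_that("boundary amplitudes are mesh-converged (mean change < 1% on halving)", {
  spec <- phantom_spec(60, optical_properties(0.01, 1), frequency_mhz = 50)
  acq <- acquisition_config(16, 50)
  b1 <- simulate_boundary(spec, acq, target_edge_mm = 0.8)
  b2 <- simulate_boundary(spec, acq, target_edge_mm = 0.4)
  rel <- abs(b1$amplitude - b2$amplitude) / b2$amplitude
  expect_lt(mean(rel), 0.01)
})

test_that("multiplicative amplitude noise has the configured relative spread", {
  spec <- homog_phantom()
  bd <- simulate_boundary(spec, acquisition_config(36, 20))
  expect_identical(add_noise(bd, 0, seed = 1), bd)
  nz <- add_noise(bd, 0.15, seed = 7)
  expect_equal(stats::sd(nz$amplitude / bd$amplitude - 1), 0.15,
               tolerance = 0.02)
  expect_identical(nz, add_noise(bd, 0.15, seed = 7))
  expect_false(identical(nz, add_noise(bd, 0.15, seed = 8)))
  expect_error(add_noise(bd, -0.1), ">= 0")
})

test_that("empirical noise s.d. approaches the nominal level at large n", {
  # law-of-large-numbers check on ~1e5 draws
  spec <- homog_phantom()
  bd <- simulate_boundary(spec, acquisition_config(36, 20))
  amp <- bd$amplitude
  devs <- unlist(lapply(1:80, function(s)
    add_noise(bd, 0.15, seed = s)$amplitude / amp - 1))
  expect_gt(length(devs), 1e5)
  expect_equal(stats::sd(devs), 0.15, tolerance = 0.005 / 0.15)
})

test_that("min-max normalization maps endpoints and clips with frozen stats", {
  bd <- structure(list(amplitude = matrix(c(2, 4, 6, 2, 4, 6), 2, 3),
                       phase = matrix(c(0, 1, 2, 0, 1, 2), 2, 3),
                       n_sources = 2L, n_detectors = 3L,
                       normalized = FALSE, noisy = FALSE,
                       norm_stats = NULL), class = "boundary_data")
  nd <- normalize_minmax(bd)
  expect_equal(sort(unique(as.vector(nd$amplitude))), c(0, 0.5, 1))
  expect_true(all(nd$amplitude >= 0 & nd$amplitude <= 1))

  # frozen training stats: out-of-range test values are clipped
  bd2 <- bd
  bd2$amplitude[1, 1] <- 100
  nd2 <- normalize_minmax(bd2, stats = nd$norm_stats)
  expect_equal(nd2$amplitude[1, 1], 1)

  bd3 <- bd
  bd3$amplitude[] <- 5
  expect_error(normalize_minmax(bd3), "degenerate")
})
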