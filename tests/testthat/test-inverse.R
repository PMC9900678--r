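test_that("adjoint Jacobian matches central finite differences", {
  fx <- small_inverse_setup()
  mesh <- fx$mesh; acq <- fx$acq; st <- fx$state
  nN <- nrow(mesh$nodes)
  meas <- function(mu_a, mu_s) {
    sys <- assemble_system(mesh, list(mu_a = mu_a, mu_s_prime = mu_s), acq)
    f <- dotrecon:::solve_system(sys, st$source_loads)
    dotrecon:::measurement_vector(
      dotrecon:::boundary_readings(f, mesh, acq), acq$n_sources)
  }
  set.seed(1)
  for (n in sample(nN, 5)) {
    for (ch in 1:2) {
      mu_a <- st$mu_a; mu_s <- st$mu_s_prime
      d <- 0.01 * (if (ch == 1) mu_a[n] else mu_s[n])
      if (ch == 1) {
        fd <- (meas(replace(mu_a, n, mu_a[n] + d), mu_s) -
                 meas(replace(mu_a, n, mu_a[n] - d), mu_s)) / (2 * d)
        col <- fx$J[, n]
      } else {
        fd <- (meas(mu_a, replace(mu_s, n, mu_s[n] + d)) -
                 meas(mu_a, replace(mu_s, n, mu_s[n] - d))) / (2 * d)
        col <- fx$J[, nN + n]
      }
      expect_lt(max(abs(col - fd)) / max(abs(fd)), 0.05)
    }
  }
})

test_that("more absorption means less light: mu_a columns of log-amplitude rows", {
  fx <- small_inverse_setup()
  nN <- nrow(fx$mesh$nodes)
  n_pairs <- fx$acq$n_sources * fx$acq$n_detectors
  expect_true(all(colSums(fx$J[seq_len(n_pairs), seq_len(nN)]) < 0))
})

test_that("linearity: zero perturbation produces zero predicted change", {
  fx <- small_inverse_setup()
  expect_equal(as.vector(fx$J %*% numeric(ncol(fx$J))),
               numeric(nrow(fx$J)))
})

test_that("regularized update solves the stacked least-squares problem", {
  set.seed(2)
  # toy square system: lambda = 0 reduces to the direct solve
  J <- matrix(rnorm(64), 8, 8) + diag(8)
  r <- rnorm(8)
  expect_equal(tr_update(J, r, 0), solve(J, r), tolerance = 1e-8)

  # stacked solution == normal-equations solution
  J2 <- matrix(rnorm(40 * 12), 40, 12)
  r2 <- rnorm(40)
  lam <- 0.3
  direct <- solve(crossprod(J2) + lam^2 * diag(12), crossprod(J2, r2))
  expect_equal(tr_update(J2, r2, lam), as.vector(direct), tolerance = 1e-6)

  # huge lambda drives the update to zero
  expect_lt(sqrt(sum(tr_update(J2, r2, 1e12)^2)), 1e-12)

  # update norm decreases monotonically in lambda
  fx <- small_inverse_setup()
  set.seed(3)
  res <- rnorm(nrow(fx$J))
  norms <- vapply(c(1e-6, 1e-4, 1e-2, 1), function(l)
    sqrt(sum(tr_update(fx$J, res, l)^2)), numeric(1))
  expect_true(all(diff(norms) <= 1e-9))

  expect_error(tr_update(fx$J, c(NaN, res[-1]), 0.1), "non-finite")
})

test_that("reconstruction from self-consistent data is a fixed point", {
  spec <- phantom_spec(50, optical_properties(0.008, 0.8),
                       frequency_mhz = 30)
  acq <- acquisition_config(8, 30)
  # same mesh for data and inversion, initialized at the truth
  bd <- simulate_boundary(spec, acq, target_edge_mm = 7)
  res <- reconstruct_tr(bd, spec, acq, init = spec$background,
                        max_iter = 3, target_edge_mm = 7)
  expect_lt(res$misfit[1], 1e-12)
  expect_equal(res$mu_a, rep(0.008, length(res$mu_a)), tolerance = 1e-4)
})

test_that("TR localizes a single inclusion and the misfit never increases", {
  spec <- phantom_spec(50, optical_properties(0.0059, 0.69), list(
    list(center = c(10, 6), radius = 5,
         props = optical_properties(0.015, 1.4))), frequency_mhz = 20)
  acq <- acquisition_config(16, 20)
  bd <- simulate_boundary(spec, acq, target_edge_mm = 3)  # noiseless
  res <- reconstruct_tr(bd, spec, acq, init = spec$background,
                        max_iter = 8, target_edge_mm = 5)
  expect_true(all(diff(res$misfit) <= 1e-12))
  img <- res$image[1, , ]
  thr <- stats::quantile(img, 0.97)
  idx <- which(img >= thr, arr.ind = TRUE)
  centers <- -25 + (seq_len(64) - 0.5) * (50 / 64)
  cx <- mean(centers[idx[, 1]]); cy <- mean(centers[idx[, 2]])
  expect_lt(sqrt((cx - 10)^2 + (cy - 6)^2), 10)
})
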