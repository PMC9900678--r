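# Measurement model shared by the inverse solver: for each source i the
# complex reading at detector j is w_j' Phi_i (boundary interpolation
# weights); the residual is parameterized as (log-amplitude, phase), which is
# better scaled than raw complex fluence.

# Detector interpolation weight matrix: nN x m sparse, column k = weights of
# boundary position k (every source angle doubles as a detector position).
detector_weights <- function(mesh, acq) {
  m <- acq$n_sources
  bn <- mesh$boundary
  nb <- length(bn)
  spacing <- 2 * pi / nb
  det_ang <- source_angles(acq)
  pos <- det_ang / spacing
  i0 <- floor(pos)
  w1 <- 1 - (pos - i0)
  idx1 <- bn[(as.integer(i0) %% nb) + 1L]
  idx2 <- bn[(as.integer(i0 + 1) %% nb) + 1L]
  Matrix::sparseMatrix(i = c(idx1, idx2), j = c(seq_len(m), seq_len(m)),
                       x = c(w1, 1 - w1), dims = c(nrow(mesh$nodes), m))
}

# Complex readings (m x m: position x source) from nodal fields.
boundary_readings <- function(fields, mesh, acq) {
  W <- as.matrix(detector_weights(mesh, acq))
  crossprod(W, Re(fields)) + 1i * crossprod(W, Im(fields))
}

# Stack readings into the (log-amplitude, phase) measurement vector, ordered
# source-major with detectors by increasing angular offset, log-amplitude
# rows first then phase rows.
measurement_vector <- function(readings, m) {
  la <- ph <- matrix(0, m, m - 1L)
  for (i in seq_len(m)) {
    dets <- ((i - 1L + seq_len(m - 1L)) %% m) + 1L
    z <- readings[dets, i]
    la[i, ] <- log(Mod(z))
    ph[i, ] <- Arg(z)
  }
  c(as.vector(t(la)), as.vector(t(ph)))
}

# Measurement vector from boundary_data (observed side).
measurement_from_data <- function(data) {
  c(as.vector(t(log(data$amplitude))), as.vector(t(data$phase)))
}

#' Inverse-problem state for Tikhonov-regularized Newton reconstruction
#'
#' Holds the current nodal estimate of both coefficients, the forward fields
#' at the estimate, and the regularization setup for the update
#' \deqn{\min_{\Delta\chi} \|J\Delta\chi - \Delta\Phi\|_2^2 +
#'       \lambda^2\|L\Delta\chi\|_2^2.}
#'
#' @param mesh A `dot_mesh`.
#' @param acq An [acquisition_config()].
#' @param mu_a,mu_s_prime Initial nodal values (scalars are recycled).
#' @param lambda Regularization parameter; `NULL` selects
#'   `0.1 * sqrt(max(diag(J'J)))` at the first update.
#' @param L Regularization matrix (default identity).
#' @return An `inverse_state`.
#' @export
inverse_state <- function(mesh, acq, mu_a, mu_s_prime, lambda = NULL,
                          L = NULL) {
  nN <- nrow(mesh$nodes)
  structure(
    list(mesh = mesh, acq = acq,
         mu_a = rep_len(mu_a, nN), mu_s_prime = rep_len(mu_s_prime, nN),
         lambda = lambda, L = L, fields = NULL, system = NULL),
    class = "inverse_state"
  )
}

# Run the forward model at the current estimate; caches system and fields.
update_forward <- function(state) {
  sys <- assemble_system(state$mesh,
                         list(mu_a = state$mu_a,
                              mu_s_prime = state$mu_s_prime),
                         state$acq)
  pts <- source_points(state$mesh, state$acq,
                       mean(state$mu_s_prime))
  state$system <- sys
  state$source_loads <- point_loads(state$mesh, pts)
  state$fields <- solve_system(sys, state$source_loads)
  state
}

#' Jacobian of boundary measurements with respect to nodal properties
#'
#' Adjoint (reciprocity-based) assembly: for reading `g = log(w_j' Phi_i)`,
#' \deqn{dg/dp = -\psi_j' (\partial K/\partial p)\, \Phi_i / (w_j'\Phi_i)}
#' where \eqn{K\psi_j = w_j} (K is symmetric, so adjoint solves are plain
#' solves). Nodal sensitivities use the element-mean property rule of
#' [assemble_system()]: node n receives 1/3 of each adjacent element's
#' sensitivity. The diffusion-channel sensitivity is mapped to
#' \eqn{(\mu_a, \mu_s')} with \eqn{\partial D/\partial \mu_a =
#' \partial D/\partial \mu_s' = -3D^2}.
#'
#' @param state An `inverse_state` with current forward fields (computed if
#'   absent).
#' @return List with the Jacobian `J` (2 m n rows: log-amplitude rows then
#'   phase rows; 2 N columns: mu_a then mu_s'), the modeled measurement
#'   vector, and the updated state.
#' @export
compute_jacobian <- function(state) {
  if (is.null(state$fields)) state <- update_forward(state)
  mesh <- state$mesh; acq <- state$acq; sys <- state$system
  m <- acq$n_sources; nN <- nrow(mesh$nodes)
  e <- mesh$elements; nE <- nrow(e)

  Wdet <- as.matrix(detector_weights(mesh, acq))
  Psi <- solve_system(sys, Wdet)   # adjoint fields, one per position
  Phi <- state$fields              # one per source
  readings <- crossprod(Wdet, Re(Phi)) + 1i * crossprod(Wdet, Im(Phi))

  # per-element 3x3 blocks of dK/dD (stiffness shape) and dK/dmu_a (mass)
  B <- sys$grad_b; C <- sys$grad_c; area <- sys$area
  # element-to-node scatter with the 1/3 mean-rule weight
  Tscat <- Matrix::sparseMatrix(i = as.vector(e),
                                j = rep(seq_len(nE), 3L),
                                x = rep(1 / 3, 3L * nE),
                                dims = c(nN, nE))
  dD <- -3 * sys$D_e^2   # dD/dmu_a = dD/dmu_s' at element level

  n_pairs <- m * (m - 1L)
  J <- matrix(0, 2L * n_pairs, 2L * nN)
  row_la <- 0L
  # precompute per-element node values of Phi and Psi
  PhiE <- array(Phi[e, ], c(nE, 3L, m))    # element x vertex x source
  PsiE <- array(Psi[e, ], c(nE, 3L, m))

  for (i in seq_len(m)) {
    dets <- ((i - 1L + seq_len(m - 1L)) %% m) + 1L
    for (jj in seq_along(dets)) {
      j <- dets[jj]
      g <- readings[j, i]
      # stiffness-channel: psi' S_e phi  = D-derivative without D factor
      sS <- numeric(nE); sM <- numeric(nE)
      for (a in 1:3) for (b in 1:3) {
        sab <- (B[, a] * B[, b] + C[, a] * C[, b]) / (4 * area)
        mab <- area / 12 * (1 + (a == b))
        pp <- PsiE[, a, j] * PhiE[, b, i]
        sS <- sS + sab * pp
        sM <- sM + mab * pp
      }
      dg_dD_e <- -sS / g          # complex, per element
      dg_dmua_e <- -sM / g
      # map to nodal (mu_a, mu_s') columns
      scat <- function(v) as.vector(Tscat %*% Re(v)) +
        1i * as.vector(Tscat %*% Im(v))
      col_mua <- scat(dg_dmua_e + dD * dg_dD_e)
      col_mus <- scat(dD * dg_dD_e)
      r <- (i - 1L) * (m - 1L) + jj
      J[r, ] <- c(Re(col_mua), Re(col_mus))
      J[n_pairs + r, ] <- c(Im(col_mua), Im(col_mus))
    }
  }
  list(J = J, modeled = measurement_vector(readings, m), state = state)
}

#' One Tikhonov-regularized Newton update
#'
#' Solves the stacked least-squares system `[J; lambda L] dx = [r; 0]`
#' (algebraically the normal-equation solution
#' `(J'J + lambda^2 L'L)^{-1} J' r`) via QR.
#'
#' @param J Jacobian matrix.
#' @param residual Measured minus modeled measurement vector.
#' @param lambda Regularization parameter.
#' @param L Regularization matrix or `NULL` for identity.
#' @return The update vector `dx` (length `ncol(J)`).
#' @export
tr_update <- function(J, residual, lambda, L = NULL) {
  if (any(!is.finite(residual))) stop("non-finite residual")
  p <- ncol(J)
  if (is.null(L)) L <- diag(p)
  A <- rbind(J, lambda * L)
  b <- c(residual, numeric(nrow(L)))
  qr.solve(A, b)
}

#' Tikhonov-regularized Newton reconstruction from boundary data
#'
#' Starting from a homogeneous background estimate, iterates forward solve ->
#' residual -> Jacobian -> [tr_update()], with step halving (up to 10 times)
#' until the data misfit decreases; stops after `max_iter` iterations or when
#' the relative misfit change drops below `tol`. The nodal result is
#' interpolated barycentrically onto the 64x64 ground-truth grid.
#'
#' @param data Un-normalized `boundary_data` (physical amplitudes/phases).
#' @param spec The [phantom_spec()] describing geometry (only diameter and
#'   frequency are used; properties start from `init`).
#' @param acq An [acquisition_config()].
#' @param init [optical_properties()] of the homogeneous starting estimate.
#' @param lambda Regularization parameter; `NULL` for the automatic choice
#'   `0.1 * sqrt(max(diag(J'J)))` at the first iteration, then held fixed.
#' @param max_iter Maximum Newton iterations.
#' @param tol Relative misfit-change stopping tolerance.
#' @param target_edge_mm Inversion mesh resolution.
#' @return A `tr_result`: `image` (array 2 x 64 x 64, physical units),
#'   nodal estimates, misfit history, `lambda`, and a status flag.
#' @export
reconstruct_tr <- function(data, spec, acq, init = spec$background,
                           lambda = NULL, max_iter = 10L, tol = 1e-4,
                           target_edge_mm = spec$diameter_mm / 8) {
  stopifnot(inherits(data, "boundary_data"), !data$normalized)
  acq <- acquisition_config(acq$n_sources, spec$frequency_mhz,
                            acq$refractive_index, acq$boundary_coefficient,
                            acq$noise_level)
  mesh <- build_mesh(phantom_spec(spec$diameter_mm, init,
                                  frequency_mhz = spec$frequency_mhz),
                     target_edge_mm)
  state <- inverse_state(mesh, acq, init$mu_a, init$mu_s_prime,
                         lambda = lambda)
  observed <- measurement_from_data(data)
  state <- update_forward(state)

  misfit <- function(st) {
    r <- observed - measurement_vector(
      boundary_readings(st$fields, mesh, acq), acq$n_sources)
    sum(r^2)
  }
  history <- misfit(state)
  status <- "converged"
  nN <- nrow(mesh$nodes)

  for (it in seq_len(max_iter)) {
    jac <- compute_jacobian(state)
    state <- jac$state
    residual <- observed - jac$modeled
    if (is.null(state$lambda))
      state$lambda <- 0.1 * sqrt(max(colSums(jac$J^2)))
    dx <- tr_update(jac$J, residual, state$lambda)
    # backtracking on the data misfit
    step <- 1
    improved <- FALSE
    base <- history[length(history)]
    for (h in 0:10) {
      cand <- state
      cand$mu_a <- clamp(state$mu_a + step * dx[seq_len(nN)], 1e-4, 1)
      cand$mu_s_prime <- clamp(state$mu_s_prime + step * dx[nN + seq_len(nN)],
                               0.01, 20)
      cand <- update_forward(cand)
      f <- misfit(cand)
      if (is.finite(f) && f < base) { improved <- TRUE; break }
      step <- step / 2
    }
    if (!improved) { status <- "stalled"; break }
    state <- cand
    history <- c(history, f)
    if (abs(base - f) / max(base, .Machine$double.eps) < tol) break
  }

  img <- array(0, c(2L, 64L, 64L))
  px_spec <- phantom_spec(spec$diameter_mm, init,
                          frequency_mhz = spec$frequency_mhz)
  img[1L, , ] <- interp_to_grid(mesh, state$mu_a, spec$diameter_mm)
  img[2L, , ] <- interp_to_grid(mesh, state$mu_s_prime, spec$diameter_mm)
  structure(
    list(image = img, mu_a = state$mu_a, mu_s_prime = state$mu_s_prime,
         misfit = history, lambda = state$lambda, status = status,
         mesh = mesh),
    class = "tr_result"
  )
}

# Barycentric interpolation of a nodal field onto the 64x64 raster covering
# the phantom bounding square; pixels outside the mesh are 0.
interp_to_grid <- function(mesh, values, diameter_mm, size = 64L) {
  R <- diameter_mm / 2
  px <- diameter_mm / size
  centers <- -R + (seq_len(size) - 0.5) * px
  pts <- cbind(rep(centers, size), rep(centers, each = size))
  loc <- locate_points(mesh, pts)
  out <- numeric(nrow(pts))
  ok <- !is.na(loc$element)
  vid <- mesh$elements[loc$element[ok], , drop = FALSE]
  out[ok] <- rowSums(matrix(values[vid], ncol = 3L) * loc$weights[ok, ])
  matrix(out, size, size)  # column-major: row index = x, col index = y
}
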