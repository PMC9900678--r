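#' Assemble the FEM system for the frequency-domain diffusion equation
#'
#' Discretizes \deqn{-\nabla\cdot D \nabla\Phi + (\mu_a - i\omega/c)\Phi = S_0}
#' with \eqn{D = 1/(3(\mu_a + \mu_s'))} on linear (P1) triangles, plus the
#' Robin boundary term \eqn{\Phi + 2AD\,\partial\Phi/\partial n = 0}
#' discretized as a boundary mass contribution scaled by \eqn{1/(2A)}. The
#' complex system \eqn{K = K_{re} + i K_{im}} is stored as two real sparse
#' matrices; \eqn{K} is symmetric (not Hermitian), which is what makes
#' source-detector reciprocity exact at the discrete level.
#'
#' @param mesh A `dot_mesh` from [build_mesh()].
#' @param props Either a list of [optical_properties()], one per region
#'   (index 1 = background, index k+1 = inclusion k), or a list with numeric
#'   vectors `mu_a` and `mu_s_prime` of per-node values (used by the inverse
#'   solver; element values are the mean of their three nodes).
#' @param acq An [acquisition_config()].
#' @return A `dot_system` holding the sparse real/imaginary parts, the mesh,
#'   the acquisition and per-element properties.
#' @export
assemble_system <- function(mesh, props, acq) {
  stopifnot(inherits(mesh, "dot_mesh"), inherits(acq, "acquisition_config"))
  e <- mesh$elements
  nN <- nrow(mesh$nodes); nE <- nrow(e)

  if (!is.null(props$mu_a) && is.numeric(props$mu_a)) {
    # nodal property fields
    stopifnot(length(props$mu_a) == nN, length(props$mu_s_prime) == nN)
    mu_a_e <- rowMeans(matrix(props$mu_a[e], nE, 3L))
    mu_s_e <- rowMeans(matrix(props$mu_s_prime[e], nE, 3L))
  } else {
    # region-wise properties
    if (length(props) < mesh$n_regions)
      stop("properties missing for ", mesh$n_regions - length(props),
           " region(s)")
    for (p in props) stopifnot(inherits(p, "optical_properties"))
    mu_a_r <- vapply(props, `[[`, numeric(1), "mu_a")
    mu_s_r <- vapply(props, `[[`, numeric(1), "mu_s_prime")
    mu_a_e <- mu_a_r[mesh$region + 1L]
    mu_s_e <- mu_s_r[mesh$region + 1L]
  }
  D_e <- 1 / (3 * (mu_a_e + mu_s_e))

  n <- mesh$nodes
  x1 <- n[e[, 1], 1]; y1 <- n[e[, 1], 2]
  x2 <- n[e[, 2], 1]; y2 <- n[e[, 2], 2]
  x3 <- n[e[, 3], 1]; y3 <- n[e[, 3], 2]
  area <- 0.5 * ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
  # P1 gradient coefficients
  b1 <- y2 - y3; b2 <- y3 - y1; b3 <- y1 - y2
  c1 <- x3 - x2; c2 <- x1 - x3; c3 <- x2 - x1
  B <- cbind(b1, b2, b3); C <- cbind(c1, c2, c3)

  ii <- jj <- integer(9L * nE)
  ss <- mm <- numeric(9L * nE)
  k <- 0L
  for (a in 1:3) for (b in 1:3) {
    idx <- k * nE + seq_len(nE)
    ii[idx] <- e[, a]; jj[idx] <- e[, b]
    ss[idx] <- D_e * (B[, a] * B[, b] + C[, a] * C[, b]) / (4 * area)
    mm[idx] <- mu_a_e * area / 12 * (1 + (a == b))
    k <- k + 1L
  }
  K_re <- Matrix::sparseMatrix(i = ii, j = jj, x = ss + mm,
                               dims = c(nN, nN))
  # mass matrix with unit coefficient (for the -i omega / c term)
  mm0 <- numeric(9L * nE); k <- 0L
  for (a in 1:3) for (b in 1:3) {
    mm0[k * nE + seq_len(nE)] <- area / 12 * (1 + (a == b))
    k <- k + 1L
  }
  M_unit <- Matrix::sparseMatrix(i = ii, j = jj, x = mm0, dims = c(nN, nN))
  K_im <- -(acq$omega / acq$c_medium) * M_unit

  # Robin boundary term: (1/(2A)) * edge-mass over the boundary polygon
  bn <- mesh$boundary
  nb <- length(bn)
  nxt <- c(bn[-1L], bn[1L])
  len <- sqrt(rowSums((mesh$nodes[nxt, , drop = FALSE] -
                       mesh$nodes[bn, , drop = FALSE])^2))
  coefA <- 1 / (2 * acq$boundary_coefficient)
  bi <- c(bn, nxt, bn, nxt)
  bj <- c(bn, nxt, nxt, bn)
  bx <- coefA * c(len / 3, len / 3, len / 6, len / 6)
  K_re <- K_re + Matrix::sparseMatrix(i = bi, j = bj, x = bx,
                                      dims = c(nN, nN))

  structure(
    list(K_re = K_re, K_im = K_im, mesh = mesh, acq = acq,
         mu_a_e = mu_a_e, mu_s_e = mu_s_e, D_e = D_e, area = area,
         grad_b = B, grad_c = C),
    class = "dot_system"
  )
}

# Solve K Phi = S for a complex sparse K via the equivalent real 2N system.
# `loads` is a real or complex N x k matrix; returns a complex N x k matrix.
# One sparse LU factorization serves all right-hand sides.
solve_system <- function(system, loads) {
  loads <- as.matrix(loads)
  nN <- nrow(system$K_re)
  M2 <- rbind(cbind(system$K_re, -system$K_im),
              cbind(system$K_im, system$K_re))
  rhs <- rbind(Re(loads), Im(loads))
  sol <- as.matrix(Matrix::solve(M2, rhs))
  out <- sol[seq_len(nN), , drop = FALSE] +
    1i * sol[nN + seq_len(nN), , drop = FALSE]
  if (any(!is.finite(Re(out))))
    stop("forward solve failed (singular or nonphysical system)")
  out
}

# Point-load vector(s): each point is distributed to the vertices of its
# containing triangle with barycentric weights, so the source position is
# exact on any mesh.
point_loads <- function(mesh, pts) {
  loc <- locate_points(mesh, pts)
  if (anyNA(loc$element)) stop("source point outside the mesh")
  nN <- nrow(mesh$nodes)
  L <- matrix(0, nN, nrow(pts))
  for (p in seq_len(nrow(pts))) {
    vid <- mesh$elements[loc$element[p], ]
    L[vid, p] <- L[vid, p] + loc$weights[p, ]
  }
  L
}

# Physical source positions: one transport length (1/mu_s' of the background)
# radially inside each boundary source angle.
source_points <- function(mesh, acq, mu_s_bg) {
  th <- source_angles(acq)
  depth <- 1 / mu_s_bg
  r <- max(mesh$radius_mm - depth, 0.5 * mesh$radius_mm)
  cbind(r * cos(th), r * sin(th))
}

#' Solve the forward problem for one or all sources
#'
#' Places an isotropic unit point source one transport length inside the
#' boundary at each requested source angle and solves the FEM system. A
#' single factorization is reused across all right-hand sides.
#'
#' @param system A `dot_system` from [assemble_system()].
#' @param source_index 1-based source index, or `NULL` for all sources.
#' @return A complex matrix of nodal fluence values, one column per source.
#' @export
solve_forward <- function(system, source_index = NULL) {
  acq <- system$acq
  mu_s_bg <- background_mu_s(system)
  pts <- source_points(system$mesh, acq, mu_s_bg)
  if (!is.null(source_index)) {
    stopifnot(source_index >= 1L, source_index <= acq$n_sources)
    pts <- pts[source_index, , drop = FALSE]
  }
  solve_system(system, point_loads(system$mesh, pts))
}

background_mu_s <- function(system) {
  bg <- system$mesh$region == 0L
  if (any(bg)) mean(system$mu_s_e[bg]) else mean(system$mu_s_e)
}

#' Sample boundary measurements from forward fields
#'
#' For source `i`, reads the complex fluence at the `m - 1` detector
#' positions (all source angles except `i`), ordered by increasing angular
#' offset from the source. Readings are linearly interpolated in angle
#' between the two adjacent boundary nodes; amplitude is `|Phi|` and phase is
#' the principal argument in (-pi, pi].
#'
#' @param fields Complex nodal field matrix with one column per source (from
#'   [solve_forward()] with `source_index = NULL`).
#' @param mesh The `dot_mesh` the fields were computed on.
#' @param acq The [acquisition_config()].
#' @return A `boundary_data` object: `amplitude` and `phase` matrices of
#'   shape `m x (m-1)`, `normalized = FALSE`, plus the layout.
#' @export
sample_boundary <- function(fields, mesh, acq) {
  m <- acq$n_sources
  stopifnot(ncol(fields) == m)
  bn <- mesh$boundary
  ang_b <- atan2(mesh$nodes[bn, 2], mesh$nodes[bn, 1]) %% (2 * pi)
  # boundary nodes are ordered CCW from angle 0 by construction
  spacing <- 2 * pi / length(bn)
  det_ang <- source_angles(acq)
  # interpolation weights for each detector angle
  pos <- det_ang / spacing
  i0 <- floor(pos)
  w1 <- 1 - (pos - i0)
  idx1 <- (as.integer(i0) %% length(bn)) + 1L
  idx2 <- (as.integer(i0 + 1) %% length(bn)) + 1L
  gap1 <- abs(ang_b[idx1] - det_ang); gap1 <- pmin(gap1, 2 * pi - gap1)
  gap2 <- abs(ang_b[idx2] - det_ang); gap2 <- pmin(gap2, 2 * pi - gap2)
  gap <- pmin(gap1, gap2)
  if (any(gap > pi / m))
    stop("mesh boundary too coarse for the detector layout")
  readings <- w1 * fields[bn[idx1], , drop = FALSE] +
    (1 - w1) * fields[bn[idx2], , drop = FALSE]  # m positions x m sources
  amplitude <- matrix(0, m, m - 1L)
  phase <- matrix(0, m, m - 1L)
  for (i in seq_len(m)) {
    dets <- ((i - 1L + seq_len(m - 1L)) %% m) + 1L  # increasing offset
    z <- readings[dets, i]
    amplitude[i, ] <- Mod(z)
    phase[i, ] <- Arg(z)
  }
  structure(
    list(amplitude = amplitude, phase = phase, n_sources = m,
         n_detectors = m - 1L, normalized = FALSE, noisy = FALSE,
         norm_stats = NULL),
    class = "boundary_data"
  )
}

#' @export
print.boundary_data <- function(x, ...) {
  cat(sprintf("boundary_data: %d x %d (%s%s)\n", x$n_sources, x$n_detectors,
              if (x$noisy) "noisy" else "clean",
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Add measurement noise to boundary data
#'
#' Amplitudes are perturbed multiplicatively by `1 + eps` with
#' `eps ~ N(0, level^2)`; phases are perturbed additively by
#' `N(0, (level * sd(phase))^2)`, scaling the phase noise to the spread of
#' the phase channel. Deterministic under a fixed seed.
#'
#' @param data Un-normalized `boundary_data`.
#' @param level Relative noise standard deviation (>= 0); 0.15 is the
#'   reference setting.
#' @param seed Integer seed.
#' @return Noisy `boundary_data`.
#' @export
add_noise <- function(data, level = 0.15, seed = 1L) {
  stopifnot(inherits(data, "boundary_data"))
  if (data$normalized) stop("add noise before normalization")
  if (level < 0) stop("noise level must be >= 0")
  if (level == 0) return(data)
  n <- length(data$amplitude)
  with_local_seed(seed, {
    eps_a <- stats::rnorm(n, 0, level)
    eps_p <- stats::rnorm(n, 0, level * stats::sd(as.vector(data$phase)))
    data$amplitude <- data$amplitude * (1 + eps_a)
    data$phase <- data$phase + eps_p
  })
  data$noisy <- TRUE
  data
}

#' Min-max normalize boundary data
#'
#' Maps each channel (amplitude, phase) through `(x - min) / (max - min)`.
#' With `stats = NULL` the statistics are computed from the data itself (the
#' training convention: statistics come from the training split and are
#' frozen); when precomputed `stats` are supplied, values falling outside the
#' training range are clipped to \[0, 1\].
#'
#' @param data Un-normalized `boundary_data`.
#' @param stats Optional list with `amp_min`, `amp_max`, `phase_min`,
#'   `phase_max` from a previous call.
#' @return Normalized `boundary_data` with `norm_stats` recorded.
#' @export
normalize_minmax <- function(data, stats = NULL) {
  stopifnot(inherits(data, "boundary_data"))
  if (data$normalized) stop("data already normalized")
  clip <- !is.null(stats)
  if (is.null(stats)) {
    stats <- list(amp_min = min(data$amplitude), amp_max = max(data$amplitude),
                  phase_min = min(data$phase), phase_max = max(data$phase))
  }
  if (stats$amp_max <= stats$amp_min || stats$phase_max <= stats$phase_min)
    stop("degenerate channel: max equals min")
  data$amplitude <- (data$amplitude - stats$amp_min) /
    (stats$amp_max - stats$amp_min)
  data$phase <- (data$phase - stats$phase_min) /
    (stats$phase_max - stats$phase_min)
  if (clip) {
    data$amplitude <- clamp(data$amplitude, 0, 1)
    data$phase <- clamp(data$phase, 0, 1)
  }
  data$normalized <- TRUE
  data$norm_stats <- stats
  data
}

#' Simulate noisy boundary data for one phantom
#'
#' Convenience wrapper: mesh, assemble, solve all sources, sample the
#' boundary and (optionally) add noise.
#'
#' @param spec A [phantom_spec()].
#' @param acq An [acquisition_config()]; its `frequency_mhz` is overridden by
#'   the phantom's own frequency.
#' @param target_edge_mm Mesh resolution passed to [build_mesh()].
#' @param noise_seed Seed for [add_noise()]; `NULL` for noise-free data.
#' @return Un-normalized `boundary_data`.
#' @export
simulate_boundary <- function(spec, acq, target_edge_mm = spec$diameter_mm / 12,
                              noise_seed = NULL) {
  acq2 <- acquisition_config(acq$n_sources, spec$frequency_mhz,
                             acq$refractive_index, acq$boundary_coefficient,
                             acq$noise_level)
  mesh <- build_mesh(spec, target_edge_mm)
  props <- c(list(spec$background), lapply(spec$inclusions, `[[`, "props"))
  sys <- assemble_system(mesh, props, acq2)
  fields <- solve_forward(sys)
  bd <- sample_boundary(fields, mesh, acq2)
  if (!is.null(noise_seed)) bd <- add_noise(bd, acq2$noise_level, noise_seed)
  bd
}
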