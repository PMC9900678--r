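#' Triangulate a circular phantom
#'
#' Builds a structured P1 triangulation of the phantom disk from concentric
#' rings of nodes (ring `i` of `R` carries `6 i` nodes, giving near-equilateral
#' triangles). The effective edge length is the requested target, capped so
#' that the circumference of the smallest inclusion is resolved by at least 8
#' element edges. Elements are labeled by the region their centroid falls in:
#' 0 for background, k for inclusion k.
#'
#' @param spec A [phantom_spec()].
#' @param target_edge_mm Requested element edge length, mm.
#' @param min_rings Minimum number of node rings across the radius.
#' @return A `dot_mesh`: `nodes` (N x 2, mm), `elements` (E x 3 vertex
#'   indices, positively oriented), `region` (length E), `boundary` (indices
#'   of boundary nodes ordered counter-clockwise starting at angle 0),
#'   `radius_mm`, `edge_mm`.
#' @export
build_mesh <- function(spec, target_edge_mm = spec$diameter_mm / 12,
                       min_rings = 4L) {
  stopifnot(inherits(spec, "phantom_spec"), target_edge_mm > 0)
  R <- spec$radius_mm
  h <- target_edge_mm
  if (length(spec$inclusions)) {
    r_min <- min(vapply(spec$inclusions, `[[`, numeric(1), "radius"))
    h <- min(h, 2 * pi * r_min / 8)
  }
  n_rings <- max(min_rings, as.integer(round(R / h)))
  dr <- R / n_rings

  nodes <- matrix(0, 1L + 3L * n_rings * (n_rings + 1L), 2L)
  ring_idx <- vector("list", n_rings)  # node indices per ring
  pos <- 1L
  for (i in seq_len(n_rings)) {
    ni <- 6L * i
    th <- 2 * pi * (seq_len(ni) - 1L) / ni
    idx <- pos + seq_len(ni)
    nodes[idx, ] <- cbind(i * dr * cos(th), i * dr * sin(th))
    ring_idx[[i]] <- idx
    pos <- pos + ni
  }

  # center fan
  tris <- matrix(0L, 0L, 3L)
  r1 <- ring_idx[[1L]]
  tris <- rbind(tris, cbind(1L, r1, c(r1[-1L], r1[1L])))
  # annuli: merge ring i (inner) with ring i+1 (outer) by angle
  for (i in seq_len(n_rings - 1L)) {
    tris <- rbind(tris, triangulate_annulus(ring_idx[[i]], ring_idx[[i + 1L]]))
  }

  # enforce positive orientation
  a <- nodes[tris[, 1L], ]; b <- nodes[tris[, 2L], ]; c2 <- nodes[tris[, 3L], ]
  s <- (b[, 1] - a[, 1]) * (c2[, 2] - a[, 2]) -
       (b[, 2] - a[, 2]) * (c2[, 1] - a[, 1])
  flip <- s < 0
  if (any(flip)) tris[flip, 2:3] <- tris[flip, 3:2]

  cx <- (nodes[tris[, 1], 1] + nodes[tris[, 2], 1] + nodes[tris[, 3], 1]) / 3
  cy <- (nodes[tris[, 1], 2] + nodes[tris[, 2], 2] + nodes[tris[, 3], 2]) / 3
  region <- integer(nrow(tris))
  for (k in seq_along(spec$inclusions)) {
    inc <- spec$inclusions[[k]]
    inside <- (cx - inc$center[1])^2 + (cy - inc$center[2])^2 <= inc$radius^2
    region[inside] <- k
  }

  structure(
    list(nodes = nodes, elements = tris, region = region,
         boundary = ring_idx[[n_rings]], radius_mm = R, edge_mm = dr,
         n_regions = length(spec$inclusions) + 1L),
    class = "dot_mesh"
  )
}

# Triangulate the annulus between two node rings by walking both rings in
# angle order (two-pointer merge with wraparound). `inner`, `outer` are node
# index vectors ordered counter-clockwise starting at angle 0. Produces
# exactly length(inner) + length(outer) triangles.
triangulate_annulus <- function(inner, outer) {
  na <- length(inner); nb <- length(outer)
  ang_a <- 2 * pi * (0:na) / na  # angle of node a, plus the wrap at 2*pi
  ang_b <- 2 * pi * (0:nb) / nb
  ia <- function(k) inner[(k - 1L) %% na + 1L]
  ib <- function(k) outer[(k - 1L) %% nb + 1L]
  tris <- matrix(0L, na + nb, 3L)
  a <- 1L; b <- 1L; t <- 0L
  while (a <= na || b <= nb) {
    t <- t + 1L
    adv_b <- (b <= nb) && (a > na || ang_b[b + 1L] <= ang_a[a + 1L])
    if (adv_b) {
      tris[t, ] <- c(ia(a), ib(b), ib(b + 1L)); b <- b + 1L
    } else {
      tris[t, ] <- c(ia(a), ib(b), ia(a + 1L)); a <- a + 1L
    }
  }
  tris[seq_len(t), , drop = FALSE]
}

# Signed areas of all elements.
element_areas <- function(mesh) {
  n <- mesh$nodes; e <- mesh$elements
  x1 <- n[e[, 1], 1]; y1 <- n[e[, 1], 2]
  x2 <- n[e[, 2], 1]; y2 <- n[e[, 2], 2]
  x3 <- n[e[, 3], 1]; y3 <- n[e[, 3], 2]
  0.5 * ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
}

# Locate points in the mesh: returns element index and barycentric weights
# for each row of `pts` (NA element for points outside the triangulation).
locate_points <- function(mesh, pts) {
  n <- mesh$nodes; e <- mesh$elements
  np <- nrow(pts)
  elem <- rep(NA_integer_, np)
  w <- matrix(NA_real_, np, 3L)
  x1 <- n[e[, 1], 1]; y1 <- n[e[, 1], 2]
  x2 <- n[e[, 2], 1]; y2 <- n[e[, 2], 2]
  x3 <- n[e[, 3], 1]; y3 <- n[e[, 3], 2]
  det <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
  for (p in seq_len(np)) {
    px <- pts[p, 1]; py <- pts[p, 2]
    l1 <- ((y2 - y3) * (px - x3) + (x3 - x2) * (py - y3)) / det
    l2 <- ((y3 - y1) * (px - x3) + (x1 - x3) * (py - y3)) / det
    l3 <- 1 - l1 - l2
    tol <- -1e-9
    hit <- which(l1 >= tol & l2 >= tol & l3 >= tol)
    if (length(hit)) {
      # prefer the element with the most interior barycentrics
      best <- hit[which.max(pmin(l1[hit], l2[hit], l3[hit]))]
      elem[p] <- best
      w[p, ] <- clamp(c(l1[best], l2[best], l3[best]), 0, 1)
      w[p, ] <- w[p, ] / sum(w[p, ])
    }
  }
  list(element = elem, weights = w)
}

#' @export
print.dot_mesh <- function(x, ...) {
  cat(sprintf("dot_mesh: %d nodes, %d elements, %d boundary nodes, edge %.3g mm\n",
              nrow(x$nodes), nrow(x$elements), length(x$boundary), x$edge_mm))
  invisible(x)
}

#' Write a mesh as plain node/element text files
#'
#' Nodes are written as `x y` lines and elements as `i j k region` lines.
#'
#' @param mesh A `dot_mesh`.
#' @param nodes_file,elements_file Output paths.
#' @export
write_mesh <- function(mesh, nodes_file, elements_file) {
  utils::write.table(mesh$nodes, nodes_file, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(cbind(mesh$elements, mesh$region), elements_file,
                     row.names = FALSE, col.names = FALSE)
  invisible(NULL)
}
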