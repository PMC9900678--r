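test_that("disk triangulation covers the phantom area and is well oriented", {
  spec <- phantom_spec(60, optical_properties(0.01, 1))
  mesh <- build_mesh(spec, 3)
  areas <- dotrecon:::element_areas(mesh)
  expect_true(all(areas > 0))
  expect_lt(abs(sum(areas) - pi * 30^2) / (pi * 30^2), 0.01)
  # boundary nodes on the circle, ordered counter-clockwise from angle ~0
  r <- sqrt(rowSums(mesh$nodes[mesh$boundary, ]^2))
  expect_equal(r, rep(30, length(r)), tolerance = 1e-9)
  ang <- atan2(mesh$nodes[mesh$boundary, 2],
               mesh$nodes[mesh$boundary, 1]) %% (2 * pi)
  expect_lt(ang[1], 1e-8)
  expect_false(is.unsorted(ang))
})

test_that("inclusion-labeled elements lie inside their disks", {
  # two-inclusion geometry with the 11.25 / 6.77 mm reference radii
  spec <- phantom_spec(70, optical_properties(0.01, 1), list(
    list(center = c(10, 5), radius = 11.25,
         props = optical_properties(0.02, 1.5)),
    list(center = c(-15, -10), radius = 6.77,
         props = optical_properties(0.03, 2))))
  mesh <- build_mesh(spec, 6)
  for (k in 1:2) {
    e <- mesh$elements[mesh$region == k, , drop = FALSE]
    expect_gt(nrow(e), 0)
    cx <- rowMeans(matrix(mesh$nodes[e, 1], nrow(e), 3))
    cy <- rowMeans(matrix(mesh$nodes[e, 2], nrow(e), 3))
    inc <- spec$inclusions[[k]]
    expect_true(all((cx - inc$center[1])^2 + (cy - inc$center[2])^2 <=
                      inc$radius^2))
  }
})

test_that("each inclusion circle is resolved by at least 8 element edges", {
  spec <- phantom_spec(150, optical_properties(0.01, 1), list(
    list(center = c(30, 0), radius = 3,
         props = optical_properties(0.02, 1.5))))
  mesh <- build_mesh(spec)  # default edge is capped by the inclusion size
  inc <- spec$inclusions[[1]]
  e <- mesh$elements
  edges <- rbind(e[, 1:2], e[, 2:3], e[, c(3, 1)])
  d1 <- sqrt((mesh$nodes[edges[, 1], 1] - inc$center[1])^2 +
               (mesh$nodes[edges[, 1], 2] - inc$center[2])^2)
  d2 <- sqrt((mesh$nodes[edges[, 2], 1] - inc$center[1])^2 +
               (mesh$nodes[edges[, 2], 2] - inc$center[2])^2)
  crossing <- (d1 - inc$radius) * (d2 - inc$radius) < 0
  expect_gte(sum(crossing) / 2, 8)  # each edge counted twice
})

test_that("invalid geometries are rejected", {
  bg <- optical_properties(0.01, 1)
  inc <- function(c1, r) list(center = c1, radius = r,
                              props = optical_properties(0.02, 1.5))
  expect_error(phantom_spec(60, bg, list(inc(c(0, 0), 10), inc(c(5, 0), 10))),
               "overlap")
  expect_error(phantom_spec(60, bg, list(inc(c(25, 0), 10))), "boundary")
})

test_that("point location returns exact barycentric interpolants", {
  spec <- phantom_spec(50, optical_properties(0.01, 1))
  mesh <- build_mesh(spec, 5)
  # a linear field is reproduced exactly by P1 interpolation
  f <- 2 + 0.3 * mesh$nodes[, 1] - 0.7 * mesh$nodes[, 2]
  pts <- cbind(c(0, 3.7, -10.1), c(0, -2.2, 8.3))
  loc <- dotrecon:::locate_points(mesh, pts)
  vals <- sapply(seq_len(3), function(p) {
    vid <- mesh$elements[loc$element[p], ]
    sum(f[vid] * loc$weights[p, ])
  })
  expect_equal(vals, 2 + 0.3 * pts[, 1] - 0.7 * pts[, 2], tolerance = 1e-10)
})
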