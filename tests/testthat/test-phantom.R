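test_that("sampled specs satisfy every invariant and are seed-reproducible", {
  for (seed in c(1, 77, 4242)) {
    for (k in 1:2) {
      sp <- sample_spec(seed, k)
      expect_gte(sp$diameter_mm, 60); expect_lte(sp$diameter_mm, 150)
      expect_gte(sp$frequency_mhz, 10); expect_lte(sp$frequency_mhz, 100)
      expect_gte(sp$background$mu_a, 0.005)
      expect_lte(sp$background$mu_a, 0.03)
      expect_gte(sp$background$mu_s_prime, 0.05)
      expect_lte(sp$background$mu_s_prime, 3)
      expect_length(sp$inclusions, k)
      for (inc in sp$inclusions) {
        expect_lt(sqrt(sum(inc$center^2)) + inc$radius, sp$radius_mm)
        expect_gte(inc$props$mu_a / sp$background$mu_a, 1.2 - 1e-9)
        expect_lte(inc$props$mu_a / sp$background$mu_a, 4 + 1e-9)
      }
      if (k == 2) {
        d <- sqrt(sum((sp$inclusions[[1]]$center -
                         sp$inclusions[[2]]$center)^2))
        expect_gt(d, sp$inclusions[[1]]$radius + sp$inclusions[[2]]$radius)
      }
      expect_identical(sample_spec(seed, k), sp)
    }
  }
})

test_that("diameter draws fill the configured uniform range", {
  d <- vapply(seq_len(10000), function(s) sample_spec(s, 1)$diameter_mm,
              numeric(1))
  # uniform order statistics on [60, 150]
  expect_lt(min(d), 62)
  expect_gt(max(d), 148)
})

test_that("rasterization assigns pixels by center-point membership", {
  bg <- optical_properties(0.01, 1)
  sp0 <- phantom_spec(64, bg)
  img0 <- rasterize(sp0)
  expect_equal(img0$pixel_mm, 1)
  expect_true(all(img0$mu_a[img0$mask] == 0.01))
  expect_true(all(img0$mu_a[!img0$mask] == 0))

  # centered inclusion: digitized-disk pixel count within a perimeter band
  sp1 <- phantom_spec(64, bg, list(
    list(center = c(0, 0), radius = 10,
         props = optical_properties(0.03, 1))))
  img1 <- rasterize(sp1)
  n_inc <- sum(img1$mu_a == 0.03)
  exact <- pi * 10^2
  perim <- 2 * pi * 10 + 4
  expect_lt(abs(n_inc - exact), perim)

  # reference test case: 50 mm phantom, 5 mm inclusion -> ~128 pixels
  sp2 <- phantom_spec(50, bg, list(
    list(center = c(5, -3), radius = 5,
         props = optical_properties(0.03, 1))))
  img2 <- rasterize(sp2)
  n2 <- sum(img2$mu_a == 0.03)
  px_area <- (50 / 64)^2
  expect_lt(abs(n2 - pi * 25 / px_area), 2 * pi * 5 / (50 / 64) + 4)
})

test_that("ground-truth rasters contain only region property values", {
  sp <- sample_spec(9, 2)
  img <- rasterize(sp)
  vals <- sort(unique(as.vector(img$mu_a)))
  expect_true(length(vals) %in% c(3L, 4L))  # 0, background, 1-2 inclusions
  expect_true(0 %in% vals)
  expect_true(sp$background$mu_a %in% vals)
})
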