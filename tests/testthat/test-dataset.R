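test_that("split sizes follow largest-remainder rounding", {
  m <- dataset_manifest(20)
  expect_equal(m$split_sizes, c(17L, 2L, 1L))
  expect_equal(sum(m$class_sizes), 20L)
  m2 <- dataset_manifest(10000)
  expect_equal(m2$split_sizes, c(8500L, 1000L, 500L))
  expect_equal(dotrecon:::largest_remainder(7, c(0.5, 0.3, 0.2)),
               c(4L, 2L, 1L))
})

test_that("generated datasets have the right shapes, classes and ranges", {
  ds <- tiny_dataset()  # 12 samples, 16 x 15
  expect_equal(dim(ds$amplitude), c(12L, 16L, 15L))
  expect_equal(dim(ds$gt_mu_a), c(12L, 64L, 64L))
  expect_equal(as.vector(table(ds$split)), c(10L, 1L, 1L))
  expect_equal(sort(as.vector(table(ds$n_inclusions))),
               sort(ds$manifest$class_sizes))
  expect_true(all(ds$amplitude_norm >= 0 & ds$amplitude_norm <= 1))
  expect_true(all(ds$phase_norm >= 0 & ds$phase_norm <= 1))
  # ground truth stays physical
  expect_gt(max(ds$gt_mu_a), 0.005)
  expect_lt(max(ds$gt_mu_a), 0.03 * 4 + 1e-9)
  # normalization statistics come from the training split only
  tr <- ds$split == "train"
  expect_equal(ds$norm_stats$amp_max, max(ds$amplitude[tr, , ]))
})

test_that("dataset generation is bit-reproducible from the global seed", {
  ds1 <- generate_dataset(dataset_manifest(6, seed = 3),
                          acquisition_config(16))
  ds2 <- generate_dataset(dataset_manifest(6, seed = 3),
                          acquisition_config(16))
  expect_identical(ds1$amplitude, ds2$amplitude)
  expect_identical(ds1$gt_mu_a, ds2$gt_mu_a)
  ds3 <- generate_dataset(dataset_manifest(6, seed = 4),
                          acquisition_config(16))
  expect_false(identical(ds1$amplitude, ds3$amplitude))
})

test_that("dataset container round-trips through its archive format", {
  ds <- tiny_dataset()
  path <- tempfile(fileext = ".rds")
  write_dataset(ds, path)
  expect_identical(read_dataset(path), ds)
  unlink(path)
})
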