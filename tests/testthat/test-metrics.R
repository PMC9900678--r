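test_that("MSE follows its closed forms", {
  a <- matrix(0, 64, 64); b <- matrix(1, 64, 64)
  expect_equal(metric_mse(a, a), 0)
  expect_equal(metric_mse(a, b), 1)
  cb <- matrix(rep(c(0, 1), length.out = 64 * 64), 64, 64)
  expect_equal(metric_mse(cb, 1 - cb), 1)  # every pixel differs by 1
  expect_error(metric_mse(a, matrix(0, 32, 32)), "shape")
})

test_that("PSNR follows 10 log10(max^2 / MSE) and its invariances", {
  x <- matrix(stats::runif(64 * 64), 64)
  x[1] <- 1  # pin the peak
  y <- x + 0.1
  expect_equal(metric_psnr(x, x + sqrt(0.01)), 20)   # max 1, MSE 0.01
  expect_equal(metric_psnr(x, x + 1), 0)             # MSE = max^2
  expect_equal(metric_psnr(10 * x, 10 * y), metric_psnr(x, y))
  expect_identical(metric_psnr(x, x), Inf)
  # strictly decreasing in MSE for fixed peak
  p <- vapply(c(0.01, 0.05, 0.2), function(s) metric_psnr(x, x + s),
              numeric(1))
  expect_true(all(diff(p) < 0))
  expect_error(metric_psnr(matrix(0, 2, 2), matrix(0, 2, 2)), "max")
})

test_that("global SSIM matches the reference implementation to 1e-6", {
  # deterministic 15x15 image pair; expected value frozen from
  # scikit-image structural_similarity with a full-image uniform window,
  # population moments, K1 = 0.01, K2 = 0.02, data_range = 1
  i <- 1:15
  x <- ((outer(i, i) * 7) %% 29) / 28
  y <- ((outer(i, i) * 5 + 3) %% 31) / 30
  expect_equal(metric_ssim(x, y), -0.0172021799700376, tolerance = 1e-6)
})

test_that("SSIM identities: self-similarity, symmetry, structure loss", {
  set.seed(4)
  x <- matrix(stats::runif(64 * 64), 64)
  y <- matrix(stats::runif(64 * 64), 64)
  expect_equal(metric_ssim(x, x), 1, tolerance = 1e-12)
  expect_equal(metric_ssim(x, y), metric_ssim(y, x))
  expect_lt(metric_ssim(x, matrix(0, 64, 64)), 1)
  expect_gte(metric_ssim(x, y), -1)
  expect_lte(metric_ssim(x, y), 1)
  expect_error(ssim_config(c1 = 0), "c1 > 0")
})

test_that("evaluate_split reports per-sample metrics and aggregates", {
  set.seed(5)
  n <- 4
  truth <- array(stats::runif(n * 2 * 64 * 64, 0.001, 0.03),
                 c(n, 2, 64, 64))
  perfect <- truth
  rep1 <- evaluate_split(perfect, truth, "perfect")
  expect_equal(nrow(rep1$per_sample), n * 2)
  expect_equal(max(rep1$aggregate$ssim_max), 1)
  expect_equal(max(rep1$per_sample$mse), 0)

  noisy <- truth + array(stats::rnorm(length(truth), 0, 0.002), dim(truth))
  rep2 <- evaluate_split(noisy, truth, "noisy")
  expect_true(all(rep2$per_sample$ssim < 1))
  expect_identical(rep2$per_sample,
                   evaluate_split(noisy, truth, "noisy")$per_sample)
  expect_error(evaluate_split(truth[0, , , , drop = FALSE],
                              truth[0, , , , drop = FALSE]), "empty")

  # CSV + JSON serialization round-trip
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_report(rep2, csv, js)
  back <- utils::read.csv(csv)
  expect_equal(nrow(back), n * 2)
  expect_true(all(c("mse", "psnr_db", "ssim") %in% names(back)))
  unlink(c(csv, js))
})
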