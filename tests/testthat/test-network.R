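test_that("width reconciliation is exact and matches the frozen defaults", {
  w <- reconcile_widths()
  expect_identical(w, dotrecon:::WIDTHS_DEFAULT)
  expect_equal(w$eff2_out + w$escalate_conv, 24L)
  # batch-norm channels across the conv stack total 402
  expect_equal(16L + sum(w$eff1) + sum(w$eff2) + w$escalate_conv, 402L)
})

test_that("network configuration enforces the architecture constraints", {
  cfg <- network_config(16L)
  expect_equal(cfg$encompass, c(64L, 128L, 256L, 4096L))
  expect_equal(cfg$flat, 8L * 7L * 24L)          # 1344 for 16 x 15
  expect_equal(network_config(36L)$flat, 18L * 17L * 24L)
  expect_equal(network_config(20L)$flat, 10L * 9L * 24L)
  expect_error(network_config(16L, 14L), "m - 1")
  bad <- dotrecon:::WIDTHS_DEFAULT
  bad$escalate_conv <- 10L
  expect_error(network_config(16L, widths = bad), "24")
})

test_that("parameter counts reproduce the published totals exactly", {
  counts <- vapply(c(16L, 20L, 36L), function(m) {
    pc <- count_parameters(build_network(network_config(m), seed = 1))
    c(pc$trainable, pc$nontrainable)
  }, numeric(2))
  expect_equal(counts[1, ], c(1258308, 1310532, 1642308))
  expect_equal(counts[2, ], rep(9892, 3))
  # layout-dependent differences come entirely from the flatten term
  expect_equal(counts[1, 2] - counts[1, 1], (10 * 9 - 8 * 7) * 24 * 64)
  expect_equal(counts[1, 3] - counts[1, 1], (18 * 17 - 8 * 7) * 24 * 64)
  # breakdown sums to the totals
  pc <- count_parameters(build_network(network_config(16L)))
  expect_equal(sum(pc$breakdown$trainable), pc$trainable)
  expect_equal(sum(pc$breakdown$nontrainable), pc$nontrainable)
})

test_that("forward pass maps boundary-shaped input to two 64x64 maps", {
  set.seed(10)
  net <- build_network(network_config(4L), seed = 2)
  x <- matrix(stats::runif(2 * 4 * 3 * 4), 2)
  out <- dotrecon:::net_forward(net, x)$y
  expect_equal(dim(out), c(4096L, 4L))
  expect_true(all(is.finite(out)))
  expect_true(all(out >= 0))  # final ReLU
})

test_that("analytic gradients agree with finite differences", {
  set.seed(42)
  net <- build_network(network_config(4L), seed = 3)
  N <- 2
  x <- matrix(stats::runif(2 * 4 * 3 * 2 * N), 2)
  tgt <- matrix(stats::runif(4096 * 2 * N), 4096)
  loss <- function(nn) mean((dotrecon:::net_forward(nn, x,
                                                    training = TRUE)$y -
                               tgt)^2)
  fw <- dotrecon:::net_forward(net, x, training = TRUE)
  grads <- dotrecon:::net_backward(net, fw$caches,
                                   2 * (fw$y - tgt) / (4096 * 2 * N))
  set.seed(7)
  for (nm in c("feature.c1.W", "efficient1.b2.W", "efficient2.b3.W",
               "efficient1.b4.W", "escalate.conv.W", "encompass.d1.W",
               "encompass.d4.W", "encompass.d2.g", "efficient2.b1.b")) {
    p <- net$par[[nm]]
    i <- sample(length(p), 1)
    eps <- 1e-6 * max(1, abs(p[i]))
    n2 <- net
    n2$par[[nm]][i] <- p[i] + eps; f1 <- loss(n2)
    n2$par[[nm]][i] <- p[i] - eps; f0 <- loss(n2)
    fd <- (f1 - f0) / (2 * eps)
    expect_equal(grads[[nm]][i], fd, tolerance = 1e-3,
                 label = paste("gradient of", nm))
  }
})

test_that("the network memorizes a 4-sample training set", {
  # capacity check: driven toward interpolation of 4 samples, the training
  # loss collapses by more than an order of magnitude from its starting
  # value (a raised learning rate and no weight decay make the trend
  # visible within a short schedule)
  ds <- tiny_dataset()
  ds$split <- factor(rep(c("train", "test"),
                         c(4L, ds$manifest$n_samples - 4L)),
                     levels = c("train", "val", "test"))
  net <- build_network(network_config(16L), seed = 4)
  tr <- train_network(net, ds, train_config(epochs = 60, batch_size = 4,
                                            lr = 1e-2, weight_decay = 0,
                                            seed = 6))
  final <- tail(tr$history$train_loss, 1)
  expect_lt(final, 0.05)
  expect_lt(final, 0.1 * tr$history$train_loss[1])
})

test_that("training is reproducible under a fixed seed", {
  ds <- tiny_dataset()
  net <- build_network(network_config(16L), seed = 8)
  h1 <- train_network(net, ds, train_config(epochs = 1, seed = 9))$history
  h2 <- train_network(net, ds, train_config(epochs = 1, seed = 9))$history
  expect_equal(h1$train_loss[1], h2$train_loss[1], tolerance = 1e-6)
})

test_that("prediction denormalizes to physical units with the right shape", {
  ds <- tiny_dataset()
  net <- build_network(network_config(16L), seed = 11)
  pred <- predict_network(net, ds)  # untrained: plumbing contract
  expect_equal(dim(pred), c(1L, 2L, 64L, 64L))
  expect_true(all(is.finite(pred)))
  te <- split_idx(ds, "test")
  truth <- array(0, c(1, 2, 64, 64))
  truth[1, 1, , ] <- ds$gt_mu_a[te[1], , ]
  truth[1, 2, , ] <- ds$gt_mu_s[te[1], , ]
  rep <- evaluate_split(pred, truth, "untrained")
  expect_s3_class(rep, "metrics_report")
  # layout mismatch is rejected
  net36 <- build_network(network_config(36L), seed = 1)
  expect_error(predict_network(net36, ds), "layout")
})

test_that("checkpoints round-trip", {
  net <- build_network(network_config(16L), seed = 12)
  path <- tempfile(fileext = ".rds")
  write_checkpoint(net, path)
  expect_identical(read_checkpoint(path)$par, net$par)
  unlink(path)
})
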