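test_that("a tiny end-to-end experiment completes with both method reports", {
  cfg <- experiment_config(n_sources = 16L, n_samples = 50L, epochs = 5L,
                           tr_iter = 2L, n_tr_samples = 1L, seed = 21L)
  bundle <- run_experiment(cfg)
  expect_equal(bundle$status, "ok")
  expect_length(bundle$metrics, 2L)
  expect_s3_class(bundle$metrics$network, "metrics_report")
  expect_s3_class(bundle$metrics$tr, "metrics_report")
  expect_s3_class(bundle$param_counts, "param_count_report")
  expect_equal(bundle$param_counts$trainable, 1258308)
  expect_true(all(c("generate", "train", "predict", "reconstruct-tr") %in%
                    bundle$log$stage))
  # dataset reproducibility across runs with the same config + seed
  ds2 <- generate_dataset(dataset_manifest(50L, seed = 21L),
                          acquisition_config(16L))
  expect_identical(ds2$amplitude, bundle$dataset$amplitude)
})

test_that("trainable counts are ordered across the three layouts", {
  tr <- vapply(c(16L, 20L, 36L), function(m)
    count_parameters(build_network(network_config(m)))$trainable, numeric(1))
  expect_true(all(diff(tr) > 0))
})
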