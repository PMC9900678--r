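#' Experiment configuration
#'
#' Bundles every stage's settings for an end-to-end run: dataset generation,
#' network training, Tikhonov-regularized (TR) reconstruction of test
#' samples, and evaluation. One global seed deterministically drives all
#' stages.
#'
#' @param n_sources Source count `m` (16, 20 or 36 for the reference
#'   layouts).
#' @param n_samples Dataset size.
#' @param epochs Training epochs.
#' @param batch_size Training batch size.
#' @param lambda TR regularization parameter (`NULL` = automatic).
#' @param tr_iter TR Newton iterations.
#' @param n_tr_samples How many test samples to reconstruct with TR (the
#'   iterative baseline is much slower than the network).
#' @param noise_level Relative measurement noise.
#' @param seed Global seed.
#' @param out_dir Optional output directory for the result bundle.
#' @return An `experiment_config`.
#' @export
experiment_config <- function(n_sources = 16L, n_samples = 200L,
                              epochs = 20L, batch_size = 64L, lambda = NULL,
                              tr_iter = 6L, n_tr_samples = 2L,
                              noise_level = 0.15, seed = 1L,
                              out_dir = NULL) {
  structure(list(n_sources = as.integer(n_sources),
                 n_samples = as.integer(n_samples),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lambda = lambda, tr_iter = as.integer(tr_iter),
                 n_tr_samples = as.integer(n_tr_samples),
                 noise_level = noise_level, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "experiment_config")
}

#' Run an end-to-end reconstruction experiment
#'
#' Generates a synthetic dataset, trains the network, reconstructs the test
#' split with both the network and the TR baseline, and evaluates both with
#' MSE/PSNR/SSIM. Stage failures are caught: the bundle is returned with the
#' stages completed so far and `status` describing the failure.
#'
#' @param cfg An [experiment_config()].
#' @param verbose Print stage progress.
#' @return An `experiment_bundle`: `dataset`, `network`, `history`,
#'   `metrics` (list of `metrics_report`s), `param_counts`, `log` (stage
#'   timing data frame), `status` ("ok" or the failed stage).
#' @export
run_experiment <- function(cfg = experiment_config(), verbose = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  bundle <- list(config = cfg, metrics = list(), status = "ok")
  log <- data.frame(stage = character(), seconds = numeric())
  tick <- function(stage, expr) {
    t0 <- Sys.time()
    r <- expr
    log <<- rbind(log, data.frame(
      stage = stage, seconds = as.numeric(Sys.time() - t0, units = "secs")))
    if (verbose) message(sprintf("[%s] %.1f s", stage,
                                 log$seconds[nrow(log)]))
    r
  }
  result <- tryCatch({
    acq <- acquisition_config(cfg$n_sources, noise_level = cfg$noise_level)
    bundle$dataset <- tick("generate", generate_dataset(
      dataset_manifest(cfg$n_samples, seed = cfg$seed), acq))
    net <- build_network(network_config(cfg$n_sources), seed = cfg$seed)
    bundle$param_counts <- count_parameters(net)
    tr <- tick("train", train_network(
      net, bundle$dataset,
      train_config(epochs = cfg$epochs, batch_size = cfg$batch_size,
                   seed = cfg$seed + 1L)))
    bundle$network <- tr$net
    bundle$history <- tr$history

    te <- split_idx(bundle$dataset, "test")
    truth <- array(0, c(length(te), 2L, 64L, 64L))
    for (k in seq_along(te)) {
      truth[k, 1L, , ] <- bundle$dataset$gt_mu_a[te[k], , ]
      truth[k, 2L, , ] <- bundle$dataset$gt_mu_s[te[k], , ]
    }
    pred <- tick("predict", predict_network(bundle$network, bundle$dataset))
    bundle$metrics$network <- evaluate_split(pred, truth, "network")
    bundle$reconstructions <- pred

    n_tr <- min(cfg$n_tr_samples, length(te))
    if (n_tr > 0L) {
      bundle$tr_images <- tick("reconstruct-tr", {
        out <- array(0, c(n_tr, 2L, 64L, 64L))
        for (k in seq_len(n_tr)) {
          i <- te[k]
          sp <- bundle$dataset$specs[[i]]
          bd <- structure(list(
            amplitude = bundle$dataset$amplitude[i, , ],
            phase = bundle$dataset$phase[i, , ],
            n_sources = acq$n_sources, n_detectors = acq$n_detectors,
            normalized = FALSE, noisy = TRUE, norm_stats = NULL),
            class = "boundary_data")
          init <- optical_properties(sp$background$mu_a,
                                     sp$background$mu_s_prime)
          res <- reconstruct_tr(bd, sp, acq, init = init,
                                lambda = cfg$lambda,
                                max_iter = cfg$tr_iter)
          out[k, , , ] <- res$image
        }
        out
      })
      bundle$metrics$tr <- evaluate_split(
        bundle$tr_images, truth[seq_len(n_tr), , , , drop = FALSE], "TR")
    }
    bundle
  }, error = function(e) {
    bundle$status <- paste0("failed: ", conditionMessage(e))
    bundle
  })
  result$log <- log
  if (!is.null(cfg$out_dir) && result$status == "ok") {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    saveRDS(result, file.path(cfg$out_dir, "bundle.rds"))
    for (nm in names(result$metrics))
      write_report(result$metrics[[nm]],
                   file.path(cfg$out_dir, paste0("metrics_", nm, ".csv")),
                   file.path(cfg$out_dir, paste0("metrics_", nm, ".json")))
    utils::write.csv(result$log, file.path(cfg$out_dir, "log.csv"),
                     row.names = FALSE)
  }
  class(result) <- "experiment_bundle"
  result
}

#' @export
print.experiment_bundle <- function(x, ...) {
  cat(sprintf("experiment_bundle [%s]: %d samples, %d x %d layout\n",
              x$status, x$config$n_samples, x$config$n_sources,
              x$config$n_sources - 1L))
  for (nm in names(x$metrics)) {
    agg <- x$metrics[[nm]]$aggregate
    cat(sprintf("  %s: max SSIM mu_a %.3f, mean MSE mu_a %.4f\n", nm,
                agg$ssim_max[agg$channel == "mu_a"],
                agg$mse_mean[agg$channel == "mu_a"]))
  }
  invisible(x)
}
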