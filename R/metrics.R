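#' SSIM stabilization constants
#'
#' The structural-similarity constants on the \[0, 1\] intensity scale:
#' `c1 = (K1 L)^2` and `c2 = (K2 L)^2` with the conventional `K1 = 0.01`,
#' `K2 = 0.02`, `L = 1`. Both must be positive; they prevent a null
#' denominator on flat images.
#'
#' @param c1,c2 Positive stabilizers.
#' @return An `ssim_config` list.
#' @export
ssim_config <- function(c1 = 0.01^2, c2 = 0.02^2) {
  stopifnot(c1 > 0, c2 > 0)
  structure(list(c1 = c1, c2 = c2), class = "ssim_config")
}

#' Mean squared error between two images
#' @param x_true,x_rec Numeric matrices of equal shape.
#' @return Mean of squared pixel differences.
#' @export
metric_mse <- function(x_true, x_rec) {
  if (!all(dim(x_true) == dim(x_rec))) stop("shape mismatch")
  mean((x_true - x_rec)^2)
}

#' Peak signal-to-noise ratio in dB
#'
#' `PSNR = 10 log10(max(x_true)^2 / MSE)`. Returns `Inf` for identical
#' images.
#'
#' @param x_true,x_rec Numeric matrices of equal shape.
#' @return PSNR in dB.
#' @export
metric_psnr <- function(x_true, x_rec) {
  mse <- metric_mse(x_true, x_rec)
  peak <- max(x_true)
  if (peak <= 0) stop("max(x_true) must be > 0")
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

#' Global structural similarity index
#'
#' Single-window SSIM over the whole image:
#' \deqn{\frac{(2\mu_t\mu_r + c_1)(2\sigma_{tr} + c_2)}
#'            {(\mu_t^2 + \mu_r^2 + c_1)(\sigma_t^2 + \sigma_r^2 + c_2)}}
#' with means, variances and covariance taken over all pixels (population
#' moments, i.e. uniform window spanning the full image). Intended for
#' images on the \[0, 1\] scale matching the default constants.
#'
#' @param x_true,x_rec Numeric matrices of equal shape.
#' @param cfg An [ssim_config()].
#' @return SSIM in \[-1, 1\].
#' @export
metric_ssim <- function(x_true, x_rec, cfg = ssim_config()) {
  if (!all(dim(x_true) == dim(x_rec))) stop("shape mismatch")
  n <- length(x_true)
  mu_t <- mean(x_true); mu_r <- mean(x_rec)
  var_t <- sum((x_true - mu_t)^2) / n
  var_r <- sum((x_rec - mu_r)^2) / n
  cov_tr <- sum((x_true - mu_t) * (x_rec - mu_r)) / n
  ((2 * mu_t * mu_r + cfg$c1) * (2 * cov_tr + cfg$c2)) /
    ((mu_t^2 + mu_r^2 + cfg$c1) * (var_t + var_r + cfg$c2))
}

# Rescale an image pair to [0,1] by the truth's own min/max (shared affine
# map, so relative errors are preserved and the truth spans [0,1]).
normalize_pair <- function(x_true, x_rec) {
  lo <- min(x_true); hi <- max(x_true)
  if (hi <= lo) stop("degenerate truth image: max equals min")
  list(true = (x_true - lo) / (hi - lo), rec = (x_rec - lo) / (hi - lo))
}

#' Evaluate reconstructions against ground truth
#'
#' Computes per-sample MSE, PSNR and global SSIM for the absorption and
#' reduced-scattering channels, on images rescaled to \[0, 1\] by each
#' truth's min/max (so the SSIM/PSNR constants are scale-consistent), plus
#' the MSE in physical units. Aggregates (mean, min, max) are reported per
#' channel; the headline summary statistic is the maximum per-sample SSIM.
#'
#' @param outputs Array `n x 2 x 64 x 64` of reconstructions (channel 1 =
#'   mu_a, channel 2 = mu_s'), physical units.
#' @param truths Array of the same shape with ground truth.
#' @param method Label recorded in the report.
#' @param cfg An [ssim_config()].
#' @return A `metrics_report`: `per_sample` data frame (sample, channel,
#'   mse, mse_physical, psnr_db, ssim) and `aggregate` data frame.
#' @export
evaluate_split <- function(outputs, truths, method = "model",
                           cfg = ssim_config()) {
  stopifnot(length(dim(outputs)) == 4L, all(dim(outputs) == dim(truths)))
  n <- dim(outputs)[1L]
  if (n == 0L) stop("empty split")
  channels <- c("mu_a", "mu_s_prime")
  rows <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    for (ch in 1:2) {
      xt <- truths[i, ch, , ]; xr <- outputs[i, ch, , ]
      p <- normalize_pair(xt, xr)
      rows[[(i - 1L) * 2L + ch]] <- data.frame(
        sample = i, channel = channels[ch],
        mse = metric_mse(p$true, p$rec),
        mse_physical = metric_mse(xt, xr),
        psnr_db = metric_psnr(p$true, p$rec),
        ssim = metric_ssim(p$true, p$rec, cfg))
    }
  }
  per_sample <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(channels, function(ch) {
    d <- per_sample[per_sample$channel == ch, ]
    data.frame(channel = ch,
               mse_mean = mean(d$mse), mse_min = min(d$mse),
               mse_max = max(d$mse),
               psnr_mean = mean(d$psnr_db), psnr_max = max(d$psnr_db),
               ssim_mean = mean(d$ssim), ssim_min = min(d$ssim),
               ssim_max = max(d$ssim))
  }))
  structure(list(per_sample = per_sample, aggregate = agg, method = method),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics_report [%s], %d samples\n", x$method,
              length(unique(x$per_sample$sample))))
  print(x$aggregate, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a metrics report as CSV + JSON summary
#'
#' @param report A `metrics_report`.
#' @param csv_path Per-sample CSV path (sample, channel, mse, psnr_db, ssim).
#' @param json_path Optional aggregate JSON path.
#' @export
write_report <- function(report, csv_path, json_path = NULL) {
  utils::write.csv(report$per_sample, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(method = report$method,
                              aggregate = report$aggregate),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
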