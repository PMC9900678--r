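#' Training configuration
#'
#' Defaults follow the reference training protocol: Adam with learning rate
#' 0.001 and first-moment decay (beta1, the "momentum") 0.5, batch size 64,
#' decoupled weight decay 1e-4 on convolution/dense weights, 20 epochs, and
#' mean-squared-error loss on min-max-normalized target images.
#'
#' @param epochs Number of passes over the training split.
#' @param batch_size Samples per gradient step.
#' @param lr Adam learning rate.
#' @param beta1,beta2 Adam moment decays.
#' @param weight_decay Decoupled L2 coefficient applied to `.W` arrays.
#' @param seed Seed controlling initialization order and batch shuffling.
#' @return A `train_config`.
#' @export
train_config <- function(epochs = 20L, batch_size = 64L, lr = 1e-3,
                         beta1 = 0.5, beta2 = 0.999, weight_decay = 1e-4,
                         seed = 1L) {
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr = lr, beta1 = beta1, beta2 = beta2,
                 weight_decay = weight_decay, seed = as.integer(seed)),
            class = "train_config")
}

# Normalized target matrix (4096 x 2B): absorption images for the first B
# columns, scattering for the rest, matching stack_input()'s pass order.
target_matrix <- function(dataset, idx) {
  B <- length(idx)
  t1 <- vapply(idx, function(i)
    as.vector(dataset$gt_mu_a[i, , ]) / dataset$target_stats$mu_a_max,
    numeric(4096L))
  t2 <- vapply(idx, function(i)
    as.vector(dataset$gt_mu_s[i, , ]) / dataset$target_stats$mu_s_max,
    numeric(4096L))
  cbind(t1, t2)
}

#' Train the reconstruction network
#'
#' Minimizes the mean squared error between predicted and min-max-normalized
#' ground-truth images over the training split, recording train and
#' validation loss per epoch. Fully deterministic for a fixed seed on one
#' platform.
#'
#' @param net A `dot_network` from [build_network()].
#' @param dataset A `dot_dataset`.
#' @param cfg A [train_config()].
#' @param verbose Print one line per epoch.
#' @return List with the trained `net` and a `history` data frame
#'   (epoch, train_loss, val_loss).
#' @export
train_network <- function(net, dataset, cfg = train_config(),
                          verbose = FALSE) {
  stopifnot(inherits(net, "dot_network"), inherits(dataset, "dot_dataset"))
  tr_idx <- split_idx(dataset, "train")
  va_idx <- split_idx(dataset, "val")
  if (!length(tr_idx)) stop("dataset has no training split")

  state <- list(m = lapply(net$par, function(p) p * 0),
                v = lapply(net$par, function(p) p * 0),
                t = 0L)
  decay_mask <- stats::setNames(grepl("\\.W$", names(net$par)),
                                names(net$par))
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  ws <- new.env(parent = emptyenv())  # reused activation buffers
  order_seeds <- derive_seeds(cfg$seed, cfg$epochs)

  for (ep in seq_len(cfg$epochs)) {
    ord <- with_local_seed(order_seeds[ep], sample(tr_idx))
    ep_loss <- 0; ep_n <- 0
    for (start in seq(1L, length(ord), by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
      x <- stack_input(dataset$amplitude_norm[idx, , , drop = FALSE],
                       dataset$phase_norm[idx, , , drop = FALSE])
      tgt <- target_matrix(dataset, idx)
      fw <- net_forward(net, x, training = TRUE, ws = ws)
      net$running <- fw$running
      err <- fw$y - tgt
      loss <- mean(err^2)
      if (!is.finite(loss))
        stop("training diverged (non-finite loss) at epoch ", ep)
      dy <- 2 * err / length(err)
      grads <- net_backward(net, fw$caches, dy, ws = ws)
      state$t <- state$t + 1L
      lr_t <- cfg$lr * sqrt(1 - cfg$beta2^state$t) / (1 - cfg$beta1^state$t)
      for (nm in names(net$par)) {
        g <- grads[[nm]]
        state$m[[nm]] <- cfg$beta1 * state$m[[nm]] + (1 - cfg$beta1) * g
        state$v[[nm]] <- cfg$beta2 * state$v[[nm]] + (1 - cfg$beta2) * g^2
        upd <- lr_t * state$m[[nm]] / (sqrt(state$v[[nm]]) + 1e-8)
        if (decay_mask[[nm]])
          upd <- upd + cfg$lr * cfg$weight_decay * net$par[[nm]]
        net$par[[nm]] <- net$par[[nm]] - upd
      }
      ep_loss <- ep_loss + loss * length(idx)
      ep_n <- ep_n + length(idx)
    }
    val_loss <- if (length(va_idx)) eval_loss(net, dataset, va_idx, ws = ws) else NA_real_
    history <- rbind(history,
                     data.frame(epoch = ep, train_loss = ep_loss / ep_n,
                                val_loss = val_loss))
    if (verbose)
      message(sprintf("epoch %2d: train %.5f  val %.5f", ep,
                      ep_loss / ep_n, val_loss))
  }
  list(net = net, history = history)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# MSE on normalized targets in evaluation mode.
eval_loss <- function(net, dataset, idx, batch = 64L, ws = NULL) {
  tot <- 0; n <- 0
  for (start in seq(1L, length(idx), by = batch)) {
    sel <- idx[start:min(start + batch - 1L, length(idx))]
    x <- stack_input(dataset$amplitude_norm[sel, , , drop = FALSE],
                     dataset$phase_norm[sel, , , drop = FALSE])
    y <- net_forward(net, x, training = FALSE, ws = ws)$y
    tgt <- target_matrix(dataset, sel)
    tot <- tot + sum((y - tgt)^2)
    n <- n + length(tgt)
  }
  tot / n
}

#' Save / load a network checkpoint
#'
#' Single-file archive of the configuration, weights and batch-norm running
#' statistics.
#'
#' @param net A `dot_network`.
#' @param path File path.
#' @export
write_checkpoint <- function(net, path) {
  saveRDS(net, path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  x <- readRDS(path)
  stopifnot(inherits(x, "dot_network"))
  x
}
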