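#' Dataset manifest: sample counts, class balance and splits
#'
#' Describes a synthetic dataset: total sample count, the one- vs
#' two-inclusion class ratio (default 44:55, renormalized), and the
#' train/validation/test split fractions (default 85/10/5). Split sizes at
#' small totals follow largest-remainder rounding; class counts are assigned
#' the same way.
#'
#' @param n_samples Total number of samples.
#' @param split Length-3 fractions (train, validation, test) summing to 1.
#' @param class_ratio Length-2 weights for one- and two-inclusion phantoms.
#' @param seed Global seed; every phantom, forward solve and noise draw is
#'   derived from it deterministically.
#' @return A `dataset_manifest`.
#' @export
dataset_manifest <- function(n_samples, split = c(0.85, 0.10, 0.05),
                             class_ratio = c(44, 55), seed = 1L) {
  stopifnot(n_samples >= 3L, length(split) == 3L,
            abs(sum(split) - 1) < 1e-9, length(class_ratio) == 2L)
  structure(
    list(n_samples = as.integer(n_samples), split = split,
         class_ratio = class_ratio, seed = as.integer(seed),
         split_sizes = largest_remainder(n_samples, split),
         class_sizes = largest_remainder(n_samples,
                                         class_ratio / sum(class_ratio))),
    class = "dataset_manifest"
  )
}

# Apportion `n` into integer parts proportional to `frac` (largest-remainder
# a.k.a. Hamilton rounding).
largest_remainder <- function(n, frac) {
  raw <- n * frac / sum(frac)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Generate a synthetic FD-DOT dataset
#'
#' For each sample: draw a phantom specification ([sample_spec()]), rasterize
#' the 64x64 ground truth, build a mesh, solve the forward problem for all
#' sources, sample the boundary and add relative Gaussian noise. Raw (noisy,
#' un-normalized) boundary data are stored together with min-max
#' normalization statistics computed on the training split only and applied
#' frozen to all splits (values outside the training range are clipped).
#' Ground-truth rasters stay in physical units; per-channel training-split
#' maxima are recorded for target normalization.
#'
#' @param manifest A [dataset_manifest()].
#' @param acq An [acquisition_config()]; each sample's frequency comes from
#'   its own phantom spec.
#' @param ranges Sampling ranges ([spec_ranges()]).
#' @param mesh_divisor Forward-mesh target edge = diameter / mesh_divisor
#'   (further capped by inclusion size inside [build_mesh()]).
#' @param progress Print a progress line every 200 samples.
#' @return A `dot_dataset`: arrays `amplitude`, `phase` (n x m x (m-1), raw),
#'   `amplitude_norm`, `phase_norm` (normalized), `gt_mu_a`, `gt_mu_s`
#'   (n x 64 x 64, physical units), `split` factor, `specs`, `norm_stats`,
#'   `target_stats`, and the layout.
#' @export
generate_dataset <- function(manifest, acq = acquisition_config(),
                             ranges = spec_ranges(), mesh_divisor = 12,
                             progress = FALSE) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  n <- manifest$n_samples
  m <- acq$n_sources; nd <- acq$n_detectors

  n_incl <- rep(c(1L, 2L), manifest$class_sizes)
  split <- rep(c("train", "val", "test"), manifest$split_sizes)
  # interleave classes across splits deterministically
  ord <- with_local_seed(manifest$seed + 1L, sample.int(n))
  n_incl <- n_incl[ord]
  seeds <- derive_seeds(manifest$seed, 2L * n)

  amplitude <- array(NA_real_, c(n, m, nd))
  phase <- array(NA_real_, c(n, m, nd))
  gt_mu_a <- array(NA_real_, c(n, 64L, 64L))
  gt_mu_s <- array(NA_real_, c(n, 64L, 64L))
  specs <- vector("list", n)

  for (i in seq_len(n)) {
    seed_i <- seeds[2L * i - 1L]
    bd <- NULL
    for (attempt in 0:4) {  # replacement draw on forward-solver failure
      sp <- sample_spec(seed_i + attempt, n_incl[i], ranges)
      bd <- tryCatch(
        simulate_boundary(sp, acq, target_edge_mm = sp$diameter_mm / mesh_divisor,
                          noise_seed = seeds[2L * i]),
        error = function(e) NULL)
      if (!is.null(bd)) break
    }
    if (is.null(bd)) stop("forward solve failed repeatedly for sample ", i)
    img <- rasterize(sp)
    amplitude[i, , ] <- bd$amplitude
    phase[i, , ] <- bd$phase
    gt_mu_a[i, , ] <- img$mu_a
    gt_mu_s[i, , ] <- img$mu_s_prime
    specs[[i]] <- sp
    if (progress && i %% 200L == 0L)
      message(sprintf("  generated %d / %d samples", i, n))
  }

  tr <- split == "train"
  stats <- list(amp_min = min(amplitude[tr, , ]),
                amp_max = max(amplitude[tr, , ]),
                phase_min = min(phase[tr, , ]),
                phase_max = max(phase[tr, , ]))
  if (stats$amp_max <= stats$amp_min || stats$phase_max <= stats$phase_min)
    stop("degenerate channel in training split")
  amplitude_norm <- clamp((amplitude - stats$amp_min) /
                            (stats$amp_max - stats$amp_min), 0, 1)
  phase_norm <- clamp((phase - stats$phase_min) /
                        (stats$phase_max - stats$phase_min), 0, 1)
  target_stats <- list(mu_a_max = max(gt_mu_a[tr, , ]),
                       mu_s_max = max(gt_mu_s[tr, , ]))

  structure(
    list(amplitude = amplitude, phase = phase,
         amplitude_norm = amplitude_norm, phase_norm = phase_norm,
         gt_mu_a = gt_mu_a, gt_mu_s = gt_mu_s,
         split = factor(split, levels = c("train", "val", "test")),
         n_inclusions = n_incl, specs = specs,
         norm_stats = stats, target_stats = target_stats,
         acq = acq, manifest = manifest),
    class = "dot_dataset"
  )
}

#' @export
print.dot_dataset <- function(x, ...) {
  cat(sprintf("dot_dataset: %d samples (%s), layout %d x %d\n",
              x$manifest$n_samples,
              paste(table(x$split), collapse = "/"),
              x$acq$n_sources, x$acq$n_detectors))
  invisible(x)
}

#' Indices of a dataset split
#' @param dataset A `dot_dataset`.
#' @param which One of "train", "val", "test".
#' @return Integer sample indices.
#' @export
split_idx <- function(dataset, which = c("train", "val", "test")) {
  which <- match.arg(which)
  which(dataset$split == which)
}

#' Save / load a dataset container
#'
#' The container is stored as a single RDS archive (a hierarchical R-native
#' serialization of the boundary arrays, ground-truth rasters, specs and
#' normalization statistics).
#'
#' @param dataset A `dot_dataset`.
#' @param path File path.
#' @export
write_dataset <- function(dataset, path) {
  saveRDS(dataset, path)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  x <- readRDS(path)
  stopifnot(inherits(x, "dot_dataset"))
  x
}
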