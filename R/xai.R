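#' Frequency response of the temporal convolution kernels
#'
#' Temporal convolutions act as FIR frequency filters; the discrete Fourier
#' magnitude of each kernel shows which bands the model prioritizes (the
#' magnitude is invariant to the time reversal implied by convolution).
#' The mean response over filters is smoothed with a Savitzky-Golay filter
#' (default window 5, order 3).
#'
#' @param model a `conformer_model`, or a plain n_filters x kernel_len
#'   matrix (then `fs` must be given).
#' @param smooth `c(window, order)` of the Savitzky-Golay smoother; the
#'   window must be odd and greater than the order.
#' @param n_points number of frequency points on \[0, fs/2\] (>= 256).
#' @param fs sampling rate, taken from the model if absent.
#' @return object of class `kernel_spectra`: `freq` (Hz), `magnitude`
#'   (n_filters x n_freqs), `mean_magnitude` (smoothed).
#' @export
kernel_frequency_response <- function(model, smooth = c(5, 3),
                                      n_points = 257, fs = NULL) {
  K <- if (inherits(model, "conformer_model")) model$params$K else model
  if (is.null(fs)) {
    if (!inherits(model, "conformer_model")) stop("fs required for a bare kernel matrix")
    fs <- model$fs
  }
  window <- smooth[1]
  order <- smooth[2]
  if (window %% 2 == 0 || window <= order) {
    stop("Savitzky-Golay window must be odd and greater than the order")
  }
  if (n_points < 256) stop("need >= 256 frequency points up to fs/2")
  nfft <- 2 * (n_points - 1)
  mag <- t(apply(K, 1, function(k) {
    abs(stats::fft(c(k, numeric(nfft - length(k)))))[seq_len(n_points)]
  }))
  dimnames(mag) <- NULL
  freq <- (seq_len(n_points) - 1) * fs / nfft
  mean_mag <- signal::sgolayfilt(colMeans(mag), p = order, n = window)
  structure(list(freq = freq, magnitude = mag, mean_magnitude = mean_mag,
                 smooth = smooth, fs = fs),
            class = "kernel_spectra")
}

#' Spatial pattern of the learned spatial filters
#'
#' The spatial filter matrix W projects channels into filter space, like a
#' common-spatial-patterns decomposition; the columns of its inverse are the
#' scalp patterns of the learned sources. W is inverted exactly when square
#' and well conditioned; otherwise (including the usual n_filters !=
#' n_channels case) the Moore-Penrose pseudo-inverse is used, with a warning
#' when a square W is ill-conditioned. Patterns are reported as per-column
#' normalized absolute values, since the sign of an oscillatory pattern
#' carries no information.
#'
#' @param model a `conformer_model`, or a plain n_filters x n_channels
#'   matrix.
#' @param cond_threshold condition number above which a square W falls back
#'   to the pseudo-inverse.
#' @return object of class `spatial_pattern`: `pattern_matrix` (n_channels
#'   x n_filters) and `normalized_abs` (same shape, column max 1).
#' @export
spatial_pattern <- function(model, cond_threshold = 1e6) {
  W <- if (inherits(model, "conformer_model")) model$params$W else model
  channels <- if (inherits(model, "conformer_model")) model$channel_names else rownames(W)
  sv <- svd(W)$d
  cond <- if (min(sv) > 0) max(sv) / min(sv) else Inf
  if (nrow(W) == ncol(W) && cond < cond_threshold) {
    pat <- solve(W)
  } else {
    if (nrow(W) == ncol(W)) {
      warning("spatial filter matrix is ill-conditioned (condition number ",
              signif(cond, 3), "); using the pseudo-inverse")
    }
    pat <- MASS::ginv(W)
  }
  norm_abs <- abs(pat)
  cmax <- apply(norm_abs, 2, max)
  nz <- cmax > 0
  norm_abs[, nz] <- sweep(norm_abs[, nz, drop = FALSE], 2, cmax[nz], "/")
  if (!is.null(channels)) rownames(pat) <- rownames(norm_abs) <- channels
  structure(list(pattern_matrix = pat, normalized_abs = norm_abs,
                 condition_number = cond),
            class = "spatial_pattern")
}

# Grad-CAM combination rule: weights are the spatial mean of the gradient
# per feature map; the map is the weighted sum WITHOUT rectification.
.cam_combine <- function(feature_maps, gradients) {
  alpha <- rowMeans(gradients)
  as.vector(t(feature_maps) %*% alpha)
}

# Nearest-token assignment of input samples (ties toward the earlier token).
.token_of_sample <- function(T, centers) {
  vapply(seq_len(T), function(t) which.min(abs(centers - t)), 0L)
}

#' Signed gradient-weighted class activation map
#'
#' Grad-CAM over the feature maps at the convolution-module output (the
#' pooled token sequence): per feature map, the weight is the spatial mean
#' of the gradient of the target-class score; the activation map is the
#' weighted sum of feature maps, kept signed (no rectification) so that
#' negative values can be read as ERD and positive values as ERS. The
#' token-resolution map is upsampled to the input time axis by
#' nearest-receptive-field-centre assignment and averaged over the trials
#' of the target class, then binned into non-overlapping 0.5-s bins.
#'
#' @param model a `conformer_model`.
#' @param epochs an `epoch_set` matching the model geometry.
#' @param target_class class label ("rest"/"slow"/"medium"/"fast") or
#'   0-based index.
#' @param bin_s bin width in seconds.
#' @return object of class `cam_result`: `class_label`, `time` (epoch
#'   axis), `cam` (signed, per input sample), `bin_starts` (s), `binned`.
#' @export
gradcam <- function(model, epochs, target_class, bin_s = 0.5) {
  stopifnot(inherits(model, "conformer_model"), inherits(epochs, "epoch_set"))
  .check_epoch_shape(model, epochs)
  if (is.numeric(target_class)) target_class <- model$class_labels[target_class + 1]
  cls_idx <- match(target_class, model$class_labels)
  if (is.na(cls_idx)) stop("unknown class: ", target_class)
  trials <- which(epochs$labels == target_class)
  if (length(trials) == 0) stop("no epochs of class '", target_class, "'")
  dims <- model$dims
  onehot <- numeric(model$config$n_classes)
  onehot[cls_idx] <- 1
  tok <- .token_of_sample(dims$T, dims$token_centers)
  trial_cam <- matrix(0, length(trials), dims$T)
  for (j in seq_along(trials)) {
    x <- matrix(epochs$data[trials[j], , ], dims$C, dims$T)
    fw <- .conformer_forward(model$params, model$config, dims, x)
    bw <- .conformer_backward(model$params, model$config, dims, fw$cache, onehot)
    trial_cam[j, ] <- .cam_combine(fw$cache$Apool, bw$dApool)[tok]
  }
  cam <- colMeans(trial_cam)
  fs <- epochs$fs
  bin_len <- round(bin_s * fs)
  n_bins <- floor(dims$T / bin_len)
  binned <- vapply(seq_len(n_bins), function(b) {
    mean(cam[(b - 1) * bin_len + seq_len(bin_len)])
  }, 0)
  structure(list(
    class_label = target_class, time = epochs$time_axis, cam = cam,
    bin_starts = epochs$time_axis[1] + (seq_len(n_bins) - 1) * bin_s,
    bin_s = bin_s, binned = binned, n_trials = length(trials), fs = fs,
    trial_cam = trial_cam, trial_index = trials
  ), class = "cam_result")
}

#' Class activation topography
#'
#' Projects the temporal class activation map onto channels: per channel,
#' the mean over time and over the trials of the target class of
#' (normalized signal x CAM value at that time point). When the
#' `cam_result` carries per-trial maps (the default from [gradcam()]), each
#' trial's signal is multiplied by that trial's own CAM, which preserves
#' phase-locked signal-attention structure that a class-averaged CAM would
#' cancel; otherwise the supplied class-level CAM is used for every trial.
#' High-magnitude channels are where the model's temporal attention
#' coincides with signal structure.
#'
#' @param cam a `cam_result` for the target class.
#' @param epochs a normalized `epoch_set` on the same time axis as `cam`.
#' @param target_class class label or 0-based index; defaults to the CAM's
#'   class.
#' @return object of class `cat_topography`: `values` (named per channel),
#'   `class_label`.
#' @export
cat_topography <- function(cam, epochs, target_class = NULL) {
  stopifnot(inherits(cam, "cam_result"), inherits(epochs, "epoch_set"))
  if (is.null(target_class)) target_class <- cam$class_label
  if (is.numeric(target_class)) target_class <- epochs$class_labels[target_class + 1]
  if (length(cam$cam) != length(epochs$time_axis) ||
      max(abs(cam$time - epochs$time_axis)) > 1e-9) {
    stop("CAM and epoch time axes are misaligned")
  }
  if (!isTRUE(epochs$normalized)) {
    warning("epochs are not normalized; CAT is defined on normalized signals")
  }
  trials <- which(epochs$labels == target_class)
  if (length(trials) == 0) stop("no epochs of class '", target_class, "'")
  per_trial <- !is.null(cam$trial_cam) &&
    identical(as.integer(cam$trial_index), as.integer(trials))
  vals <- numeric(dim(epochs$data)[2])
  for (j in seq_along(trials)) {
    x <- epochs$data[trials[j], , , drop = TRUE]
    w <- if (per_trial) cam$trial_cam[j, ] else cam$cam
    vals <- vals + as.vector(x %*% w) / length(w)
  }
  vals <- vals / length(trials)
  names(vals) <- epochs$channel_names
  structure(list(values = vals, class_label = target_class,
                 n_trials = length(trials)),
            class = "cat_topography")
}

#' @export
print.kernel_spectra <- function(x, ...) {
  pk <- x$freq[which.max(x$mean_magnitude)]
  cat("<kernel_spectra> ", nrow(x$magnitude), " filters, ", length(x$freq),
      " frequency points on [0, ", max(x$freq), "] Hz; mean response peaks at ",
      round(pk, 1), " Hz\n", sep = "")
  invisible(x)
}

#' @export
print.cam_result <- function(x, ...) {
  cat("<cam_result> class '", x$class_label, "', ", length(x$binned),
      " bins of ", x$bin_s, " s over [", min(x$time), ", ",
      max(x$time), "] s (", x$n_trials, " trials)\n", sep = "")
  invisible(x)
}

#' @export
plot.cam_result <- function(x, ...) {
  graphics::plot(x$bin_starts + x$bin_s / 2, x$binned, type = "h",
                 xlab = "Time relative to MI onset (s)",
                 ylab = "signed CAM", main = x$class_label, ...)
  graphics::abline(h = 0, v = 0, lty = 3)
  invisible(x)
}
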