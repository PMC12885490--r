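#' Current source density (surface Laplacian) transform
#'
#' Spherical-spline surface Laplacian (Perrin-style) applied per trial and
#' time point, sharpening spatial focality. The transform is linear and maps
#' a spatially constant field to zero exactly.
#'
#' @param epochs an `epoch_set` (microvolts).
#' @param positions optional data.frame with columns `channel`, `x`, `y`,
#'   `z` (unit sphere); default looks the epoch channels up in the built-in
#'   idealized montage. An error lists any channel without a position.
#' @param m spline stiffness (default 4).
#' @param lambda ridge regularization (default 1e-5).
#' @param head_radius scalp radius in meters; output units are uV/m^2.
#' @param n_terms number of Legendre terms.
#' @return the `epoch_set` with CSD-transformed data.
#' @export
csd_transform <- function(epochs, positions = NULL, m = 4, lambda = 1e-5,
                          head_radius = 0.09, n_terms = 50) {
  stopifnot(inherits(epochs, "epoch_set"))
  ch <- epochs$channel_names
  if (length(ch) < 4) stop("CSD needs >= 4 channels")
  if (is.null(positions)) {
    positions <- montage_positions(ch)
  } else {
    missing <- setdiff(ch, positions$channel)
    if (length(missing) > 0) {
      stop("no scalp position for channel(s): ", paste(missing, collapse = ", "))
    }
    positions <- positions[match(ch, positions$channel), ]
  }
  M <- .csd_matrix(as.matrix(positions[, c("x", "y", "z")]), m, lambda,
                   head_radius, n_terms)
  out <- epochs
  for (i in seq_len(dim(epochs$data)[1])) {
    out$data[i, , ] <- M %*% epochs$data[i, , ]
  }
  out
}

# Legendre polynomial expansion sums for the spherical spline.
.csd_matrix <- function(xyz, m, lambda, head_radius, n_terms) {
  C <- nrow(xyz)
  x <- tcrossprod(xyz)  # cos(angle) between electrodes
  x[] <- pmax(-1, pmin(1, x))
  G <- matrix(0, C, C)
  Hm <- matrix(0, C, C)
  Pnm1 <- matrix(1, C, C)  # P_0
  Pn <- x                  # P_1
  for (n in seq_len(n_terms)) {
    if (n > 1) {
      Pnew <- ((2 * n - 1) * x * Pn - (n - 1) * Pnm1) / n
      Pnm1 <- Pn
      Pn <- Pnew
    }
    G <- G + (2 * n + 1) / (n * (n + 1))^m * Pn
    Hm <- Hm + (2 * n + 1) / (n * (n + 1))^(m - 1) * Pn
  }
  G <- G / (4 * pi)
  Hm <- Hm / (4 * pi)
  Ginv <- solve(G + lambda * diag(C))
  ones <- rep(1, C)
  Tmat <- Ginv - (Ginv %*% ones %*% t(ones) %*% Ginv) / sum(Ginv)
  # CSD = -surface Laplacian; spherical harmonic of degree n scales by
  # -n(n+1)/r^2 under the Laplacian, absorbed into Hm above.
  (Hm %*% Tmat) / head_radius^2
}

#' Welch power spectral density over a channel set
#'
#' Averages Blackman-tapered segment periodograms across segments, the
#' channels of the set, and trials of the epoch set. One-sided density in
#' uV^2/Hz plus a dB conversion (`10*log10`, floored at -300 dB with a
#' warning for zero-power bins).
#'
#' @param epochs an `epoch_set`.
#' @param channels channel names, or a set name (`"ssmrp"`/`"ssvep"`), or
#'   `NULL` for all channels.
#' @param segment_s segment length in seconds; `NULL` uses the full
#'   selected window (periodogram mode). Must not exceed the selected
#'   window.
#' @param overlap fractional segment overlap in \[0, 1).
#' @param t_range time window (seconds, epoch axis) to analyze, e.g.
#'   `c(0, 5)` for the MI period. `NULL` uses the whole epoch.
#' @return object of class `psd_estimate`: `freq` (Hz), `psd` (linear),
#'   `psd_db`, `fs`, `n_trials`, `channels`.
#' @export
welch_psd <- function(epochs, channels = NULL, segment_s = 2.5,
                      overlap = 0.5, t_range = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (is.character(channels) && length(channels) == 1 &&
      channels %in% c("ssmrp", "ssvep")) {
    channels <- channel_set(channels)
  }
  if (is.null(channels)) channels <- epochs$channel_names
  ci <- match(channels, epochs$channel_names)
  if (anyNA(ci)) {
    stop("unknown channel(s): ", paste(channels[is.na(ci)], collapse = ", "))
  }
  fs <- epochs$fs
  ti <- if (is.null(t_range)) {
    seq_along(epochs$time_axis)
  } else {
    which(epochs$time_axis >= t_range[1] & epochs$time_axis < t_range[2])
  }
  n_win <- length(ti)
  nseg <- if (is.null(segment_s)) n_win else round(segment_s * fs)
  if (nseg > n_win) stop("segment length exceeds the analyzed window")
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  step <- max(1, round(nseg * (1 - overlap)))
  starts <- seq(1, n_win - nseg + 1, by = step)
  w <- signal::blackman(nseg)
  scale <- 1 / (fs * sum(w^2))
  n_freq <- floor(nseg / 2) + 1
  freq <- (seq_len(n_freq) - 1) * fs / nseg
  acc <- numeric(n_freq)
  n_avg <- 0
  for (tr in seq_len(dim(epochs$data)[1])) {
    for (c in ci) {
      x <- epochs$data[tr, c, ti]
      for (s0 in starts) {
        seg <- x[s0 + seq_len(nseg) - 1]
        seg <- (seg - mean(seg)) * w
        sp <- abs(stats::fft(seg)[seq_len(n_freq)])^2 * scale
        sp[-1] <- sp[-1] * 2
        if (nseg %% 2 == 0) sp[n_freq] <- sp[n_freq] / 2
        acc <- acc + sp
        n_avg <- n_avg + 1
      }
    }
  }
  psd <- acc / n_avg
  if (any(psd == 0)) warning("zero-power bins floored at -300 dB")
  psd_db <- ifelse(psd > 0, 10 * log10(psd), -300)
  structure(list(freq = freq, psd = psd, psd_db = psd_db, fs = fs,
                 n_trials = dim(epochs$data)[1], channels = channels),
            class = "psd_estimate")
}

#' Neighbor-bin signal-to-noise spectrum
#'
#' SNR at each frequency bin is its linear power divided by the mean power
#' of the `n_neighbors` bins on each side (the bin itself excluded). The
#' `n_neighbors` edge bins on each end have no full neighborhood and are
#' flagged undefined (`NA`).
#'
#' @param freq uniform frequency grid (Hz), or a `psd_estimate` (then
#'   `psd` is taken from it).
#' @param psd linear power at each bin.
#' @param n_neighbors neighbors per side (>= 1).
#' @return object of class `snr_spectrum`: `freq`, `snr` (linear ratio, NA
#'   at edges), `psd_db`, `n_neighbors`, `excluded_edges` (Hz ranges).
#' @export
#' @examples
#' s <- snr_spectrum(0:4, c(1, 1, 4, 1, 1), n_neighbors = 2)
#' s$snr[3]  # 4
snr_spectrum <- function(freq, psd = NULL, n_neighbors = 5) {
  if (inherits(freq, "psd_estimate")) {
    psd <- freq$psd
    freq <- freq$freq
  }
  n <- length(psd)
  if (length(freq) != n) stop("freq and psd lengths differ")
  if (n_neighbors < 1) stop("n_neighbors must be >= 1")
  if (n < 2 * n_neighbors + 1) {
    stop("spectrum has ", n, " bins; need at least ", 2 * n_neighbors + 1)
  }
  df <- diff(freq)
  if (max(abs(df - df[1])) > 1e-6 * df[1]) stop("frequency grid must be uniform")
  snr <- rep(NA_real_, n)
  for (i in (n_neighbors + 1):(n - n_neighbors)) {
    nb <- psd[c((i - n_neighbors):(i - 1), (i + 1):(i + n_neighbors))]
    snr[i] <- psd[i] / mean(nb)
  }
  structure(list(
    freq = freq, snr = snr,
    psd_db = ifelse(psd > 0, 10 * log10(psd), -300),
    n_neighbors = n_neighbors,
    excluded_edges = list(c(freq[1], freq[n_neighbors]),
                          c(freq[n - n_neighbors + 1], freq[n]))
  ), class = "snr_spectrum")
}

#' Read SNR at pacing harmonics
#'
#' Looks the SNR spectrum up at the grid bin nearest each harmonic `h * f0`
#' (ties toward the lower frequency) and marks whether that bin is the
#' global SNR maximum over the 1-8 Hz band.
#'
#' @param snr an `snr_spectrum`.
#' @param f0 pacing fundamental in Hz (> 0).
#' @param n_harmonics number of harmonics to read.
#' @param band band (Hz) over which the global maximum is sought.
#' @return data.frame with columns `h`, `freq` (grid bin), `snr`,
#'   `is_global_max`.
#' @export
harmonic_readout <- function(snr, f0, n_harmonics = 4, band = c(1, 8)) {
  stopifnot(inherits(snr, "snr_spectrum"))
  if (f0 <= 0) stop("f0 must be > 0")
  defined <- which(!is.na(snr$snr))
  in_band <- defined[snr$freq[defined] >= band[1] & snr$freq[defined] <= band[2]]
  if (length(in_band) == 0) stop("no defined SNR bins inside the band")
  gmax_bin <- in_band[which.max(snr$snr[in_band])]
  rows <- lapply(seq_len(n_harmonics), function(h) {
    target <- h * f0
    d <- abs(snr$freq[defined] - target)
    bin <- defined[which(d == min(d))[1]]  # ties -> lower frequency
    data.frame(h = h, freq = snr$freq[bin], snr = snr$snr[bin],
               is_global_max = bin == gmax_bin)
  })
  do.call(rbind, rows)
}

#' @export
print.snr_spectrum <- function(x, ...) {
  ok <- !is.na(x$snr)
  cat("<snr_spectrum> ", sum(ok), " defined bins on [",
      min(x$freq[ok]), ", ", max(x$freq[ok]), "] Hz (+/-", x$n_neighbors,
      " neighbor bins); peak SNR ", round(max(x$snr[ok]), 2), " at ",
      x$freq[ok][which.max(x$snr[ok])], " Hz\n", sep = "")
  invisible(x)
}

#' @export
plot.snr_spectrum <- function(x, xlim = c(0, 40), ...) {
  graphics::plot(x$freq, x$snr, type = "l", xlab = "Frequency (Hz)",
                 ylab = "SNR (linear)", xlim = xlim, ...)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}
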