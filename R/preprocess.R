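#' Zero-phase band-pass filter a session
#'
#' Applies a 4th-order Butterworth band-pass forward and backward
#' ([signal::filtfilt()]) per channel, so the group delay is zero.
#'
#' @param session a `raw_session`.
#' @param low,high band edges in Hz; must satisfy 0 < low < high < fs/2.
#' @param order Butterworth order (applied twice by filtfilt).
#' @return the session with filtered `data`.
#' @export
bandpass <- function(session, low = 4, high = 40, order = 4) {
  stopifnot(inherits(session, "raw_session"))
  fs <- session$fs
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop("band edges must satisfy 0 < low < high < fs/2 (fs = ", fs, ")")
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  out <- session
  for (c in seq_len(nrow(session$data))) {
    out$data[c, ] <- signal::filtfilt(bf, session$data[c, ])
  }
  out
}

#' Cut a session into trial epochs
#'
#' Extracts a `[t_min, t_max)` window around every event, with t = 0 at MI
#' onset (the beep ending the cue).
#'
#' @param session a `raw_session`.
#' @param t_min,t_max window in seconds relative to MI onset; `t_min < t_max`.
#' @return object of class `epoch_set`: `data` is a trials x channels x
#'   samples array; `labels` (character), `label_index` (0 = rest .. 3 =
#'   fast), `run`, `time_axis` (seconds), `fs`, `channel_names`.
#' @export
#' @examples
#' s <- generate_session(session_design(n_runs = 1), seed = 1)
#' e <- epoch_session(s, -1, 5)
#' dim(e$data)  # 35 x 14 x 1500
epoch_session <- function(session, t_min = -1, t_max = 5) {
  stopifnot(inherits(session, "raw_session"))
  if (t_min >= t_max) stop("t_min must be < t_max")
  fs <- session$fs
  n_samp <- round((t_max - t_min) * fs)
  offset <- round(t_min * fs)
  ev <- session$events
  n_total <- ncol(session$data)
  labels_all <- c("rest", "slow", "medium", "fast")
  data <- array(0, dim = c(nrow(ev), nrow(session$data), n_samp))
  for (i in seq_len(nrow(ev))) {
    first <- ev$onset_sample[i] + offset  # 0-based
    if (first < 0 || first + n_samp > n_total) {
      stop("epoch window [", t_min, ", ", t_max, "] s out of bounds for event ",
           i, " (onset sample ", ev$onset_sample[i], ")")
    }
    data[i, , ] <- session$data[, first + seq_len(n_samp)]
  }
  structure(list(
    data = data,
    labels = ev$label,
    label_index = match(ev$label, labels_all) - 1L,
    run = ev$run,
    time_axis = t_min + (seq_len(n_samp) - 1) / fs,
    fs = fs,
    channel_names = session$channel_names,
    class_labels = labels_all,
    normalized = FALSE
  ), class = "epoch_set")
}

#' Z-score every channel of every epoch
#'
#' Per trial and channel, subtracts the mean and divides by the standard
#' deviation over the epoch. Zero-variance channels map to all-zero.
#' Idempotent up to numerical tolerance.
#'
#' @param epochs an `epoch_set`.
#' @return the `epoch_set` with dimensionless data and `normalized = TRUE`.
#' @export
normalize_epochs <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (length(epochs$labels) == 0) stop("empty epoch set")
  d <- epochs$data
  for (i in seq_len(dim(d)[1])) {
    x <- d[i, , , drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, nrow = dim(d)[2])
    mu <- rowMeans(x)
    sdv <- sqrt(rowMeans((x - mu)^2))
    sdv[sdv == 0] <- Inf  # zero-variance channel -> zeros
    d[i, , ] <- (x - mu) / sdv
  }
  epochs$data <- d
  epochs$normalized <- TRUE
  epochs
}

#' Subset an epoch set by trial index
#'
#' @param epochs an `epoch_set`.
#' @param idx integer trial indices.
#' @return the subsetted `epoch_set`.
#' @export
epoch_subset <- function(epochs, idx) {
  stopifnot(inherits(epochs, "epoch_set"))
  out <- epochs
  out$data <- epochs$data[idx, , , drop = FALSE]
  out$labels <- epochs$labels[idx]
  out$label_index <- epochs$label_index[idx]
  out$run <- epochs$run[idx]
  out
}

#' Split epochs into cross-validation folds
#'
#' Two schemes: `"loro"` (leave-one-run-out; each run is the test set once,
#' respecting the session's run structure) and `"stratified"` (seeded
#' k-fold preserving class proportions). Folds are disjoint and their test
#' sets cover all trials.
#'
#' @param epochs an `epoch_set`.
#' @param scheme `"loro"` or `"stratified"`.
#' @param k number of folds for the stratified scheme.
#' @param seed RNG seed for the stratified shuffle (ignored for loro).
#' @return list of folds; each fold is `list(train =, test =)` of
#'   `epoch_set`s.
#' @export
split_epochs <- function(epochs, scheme = c("loro", "stratified"), k = 5,
                         seed = 1) {
  stopifnot(inherits(epochs, "epoch_set"))
  scheme <- match.arg(scheme)
  tab <- table(epochs$labels)
  if (any(tab < 2)) {
    stop("every class needs >= 2 trials; got: ",
         paste(names(tab), tab, sep = "=", collapse = ", "))
  }
  if (scheme == "loro") {
    runs <- sort(unique(epochs$run))
    if (length(runs) < 2) stop("leave-one-run-out needs >= 2 runs")
    assign <- match(epochs$run, runs)
    k <- length(runs)
  } else {
    assign <- integer(length(epochs$labels))
    .with_seed(seed, {
      for (cl in unique(epochs$labels)) {
        idx <- which(epochs$labels == cl)
        idx <- sample(idx)
        assign[idx] <- rep_len(seq_len(k), length(idx))
      }
    })
  }
  lapply(seq_len(k), function(f) {
    list(train = epoch_subset(epochs, which(assign != f)),
         test = epoch_subset(epochs, which(assign == f)))
  })
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat("<epoch_set> ", d[1], " trials x ", d[2], " channels x ", d[3],
      " samples @ ", x$fs, " Hz, t in [", min(x$time_axis), ", ",
      max(x$time_axis) + 1 / x$fs, ") s",
      if (isTRUE(x$normalized)) ", normalized" else "", "\n", sep = "")
  invisible(x)
}
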