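# Session I/O: 16-bit EDF raw signals + BIDS-style events.tsv.
# The EDF writer/reader below covers the classic continuous layout (one data
# record spanning the session); event markers live in the tab-separated
# sidecar, not in embedded annotations.

# Format a number into at most `width` ASCII characters (EDF header fields).
.edf_num <- function(x, width = 8) {
  for (digits in 7:1) {
    s <- sprintf("%.*g", digits, x)
    if (nchar(s) <= width) return(s)
  }
  stop("cannot format ", x, " in ", width, " characters")
}

.edf_pad <- function(s, width) {
  s <- substr(s, 1, width)
  formatC(s, width = -width)  # left-justified, space padded
}

#' Write a session to disk
#'
#' Writes `session.edf` (16-bit EDF, microvolts, one continuous data
#' record) and `events.tsv` (columns `onset` and `duration` in seconds,
#' `trial_type`, `run`) into `directory`. Reading back recovers events and
#' channel names exactly and the signal up to 16-bit quantization of each
#' channel's range.
#'
#' @param session a `raw_session`.
#' @param directory output directory (created if absent).
#' @return the directory, invisibly.
#' @export
write_session <- function(session, directory) {
  stopifnot(inherits(session, "raw_session"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  .write_edf(file.path(directory, "session.edf"), session$data, session$fs)
  ev <- session$events
  mi_s <- if (!is.null(session$design)) session$design$mi_s else NA_real_
  tsv <- data.frame(onset = ev$onset_sample / session$fs,
                    duration = rep(mi_s, nrow(ev)),
                    trial_type = ev$label, run = ev$run)
  utils::write.table(tsv, file.path(directory, "events.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(directory)
}

#' Read a session from disk
#'
#' Counterpart of [write_session()]. Fails with an explicit error naming
#' any missing file, and rejects events whose `trial_type` is not one of
#' rest/slow/medium/fast.
#'
#' @param directory directory holding `session.edf` and `events.tsv`.
#' @return a `raw_session` (without simulator ground truth).
#' @export
read_session <- function(directory) {
  edf_path <- file.path(directory, "session.edf")
  ev_path <- file.path(directory, "events.tsv")
  for (p in c(edf_path, ev_path)) {
    if (!file.exists(p)) stop("missing file: ", p)
  }
  rec <- .read_edf(edf_path)
  ev <- utils::read.delim(ev_path, stringsAsFactors = FALSE)
  labels <- c("rest", "slow", "medium", "fast")
  if (nrow(ev) > 0) {
    bad <- setdiff(unique(ev$trial_type), labels)
    if (length(bad) > 0) {
      stop("unknown trial_type value(s): ", paste(bad, collapse = ", "),
           "; valid labels are: ", paste(labels, collapse = ", "))
    }
  }
  events <- data.frame(onset_sample = as.integer(round(ev$onset * rec$fs)),
                       label = as.character(ev$trial_type),
                       run = as.integer(ev$run), stringsAsFactors = FALSE)
  structure(list(
    data = rec$data, fs = rec$fs, channel_names = rownames(rec$data),
    events = events[order(events$onset_sample), , drop = FALSE],
    design = NULL, ground_truth = NULL
  ), class = "raw_session")
}

.write_edf <- function(path, data, fs) {
  ns <- nrow(data)
  n_samp <- ncol(data)
  n_records <- if (n_samp > 0) 1L else 0L
  # Per-channel physical range: format to ASCII first, then quantize against
  # the parsed values so the round trip is limited only by the 16-bit step.
  pmin_s <- pmax_s <- character(ns)
  pmin <- pmax <- numeric(ns)
  for (c in seq_len(ns)) {
    lo <- if (n_samp > 0) min(data[c, ]) else -1
    hi <- if (n_samp > 0) max(data[c, ]) else 1
    if (hi <= lo) hi <- lo + 1
    margin <- (hi - lo) * 1e-4
    pmin_s[c] <- .edf_num(lo - margin)
    pmax_s[c] <- .edf_num(hi + margin)
    pmin[c] <- as.numeric(pmin_s[c])
    pmax[c] <- as.numeric(pmax_s[c])
    if (pmin[c] > lo || pmax[c] < hi) {  # ASCII rounding clipped the range
      pmin_s[c] <- .edf_num(lo - (hi - lo) * 0.01)
      pmax_s[c] <- .edf_num(hi + (hi - lo) * 0.01)
      pmin[c] <- as.numeric(pmin_s[c])
      pmax[c] <- as.numeric(pmax_s[c])
    }
  }
  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(s, w) writeChar(.edf_pad(s, w), con, nchars = w, eos = NULL)
  put("0", 8)
  put("synthetic", 80)
  put("mispeed simulated session", 80)
  put("01.01.26", 8)
  put("00.00.00", 8)
  put(as.character(256L * (ns + 1L)), 8)
  put("", 44)
  put(as.character(n_records), 8)
  put(if (n_records > 0) .edf_num(n_samp / fs) else "1", 8)
  put(as.character(ns), 4)
  labs <- rownames(data)
  if (is.null(labs)) labs <- paste0("ch", seq_len(ns))
  for (s in labs) put(s, 16)
  for (s in labs) put("EEG electrode", 80)
  for (s in labs) put("uV", 8)
  for (c in seq_len(ns)) put(pmin_s[c], 8)
  for (c in seq_len(ns)) put(pmax_s[c], 8)
  for (c in seq_len(ns)) put("-32768", 8)
  for (c in seq_len(ns)) put("32767", 8)
  for (s in labs) put("none", 80)
  for (c in seq_len(ns)) put(as.character(n_samp), 8)
  for (c in seq_len(ns)) put("", 32)
  if (n_records > 0) {
    for (c in seq_len(ns)) {
      dig <- round((data[c, ] - pmin[c]) / (pmax[c] - pmin[c]) * 65535) - 32768
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

.read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  get <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  get(8); get(80); get(80); get(8); get(8)
  get(8)  # header bytes
  get(44)
  n_records <- as.integer(get(8))
  rec_dur <- as.numeric(get(8))
  ns <- as.integer(get(4))
  labs <- vapply(seq_len(ns), function(i) get(16), "")
  for (i in seq_len(ns)) get(80)
  for (i in seq_len(ns)) get(8)  # phys dim
  pmin <- vapply(seq_len(ns), function(i) as.numeric(get(8)), 0)
  pmax <- vapply(seq_len(ns), function(i) as.numeric(get(8)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(get(8)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(get(8)), 0)
  for (i in seq_len(ns)) get(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(get(8)), 0L)
  for (i in seq_len(ns)) get(32)
  n_samp <- if (n_records > 0) spr[1] * n_records else 0L
  fs <- if (n_records > 0) spr[1] / rec_dur else NA_real_
  data <- matrix(0, ns, n_samp, dimnames = list(labs, NULL))
  for (r in seq_len(n_records)) {
    for (c in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[c], size = 2, endian = "little")
      data[c, (r - 1) * spr[c] + seq_len(spr[c])] <-
        (dig - dmin[c]) / (dmax[c] - dmin[c]) * (pmax[c] - pmin[c]) + pmin[c]
    }
  }
  list(data = data, fs = fs)
}
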