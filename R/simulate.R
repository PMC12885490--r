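#' Build the event schedule of a session
#'
#' Lays out trials back-to-back within each run (inter-trial spacing is
#' exactly cue + MI + break) and shuffles class order within each run with a
#' seeded RNG. Event onsets mark the start of the MI period (the beep at the
#' end of the cue), as 0-based sample indices into the continuous recording.
#'
#' @param design a [session_design()].
#' @param seed integer seed; the same design and seed always yield the same
#'   schedule.
#' @return data.frame with columns `onset_sample` (0-based, MI onset),
#'   `label` (class label), `run` (1-based run index), sorted by onset.
#' @export
#' @examples
#' ev <- make_schedule(session_design(), seed = 1)
#' table(ev$label)  # 15 rest, 30 per MI class
make_schedule <- function(design, seed) {
  stopifnot(inherits(design, "session_design"))
  fs <- design$fs
  trial_len <- round(design$trial_s * fs)
  cue_len <- round(design$cue_s * fs)
  counts <- design$trials_per_class_per_run
  per_run <- rep(names(counts), times = counts)
  n_runs <- design$n_runs
  if (n_runs == 0 || length(per_run) == 0) {
    return(data.frame(onset_sample = integer(0), label = character(0),
                      run = integer(0), stringsAsFactors = FALSE))
  }
  run_seeds <- .derive_seeds(seed, n_runs)
  ev <- lapply(seq_len(n_runs), function(r) {
    labs <- .with_seed(run_seeds[r], sample(per_run))
    start <- (r - 1) * length(per_run) * trial_len
    data.frame(
      onset_sample = as.integer(start + (seq_along(labs) - 1) * trial_len + cue_len),
      label = labs, run = r, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, ev)
}

# Unit-RMS 1/f^exponent noise of length n (power-law spectral shaping).
.pink_noise <- function(n, fs, exponent) {
  if (n == 0) return(numeric(0))
  w <- stats::rnorm(n)
  if (exponent == 0) return(w / stats::sd(w))
  f <- abs(seq(0, fs, length.out = n + 1)[-(n + 1)])
  f <- pmin(f, fs - f)
  shape <- c(0, f[-1]^(-exponent / 2))
  x <- Re(stats::fft(stats::fft(w) * shape, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) x else x / s
}

# Unit-RMS narrowband noise centred at f0 with Gaussian bandwidth sigma_f.
.narrowband_noise <- function(n, fs, f0, sigma_f) {
  if (n == 0) return(numeric(0))
  w <- stats::rnorm(n)
  f <- abs(seq(0, fs, length.out = n + 1)[-(n + 1)])
  f <- pmin(f, fs - f)
  shape <- exp(-(f - f0)^2 / (2 * sigma_f^2))
  x <- Re(stats::fft(stats::fft(w) * shape, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) x else x / s
}

# Cross-channel mixing factor L (L %*% sources) giving correlation
# exp(-angle^2 / (2 * smoothness^2)) between channels, unit variances.
.spatial_mixing <- function(channels, smoothness) {
  C <- length(channels)
  if (smoothness <= 0) return(diag(C))
  pos <- as.matrix(montage_positions(channels)[, c("x", "y", "z")])
  cosang <- tcrossprod(pos)
  cosang[] <- pmax(-1, pmin(1, cosang))
  ang <- acos(cosang)
  R <- exp(-ang^2 / (2 * smoothness^2))
  e <- eigen(R, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

# ERD gain time course: 1 outside, (1 - depth) from (mi_onset - lead) to
# mi_end, with raised-cosine ramps of ramp_s at both edges.
.erd_gain <- function(n, fs, mi_on_s, mi_s, lead_s, depth, ramp_s = 0.2) {
  g <- rep(1, n)
  if (depth <= 0) return(g)
  t <- (seq_len(n) - 1) / fs
  t0 <- max(0, mi_on_s - lead_s)
  t1 <- mi_on_s + mi_s
  core <- t >= t0 & t <= t1
  g[core] <- 1 - depth
  ramp_in <- t >= t0 - ramp_s & t < t0
  g[ramp_in] <- 1 - depth * (1 + cos(pi * (t0 - t[ramp_in]) / ramp_s)) / 2
  ramp_out <- t > t1 & t <= t1 + ramp_s
  g[ramp_out] <- 1 - depth * (1 + cos(pi * (t[ramp_out] - t1) / ramp_s)) / 2
  g
}

# Sum of harmonics a_h sin(2 pi h f0 t + phase_h); harmonics above Nyquist
# are dropped with a warning.
.harmonic_stack <- function(t, f0, amps, phases, fs, what = "SSMRP") {
  s <- numeric(length(t))
  for (h in seq_along(amps)) {
    if (amps[h] == 0) next
    fh <- h * f0
    if (fh > fs / 2) {
      warning(what, " harmonic ", h, " (", fh, " Hz) above Nyquist; dropped")
      next
    }
    s <- s + amps[h] * sin(2 * pi * fh * t + phases[h])
  }
  s
}

#' Synthesize one trial of multichannel EEG
#'
#' Generates cue + MI + break worth of samples for one condition:
#' spatially correlated 1/f background, ongoing alpha/beta rhythms over
#' sensorimotor cortex (attenuated by the condition's ERD from
#' `pre_lead_s` before MI onset through the end of MI), a steady-state
#' movement-related potential (harmonic stack at the pacing fundamental,
#' sensorimotor topography) during MI, and a steady-state visual evoked
#' potential (occipital topography) during MI. Rest trials (`f0 = 0`)
#' contain background and rhythms only.
#'
#' @param cond a [condition_spec()].
#' @param noise a [noise_spec()].
#' @param design a [session_design()] (provides timing and fs).
#' @param seed integer seed; output is bit-reproducible.
#' @param channels montage channel names.
#' @return channels x samples matrix (microvolts), with channel names as
#'   rownames.
#' @export
synthesize_trial <- function(cond, noise, design, seed,
                             channels = default_channels()) {
  stopifnot(inherits(cond, "condition_spec"), inherits(noise, "noise_spec"),
            inherits(design, "session_design"))
  fs <- design$fs
  n <- round(design$trial_s * fs)
  C <- length(channels)
  .with_seed(seed, {
    H <- length(cond$harmonic_amps)
    phases_mrp <- stats::runif(H, 0, 2 * pi)
    phases_vep <- stats::runif(H, 0, 2 * pi)

    x <- matrix(0, C, n, dimnames = list(channels, NULL))
    if (noise$noise_scale > 0) {
      gain <- if (noise$background_jitter > 0) {
        exp(stats::rnorm(1, 0, noise$background_jitter))
      } else 1
      src <- matrix(0, C, n)
      for (c in seq_len(C)) {
        src[c, ] <- .pink_noise(n, fs, noise$one_over_f_exponent)
      }
      L <- .spatial_mixing(channels, noise$spatial_smoothness)
      x <- x + gain * noise$noise_scale * (L %*% src)
    }

    motor_topo <- cond$ssmrp_topography[channels]
    is_mi <- cond$f0 > 0
    g_alpha <- .erd_gain(n, fs, design$cue_s, design$mi_s, cond$pre_lead_s,
                         if (is_mi) cond$erd_alpha else 0)
    g_beta <- .erd_gain(n, fs, design$cue_s, design$mi_s, cond$pre_lead_s,
                        if (is_mi) cond$erd_beta else 0)
    if (noise$alpha_rhythm_amp > 0) {
      a <- noise$alpha_rhythm_amp * .narrowband_noise(n, fs, 10, 1) * g_alpha
      x <- x + outer(motor_topo, a)
    }
    if (noise$beta_rhythm_amp > 0) {
      b <- noise$beta_rhythm_amp * .narrowband_noise(n, fs, 20, 2) * g_beta
      x <- x + outer(motor_topo, b)
    }

    if (is_mi) {
      mi_idx <- round(design$cue_s * fs) + seq_len(round(design$mi_s * fs))
      t_mi <- (seq_along(mi_idx) - 1) / fs
      s_mrp <- .harmonic_stack(t_mi, cond$f0, cond$harmonic_amps, phases_mrp,
                               fs, "SSMRP")
      x[, mi_idx] <- x[, mi_idx] + outer(motor_topo, s_mrp)
      if (cond$ssvep_amp > 0 && max(cond$harmonic_amps) > 0) {
        amps_vep <- cond$harmonic_amps / max(cond$harmonic_amps) * cond$ssvep_amp
        s_vep <- .harmonic_stack(t_mi, cond$f0, amps_vep, phases_vep,
                                 fs, "SSVEP")
        x[, mi_idx] <- x[, mi_idx] + outer(cond$ssvep_topography[channels], s_vep)
      }
    }
    x
  })
}

#' Generate a full EEG session with ground truth
#'
#' Builds the seeded schedule, synthesizes every trial, and concatenates
#' them into one continuous recording. Fully reproducible: the same design,
#' condition map, noise spec and seed give bit-identical output.
#'
#' @param design a [session_design()].
#' @param conditions named list of [condition_spec()], one per class label
#'   (see [default_conditions()]).
#' @param noise a [noise_spec()].
#' @param seed integer seed.
#' @param channels montage channel names.
#' @return object of class `raw_session`: list with `data` (channels x
#'   samples, microvolts), `fs`, `channel_names`, `events` (data.frame),
#'   `design`, and `ground_truth` (the condition map and noise spec used).
#' @export
#' @examples
#' s <- generate_session(session_design(n_runs = 1), seed = 7)
#' nrow(s$events)  # 35
generate_session <- function(design = session_design(),
                             conditions = default_conditions(),
                             noise = noise_spec(), seed = 1,
                             channels = default_channels()) {
  stopifnot(inherits(design, "session_design"))
  missing <- setdiff(design$class_labels, names(conditions))
  if (length(missing) > 0) stop("conditions missing for: ", paste(missing, collapse = ", "))
  events <- make_schedule(design, seed)
  fs <- design$fs
  trial_len <- round(design$trial_s * fs)
  cue_len <- round(design$cue_s * fs)
  n_total <- design$n_runs * design$trials_per_run * trial_len
  data <- matrix(0, length(channels), n_total,
                 dimnames = list(channels, NULL))
  if (nrow(events) > 0) {
    trial_seeds <- .derive_seeds(seed + 1L, nrow(events))
    for (i in seq_len(nrow(events))) {
      start <- events$onset_sample[i] - cue_len
      tr <- synthesize_trial(conditions[[events$label[i]]], noise, design,
                             trial_seeds[i], channels)
      data[, start + seq_len(trial_len)] <- tr
    }
  }
  structure(list(
    data = data, fs = fs, channel_names = channels, events = events,
    design = design,
    ground_truth = list(conditions = conditions, noise = noise, seed = seed)
  ), class = "raw_session")
}

#' @export
print.raw_session <- function(x, ...) {
  cat("<raw_session> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$fs, " Hz (", round(ncol(x$data) / x$fs, 1), " s), ",
      nrow(x$events), " events\n", sep = "")
  invisible(x)
}
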