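#' Session design for a paced motor-imagery experiment
#'
#' Describes the trial timing and composition of one recording session:
#' a visual cue, a paced motor-imagery (MI) period opened by a beep, and a
#' break, repeated over several runs. The default reproduces the study
#' design this package emulates: 3 runs of 35 trials each (10 per MI speed
#' class, 5 rest), 1-s cue, 5-s MI, 2-s break.
#'
#' @param n_runs number of runs.
#' @param trials_per_class_per_run named integer vector (names must be the
#'   class labels in order rest, slow, medium, fast).
#' @param cue_s,mi_s,break_s durations in seconds; all must be positive and
#'   sample-aligned at `fs`.
#' @param fs sampling rate in Hz (>= 100).
#' @return object of class `session_design`.
#' @export
#' @examples
#' d <- session_design()
#' d$trials_per_run  # 35
session_design <- function(n_runs = 3,
                           trials_per_class_per_run = c(rest = 5, slow = 10,
                                                        medium = 10, fast = 10),
                           cue_s = 1, mi_s = 5, break_s = 2, fs = 250) {
  labels <- c("rest", "slow", "medium", "fast")
  if (!identical(names(trials_per_class_per_run), labels)) {
    stop("trials_per_class_per_run must be named, in order: ",
         paste(labels, collapse = ", "))
  }
  if (any(trials_per_class_per_run < 0) ||
      any(trials_per_class_per_run != round(trials_per_class_per_run))) {
    stop("trial counts must be non-negative integers")
  }
  if (n_runs < 0 || n_runs != round(n_runs)) stop("n_runs must be a non-negative integer")
  if (cue_s <= 0 || mi_s <= 0 || break_s <= 0) stop("all durations must be > 0")
  if (fs < 100) stop("fs must be >= 100 Hz")
  for (d in c(cue_s, mi_s, break_s)) {
    if (abs(d * fs - round(d * fs)) > 1e-9) {
      stop("duration ", d, " s is not sample-aligned at fs = ", fs, " Hz")
    }
  }
  structure(list(
    n_runs = as.integer(n_runs),
    trials_per_class_per_run = trials_per_class_per_run,
    cue_s = cue_s, mi_s = mi_s, break_s = break_s, fs = fs,
    class_labels = labels,
    trials_per_run = sum(trials_per_class_per_run),
    trial_s = cue_s + mi_s + break_s
  ), class = "session_design")
}

#' Per-condition signal specification
#'
#' Ground-truth generative parameters for one class: the pacing fundamental
#' and harmonic amplitude profile of the steady-state movement-related
#' potential (SSMRP), the steady-state visual evoked potential (SSVEP)
#' driven by the pacing stimulus, and the event-related desynchronization
#' (ERD) of ongoing alpha/beta rhythms over sensorimotor cortex, including
#' an anticipatory lead before MI onset.
#'
#' @param f0 pacing fundamental in Hz; 0 for the rest condition (no
#'   steady-state components, no ERD).
#' @param harmonic_amps amplitudes (microvolts) of harmonics 1..H of `f0`.
#'   The default profile peaks at the second harmonic and attenuates
#'   gradually above it.
#' @param erd_alpha,erd_beta fractional amplitude reduction of the alpha
#'   (8-12 Hz) and beta (12-30 Hz) rhythms during MI, in \[0, 1\].
#' @param pre_lead_s anticipatory ERD lead before MI onset, seconds.
#' @param ssvep_amp SSVEP amplitude scale (microvolts); applied with the
#'   same harmonic profile shape on the occipital topography.
#' @param ssmrp_topography,ssvep_topography named per-channel weights; by
#'   default Gaussian bumps over the sensorimotor and occipito-parietal
#'   channel sets.
#' @param channels montage used for the default topographies.
#' @return object of class `condition_spec`.
#' @export
condition_spec <- function(f0,
                           harmonic_amps = 2 * c(0.6, 1.0, 0.5, 0.25),
                           erd_alpha = 0, erd_beta = 0,
                           pre_lead_s = 1,
                           ssvep_amp = 1.5 * max(harmonic_amps),
                           ssmrp_topography = NULL,
                           ssvep_topography = NULL,
                           channels = default_channels()) {
  if (f0 < 0) stop("f0 must be >= 0")
  if (any(harmonic_amps < 0)) stop("harmonic_amps must be nonnegative")
  if (erd_alpha < 0 || erd_alpha > 1 || erd_beta < 0 || erd_beta > 1) {
    stop("erd_alpha and erd_beta must lie in [0, 1]")
  }
  if (pre_lead_s < 0) stop("pre_lead_s must be >= 0")
  if (is.null(ssmrp_topography)) {
    ssmrp_topography <- gaussian_topography(channel_set("ssmrp"), channels)
  }
  if (is.null(ssvep_topography)) {
    ssvep_topography <- gaussian_topography(channel_set("ssvep"), channels)
  }
  structure(list(
    f0 = f0, harmonic_amps = harmonic_amps,
    erd_alpha = erd_alpha, erd_beta = erd_beta,
    pre_lead_s = pre_lead_s, ssvep_amp = ssvep_amp,
    ssmrp_topography = ssmrp_topography,
    ssvep_topography = ssvep_topography
  ), class = "condition_spec")
}

#' Default condition map for the four speed classes
#'
#' Pacing fundamentals follow the paced-grasping rates of the emulated study
#' (0.93, 2.12 and 2.56 Hz for slow/medium/fast). `grid_aligned = TRUE`
#' switches to 0.9/2.1/2.6 Hz so that every harmonic falls exactly on a
#' 0.1-Hz frequency grid — the variant used by the spectral-recovery
#' fixtures. ERD depth grows with imagined speed; rest has no pacing drive
#' and no ERD.
#'
#' @param grid_aligned use grid-aligned fundamentals (0.9/2.1/2.6 Hz).
#' @param channels montage for the default topographies.
#' @param erd_alpha,erd_beta named vectors of ERD depths per class.
#' @param ... forwarded to [condition_spec()] for every class.
#' @return named list of `condition_spec`, one per class label.
#' @export
#' @examples
#' conds <- default_conditions(grid_aligned = TRUE)
#' conds$medium$f0  # 2.1
default_conditions <- function(grid_aligned = FALSE,
                               channels = default_channels(),
                               erd_alpha = c(rest = 0, slow = 0.2,
                                             medium = 0.35, fast = 0.5),
                               erd_beta = c(rest = 0, slow = 0.1,
                                            medium = 0.2, fast = 0.3),
                               ...) {
  f0 <- if (grid_aligned) {
    c(rest = 0, slow = 0.9, medium = 2.1, fast = 2.6)
  } else {
    c(rest = 0, slow = 0.93, medium = 2.12, fast = 2.56)
  }
  out <- lapply(names(f0), function(cl) {
    condition_spec(f0 = f0[[cl]], erd_alpha = erd_alpha[[cl]],
                   erd_beta = erd_beta[[cl]], channels = channels, ...)
  })
  names(out) <- names(f0)
  out
}

#' Background noise specification
#'
#' Parameters of the simulated EEG background: 1/f ("pink") broadband noise
#' with spatial correlation across channels, plus ongoing narrowband alpha
#' and beta rhythms over sensorimotor cortex (the rhythms that ERD
#' attenuates). Defaults are desk-scale realistic values for scalp EEG in
#' microvolts.
#'
#' @param one_over_f_exponent spectral slope of the background, in \[0, 2\].
#' @param noise_scale per-channel RMS of the broadband background
#'   (microvolts).
#' @param alpha_rhythm_amp,beta_rhythm_amp RMS amplitude (microvolts) of the
#'   ongoing ~10 Hz and ~20 Hz rhythms.
#' @param spatial_smoothness correlation length (radians of great-circle
#'   distance) of the background across channels; 0 gives independent
#'   channels. Volume conduction makes real EEG background spatially smooth,
#'   which matters for the current-source-density transform.
#' @param background_jitter standard deviation of a per-trial lognormal gain
#'   on the broadband background, emulating the trial-to-trial
#'   non-stationarity of real EEG backgrounds; 0 (default) keeps the
#'   background amplitude stationary across trials.
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(one_over_f_exponent = 1, noise_scale = 5,
                       alpha_rhythm_amp = 4, beta_rhythm_amp = 2,
                       spatial_smoothness = 0.8, background_jitter = 0) {
  if (one_over_f_exponent < 0 || one_over_f_exponent > 2) {
    stop("one_over_f_exponent must lie in [0, 2]")
  }
  if (noise_scale < 0 || alpha_rhythm_amp < 0 || beta_rhythm_amp < 0 ||
      spatial_smoothness < 0 || background_jitter < 0) {
    stop("scales must be >= 0")
  }
  structure(list(
    one_over_f_exponent = one_over_f_exponent,
    noise_scale = noise_scale,
    alpha_rhythm_amp = alpha_rhythm_amp,
    beta_rhythm_amp = beta_rhythm_amp,
    spatial_smoothness = spatial_smoothness,
    background_jitter = background_jitter
  ), class = "noise_spec")
}

#' @export
print.session_design <- function(x, ...) {
  cat("<session_design> ", x$n_runs, " run(s) x ", x$trials_per_run,
      " trials (", paste(sprintf("%s=%d", names(x$trials_per_class_per_run),
                                 x$trials_per_class_per_run), collapse = ", "),
      ")\n  cue ", x$cue_s, " s | MI ", x$mi_s, " s | break ", x$break_s,
      " s | fs ", x$fs, " Hz\n", sep = "")
  invisible(x)
}
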