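test_that("schedule reproduces the study composition and is deterministic", {
  d <- session_design()  # 3 runs x (10/10/10 MI + 5 rest)
  ev <- make_schedule(d, seed = 7)
  expect_equal(nrow(ev), 105)
  counts <- table(ev$label)
  expect_equal(unname(counts[c("slow", "medium", "fast")]), rep(30L, 3),
               ignore_attr = TRUE)
  expect_equal(unname(counts["rest"]), 15L, ignore_attr = TRUE)
  expect_true(all(table(ev$run) == 35))
  # inter-trial spacing within a run is exactly cue + MI + break
  on1 <- ev$onset_sample[ev$run == 1]
  expect_equal(unique(diff(on1)), d$trial_s * d$fs)
  expect_identical(ev, make_schedule(d, seed = 7))
  expect_false(identical(ev$label, make_schedule(d, seed = 8)$label))
})

test_that("degenerate schedules and invalid timing are handled", {
  d1 <- session_design(n_runs = 1,
                       trials_per_class_per_run = c(rest = 0, slow = 1,
                                                    medium = 0, fast = 0))
  ev <- make_schedule(d1, seed = 1)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$onset_sample, d1$cue_s * d1$fs)
  expect_equal(nrow(make_schedule(session_design(n_runs = 0), seed = 1)), 0)
  # durations that are not sample-aligned are rejected up front
  expect_error(session_design(cue_s = 1.0001), "sample-aligned")
  expect_error(session_design(fs = 50), "fs")
})

test_that("a noiseless single-harmonic trial is a pure sine during MI", {
  d <- session_design(n_runs = 1, cue_s = 1, mi_s = 1, break_s = 1, fs = 250)
  cond <- condition_spec(f0 = 2, harmonic_amps = 1, ssvep_amp = 0,
                         ssmrp_topography = c(Cz = 1), channels = "Cz")
  x <- synthesize_trial(cond, quiet_noise(), d, seed = 3, channels = "Cz")
  mi <- 250 + seq_len(250)
  t <- (seq_len(250) - 1) / 250
  # recover the phase by quadrature projection, then compare exactly
  a <- 2 * mean(x[1, mi] * sin(2 * pi * 2 * t))
  b <- 2 * mean(x[1, mi] * cos(2 * pi * 2 * t))
  expect_equal(sqrt(a^2 + b^2), 1, tolerance = 1e-6)
  expect_equal(x[1, mi], sin(2 * pi * 2 * t + atan2(b, a)), tolerance = 1e-9)
  # outside MI the channel is silent (no background requested)
  expect_equal(x[1, 1:250], rep(0, 250))
})

test_that("harmonic energy in a noiseless trial peaks at the second harmonic", {
  d <- session_design(n_runs = 1)
  cond <- default_conditions(grid_aligned = TRUE)$medium  # f0 = 2.1 Hz
  x <- synthesize_trial(cond, quiet_noise(), d, seed = 5)
  mi <- 250 + seq_len(1250)
  cz <- x[which(default_channels() == "Cz"), mi]
  sp <- abs(fft(cz))^2
  freqs <- (seq_along(sp) - 1) * 250 / length(sp)
  harm_bins <- vapply(1:4, function(h) which.min(abs(freqs - h * 2.1)), 0L)
  expect_equal(which.max(sp[harm_bins]), 2)
})

test_that("noiseless periodogram peaks only at harmonic bins", {
  # f0 = 2 Hz puts every harmonic exactly on the 0.2-Hz grid of a 5-s MI span
  d <- session_design(n_runs = 1)
  cond <- condition_spec(f0 = 2, ssvep_amp = 0,
                         ssmrp_topography = c(Cz = 1), channels = "Cz")
  x <- synthesize_trial(cond, quiet_noise(), d, seed = 5, channels = "Cz")
  cz <- x[1, 250 + seq_len(1250)]
  sp <- abs(fft(cz))^2
  freqs <- (seq_along(sp) - 1) * 250 / length(sp)
  harm_bins <- vapply(1:4, function(h) which.min(abs(freqs - h * 2)), 0L)
  off <- setdiff(which(freqs < 125), harm_bins)
  expect_lt(max(sp[off]) / max(sp[harm_bins]), 1e-6)
})

test_that("harmonics above Nyquist are dropped with a warning", {
  d <- session_design(n_runs = 1, fs = 100)
  cond <- condition_spec(f0 = 30, harmonic_amps = c(1, 1),  # 2nd harmonic 60 Hz
                         ssvep_amp = 0)
  expect_warning(synthesize_trial(cond, quiet_noise(), d, seed = 1),
                 "SSMRP harmonic 2.*above Nyquist")
})

test_that("rest trials show no steady-state peaks (SNR ~ 1 at harmonics)", {
  d <- session_design(n_runs = 1)
  conds <- default_conditions(grid_aligned = TRUE)
  seeds <- mispeed:::.derive_seeds(42, 100)
  dat <- array(0, c(100, 14, 1250))
  for (i in 1:100) {
    tr <- synthesize_trial(conds$rest, noise_spec(), d, seeds[i])
    dat[i, , ] <- tr[, 251:1500]
  }
  ep <- manual_epochs(dat, fs = 250, labels = rep("rest", 100),
                      channels = default_channels())
  snr <- snr_spectrum(welch_psd(ep, "ssmrp", segment_s = NULL, overlap = 0))
  harm <- harmonic_readout(snr, f0 = 2.1, n_harmonics = 3)
  expect_true(all(harm$snr > 0.5 & harm$snr < 2))
  expect_false(any(harm$is_global_max & harm$snr > 2))
})

test_that("ERD attenuates MI-period alpha power by (1 - erd_alpha)^2", {
  d <- session_design(n_runs = 1)
  erd <- 0.5
  conds <- default_conditions(erd_alpha = c(rest = 0, slow = 0, medium = 0,
                                            fast = erd))
  nz <- noise_spec(noise_scale = 0.1, alpha_rhythm_amp = 4,
                   beta_rhythm_amp = 0)
  seeds <- mispeed:::.derive_seeds(9, 200)
  cz <- which(default_channels() == "Cz")
  mi <- 250 + 125 + seq_len(1000)  # interior of MI, clear of ramps
  bp <- function(x) {
    sp <- abs(fft(x))^2
    f <- (seq_along(x) - 1) * 250 / length(x)
    mean(sp[f >= 8 & f <= 12])
  }
  p_fast <- mean(vapply(1:100, function(i) {
    bp(synthesize_trial(conds$fast, nz, d, seeds[i])[cz, mi])
  }, 0))
  p_rest <- mean(vapply(101:200, function(i) {
    bp(synthesize_trial(conds$rest, nz, d, seeds[i])[cz, mi])
  }, 0))
  expect_equal(p_fast / p_rest, (1 - erd)^2, tolerance = 0.1)
})

test_that("sessions are seed-reproducible with conserved class counts", {
  d <- session_design(n_runs = 1,
                      trials_per_class_per_run = c(rest = 1, slow = 1,
                                                   medium = 1, fast = 1))
  s1 <- generate_session(d, seed = 5)
  s2 <- generate_session(d, seed = 5)
  expect_identical(s1$data, s2$data)
  s3 <- generate_session(d, seed = 6)
  expect_false(identical(s1$data, s3$data))
  expect_equal(table(s1$events$label), table(s3$events$label))
  # every event window fits in the recording
  expect_true(all(s1$events$onset_sample + d$mi_s * d$fs <= ncol(s1$data)))
  empty <- generate_session(session_design(n_runs = 0), seed = 1)
  expect_equal(nrow(empty$events), 0)
  expect_equal(ncol(empty$data), 0)
})

test_that("EDF + events round trip preserves events and quantized signal", {
  s <- generate_session(
    session_design(n_runs = 1,
                   trials_per_class_per_run = c(rest = 1, slow = 1,
                                                medium = 1, fast = 2)),
    seed = 12)
  dir <- withr::local_tempdir()
  write_session(s, dir)
  r <- read_session(dir)
  expect_identical(r$channel_names, s$channel_names)
  expect_equal(r$fs, s$fs)
  expect_identical(r$events$onset_sample, s$events$onset_sample)
  expect_identical(r$events$label, s$events$label)
  # quantization: error bounded by one 16-bit step of each channel's range
  step <- apply(s$data, 1, function(x) diff(range(x))) / 65000
  expect_true(all(abs(r$data - s$data) <= step * 1.2))
})

test_that("session reader rejects bad inputs explicitly", {
  expect_error(read_session(file.path(tempdir(), "nope")), "missing file")
  s <- generate_session(session_design(
    n_runs = 1, trials_per_class_per_run = c(rest = 1, slow = 1, medium = 1,
                                             fast = 1)), seed = 2)
  dir <- withr::local_tempdir()
  write_session(s, dir)
  ev <- utils::read.delim(file.path(dir, "events.tsv"))
  ev$trial_type[1] <- "sprint"
  utils::write.table(ev, file.path(dir, "events.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_error(read_session(dir), "sprint.*rest, slow, medium, fast")
})

test_that("an empty-event session round-trips", {
  empty <- generate_session(session_design(n_runs = 0), seed = 1)
  dir <- withr::local_tempdir()
  write_session(empty, dir)
  r <- read_session(dir)
  expect_equal(nrow(r$events), 0)
})
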