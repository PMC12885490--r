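# Shared fixtures. Everything is generated in code; heavier objects are
# built once per test run and reused read-only.

quiet_noise <- function() {
  noise_spec(noise_scale = 0, alpha_rhythm_amp = 0, beta_rhythm_amp = 0)
}

# A one-run default-design session with full noise (generated once).
fixture_env <- new.env()

small_session <- function() {
  if (is.null(fixture_env$small_session)) {
    fixture_env$small_session <- generate_session(
      session_design(n_runs = 1), seed = 101)
  }
  fixture_env$small_session
}

# Minimal epoch_set built directly from an array (bypasses simulation).
manual_epochs <- function(data, fs, t0 = 0, labels = NULL, run = NULL,
                          channels = NULL, normalized = FALSE) {
  d <- dim(data)
  structure(list(
    data = data,
    labels = labels %||% rep("medium", d[1]),
    label_index = match(labels %||% rep("medium", d[1]),
                        c("rest", "slow", "medium", "fast")) - 1L,
    run = run %||% rep(1L, d[1]),
    time_axis = t0 + (seq_len(d[3]) - 1) / fs,
    fs = fs,
    channel_names = channels %||% paste0("ch", seq_len(d[2])),
    class_labels = c("rest", "slow", "medium", "fast"),
    normalized = normalized
  ), class = "epoch_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Tiny conformer geometry used by model/xai unit tests.
tiny_config <- function(dropout = 0) {
  conformer_config(n_temporal_filters = 4, temporal_kernel_len = 5,
                   pool_len = 10, pool_stride = 5, embed_dim = 4,
                   n_attention_layers = 2, n_heads = 2, dropout = dropout,
                   n_classes = 4, ffn_mult = 2)
}

# An untrained model wrapper around seeded random parameters, for
# interpretation-path tests that do not need a fitted decoder.
untrained_model <- function(cfg, C, T, fs, seed = 1,
                            channels = paste0("ch", seq_len(C)),
                            t0 = 0) {
  dims <- mispeed:::.conformer_dims(cfg, C, T)
  p <- mispeed:::.with_seed(seed, mispeed:::.conformer_init(cfg, dims))
  structure(list(params = p, config = cfg, dims = dims,
                 training_log = NULL, seed = seed,
                 channel_names = channels,
                 class_labels = c("rest", "slow", "medium", "fast"),
                 fs = fs, time_axis = t0 + (seq_len(T) - 1) / fs),
            class = "conformer_model")
}
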