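#' Majority-class chance level
#'
#' With unbalanced trial counts the accuracy of always predicting the
#' majority class; for the default session design (30 trials per MI class,
#' 15 rest) this is 30/105 = 0.2857.
#'
#' @param class_counts positive counts, one per class.
#' @return proportion in (0, 1\].
#' @export
#' @examples
#' chance_level(c(rest = 15, slow = 30, medium = 30, fast = 30))
chance_level <- function(class_counts) {
  if (length(class_counts) == 0) stop("empty class counts")
  if (any(class_counts <= 0)) stop("class counts must be positive")
  max(class_counts) / sum(class_counts)
}

#' Classification metrics report
#'
#' Accuracy (percent), macro and support-weighted F1, Cohen's kappa,
#' per-class precision/recall with weighted means, the raw confusion
#' matrix (rows = true, columns = predicted) and its predicted-normalized
#' form (columns as proportions), and the majority-class chance level of
#' the true labels. Precision of a never-predicted class is reported as 0
#' and flagged.
#'
#' @param truth,pred equal-length vectors of labels: 0-based class indices
#'   or label strings drawn from `class_labels`.
#' @param class_labels ordered class label set.
#' @return object of class `metrics_report`.
#' @export
compute_metrics <- function(truth, pred,
                            class_labels = c("rest", "slow", "medium", "fast")) {
  to_idx <- function(x, what) {
    if (is.numeric(x)) {
      if (any(x < 0 | x >= length(class_labels))) {
        stop(what, " contains a class index outside 0..", length(class_labels) - 1)
      }
      as.integer(x) + 1L
    } else {
      i <- match(as.character(x), class_labels)
      if (anyNA(i)) {
        stop(what, " contains label(s) outside the class set: ",
             paste(unique(x[is.na(i)]), collapse = ", "))
      }
      i
    }
  }
  if (length(truth) != length(pred) || length(truth) == 0) {
    stop("truth and pred must be nonempty and of equal length")
  }
  ti <- to_idx(truth, "truth")
  pi <- to_idx(pred, "pred")
  k <- length(class_labels)
  n <- length(ti)
  cm <- matrix(0L, k, k, dimnames = list(true = class_labels, pred = class_labels))
  for (i in seq_len(n)) cm[ti[i], pi[i]] <- cm[ti[i], pi[i]] + 1L
  p_o <- sum(diag(cm)) / n
  row_m <- rowSums(cm) / n
  col_m <- colSums(cm) / n
  p_e <- sum(row_m * col_m)
  kappa <- if (p_e < 1) (p_o - p_e) / (1 - p_e) else 0
  support <- rowSums(cm)
  pred_tot <- colSums(cm)
  precision <- ifelse(pred_tot > 0, diag(cm) / pred_tot, 0)
  precision_undefined <- pred_tot == 0
  recall <- ifelse(support > 0, diag(cm) / support, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  wts <- support / n
  cm_pred_norm <- matrix(NA_real_, k, k,
                         dimnames = dimnames(cm))
  nzc <- pred_tot > 0
  cm_pred_norm[, nzc] <- sweep(cm[, nzc, drop = FALSE], 2, pred_tot[nzc], "/")
  structure(list(
    accuracy = 100 * p_o,
    f1_macro = mean(f1),
    f1_weighted = sum(wts * f1),
    kappa = kappa,
    precision = precision,
    recall = recall,
    precision_undefined = precision_undefined,
    precision_weighted = sum(wts * precision),
    recall_weighted = sum(wts * recall),
    confusion_raw = cm,
    confusion_pred_normalized = cm_pred_norm,
    chance_level = chance_level(table(factor(class_labels[ti], levels = class_labels))),
    n = n, class_labels = class_labels
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> n = ", x$n, "\n",
      sprintf("  accuracy %.2f%% | kappa %.4f | F1 macro %.4f | F1 weighted %.4f\n",
              x$accuracy, x$kappa, x$f1_macro, x$f1_weighted),
      sprintf("  weighted precision %.4f | weighted recall %.4f | chance %.4f\n",
              x$precision_weighted, x$recall_weighted, x$chance_level), sep = "")
  print(x$confusion_raw)
  invisible(x)
}

#' Pipeline configuration profiles
#'
#' Bundles every stage's parameters. `"default"` is the full desk-scale
#' study design; `"high_separability"` strengthens the class-discriminative
#' components (deeper, more graded ERD; larger steady-state amplitudes;
#' less background noise) for decoder-recovery runs; `"tiny"` is a
#' smoke-test profile (2 runs, 2-3 trials per class, small model).
#'
#' @param profile one of `"default"`, `"high_separability"`, `"tiny"`.
#' @param ... named overrides of top-level config entries.
#' @return nested list of stage parameters.
#' @export
pipeline_config <- function(profile = c("default", "high_separability", "tiny"),
                            ...) {
  profile <- match.arg(profile)
  cfg <- list(
    profile = profile,
    design = list(n_runs = 3,
                  trials_per_class_per_run = c(rest = 5, slow = 10,
                                               medium = 10, fast = 10),
                  cue_s = 1, mi_s = 5, break_s = 2, fs = 250),
    conditions = list(grid_aligned = FALSE,
                      erd_alpha = c(rest = 0, slow = 0.2, medium = 0.35, fast = 0.5),
                      erd_beta = c(rest = 0, slow = 0.1, medium = 0.2, fast = 0.3),
                      amp_scale = 1),
    noise = list(one_over_f_exponent = 1, noise_scale = 5,
                 alpha_rhythm_amp = 4, beta_rhythm_amp = 2,
                 spatial_smoothness = 0.8),
    preprocess = list(band = c(4, 40), window = c(-1, 5), scheme = "loro"),
    model = list(n_temporal_filters = 40, temporal_kernel_len = 25,
                 pool_len = 75, pool_stride = 15, embed_dim = 40,
                 n_attention_layers = 2, n_heads = 4, dropout = 0.5),
    train = list(lr = 1e-3, batch_size = 16, max_passes = 100, patience = 20,
                 val_fraction = 0.2),
    spectral = list(segment_s = NULL, overlap = 0, n_neighbors = 5,
                    n_harmonics = 4, use_csd = FALSE)
  )
  if (profile == "high_separability") {
    cfg$design$fs <- 125
    cfg$conditions$erd_alpha <- c(rest = 0, slow = 0.35, medium = 0.65, fast = 0.9)
    cfg$conditions$erd_beta <- c(rest = 0, slow = 0.25, medium = 0.5, fast = 0.75)
    cfg$conditions$amp_scale <- 4
    cfg$noise$noise_scale <- 2
    cfg$train <- list(lr = 2e-3, batch_size = 8, max_passes = 70,
                      patience = 15, val_fraction = 0.25)
  }
  if (profile == "tiny") {
    cfg$design$n_runs <- 2
    cfg$design$trials_per_class_per_run <- c(rest = 2, slow = 3, medium = 3, fast = 3)
    cfg$design$fs <- 100
    cfg$preprocess$band <- c(4, 40)
    cfg$model <- list(n_temporal_filters = 8, temporal_kernel_len = 11,
                      pool_len = 30, pool_stride = 10, embed_dim = 8,
                      n_attention_layers = 1, n_heads = 2, dropout = 0.25)
    cfg$train <- list(lr = 1e-3, batch_size = 8, max_passes = 3, patience = 3,
                      val_fraction = 0.25)
  }
  overrides <- list(...)
  for (nm in names(overrides)) cfg[[nm]] <- utils::modifyList(
    if (is.list(cfg[[nm]])) cfg[[nm]] else list(), overrides[[nm]],
    keep.null = TRUE)
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys mirror [pipeline_config()].
#' @return nested config list (missing entries filled from the default
#'   profile).
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- pipeline_config(profile = user$profile %||% "default")
  for (nm in setdiff(names(user), "profile")) {
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      u <- user[[nm]]
      # YAML maps come back as lists; coerce per-class maps to named vectors
      for (k in names(u)) if (is.list(u[[k]])) u[[k]] <- unlist(u[[k]])
      base[[nm]] <- utils::modifyList(base[[nm]], u)
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.cfg_objects <- function(cfg) {
  design <- do.call(session_design, cfg$design)
  conditions <- default_conditions(
    grid_aligned = isTRUE(cfg$conditions$grid_aligned),
    erd_alpha = cfg$conditions$erd_alpha,
    erd_beta = cfg$conditions$erd_beta,
    harmonic_amps = cfg$conditions$amp_scale * 2 * c(0.6, 1.0, 0.5, 0.25))
  noise <- do.call(noise_spec, cfg$noise)
  list(design = design, conditions = conditions, noise = noise)
}

#' Run the full analysis pipeline
#'
#' simulate -> band-pass -> epoch -> normalize -> leave-one-run-out
#' training -> pooled metrics -> model interpretation (kernel spectra,
#' spatial pattern, CAM, CAT) -> steady-state PSD/SNR analysis. Writes
#' tab-separated tables, a machine-readable `summary.json` (deterministic
#' for a given config and seed) and a human-readable `report.txt` under
#' `out_dir`.
#'
#' @param config a [pipeline_config()] list (or path to a YAML file).
#' @param seed integer master seed for simulation and training.
#' @param out_dir output directory.
#' @param stages subset of `c("simulate", "preprocess", "train", "xai",
#'   "spectral")`; later stages require earlier ones.
#' @return invisibly, a list with the session, epochs, fold results, pooled
#'   metrics and xai/spectral outputs (those that ran).
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1,
                         out_dir = "mispeed_report",
                         stages = c("simulate", "preprocess", "train",
                                    "xai", "spectral")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(s) s %in% stages
  res <- list(seed = seed)
  obj <- .cfg_objects(config)

  message("[simulate] generating session (seed ", seed, ")")
  session <- generate_session(obj$design, obj$conditions, obj$noise, seed = seed)
  res$session <- session
  write_session(session, file.path(out_dir, "session"))
  if (!any(stage(c("preprocess", "train", "xai", "spectral")))) {
    .write_summary(res, config, out_dir)
    return(invisible(res))
  }

  message("[preprocess] band-pass ", config$preprocess$band[1], "-",
          config$preprocess$band[2], " Hz, window [",
          config$preprocess$window[1], ", ", config$preprocess$window[2], "] s")
  filtered <- bandpass(session, config$preprocess$band[1], config$preprocess$band[2])
  epochs <- epoch_session(filtered, config$preprocess$window[1],
                          config$preprocess$window[2])
  epochs_n <- normalize_epochs(epochs)
  res$epochs <- epochs_n

  if (stage("train")) {
    folds <- split_epochs(epochs_n, scheme = config$preprocess$scheme)
    mcfg <- do.call(conformer_config, config$model)
    fold_seeds <- .derive_seeds(seed + 2L, length(folds))
    fold_out <- list()
    truth_all <- integer(0)
    pred_all <- integer(0)
    for (f in seq_along(folds)) {
      message("[train] fold ", f, "/", length(folds))
      tr <- folds[[f]]$train
      inner <- .inner_val_split(tr, config$train$val_fraction, fold_seeds[f])
      model <- train_conformer(mcfg, inner$train, inner$val,
                               seed = fold_seeds[f],
                               lr = config$train$lr,
                               batch_size = config$train$batch_size,
                               max_passes = config$train$max_passes,
                               patience = config$train$patience)
      pred <- predict_classes(model, folds[[f]]$test)
      truth_all <- c(truth_all, folds[[f]]$test$label_index)
      pred_all <- c(pred_all, unname(pred))
      fold_out[[f]] <- list(model = model,
                            metrics = compute_metrics(folds[[f]]$test$label_index, pred))
    }
    res$folds <- fold_out
    res$metrics <- compute_metrics(truth_all, pred_all)
    message(sprintf("[evaluate] pooled accuracy %.2f%%, kappa %.4f",
                    res$metrics$accuracy, res$metrics$kappa))
  }

  if (stage("xai") && !is.null(res$folds)) {
    message("[xai] interpreting fold-1 model")
    model <- res$folds[[1]]$model
    ks <- kernel_frequency_response(model)
    sp <- spatial_pattern(model)
    cams <- lapply(model$class_labels, function(cl) gradcam(model, epochs_n, cl))
    names(cams) <- model$class_labels
    cats <- lapply(model$class_labels, function(cl) {
      cat_topography(cams[[cl]], epochs_n, cl)
    })
    names(cats) <- model$class_labels
    res$xai <- list(kernel_spectra = ks, spatial_pattern = sp,
                    cam = cams, cat = cats)
    utils::write.table(
      data.frame(freq = ks$freq, mean_magnitude = ks$mean_magnitude),
      file.path(out_dir, "kernel_spectra.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(channel = rownames(sp$normalized_abs), sp$normalized_abs),
      file.path(out_dir, "spatial_pattern.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    cam_tab <- do.call(rbind, lapply(names(cams), function(cl) {
      data.frame(class = cl, bin_start_s = cams[[cl]]$bin_starts,
                 value = cams[[cl]]$binned)
    }))
    utils::write.table(cam_tab, file.path(out_dir, "cam.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cat_tab <- do.call(rbind, lapply(names(cats), function(cl) {
      data.frame(class = cl, channel = names(cats[[cl]]$values),
                 value = unname(cats[[cl]]$values))
    }))
    utils::write.table(cat_tab, file.path(out_dir, "cat.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (stage("spectral")) {
    message("[spectral] steady-state PSD/SNR")
    raw_epochs <- epoch_session(session, 0, obj$design$mi_s)
    if (isTRUE(config$spectral$use_csd)) raw_epochs <- csd_transform(raw_epochs)
    sp_out <- list()
    for (cl in c("medium", "fast")) {
      sub <- epoch_subset(raw_epochs, which(raw_epochs$labels == cl))
      if (dim(sub$data)[1] == 0) next
      psd <- welch_psd(sub, channels = "ssmrp",
                       segment_s = config$spectral$segment_s,
                       overlap = config$spectral$overlap)
      snr <- snr_spectrum(psd, n_neighbors = config$spectral$n_neighbors)
      harm <- harmonic_readout(snr, obj$conditions[[cl]]$f0,
                               config$spectral$n_harmonics)
      sp_out[[cl]] <- list(psd = psd, snr = snr, harmonics = harm)
      utils::write.table(
        data.frame(freq = psd$freq, psd_db = psd$psd_db, snr = snr$snr),
        file.path(out_dir, paste0("snr_", cl, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(harm, file.path(out_dir, paste0("harmonics_", cl, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    res$spectral <- sp_out
  }

  .write_summary(res, config, out_dir)
  invisible(res)
}

# Stratified inner train/validation split for early stopping.
.inner_val_split <- function(epochs, val_fraction, seed) {
  idx_val <- integer(0)
  .with_seed(seed, {
    for (cl in unique(epochs$labels)) {
      idx <- which(epochs$labels == cl)
      n_val <- max(1, round(length(idx) * val_fraction))
      idx_val <- c(idx_val, sample(idx, n_val))
    }
  })
  list(train = epoch_subset(epochs, setdiff(seq_along(epochs$labels), idx_val)),
       val = epoch_subset(epochs, sort(idx_val)))
}

.write_summary <- function(res, config, out_dir) {
  s <- list(schema_version = "1.0", seed = res$seed, profile = config$profile)
  if (!is.null(res$session)) {
    s$session <- list(
      n_events = nrow(res$session$events),
      per_class = as.list(table(res$session$events$label)),
      fs = res$session$fs, n_channels = nrow(res$session$data))
  }
  if (!is.null(res$metrics)) {
    m <- res$metrics
    s$metrics <- list(
      accuracy = m$accuracy, f1_macro = m$f1_macro, f1_weighted = m$f1_weighted,
      kappa = m$kappa, precision = as.list(m$precision),
      recall = as.list(m$recall),
      precision_weighted = m$precision_weighted,
      recall_weighted = m$recall_weighted,
      chance_level = m$chance_level,
      per_fold_accuracy = vapply(res$folds, function(f) f$metrics$accuracy, 0),
      confusion_raw = unname(apply(m$confusion_raw, 1, as.list)))
  }
  if (!is.null(res$spectral)) {
    s$spectral <- lapply(res$spectral, function(x) {
      peak <- x$harmonics[x$harmonics$is_global_max, , drop = FALSE]
      list(global_max_freq = if (nrow(peak) > 0) peak$freq[1] else NA,
           harmonics = list(freq = x$harmonics$freq, snr = x$harmonics$snr))
    })
  }
  jsonlite::write_json(s, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  rpt <- file.path(out_dir, "report.txt")
  lines <- c("mispeed pipeline report",
             paste0("seed: ", res$seed, "  profile: ", config$profile))
  if (!is.null(res$metrics)) {
    lines <- c(lines,
               sprintf("pooled accuracy: %.2f%% (chance %.4f)",
                       res$metrics$accuracy, res$metrics$chance_level),
               sprintf("kappa: %.4f  F1(macro): %.4f  F1(weighted): %.4f",
                       res$metrics$kappa, res$metrics$f1_macro,
                       res$metrics$f1_weighted))
  }
  writeLines(lines, rpt)
  invisible(s)
}
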