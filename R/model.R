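#' Conv-transformer configuration
#'
#' Architecture of the EEG speed decoder: a convolution module (temporal
#' filter bank applied per channel, then a spatial filter matrix mixing
#' channels per filter, ELU, average pooling into a token sequence), a
#' self-attention module (post-norm transformer encoder layers), and a
#' classification module (flatten + fully connected). Defaults are
#' desk-scale: small enough that one synthetic session trains on a single
#' CPU in minutes.
#'
#' @param n_temporal_filters number of temporal kernels.
#' @param temporal_kernel_len kernel length in samples.
#' @param pool_len,pool_stride average-pooling window and stride (samples of
#'   the convolution output).
#' @param embed_dim token embedding dimension; must be divisible by
#'   `n_heads`.
#' @param n_attention_layers transformer encoder depth.
#' @param n_heads attention heads.
#' @param dropout dropout probability (tokens, attention output, feed-forward
#'   output, pre-classifier).
#' @param n_classes number of classes (4: rest/slow/medium/fast).
#' @param ffn_mult feed-forward hidden width as a multiple of `embed_dim`.
#' @return object of class `conformer_config`.
#' @export
conformer_config <- function(n_temporal_filters = 40, temporal_kernel_len = 25,
                             pool_len = 75, pool_stride = 15, embed_dim = 40,
                             n_attention_layers = 2, n_heads = 4,
                             dropout = 0.5, n_classes = 4, ffn_mult = 2) {
  if (embed_dim %% n_heads != 0) stop("embed_dim must be divisible by n_heads")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  structure(as.list(environment()), class = "conformer_config")
}

# Geometry derived from a config and an input shape (channels x samples).
.conformer_dims <- function(cfg, C, T) {
  L <- cfg$temporal_kernel_len
  if (L >= T) stop("temporal kernel (", L, ") must be shorter than the epoch (", T, ")")
  T1 <- T - L + 1
  if (cfg$pool_len > T1) stop("pool window exceeds the convolution output")
  n_tok <- floor((T1 - cfg$pool_len) / cfg$pool_stride) + 1
  Pm <- matrix(0, T1, n_tok)
  for (k in seq_len(n_tok)) {
    Pm[(k - 1) * cfg$pool_stride + seq_len(cfg$pool_len), k] <- 1 / cfg$pool_len
  }
  # receptive-field centre of each token on the input sample axis (1-based)
  token_centers <- (seq_len(n_tok) - 1) * cfg$pool_stride + 1 +
    (cfg$pool_len - 1) / 2 + (L - 1) / 2
  list(C = C, T = T, T1 = T1, L = L, F = cfg$n_temporal_filters,
       D = cfg$embed_dim, H = cfg$n_heads, dh = cfg$embed_dim / cfg$n_heads,
       Dff = cfg$ffn_mult * cfg$embed_dim, n_classes = cfg$n_classes,
       n_layers = cfg$n_attention_layers, n_tok = n_tok, Pm = Pm,
       token_centers = token_centers)
}

.glorot <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

.conformer_init <- function(cfg, dims) {
  p <- list(
    # temporal kernels start small so the trained filter bank's spectrum
    # reflects learned structure rather than the random initialization
    K = 0.2 * .glorot(dims$F, dims$L),
    W = .glorot(dims$F, dims$C),
    b_conv = numeric(dims$F),
    Wp = .glorot(dims$D, dims$F),
    bp = numeric(dims$D)
  )
  for (l in seq_len(dims$n_layers)) {
    p[[paste0("Wq", l)]] <- .glorot(dims$D, dims$D)
    p[[paste0("Wk", l)]] <- .glorot(dims$D, dims$D)
    p[[paste0("Wv", l)]] <- .glorot(dims$D, dims$D)
    p[[paste0("Wo", l)]] <- .glorot(dims$D, dims$D)
    p[[paste0("bq", l)]] <- numeric(dims$D)
    p[[paste0("bk", l)]] <- numeric(dims$D)
    p[[paste0("bv", l)]] <- numeric(dims$D)
    p[[paste0("bo", l)]] <- numeric(dims$D)
    p[[paste0("g1", l)]] <- rep(1, dims$D)
    p[[paste0("h1", l)]] <- numeric(dims$D)
    p[[paste0("W1", l)]] <- .glorot(dims$Dff, dims$D)
    p[[paste0("b1", l)]] <- numeric(dims$Dff)
    p[[paste0("W2", l)]] <- .glorot(dims$D, dims$Dff)
    p[[paste0("b2", l)]] <- numeric(dims$D)
    p[[paste0("g2", l)]] <- rep(1, dims$D)
    p[[paste0("h2", l)]] <- numeric(dims$D)
  }
  p$Wc <- .glorot(cfg$n_classes, dims$n_tok * dims$D)
  p$bc <- numeric(cfg$n_classes)
  p
}


.layernorm <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  v <- rowMeans(x^2) - mu^2
  sig <- sqrt(v + eps)
  xhat <- (x - mu) / sig
  list(y = sweep(xhat, 2, g, "*") + rep(b, each = nrow(x)),
       xhat = xhat, sig = sig)
}

.layernorm_grad <- function(dy, ln, g) {
  gy <- sweep(dy, 2, g, "*")
  dg <- colSums(dy * ln$xhat)
  db <- colSums(dy)
  dx <- (gy - rowMeans(gy) - ln$xhat * rowMeans(gy * ln$xhat)) / ln$sig
  list(dx = dx, dg = dg, db = db)
}

.row_softmax <- function(x) {
  m <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  e <- exp(x - m)
  e / rowSums(e)
}

# Forward pass for one trial (x: channels x samples). `drop` is NULL (eval
# mode) or a dropout probability; masks are drawn from the current RNG
# stream. The temporal convolution (valid, with the time-reversed kernel)
# and the per-filter spatial projection commute, so the cheap spatial
# projection is applied first: S[f, ] = conv(W[f, ] %*% X, K[f, ]).
.conformer_forward <- function(p, cfg, dims, x, drop = NULL) {
  cache <- list(x = x)
  Xs <- p$W %*% x  # F x T spatially projected signals
  S <- matrix(p$b_conv, dims$F, dims$T1)
  for (l in seq_len(dims$L)) {
    S <- S + Xs[, l:(l + dims$T1 - 1), drop = FALSE] * p$K[, l]
  }
  cache$Xs <- Xs
  A <- .elu(S)
  Apool <- A %*% dims$Pm
  cache$S <- S; cache$Apool <- Apool

  keep <- function(nr, nc) {
    if (is.null(drop) || drop == 0) return(NULL)
    matrix(stats::rbinom(nr * nc, 1, 1 - drop), nr, nc) / (1 - drop)
  }
  Z0 <- t(Apool)
  m_tok <- keep(dims$n_tok, dims$F)
  if (!is.null(m_tok)) Z0 <- Z0 * m_tok
  cache$m_tok <- m_tok; cache$Z0 <- Z0
  Z <- tcrossprod(Z0, p$Wp) + rep(p$bp, each = dims$n_tok)

  cache$layers <- vector("list", dims$n_layers)
  for (l in seq_len(dims$n_layers)) {
    lc <- list(Zin = Z)
    Q <- tcrossprod(Z, p[[paste0("Wq", l)]]) + rep(p[[paste0("bq", l)]], each = dims$n_tok)
    Km <- tcrossprod(Z, p[[paste0("Wk", l)]]) + rep(p[[paste0("bk", l)]], each = dims$n_tok)
    V <- tcrossprod(Z, p[[paste0("Wv", l)]]) + rep(p[[paste0("bv", l)]], each = dims$n_tok)
    O <- matrix(0, dims$n_tok, dims$D)
    lc$P <- vector("list", dims$H)
    for (h in seq_len(dims$H)) {
      hi <- (h - 1) * dims$dh + seq_len(dims$dh)
      Sc <- tcrossprod(Q[, hi, drop = FALSE], Km[, hi, drop = FALSE]) / sqrt(dims$dh)
      P <- .row_softmax(Sc)
      lc$P[[h]] <- P
      O[, hi] <- P %*% V[, hi, drop = FALSE]
    }
    lc$Q <- Q; lc$Km <- Km; lc$V <- V; lc$O <- O
    O2 <- tcrossprod(O, p[[paste0("Wo", l)]]) + rep(p[[paste0("bo", l)]], each = dims$n_tok)
    lc$m_att <- keep(dims$n_tok, dims$D)
    if (!is.null(lc$m_att)) O2 <- O2 * lc$m_att
    R1 <- Z + O2
    ln1 <- .layernorm(R1, p[[paste0("g1", l)]], p[[paste0("h1", l)]])
    Z1 <- ln1$y
    pre1 <- tcrossprod(Z1, p[[paste0("W1", l)]]) + rep(p[[paste0("b1", l)]], each = dims$n_tok)
    Ff <- .gelu(pre1)
    F2 <- tcrossprod(Ff, p[[paste0("W2", l)]]) + rep(p[[paste0("b2", l)]], each = dims$n_tok)
    lc$m_ffn <- keep(dims$n_tok, dims$D)
    if (!is.null(lc$m_ffn)) F2 <- F2 * lc$m_ffn
    R2 <- Z1 + F2
    ln2 <- .layernorm(R2, p[[paste0("g2", l)]], p[[paste0("h2", l)]])
    lc$ln1 <- ln1; lc$Z1 <- Z1; lc$pre1 <- pre1; lc$Ff <- Ff; lc$ln2 <- ln2
    Z <- ln2$y
    cache$layers[[l]] <- lc
  }
  hvec <- as.vector(Z)
  m_cls <- keep(length(hvec), 1)
  if (!is.null(m_cls)) hvec <- hvec * as.vector(m_cls)
  cache$m_cls <- m_cls; cache$hvec <- hvec; cache$Zout <- Z
  scores <- as.vector(p$Wc %*% hvec + p$bc)
  list(scores = scores, cache = cache)
}

# Backward pass for one trial. Returns parameter gradients (same shapes as
# `p`) and the gradient at the pooled feature maps (`dApool`, used by
# Grad-CAM).
.conformer_backward <- function(p, cfg, dims, cache, dscores) {
  g <- list()
  g$Wc <- dscores %o% cache$hvec
  g$bc <- dscores
  dh <- as.vector(crossprod(p$Wc, dscores))
  if (!is.null(cache$m_cls)) dh <- dh * as.vector(cache$m_cls)
  dZ <- matrix(dh, dims$n_tok, dims$D)

  for (l in rev(seq_len(dims$n_layers))) {
    lc <- cache$layers[[l]]
    lg2 <- .layernorm_grad(dZ, lc$ln2, p[[paste0("g2", l)]])
    g[[paste0("g2", l)]] <- lg2$dg
    g[[paste0("h2", l)]] <- lg2$db
    dR2 <- lg2$dx
    dF2 <- dR2
    if (!is.null(lc$m_ffn)) dF2 <- dF2 * lc$m_ffn
    g[[paste0("W2", l)]] <- crossprod(dF2, lc$Ff)
    g[[paste0("b2", l)]] <- colSums(dF2)
    dFf <- dF2 %*% p[[paste0("W2", l)]]
    dpre1 <- dFf * .gelu_grad(lc$pre1)
    g[[paste0("W1", l)]] <- crossprod(dpre1, lc$Z1)
    g[[paste0("b1", l)]] <- colSums(dpre1)
    dZ1 <- dR2 + dpre1 %*% p[[paste0("W1", l)]]
    lg1 <- .layernorm_grad(dZ1, lc$ln1, p[[paste0("g1", l)]])
    g[[paste0("g1", l)]] <- lg1$dg
    g[[paste0("h1", l)]] <- lg1$db
    dR1 <- lg1$dx
    dO2 <- dR1
    if (!is.null(lc$m_att)) dO2 <- dO2 * lc$m_att
    g[[paste0("Wo", l)]] <- crossprod(dO2, lc$O)
    g[[paste0("bo", l)]] <- colSums(dO2)
    dO <- dO2 %*% p[[paste0("Wo", l)]]
    dQ <- matrix(0, dims$n_tok, dims$D)
    dKm <- matrix(0, dims$n_tok, dims$D)
    dV <- matrix(0, dims$n_tok, dims$D)
    for (h in seq_len(dims$H)) {
      hi <- (h - 1) * dims$dh + seq_len(dims$dh)
      P <- lc$P[[h]]
      dOl <- dO[, hi, drop = FALSE]
      dP <- tcrossprod(dOl, lc$V[, hi, drop = FALSE])
      dV[, hi] <- crossprod(P, dOl)
      dSc <- P * (dP - rowSums(P * dP))
      dQ[, hi] <- dSc %*% lc$Km[, hi, drop = FALSE] / sqrt(dims$dh)
      dKm[, hi] <- crossprod(dSc, lc$Q[, hi, drop = FALSE]) / sqrt(dims$dh)
    }
    Zin <- lc$Zin
    g[[paste0("Wq", l)]] <- crossprod(dQ, Zin)
    g[[paste0("Wk", l)]] <- crossprod(dKm, Zin)
    g[[paste0("Wv", l)]] <- crossprod(dV, Zin)
    g[[paste0("bq", l)]] <- colSums(dQ)
    g[[paste0("bk", l)]] <- colSums(dKm)
    g[[paste0("bv", l)]] <- colSums(dV)
    dZ <- dR1 + dQ %*% p[[paste0("Wq", l)]] + dKm %*% p[[paste0("Wk", l)]] +
      dV %*% p[[paste0("Wv", l)]]
  }

  g$Wp <- crossprod(dZ, cache$Z0)
  g$bp <- colSums(dZ)
  dZ0 <- dZ %*% p$Wp
  if (!is.null(cache$m_tok)) dZ0 <- dZ0 * cache$m_tok
  dApool <- t(dZ0)
  dA <- tcrossprod(dApool, dims$Pm)
  dS <- dA * .elu_grad(cache$S)
  g$b_conv <- rowSums(dS)
  gK <- matrix(0, dims$F, dims$L)
  dXs <- matrix(0, dims$F, dims$T)
  for (l in seq_len(dims$L)) {
    cols <- l:(l + dims$T1 - 1)
    gK[, l] <- rowSums(dS * cache$Xs[, cols, drop = FALSE])
    dXs[, cols] <- dXs[, cols, drop = FALSE] + dS * p$K[, l]
  }
  g$K <- gK
  g$W <- tcrossprod(dXs, cache$x)
  list(grads = g, dApool = dApool)
}

.check_epoch_shape <- function(model, epochs) {
  d <- dim(epochs$data)
  if (d[2] != model$dims$C || d[3] != model$dims$T) {
    stop("epoch shape (channels x samples = ", d[2], " x ", d[3],
         ") does not match the model (", model$dims$C, " x ", model$dims$T, ")")
  }
}

#' Class scores for a batch of epochs
#'
#' Deterministic evaluation-mode forward pass (dropout disabled).
#'
#' @param model a `conformer_model` from [train_conformer()].
#' @param epochs an `epoch_set` with the channel/sample geometry the model
#'   was trained on.
#' @return trials x n_classes score matrix (pre-softmax).
#' @export
conformer_forward <- function(model, epochs) {
  stopifnot(inherits(model, "conformer_model"), inherits(epochs, "epoch_set"))
  .check_epoch_shape(model, epochs)
  n <- dim(epochs$data)[1]
  out <- matrix(0, n, model$config$n_classes)
  for (i in seq_len(n)) {
    x <- matrix(epochs$data[i, , ], model$dims$C, model$dims$T)
    out[i, ] <- .conformer_forward(model$params, model$config, model$dims, x)$scores
  }
  colnames(out) <- model$class_labels
  out
}

#' Predict class labels
#'
#' Argmax over class scores; ties break toward the lower class index
#' (rest < slow < medium < fast).
#'
#' @inheritParams conformer_forward
#' @return integer vector of 0-based class indices (0 = rest .. 3 = fast),
#'   with the label names as names.
#' @export
predict_classes <- function(model, epochs) {
  scores <- conformer_forward(model, epochs)
  idx <- apply(scores, 1, which.max) - 1L  # which.max ties -> lowest index
  names(idx) <- model$class_labels[idx + 1L]
  idx
}

#' Train the conv-transformer decoder
#'
#' Minimizes softmax cross-entropy with Adam over shuffled mini-batches.
#' Early stopping monitors validation loss and restores the best
#' parameters. All randomness (initialization, batch order, dropout) is
#' driven by `seed`, so the same inputs and seed reproduce the training log
#' exactly.
#'
#' @param config a [conformer_config()].
#' @param train_epochs,val_epochs `epoch_set`s; every class must appear at
#'   least once in `train_epochs`. `val_epochs = NULL` monitors training
#'   loss instead.
#' @param seed integer seed.
#' @param lr Adam learning rate.
#' @param batch_size mini-batch size.
#' @param max_passes maximum passes over the training set.
#' @param patience early-stopping patience (passes without validation
#'   improvement).
#' @param weight_decay decoupled (AdamW-style) weight decay applied to the
#'   weight matrices; biases and layer-norm parameters are exempt.
#' @param verbose print per-pass progress.
#' @return object of class `conformer_model`: `params` (including the
#'   temporal kernels `K` and spatial filter matrix `W`), `config`, `dims`,
#'   `training_log` (data.frame), `seed`, plus the epoch geometry
#'   (`channel_names`, `fs`, `time_axis`, `class_labels`).
#' @export
train_conformer <- function(config, train_epochs, val_epochs = NULL, seed = 1,
                            lr = 1e-3, batch_size = 16, max_passes = 100,
                            patience = 20, weight_decay = 1e-3,
                            verbose = FALSE) {
  stopifnot(inherits(config, "conformer_config"),
            inherits(train_epochs, "epoch_set"))
  labs_present <- unique(train_epochs$label_index)
  if (length(labs_present) < config$n_classes) {
    stop("training set must contain every class at least once")
  }
  d <- dim(train_epochs$data)
  dims <- .conformer_dims(config, d[2], d[3])
  n_train <- d[1]
  y_train <- train_epochs$label_index + 1L

  x_train <- lapply(seq_len(n_train), function(i) {
    matrix(train_epochs$data[i, , ], dims$C, dims$T)
  })
  x_val <- NULL
  y_val <- NULL
  if (!is.null(val_epochs)) {
    dv <- dim(val_epochs$data)
    if (dv[2] != d[2] || dv[3] != d[3]) stop("train/val epoch shapes differ")
    x_val <- lapply(seq_len(dv[1]), function(i) {
      matrix(val_epochs$data[i, , ], dims$C, dims$T)
    })
    y_val <- val_epochs$label_index + 1L
  }

  eval_set <- function(p, xs, y) {
    loss <- 0
    correct <- 0
    for (i in seq_along(xs)) {
      sc <- .conformer_forward(p, config, dims, xs[[i]])$scores
      pr <- .softmax(sc)
      loss <- loss - log(max(pr[y[i]], 1e-12))
      if (which.max(sc) == y[i]) correct <- correct + 1
    }
    c(loss = loss / length(xs), acc = correct / length(xs))
  }

  # decoupled weight decay applies to weight matrices only (not biases or
  # layer-norm parameters); it shrinks directions the loss does not constrain
  decay_set <- c("K", "W", "Wp", "Wc",
                 paste0(rep(c("Wq", "Wk", "Wv", "Wo", "W1", "W2"),
                            each = config$n_attention_layers),
                        seq_len(config$n_attention_layers)))
  .with_seed(seed, {
    p <- .conformer_init(config, dims)
    mom <- lapply(p, function(x) x * 0)
    vel <- lapply(p, function(x) x * 0)
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    step <- 0
    log_rows <- list()
    best_loss <- Inf
    best_p <- p
    stale <- 0
    for (pass in seq_len(max_passes)) {
      ord <- sample(n_train)
      tr_loss <- 0
      tr_correct <- 0
      for (b0 in seq(1, n_train, by = batch_size)) {
        idx <- ord[b0:min(b0 + batch_size - 1, n_train)]
        acc_g <- NULL
        for (i in idx) {
          fw <- .conformer_forward(p, config, dims, x_train[[i]],
                                   drop = config$dropout)
          pr <- .softmax(fw$scores)
          tr_loss <- tr_loss - log(max(pr[y_train[i]], 1e-12))
          if (which.max(fw$scores) == y_train[i]) tr_correct <- tr_correct + 1
          dsc <- pr
          dsc[y_train[i]] <- dsc[y_train[i]] - 1
          bw <- .conformer_backward(p, config, dims, fw$cache, dsc)
          acc_g <- if (is.null(acc_g)) bw$grads else {
            Map(`+`, acc_g, bw$grads)
          }
        }
        acc_g <- lapply(acc_g, function(x) x / length(idx))
        step <- step + 1
        for (nm in names(p)) {
          mom[[nm]] <- beta1 * mom[[nm]] + (1 - beta1) * acc_g[[nm]]
          vel[[nm]] <- beta2 * vel[[nm]] + (1 - beta2) * acc_g[[nm]]^2
          mhat <- mom[[nm]] / (1 - beta1^step)
          vhat <- vel[[nm]] / (1 - beta2^step)
          wd <- if (nm %in% decay_set) weight_decay else 0
          p[[nm]] <- p[[nm]] - lr * (mhat / (sqrt(vhat) + eps) + wd * p[[nm]])
        }
        # the DC response of a temporal kernel is unidentifiable for
        # high-pass-filtered input; keep kernels zero-mean so that
        # unconstrained direction cannot drift and bias their spectra
        p$K <- p$K - rowMeans(p$K)
      }
      tr_loss <- tr_loss / n_train
      if (!is.finite(tr_loss)) {
        stop("training diverged at pass ", pass, " (non-finite loss)")
      }
      if (!is.null(x_val)) {
        ev <- eval_set(p, x_val, y_val)
      } else {
        ev <- c(loss = tr_loss, acc = tr_correct / n_train)
      }
      log_rows[[pass]] <- data.frame(
        pass = pass, train_loss = tr_loss, train_acc = tr_correct / n_train,
        val_loss = unname(ev["loss"]), val_acc = unname(ev["acc"]))
      if (verbose) {
        message(sprintf("pass %3d  train loss %.4f acc %.3f  val loss %.4f acc %.3f",
                        pass, tr_loss, tr_correct / n_train, ev["loss"], ev["acc"]))
      }
      if (ev["loss"] < best_loss - 1e-6) {
        best_loss <- ev["loss"]
        best_p <- p
        stale <- 0
      } else {
        stale <- stale + 1
        if (stale >= patience) break
      }
    }
    structure(list(
      params = best_p, config = config, dims = dims,
      training_log = do.call(rbind, log_rows), seed = seed,
      channel_names = train_epochs$channel_names,
      class_labels = train_epochs$class_labels,
      fs = train_epochs$fs, time_axis = train_epochs$time_axis
    ), class = "conformer_model")
  })
}

#' @export
print.conformer_model <- function(x, ...) {
  lg <- x$training_log
  cat("<conformer_model> ", x$dims$F, " temporal filters x ", x$dims$L,
      " samples, ", x$dims$C, " channels, ", x$dims$n_tok, " tokens x ",
      x$dims$D, " dims, ", x$dims$n_layers, " attention layer(s)\n",
      "  trained ", nrow(lg), " pass(es); best val loss ",
      round(min(lg$val_loss), 4), ", val acc ",
      round(lg$val_acc[which.min(lg$val_loss)], 3), "\n", sep = "")
  invisible(x)
}
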