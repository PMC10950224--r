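# Pooling-based artificial neural network (stage 1): a 6-block convolutional
# encoder over single recordings, adaptive max/avg/min pooling to a fixed
# 30-value summary per channel, fusion with the one-hot auscultation
# location, and a 3-class decision head. After training, the model is used
# as a frozen feature generator for the patient-level stage.

MURMUR_CLASSES <- c("Present", "Unknown", "Absent")

#' PANN configuration
#'
#' @param n_blocks encoder base blocks (conv -> batch norm -> conv ->
#'   dropout -> max pool stride 2).
#' @param kernel convolution kernel size (same padding).
#' @param dropout dropout rate inside each block.
#' @param channels channel width per block; the last must be 64 (the fully
#'   connected stage expects 30 x 64 + 5 inputs).
#' @param pool_sizes adaptive pooling segment counts (max, avg, min);
#'   must sum to 30.
#' @param hidden fully connected hidden width.
#' @param encoded number of encoded output features.
#' @param lr initial learning rate.
#' @param lr_decay_every,lr_decay_factor schedule (epochs, factor).
#' @param epochs maximum epochs.
#' @param batch_size minibatch size.
#' @param val_fraction validation fraction of recordings.
#' @param input_length fixed training crop length in samples (power of 2
#'   at least 2^6).
#' @param augment logical: apply the augmentation policy during training.
#' @return a `pann_config` list.
#' @export
pann_config <- function(n_blocks = 6, kernel = 5, dropout = 0.1,
                        channels = c(16, 24, 32, 40, 52, 64),
                        pool_sizes = c(max = 15, avg = 10, min = 5),
                        hidden = 100, encoded = 20,
                        lr = 0.001, lr_decay_every = 30,
                        lr_decay_factor = 0.3, epochs = 25, batch_size = 16,
                        val_fraction = 0.2, input_length = 2^12,
                        augment = TRUE) {
  stopifnot(n_blocks == length(channels), sum(pool_sizes) == 30,
            channels[length(channels)] == 64,
            input_length %% 2^n_blocks == 0, input_length >= 2^6)
  structure(list(n_blocks = n_blocks, kernel = kernel, dropout = dropout,
                 channels = channels, pool_sizes = pool_sizes,
                 hidden = hidden, encoded = encoded, lr = lr,
                 lr_decay_every = lr_decay_every,
                 lr_decay_factor = lr_decay_factor, epochs = epochs,
                 batch_size = batch_size, val_fraction = val_fraction,
                 input_length = as.integer(input_length), augment = augment),
            class = "pann_config")
}

#' Build an untrained PANN
#'
#' @param config a [pann_config()].
#' @param seed RNG seed for initialization.
#' @return an object of class `pann`.
#' @export
build_pann <- function(config = pann_config(), seed = 1L) {
  with_seed(seed, {
    par <- list()
    in_ch <- 1L
    for (i in seq_len(config$n_blocks)) {
      ch <- config$channels[i]
      par[[sprintf("conv%da", i)]] <- nn_init_conv(in_ch, ch, config$kernel)
      par[[sprintf("bn%d", i)]] <- nn_init_bn(ch)
      par[[sprintf("conv%db", i)]] <- nn_init_conv(ch, ch, config$kernel)
      in_ch <- ch
    }
    n_pool_feats <- 30L * config$channels[config$n_blocks]
    par$fc1 <- nn_init_dense(n_pool_feats + 5L, config$hidden)
    par$fc2 <- nn_init_dense(config$hidden, config$encoded)
    par$decision <- nn_init_dense(config$encoded, 3L)
    structure(list(params = par, config = config, trained = FALSE,
                   history = NULL),
              class = "pann")
  })
}

#' @export
print.pann <- function(x, ...) {
  cat(sprintf(
    "PANN: %d conv blocks (%s ch), 30 adaptive-pool features/channel, FC %d -> %d -> 3%s\n",
    x$config$n_blocks, paste(x$config$channels, collapse = "/"),
    x$config$hidden, x$config$encoded,
    if (x$trained) " (trained)" else " (untrained)"))
  invisible(x)
}

# one-hot auscultation location (AV, PV, TV, MV, other)
location_onehot <- function(location) {
  location <- match.arg(location, AUSCULTATION_LOCATIONS)
  as.numeric(AUSCULTATION_LOCATIONS == location)
}

# forward pass through the encoder + pooling + FC head.
# X: 1 x (L*B); loc: 5 x B one-hot matrix. Returns probs, encoded, pooled.
pann_fwd <- function(model, X, L, B, loc, train = FALSE, want_cache = FALSE) {
  cfg <- model$config
  par <- model$params
  caches <- list()
  cur <- X
  Lc <- L
  for (i in seq_len(cfg$n_blocks)) {
    a <- conv1d_fwd(cur, par[[sprintf("conv%da", i)]], Lc, B)
    bn <- bn_fwd(a$Y, par[[sprintf("bn%d", i)]], train = train)
    if (train) model$params[[sprintf("bn%d", i)]] <- bn$par
    ra <- relu_fwd(bn$Y)
    b <- conv1d_fwd(ra$Y, par[[sprintf("conv%db", i)]], Lc, B)
    rb <- relu_fwd(b$Y)
    dr <- dropout_fwd(rb$Y, cfg$dropout, train = train)
    p <- maxpool2_fwd(dr$Y, Lc, B)
    if (want_cache) caches[[sprintf("blk%d", i)]] <-
      list(a = a$cache, bn = bn$cache, ra = ra$cache, b = b$cache,
           rb = rb$cache, dr = dr$cache, pool = p$cache)
    cur <- p$Y
    Lc <- Lc %/% 2L
  }
  pools <- list(
    mx = adaptive_pool_fwd(cur, Lc, B, cfg$pool_sizes[["max"]], "max"),
    av = adaptive_pool_fwd(cur, Lc, B, cfg$pool_sizes[["avg"]], "avg"),
    mn = adaptive_pool_fwd(cur, Lc, B, cfg$pool_sizes[["min"]], "min"))
  C <- nrow(cur)
  # per-sample flattening: channels x (m*B) -> (C*30) x B, then + location
  flat_one <- function(Y, m) {
    array(Y, dim = c(C * m, B))
  }
  pooled <- rbind(flat_one(pools$mx$Y, cfg$pool_sizes[["max"]]),
                  flat_one(pools$av$Y, cfg$pool_sizes[["avg"]]),
                  flat_one(pools$mn$Y, cfg$pool_sizes[["min"]]))
  fc_in <- rbind(pooled, loc)
  f1 <- dense_fwd(fc_in, par$fc1)
  r1 <- relu_fwd(f1$Y)
  f2 <- dense_fwd(r1$Y, par$fc2)
  enc <- f2$Y
  dec <- dense_fwd(enc, par$decision)
  probs <- softmax_cols(dec$Y)
  if (want_cache) {
    caches$pools <- pools
    caches$shapes <- list(C = C, Lc = Lc, B = B)
    caches$fc <- list(fc_in = fc_in, f1 = f1$cache, r1 = r1$cache,
                      f2 = f2$cache, dec = dec$cache)
  }
  list(probs = probs, encoded = enc, pooled = pooled, caches = caches,
       model = model)
}

# backward from dlogits (3 x B) of the decision layer
pann_bwd <- function(model, caches, dlogits) {
  cfg <- model$config
  par <- model$params
  grads <- list()
  g <- dense_bwd(dlogits, par$decision, caches$fc$dec)
  grads[["decision.W"]] <- g$dW; grads[["decision.b"]] <- g$db
  g2 <- dense_bwd(g$dX, par$fc2, caches$fc$f2)
  grads[["fc2.W"]] <- g2$dW; grads[["fc2.b"]] <- g2$db
  dr1 <- relu_bwd(g2$dX, caches$fc$r1)
  g1 <- dense_bwd(dr1, par$fc1, caches$fc$f1)
  grads[["fc1.W"]] <- g1$dW; grads[["fc1.b"]] <- g1$db
  sh <- caches$shapes
  d_fc_in <- g1$dX
  n_pool <- 30L * sh$C
  d_pooled <- d_fc_in[seq_len(n_pool), , drop = FALSE]
  m_mx <- cfg$pool_sizes[["max"]]; m_av <- cfg$pool_sizes[["avg"]]
  m_mn <- cfg$pool_sizes[["min"]]
  split1 <- sh$C * m_mx; split2 <- split1 + sh$C * m_av
  d_mx <- matrix(d_pooled[seq_len(split1), ], sh$C, m_mx * sh$B)
  d_av <- matrix(d_pooled[(split1 + 1):split2, ], sh$C, m_av * sh$B)
  d_mn <- matrix(d_pooled[(split2 + 1):n_pool, ], sh$C, m_mn * sh$B)
  d_cur <- adaptive_pool_bwd(d_mx, caches$pools$mx$cache) +
           adaptive_pool_bwd(d_av, caches$pools$av$cache) +
           adaptive_pool_bwd(d_mn, caches$pools$mn$cache)
  for (i in rev(seq_len(cfg$n_blocks))) {
    cc <- caches[[sprintf("blk%d", i)]]
    d_dr <- maxpool2_bwd(d_cur, cc$pool)
    d_rb <- dropout_bwd(d_dr, cc$dr)
    d_b <- relu_bwd(d_rb, cc$rb)
    gb <- conv1d_bwd(d_b, par[[sprintf("conv%db", i)]], cc$b)
    grads[[sprintf("conv%db.W", i)]] <- gb$dW
    grads[[sprintf("conv%db.b", i)]] <- gb$db
    d_ra <- relu_bwd(gb$dX, cc$ra)
    gbn <- bn_bwd(d_ra, cc$bn)
    grads[[sprintf("bn%d.gamma", i)]] <- gbn$dgamma
    grads[[sprintf("bn%d.beta", i)]] <- gbn$dbeta
    ga <- conv1d_bwd(gbn$dX, par[[sprintf("conv%da", i)]], cc$a)
    grads[[sprintf("conv%da.W", i)]] <- ga$dW
    grads[[sprintf("conv%da.b", i)]] <- ga$db
    d_cur <- ga$dX
  }
  grads
}

#' Inverse-relative-frequency class weights
#'
#' @param labels factor or character vector of class labels.
#' @param classes class ordering for the returned weights.
#' @return numeric weights proportional to 1 / relative class frequency,
#'   normalized to mean 1 over the observed classes; classes absent from
#'   `labels` receive weight 0 (they never enter the loss). At least two
#'   classes must be observed.
#' @export
class_weights <- function(labels, classes = MURMUR_CLASSES) {
  counts <- table(factor(labels, levels = classes))
  if (sum(counts > 0) < 2)
    stop("need at least two observed classes; missing: ",
         paste(classes[counts == 0], collapse = ", "))
  w <- ifelse(counts > 0, sum(counts) / pmax(as.numeric(counts), 1), 0)
  stats::setNames(w / mean(w[w > 0]), classes)
}

# weighted cross-entropy on softmax columns; y integer class index 1..K
wce_loss_grad <- function(probs, y, w) {
  B <- ncol(probs)
  pc <- pmax(probs[cbind(y, seq_len(B))], 1e-12)
  wt <- w[y]
  loss <- sum(-wt * log(pc)) / B
  # gradient w.r.t. logits of softmax + WCE
  dlog <- probs * matrix(wt, nrow(probs), B, byrow = TRUE)
  dlog[cbind(y, seq_len(B))] <- dlog[cbind(y, seq_len(B))] - wt
  list(loss = loss, dlogits = dlog / B)
}

# fixed-length crop/pad of one recording for PANN training
pann_crop <- function(x, L) {
  if (length(x) >= L) x[seq_len(L)]
  else c(x, numeric(L - length(x)))
}

#' Train the PANN on single recordings
#'
#' Recording-level 3-class murmur labels (Present / Unknown / Absent),
#' weighted cross-entropy with inverse-relative-frequency class weights,
#' Adam with step-decayed learning rate, optional augmentation, stratified
#' validation split; the best model by the mean of training and validation
#' accuracy is returned.
#'
#' @param signals list of preprocessed numeric vectors.
#' @param labels character vector over Present/Unknown/Absent.
#' @param locations character vector of auscultation locations.
#' @param config a [pann_config()].
#' @param policy an [augmentation_policy()] used when `config$augment`.
#' @param seed RNG seed.
#' @param verbose print per-epoch progress.
#' @return a trained `pann` with `history`.
#' @export
train_pann <- function(signals, labels, locations,
                       config = pann_config(),
                       policy = augmentation_policy(), seed = 1L,
                       verbose = FALSE) {
  stopifnot(length(signals) == length(labels),
            length(labels) == length(locations))
  y <- match(labels, MURMUR_CLASSES)
  if (anyNA(y)) stop("labels must be Present/Unknown/Absent")
  w <- class_weights(labels)
  model <- build_pann(config, seed = seed)
  if (config$epochs == 0L) return(model)
  L <- config$input_length
  with_seed(seed + 1L, {
    val_idx <- unlist(lapply(split(seq_along(y), y), function(ix)
      sample(ix, max(1L, round(config$val_fraction * length(ix))))))
    tr_idx <- setdiff(seq_along(y), val_idx)
    loc_mat <- vapply(locations, location_onehot, numeric(5))
    Xval <- matrix(0, 1, L * length(val_idx))
    for (j in seq_along(val_idx))
      Xval[1, (j - 1) * L + seq_len(L)] <- pann_crop(signals[[val_idx[j]]], L)
    flat <- flatten_params(model$params)
    opt <- adam_init(flat)
    lr <- config$lr
    best_score <- -Inf; best <- model; hist <- data.frame()
    for (ep in seq_len(config$epochs)) {
      if (ep > 1 && (ep - 1) %% config$lr_decay_every == 0)
        lr <- lr * config$lr_decay_factor
      ord <- sample(tr_idx)
      ep_loss <- 0; n_b <- 0; tr_correct <- 0
      for (start in seq(1, length(ord), by = config$batch_size)) {
        bi <- ord[start:min(start + config$batch_size - 1, length(ord))]
        B <- length(bi)
        X <- matrix(0, 1, L * B)
        for (j in seq_len(B)) {
          xs <- signals[[bi[j]]]
          if (config$augment) xs <- compose_augmentations(xs, 2000, policy)
          X[1, (j - 1) * L + seq_len(L)] <- pann_crop(xs, L)
        }
        model$params <- unflatten_params(flat, model$params)
        fw <- pann_fwd(model, X, L, B, loc_mat[, bi, drop = FALSE],
                       train = TRUE, want_cache = TRUE)
        model <- fw$model   # running batch-norm stats
        lg <- wce_loss_grad(fw$probs, y[bi], w)
        grads <- clip_gradients(pann_bwd(model, fw$caches, lg$dlogits), 5)
        st <- adam_step(flat, grads, opt, lr)
        flat <- st$params; opt <- st$state
        ep_loss <- ep_loss + lg$loss; n_b <- n_b + 1
        tr_correct <- tr_correct + sum(apply(fw$probs, 2, which.max) == y[bi])
      }
      model$params <- unflatten_params(flat, model$params)
      fw <- pann_fwd(model, Xval, L, length(val_idx),
                     loc_mat[, val_idx, drop = FALSE], train = FALSE)
      val_acc <- mean(apply(fw$probs, 2, which.max) == y[val_idx])
      tr_acc <- tr_correct / length(tr_idx)
      score <- mean(c(tr_acc, val_acc))
      hist <- rbind(hist, data.frame(epoch = ep, loss = ep_loss / n_b,
                                     train_acc = tr_acc, val_acc = val_acc,
                                     lr = lr))
      if (verbose)
        message(sprintf("epoch %d: loss %.4f train acc %.3f val acc %.3f",
                        ep, ep_loss / n_b, tr_acc, val_acc))
      if (score > best_score) {
        best_score <- score
        best <- model
        best$params <- unflatten_params(flat, model$params)
      }
    }
    best$trained <- TRUE
    best$history <- hist
    best$class_weights <- w
    best
  })
}

#' PANN features and class probabilities for one recording
#'
#' Inference is deterministic (dropout off, batch norm running statistics).
#'
#' @param model a trained `pann`.
#' @param samples preprocessed signal (any length >= 2^`n_blocks`; pooled
#'   dimensionality is independent of length).
#' @param location auscultation location (AV/PV/TV/MV/other).
#' @return list with `probs` (named, sums to 1), `encoded` (20 values),
#'   `pooled` (30 x 64 values) and `location`.
#' @export
pann_features <- function(model, samples, location) {
  stopifnot(inherits(model, "pann"))
  cfg <- model$config
  stride <- 2^cfg$n_blocks
  if (length(samples) < 2 * stride)
    stop("input too short for ", cfg$n_blocks, " stride-2 pooling steps")
  L <- as.integer(floor(length(samples) / stride) * stride)
  X <- matrix(samples[seq_len(L)], 1)
  loc <- matrix(location_onehot(location), 5)
  fw <- pann_fwd(model, X, L, 1L, loc, train = FALSE)
  list(probs = stats::setNames(fw$probs[, 1], MURMUR_CLASSES),
       encoded = fw$encoded[, 1], pooled = fw$pooled[, 1],
       location = location)
}

#' @export
predict.pann <- function(object, samples, location = "AV", ...) {
  pann_features(object, samples, location)$probs
}
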