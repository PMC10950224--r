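# Multiple-instance learning for murmur localization. A recording is a bag
# whose instances are its samples; a 1D U-Net produces a per-sample logit,
# the sigmoid of which is the instance probability ("murmurness"), and
# softmax pooling condenses the instances into the bag probability used
# against the weak recording-level label. Postprocessing turns the trace
# into murmur segments, and the phase-precision evaluation quantifies how
# well the segments agree with the annotated murmur phase.

#' Softmax pooling of instance probabilities
#'
#' Bag probability `sum_x p(x) * softmax(p)(x)`: every instance contributes,
#' weighted by the softmax of its own prediction, so the most prominent
#' instance has the largest impact while remaining differentiable through
#' all instances.
#'
#' @param p numeric vector of instance probabilities in \[0, 1\].
#' @return scalar bag probability in \[min(p), max(p)\].
#' @export
softmax_pool <- function(p) {
  if (!length(p)) stop("softmax_pool needs at least one instance")
  stopifnot(all(p >= 0 & p <= 1))
  w <- exp(p)
  sum(p * w) / sum(w)
}

#' MIL training configuration
#'
#' @param batch_size minibatch size (bags).
#' @param lr initial Adam learning rate.
#' @param lr_decay_every,lr_decay_factor step-decay schedule (epochs, factor).
#' @param epochs maximum training epochs.
#' @param patience early-stopping patience on inner-validation loss.
#' @param val_fraction inner validation fraction of the training bags.
#' @param fixed_length fixed signal length (samples); shorter signals are
#'   zero-padded, and padding is excluded from the pooling.
#' @param clip_norm global gradient-norm clip (stabilizes the occasional
#'   saturated-bag gradient spike).
#' @return a `mil_train_config` list.
#' @export
mil_train_config <- function(batch_size = 128, lr = 0.001,
                             lr_decay_every = 10, lr_decay_factor = 0.5,
                             epochs = 30, patience = 10, val_fraction = 0.2,
                             fixed_length = 2^14, clip_norm = 5) {
  stopifnot(batch_size >= 1, lr > 0, epochs >= 0,
            val_fraction > 0, val_fraction < 1,
            fixed_length %% 32 == 0)
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 lr_decay_every = lr_decay_every,
                 lr_decay_factor = lr_decay_factor,
                 epochs = as.integer(epochs), patience = patience,
                 val_fraction = val_fraction,
                 fixed_length = as.integer(fixed_length),
                 clip_norm = clip_norm),
            class = "mil_train_config")
}

#' Build an untrained MIL U-Net
#'
#' Fully convolutional 1D encoder-decoder: 5 downsampling steps (max pool
#' /2), kernel size 5, ReLU activations, nearest-neighbour upsampling with
#' skip concatenation, and a single-channel 1x1 output head producing
#' per-sample logits. Output length equals input length (which must be a
#' multiple of 32; [murmurness()] pads automatically).
#'
#' @param widths channel widths per resolution level (length 6: five
#'   encoder levels plus the bottleneck).
#' @param seed RNG seed for weight initialization.
#' @return an object of class `mil_unet`.
#' @export
build_mil_unet <- function(widths = c(6, 8, 12, 16, 24, 32), seed = 1L) {
  stopifnot(length(widths) == 6, all(widths >= 1))
  with_seed(seed, {
    par <- list()
    in_ch <- 1L
    for (i in 1:6) {
      par[[sprintf("enc%da", i)]] <- nn_init_conv(in_ch, widths[i], 5L)
      par[[sprintf("enc%db", i)]] <- nn_init_conv(widths[i], widths[i], 5L)
      in_ch <- widths[i]
    }
    for (i in 5:1) {
      par[[sprintf("dec%da", i)]] <- nn_init_conv(widths[i + 1] + widths[i],
                                                  widths[i], 5L)
      par[[sprintf("dec%db", i)]] <- nn_init_conv(widths[i], widths[i], 5L)
    }
    par$out <- nn_init_conv(widths[1], 1L, 1L)
    structure(list(params = par, widths = widths, kernel = 5L,
                   history = NULL, trained = FALSE),
              class = "mil_unet")
  })
}

#' @export
print.mil_unet <- function(x, ...) {
  n_par <- sum(vapply(flatten_params(x$params), length, numeric(1)))
  cat(sprintf("MIL U-Net: 5 down/up steps, kernel 5, widths %s (%d parameters)%s\n",
              paste(x$widths, collapse = "/"), n_par,
              if (x$trained) ", trained" else ", untrained"))
  invisible(x)
}

# forward pass; X is 1 x (L*B), L divisible by 32
unet_fwd <- function(model, X, L, B, want_cache = FALSE) {
  par <- model$params
  caches <- list()
  skips <- list()
  cur <- X
  Lc <- L
  for (i in 1:6) {
    a <- conv1d_fwd(cur, par[[sprintf("enc%da", i)]], Lc, B)
    ra <- relu_fwd(a$Y)
    b <- conv1d_fwd(ra$Y, par[[sprintf("enc%db", i)]], Lc, B)
    rb <- relu_fwd(b$Y)
    if (want_cache) caches[[sprintf("enc%d", i)]] <-
      list(a = a$cache, ra = ra$cache, b = b$cache, rb = rb$cache, L = Lc)
    skips[[i]] <- rb$Y
    if (i < 6) {
      p <- maxpool2_fwd(rb$Y, Lc, B)
      if (want_cache) caches[[sprintf("pool%d", i)]] <- p$cache
      cur <- p$Y
      Lc <- Lc %/% 2L
    }
  }
  cur <- skips[[6]]
  for (i in 5:1) {
    up <- upsample2_fwd(cur)
    Lc <- Lc * 2L
    cat_in <- rbind(up, skips[[i]])
    a <- conv1d_fwd(cat_in, par[[sprintf("dec%da", i)]], Lc, B)
    ra <- relu_fwd(a$Y)
    b <- conv1d_fwd(ra$Y, par[[sprintf("dec%db", i)]], Lc, B)
    rb <- relu_fwd(b$Y)
    if (want_cache) caches[[sprintf("dec%d", i)]] <-
      list(a = a$cache, ra = ra$cache, b = b$cache, rb = rb$cache,
           n_up = nrow(up))
    cur <- rb$Y
  }
  out <- conv1d_fwd(cur, par$out, L, B)
  if (want_cache) caches$out <- out$cache
  list(logits = out$Y, caches = caches)
}

# backward pass: returns flat gradient list matching flatten_params(model$params)
unet_bwd <- function(model, caches, dlogits, L, B) {
  par <- model$params
  grads <- list()
  g <- conv1d_bwd(dlogits, par$out, caches$out)
  grads[["out.W"]] <- g$dW; grads[["out.b"]] <- g$db
  d_cur <- g$dX
  d_skip <- vector("list", 6)
  for (i in 1:5) {
    cc <- caches[[sprintf("dec%d", i)]]
    d_rb <- relu_bwd(d_cur, cc$rb)
    gb <- conv1d_bwd(d_rb, par[[sprintf("dec%db", i)]], cc$b)
    grads[[sprintf("dec%db.W", i)]] <- gb$dW
    grads[[sprintf("dec%db.b", i)]] <- gb$db
    d_ra <- relu_bwd(gb$dX, cc$ra)
    ga <- conv1d_bwd(d_ra, par[[sprintf("dec%da", i)]], cc$a)
    grads[[sprintf("dec%da.W", i)]] <- ga$dW
    grads[[sprintf("dec%da.b", i)]] <- ga$db
    n_up <- cc$n_up
    d_skip[[i]] <- ga$dX[(n_up + 1):nrow(ga$dX), , drop = FALSE]
    d_cur <- upsample2_bwd(ga$dX[seq_len(n_up), , drop = FALSE])
  }
  d_skip[[6]] <- d_cur
  d_below <- NULL
  for (i in 6:1) {
    d_out <- d_skip[[i]]
    if (!is.null(d_below)) d_out <- d_out + d_below
    cc <- caches[[sprintf("enc%d", i)]]
    d_rb <- relu_bwd(d_out, cc$rb)
    gb <- conv1d_bwd(d_rb, par[[sprintf("enc%db", i)]], cc$b)
    grads[[sprintf("enc%db.W", i)]] <- gb$dW
    grads[[sprintf("enc%db.b", i)]] <- gb$db
    d_ra <- relu_bwd(gb$dX, cc$ra)
    ga <- conv1d_bwd(d_ra, par[[sprintf("enc%da", i)]], cc$a)
    grads[[sprintf("enc%da.W", i)]] <- ga$dW
    grads[[sprintf("enc%da.b", i)]] <- ga$db
    d_below <- if (i > 1) maxpool2_bwd(ga$dX, caches[[sprintf("pool%d", i - 1)]])
               else NULL
  }
  grads
}

# assemble a fixed-length batch matrix from a list of signals
mil_batch <- function(signals, fixed_length) {
  B <- length(signals)
  X <- matrix(0, 1, fixed_length * B)
  valid <- integer(B)
  for (b in seq_len(B)) {
    s <- signals[[b]]
    v <- min(length(s), fixed_length)
    X[1, (b - 1L) * fixed_length + seq_len(v)] <- s[seq_len(v)]
    valid[b] <- v
  }
  list(X = X, valid = valid)
}

#' Softmax pooling with instance weights on the logit scale
#'
#' Bag probability `sum_x sigmoid(z_x) * softmax(z)(x)`. The weights
#' concentrate exponentially on the most prominent instances, so a bag with
#' few strong instances can still pool close to 1 — the behavior the MIL
#' assumption asks for. This variant is used during training and for bag
#' prediction; [softmax_pool()] is the probability-scale form.
#'
#' @param z numeric vector of per-instance logits.
#' @return scalar bag probability in \[0, 1\].
#' @export
softmax_pool_logits <- function(z) {
  if (!length(z)) stop("softmax_pool_logits needs at least one instance")
  w <- exp(z - max(z))
  sum(sigmoid(z) * w) / sum(w)
}

# loss + gradient of BCE(softmax_pool_logits(z), y) for one batch; the
# softmax weights live on the logit scale (see softmax_pool_logits)
mil_loss_grad <- function(logits, valid, y, fixed_length, want_grad = TRUE) {
  B <- length(y)
  dlogits <- if (want_grad) matrix(0, 1, ncol(logits)) else NULL
  loss <- 0
  probs <- numeric(B)
  for (b in seq_len(B)) {
    idx <- (b - 1L) * fixed_length + seq_len(valid[b])
    z <- logits[1, idx]
    w <- exp(z - max(z)); s <- w / sum(w)
    p <- sigmoid(z)
    P <- sum(p * s)
    Pc <- clamp(P, 1e-7, 1 - 1e-7)
    loss <- loss - (y[b] * log(Pc) + (1 - y[b]) * log(1 - Pc)) / B
    probs[b] <- P
    if (want_grad) {
      dP <- (Pc - y[b]) / (Pc * (1 - Pc)) / B
      # d/dz_j [sum_i p_i s_i] = s_j (p_j (1 - p_j) + p_j - P)
      dlogits[1, idx] <- dP * s * (p * (1 - p) + p - P)
    }
  }
  list(loss = loss, dlogits = dlogits, probs = probs)
}

#' Train the MIL U-Net on weakly labeled recordings
#'
#' Binary cross-entropy on the softmax-pooled bag probability, Adam with
#' step-decayed learning rate, inner validation split and early stopping;
#' the returned model carries the parameters of the best validation epoch.
#' Recordings labeled "Unknown" must be excluded by the caller (training is
#' binary murmur presence).
#'
#' @param signals list of preprocessed numeric vectors (one per recording).
#' @param labels binary vector (1 = murmur present).
#' @param config a [mil_train_config()].
#' @param model optional pre-built [build_mil_unet()] to continue from.
#' @param seed RNG seed controlling initialization, splits and batching.
#' @param verbose print per-epoch losses.
#' @return a trained `mil_unet` with a `history` data.frame.
#' @export
train_mil <- function(signals, labels, config = mil_train_config(),
                      model = NULL, seed = 1L, verbose = FALSE) {
  stopifnot(length(signals) == length(labels))
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2)
    stop("MIL training needs both murmur-present and murmur-absent bags")
  if (is.null(model)) model <- build_mil_unet(seed = seed)
  if (config$epochs == 0L) {
    model$history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                                val_loss = numeric(0), lr = numeric(0))
    return(model)
  }
  Lfix <- config$fixed_length
  with_seed(seed + 1L, {
    # stratified inner validation split
    idx_pos <- which(labels == 1); idx_neg <- which(labels == 0)
    n_vp <- max(1L, round(config$val_fraction * length(idx_pos)))
    n_vn <- max(1L, round(config$val_fraction * length(idx_neg)))
    val_idx <- c(sample(idx_pos, n_vp), sample(idx_neg, n_vn))
    tr_idx <- setdiff(seq_along(labels), val_idx)
    val_batch <- mil_batch(signals[val_idx], Lfix)
    flat <- flatten_params(model$params)
    opt <- adam_init(flat)
    lr <- config$lr
    best_val <- Inf; best_flat <- flat; wait <- 0
    hist <- data.frame()
    for (ep in seq_len(config$epochs)) {
      if (ep > 1 && (ep - 1) %% config$lr_decay_every == 0)
        lr <- lr * config$lr_decay_factor
      ord <- sample(tr_idx)
      tr_loss <- 0; n_b <- 0
      for (start in seq(1, length(ord), by = config$batch_size)) {
        bi <- ord[start:min(start + config$batch_size - 1, length(ord))]
        bat <- mil_batch(signals[bi], Lfix)
        model$params <- unflatten_params(flat, model$params)
        fw <- unet_fwd(model, bat$X, Lfix, length(bi), want_cache = TRUE)
        lg <- mil_loss_grad(fw$logits, bat$valid, labels[bi], Lfix)
        grads <- clip_gradients(unet_bwd(model, fw$caches, lg$dlogits,
                                         Lfix, length(bi)), config$clip_norm)
        st <- adam_step(flat, grads, opt, lr)
        flat <- st$params; opt <- st$state
        tr_loss <- tr_loss + lg$loss; n_b <- n_b + 1
      }
      model$params <- unflatten_params(flat, model$params)
      fw <- unet_fwd(model, val_batch$X, Lfix, length(val_idx))
      vl <- mil_loss_grad(fw$logits, val_batch$valid, labels[val_idx],
                          Lfix, want_grad = FALSE)$loss
      hist <- rbind(hist, data.frame(epoch = ep, train_loss = tr_loss / n_b,
                                     val_loss = vl, lr = lr))
      if (verbose)
        message(sprintf("epoch %d: train %.4f val %.4f (lr %.2e)",
                        ep, tr_loss / n_b, vl, lr))
      if (vl < best_val - 1e-6) {
        best_val <- vl; best_flat <- flat; wait <- 0
      } else {
        wait <- wait + 1
        if (wait >= config$patience) break
      }
    }
    model$params <- unflatten_params(best_flat, model$params)
    model$history <- hist
    model$trained <- TRUE
    model
  })
}

#' Per-sample murmur probability trace
#'
#' @param model a `mil_unet`.
#' @param samples preprocessed signal.
#' @return numeric vector in \[0, 1\], same length as `samples`.
#' @export
murmurness <- function(model, samples) {
  stopifnot(inherits(model, "mil_unet"))
  n <- length(samples)
  Lp <- as.integer(ceiling(n / 32) * 32)
  X <- matrix(0, 1, Lp)
  X[1, seq_len(n)] <- samples
  fw <- unet_fwd(model, X, Lp, 1L)
  sigmoid(fw$logits[1, seq_len(n)])
}

#' @export
predict.mil_unet <- function(object, samples,
                             type = c("trace", "bag"), ...) {
  type <- match.arg(type)
  n <- length(samples)
  Lp <- as.integer(ceiling(n / 32) * 32)
  X <- matrix(0, 1, Lp)
  X[1, seq_len(n)] <- samples
  z <- unet_fwd(object, X, Lp, 1L)$logits[1, seq_len(n)]
  if (type == "trace") sigmoid(z) else softmax_pool_logits(z)
}

#' Postprocess a murmurness trace into murmur segments
#'
#' Thresholds the trace, finds peaks (local maxima above the threshold with
#' prominence at least `prominence`), merges peaks closer than `merge_ms`
#' into one murmur instance, and reports each instance as the above-threshold
#' extent from its first to its last peak.
#'
#' @param trace numeric vector in \[0, 1\].
#' @param rate sampling rate, Hz.
#' @param threshold activation threshold (default 0.6).
#' @param merge_ms peak-merging margin in milliseconds (default 60).
#' @param prominence minimum peak prominence.
#' @return data.frame with `start`, `end` (0-based half-open samples) and
#'   `peak` (maximum murmurness inside the segment).
#' @export
postprocess_trace <- function(trace, rate, threshold = 0.6, merge_ms = 60,
                              prominence = 0.1) {
  n <- length(trace)
  empty <- data.frame(start = integer(0), end = integer(0), peak = numeric(0))
  if (n < 3) return(empty)
  pk <- find_peaks(trace, threshold, prominence)
  if (!length(pk)) return(empty)
  margin <- merge_ms / 1000 * rate
  grp <- cumsum(c(1, diff(pk) > margin))
  above <- trace >= threshold
  runs <- true_runs(above)
  run_of <- function(i) which(runs[, 1] <= i & runs[, 2] >= i)
  out <- lapply(split(pk, grp), function(g) {
    a <- runs[run_of(g[1]), 1]
    b <- runs[run_of(g[length(g)]), 2]
    data.frame(start = a - 1L, end = b, peak = max(trace[g]))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# local maxima above `threshold` with prominence >= prom (classic definition:
# height above the higher of the two bracketing minima, where brackets run to
# the nearest strictly higher sample or the array edge)
find_peaks <- function(x, threshold, prom) {
  n <- length(x)
  cand <- which(c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] &
                         x[2:(n - 1)] >= x[3:n], FALSE) & x >= threshold)
  if (!length(cand)) return(integer(0))
  keep <- vapply(cand, function(i) {
    v <- x[i]
    j <- i - 1L; lmin <- v
    while (j >= 1L && x[j] <= v) { lmin <- min(lmin, x[j]); j <- j - 1L }
    if (j < 1L) lmin <- min(x[1:i])
    j <- i + 1L; rmin <- v
    while (j <= n && x[j] <= v) { rmin <- min(rmin, x[j]); j <- j + 1L }
    if (j > n) rmin <- min(x[i:n])
    (v - max(lmin, rmin)) >= prom
  }, logical(1))
  cand[keep]
}

#' Phase precision of murmur activations
#'
#' Fraction of activations (postprocessed murmur segments) that overlap any
#' interval of the annotated murmur phase. An activation "lies in" a phase
#' when its extent overlaps at least one interval with that label.
#'
#' @param segments data.frame from [postprocess_trace()].
#' @param segmentation a [phase_segmentation()].
#' @param murmur_phase "systolic", "diastolic" or "both".
#' @return list with `precision` (in \[0, 1\], `NA` when there is no
#'   activation), `n_activations`, `n_in_phase` and `no_activation` flag.
#' @export
phase_precision <- function(segments, segmentation,
                            murmur_phase = c("systolic", "diastolic", "both")) {
  murmur_phase <- match.arg(murmur_phase)
  phases <- switch(murmur_phase, systolic = "systole", diastolic = "diastole",
                   both = c("systole", "diastole"))
  if (is.null(segments) || nrow(segments) == 0)
    return(list(precision = NA_real_, n_activations = 0L, n_in_phase = 0L,
                no_activation = TRUE))
  ph <- segmentation[segmentation$label %in% phases, , drop = FALSE]
  hit <- vapply(seq_len(nrow(segments)), function(i) {
    any(segments$start[i] < ph$end & segments$end[i] > ph$start)
  }, logical(1))
  list(precision = mean(hit), n_activations = nrow(segments),
       n_in_phase = sum(hit), no_activation = FALSE)
}

#' Pseudo precision on murmur-free recordings
#'
#' [phase_precision()] with the phase forced to systole, applied to
#' recordings without murmur: the expected dominant outcome is no activation
#' at all, and any activation that does occur is scored as if a systolic
#' murmur had been assumed.
#'
#' @inheritParams phase_precision
#' @return same structure as [phase_precision()].
#' @export
pseudo_precision <- function(segments, segmentation) {
  phase_precision(segments, segmentation, "systolic")
}
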