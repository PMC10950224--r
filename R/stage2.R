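# Patient-level multitask classifier (stage 2): fuses the selected
# handcrafted features (averaged over a patient's recordings), the frozen
# PANN encodings and class probabilities per auscultation location (with
# explicit missing-location masks), and demographics; predicts 3-class
# murmur and 2-class clinical outcome with a summed weighted cross-entropy.

OUTCOME_CLASSES <- c("Normal", "Abnormal")
STAGE2_LOCATIONS <- c("AV", "PV", "TV", "MV")

#' Stage-2 configuration
#'
#' @param hidden hidden layer widths (4 hidden layers + output = 5 layers).
#' @param dropout dropout rate after hidden layers.
#' @param leaky_alpha leaky-ReLU negative slope.
#' @param murmur_weight_factors per-class factors over (Present, Unknown,
#'   Absent), multiplied by inverse class frequencies.
#' @param outcome_weight_factors factors over (Normal, Abnormal).
#' @param lr Adam learning rate.
#' @param weight_decay L2 penalty on the dense-layer weights.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param val_fraction validation fraction.
#' @return a `stage2_config` list.
#' @export
stage2_config <- function(hidden = c(123, 492, 246, 20), dropout = 0.1,
                          leaky_alpha = 0.01,
                          murmur_weight_factors = c(Present = 5, Unknown = 3,
                                                    Absent = 1),
                          outcome_weight_factors = c(Normal = 1, Abnormal = 5),
                          lr = 0.01, weight_decay = 1e-3, epochs = 150,
                          batch_size = 32, val_fraction = 0.2) {
  stopifnot(length(hidden) == 4, all(hidden >= 1), dropout >= 0, dropout < 1,
            lr > 0, epochs >= 0)
  structure(list(hidden = hidden, dropout = dropout,
                 leaky_alpha = leaky_alpha,
                 murmur_weight_factors = murmur_weight_factors,
                 outcome_weight_factors = outcome_weight_factors,
                 lr = lr, weight_decay = weight_decay, epochs = epochs,
                 batch_size = batch_size, val_fraction = val_fraction),
            class = "stage2_config")
}

#' Assemble the stage-2 feature vector for one patient
#'
#' Selected handcrafted features are averaged across the patient's
#' recordings (NA-aware); each standard location slot holds the PANN
#' 20-value encoding, its 3 class probabilities and a presence-mask bit
#' (zeros + mask 0 when the location was not recorded); demographics
#' contribute age and weight.
#'
#' @param recording_outputs list with one element per recording: each a
#'   list with `features` (the named 622-vector or a subset containing the
#'   selected names), `pann` (a [pann_features()] result) and `location`.
#' @param selection a `feature_selection` from [rank_and_select()] or a
#'   character vector of selected feature names.
#' @param demographics a [demographic_record()].
#' @return named numeric vector (no NAs; missing values become 0 after
#'   masking).
#' @export
assemble_patient_features <- function(recording_outputs, selection,
                                      demographics = demographic_record()) {
  if (!length(recording_outputs)) stop("patient has no recordings")
  sel <- if (inherits(selection, "feature_selection")) selection$selected
         else as.character(selection)
  fmat <- vapply(recording_outputs, function(ro) ro$features[sel],
                 numeric(length(sel)))
  fmat <- matrix(fmat, nrow = length(sel))
  hand <- rowMeans(fmat, na.rm = TRUE)
  hand[!is.finite(hand)] <- 0
  names(hand) <- paste0("sel_", sel)
  loc_feats <- numeric(0)
  for (loc in STAGE2_LOCATIONS) {
    hit <- which(vapply(recording_outputs, function(ro)
      identical(ro$location, loc), logical(1)))
    if (length(hit)) {
      pf <- recording_outputs[[hit[1]]]$pann
      v <- c(pf$encoded, pf$probs, 1)
    } else {
      v <- c(numeric(23), 0)
    }
    names(v) <- paste0(loc, "_", c(paste0("enc", 1:20),
                                   paste0("p_", MURMUR_CLASSES), "mask"))
    loc_feats <- c(loc_feats, v)
  }
  demo <- c(age = ifelse(is.na(demographics$age), 0, demographics$age),
            weight = ifelse(is.na(demographics$weight), 0,
                            demographics$weight))
  c(hand, loc_feats, demo)
}

#' Stage-2 multitask loss
#'
#' Sum of the murmur and outcome weighted cross-entropies:
#' `L = L_CE(y_m, p_m, w_m) + L_CE(y_o, p_o, w_o)`, each term
#' `-w[y] log p[y]` with the true-class probability clamped at 1e-12.
#'
#' @param murmur_probs named numeric over (Present, Unknown, Absent).
#' @param outcome_probs named numeric over (Normal, Abnormal).
#' @param murmur_label,outcome_label true class names.
#' @param murmur_weights,outcome_weights per-class weight vectors.
#' @return scalar loss (non-negative; zero iff both predictions are
#'   one-hot correct).
#' @export
stage2_loss <- function(murmur_probs, outcome_probs, murmur_label,
                        outcome_label,
                        murmur_weights = c(Present = 5, Unknown = 3,
                                           Absent = 1),
                        outcome_weights = c(Normal = 1, Abnormal = 5)) {
  pm <- max(murmur_probs[[murmur_label]], 1e-12)
  po <- max(outcome_probs[[outcome_label]], 1e-12)
  -murmur_weights[[murmur_label]] * log(pm) -
    outcome_weights[[outcome_label]] * log(po)
}

# forward through the MLP; X is features x batch
stage2_fwd <- function(model, X, train = FALSE, want_cache = FALSE) {
  par <- model$params
  cfg <- model$config
  caches <- list()
  cur <- X
  for (i in seq_along(cfg$hidden)) {
    d <- dense_fwd(cur, par[[sprintf("fc%d", i)]])
    bn <- bn_fwd(d$Y, par[[sprintf("bn%d", i)]], train = train)
    if (train) model$params[[sprintf("bn%d", i)]] <- bn$par
    lr <- leaky_relu_fwd(bn$Y, cfg$leaky_alpha)
    dr <- dropout_fwd(lr$Y, cfg$dropout, train = train)
    if (want_cache) caches[[sprintf("h%d", i)]] <-
      list(d = d$cache, bn = bn$cache, lr = lr$cache, dr = dr$cache)
    cur <- dr$Y
  }
  out <- dense_fwd(cur, par$head)
  if (want_cache) caches$head <- out$cache
  zm <- out$Y[1:3, , drop = FALSE]
  zo <- out$Y[4:5, , drop = FALSE]
  list(murmur_probs = softmax_cols(zm), outcome_probs = softmax_cols(zo),
       caches = caches, model = model)
}

stage2_bwd <- function(model, caches, dm, do_) {
  par <- model$params
  cfg <- model$config
  grads <- list()
  dhead <- rbind(dm, do_)
  g <- dense_bwd(dhead, par$head, caches$head)
  grads[["head.W"]] <- g$dW; grads[["head.b"]] <- g$db
  d_cur <- g$dX
  for (i in rev(seq_along(cfg$hidden))) {
    cc <- caches[[sprintf("h%d", i)]]
    d_dr <- dropout_bwd(d_cur, cc$dr)
    d_lr <- leaky_relu_bwd(d_dr, cc$lr)
    gbn <- bn_bwd(d_lr, cc$bn)
    grads[[sprintf("bn%d.gamma", i)]] <- gbn$dgamma
    grads[[sprintf("bn%d.beta", i)]] <- gbn$dbeta
    gd <- dense_bwd(gbn$dX, par[[sprintf("fc%d", i)]], cc$d)
    grads[[sprintf("fc%d.W", i)]] <- gd$dW
    grads[[sprintf("fc%d.b", i)]] <- gd$db
    d_cur <- gd$dX
  }
  grads
}

#' Train the stage-2 patient classifier
#'
#' 5 feed-forward layers (4 hidden + heads), batch norm and leaky ReLU per
#' hidden layer, dropout after hidden layers; summed weighted cross-entropy
#' over the murmur and outcome heads with inverse-class-frequency base
#' weights scaled by the configured factors.
#'
#' @param X numeric matrix, rows = patients, columns = assembled features
#'   ([assemble_patient_features()]).
#' @param murmur_labels character over Present/Unknown/Absent (all three
#'   need not be present, but at least two).
#' @param outcome_labels character over Normal/Abnormal.
#' @param config a [stage2_config()].
#' @param seed RNG seed.
#' @param verbose print progress.
#' @return a trained `stage2` model.
#' @export
train_stage2 <- function(X, murmur_labels, outcome_labels,
                         config = stage2_config(), seed = 1L,
                         verbose = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n == length(murmur_labels), n == length(outcome_labels))
  ym <- match(murmur_labels, MURMUR_CLASSES)
  yo <- match(outcome_labels, OUTCOME_CLASSES)
  if (anyNA(ym)) stop("murmur labels must be Present/Unknown/Absent")
  if (anyNA(yo)) stop("outcome labels must be Normal/Abnormal")
  if (length(unique(ym)) < 2) stop("single-class murmur task")
  if (length(unique(yo)) < 2) stop("single-class outcome task")
  # inverse relative frequency, absent classes get weight 0 contribution
  freq_m <- table(factor(murmur_labels, levels = MURMUR_CLASSES))
  wm_base <- ifelse(freq_m > 0, n / pmax(as.numeric(freq_m), 1), 0)
  wm <- wm_base / mean(wm_base[wm_base > 0]) *
    config$murmur_weight_factors[MURMUR_CLASSES]
  freq_o <- table(factor(outcome_labels, levels = OUTCOME_CLASSES))
  wo_base <- n / pmax(as.numeric(freq_o), 1)
  wo <- wo_base / mean(wo_base) * config$outcome_weight_factors[OUTCOME_CLASSES]
  # feature standardization (stored for prediction)
  mu <- colMeans(X); sdv <- apply(X, 2, stats::sd); sdv[sdv < 1e-8] <- 1
  Xs <- t((t(X) - mu) / sdv)
  with_seed(seed, {
    par <- list()
    d_in <- ncol(X)
    for (i in seq_along(config$hidden)) {
      par[[sprintf("fc%d", i)]] <- nn_init_dense(d_in, config$hidden[i])
      par[[sprintf("bn%d", i)]] <- nn_init_bn(config$hidden[i])
      d_in <- config$hidden[i]
    }
    par$head <- nn_init_dense(d_in, 5L)
    model <- structure(list(params = par, config = config, center = mu,
                            scale = sdv, trained = FALSE, history = NULL),
                       class = "stage2")
    if (config$epochs == 0L) return(model)
    # stratified validation split over the murmur classes
    val_idx <- unlist(lapply(split(seq_len(n), ym), function(ix)
      sample(ix, max(1L, round(config$val_fraction * length(ix))))))
    tr_idx <- setdiff(seq_len(n), val_idx)
    flat <- flatten_params(par)
    opt <- adam_init(flat)
    best_val <- Inf; best_params <- model$params; hist <- data.frame()
    wm_v <- unname(wm); wo_v <- unname(wo)
    batch_loss_grad <- function(fw, idx) {
      B <- length(idx)
      lm <- wce_loss_grad(fw$murmur_probs, ym[idx], wm_v)
      lo <- wce_loss_grad(fw$outcome_probs, yo[idx], wo_v)
      list(loss = lm$loss + lo$loss, dm = lm$dlogits, do_ = lo$dlogits)
    }
    for (ep in seq_len(config$epochs)) {
      ord <- sample(tr_idx)
      ep_loss <- 0; n_b <- 0
      for (start in seq(1, length(ord), by = config$batch_size)) {
        bi <- ord[start:min(start + config$batch_size - 1, length(ord))]
        model$params <- unflatten_params(flat, model$params)
        fw <- stage2_fwd(model, t(Xs[bi, , drop = FALSE]), train = TRUE,
                         want_cache = TRUE)
        model <- fw$model
        lg <- batch_loss_grad(fw, bi)
        grads <- stage2_bwd(model, fw$caches, lg$dm, lg$do_)
        if (config$weight_decay > 0) {
          for (nm in grep("\\.W$", names(grads), value = TRUE))
            grads[[nm]] <- grads[[nm]] + config$weight_decay * flat[[nm]]
        }
        grads <- clip_gradients(grads, 5)
        st <- adam_step(flat, grads, opt, config$lr)
        flat <- st$params; opt <- st$state
        ep_loss <- ep_loss + lg$loss; n_b <- n_b + 1
      }
      model$params <- unflatten_params(flat, model$params)
      fw <- stage2_fwd(model, t(Xs[val_idx, , drop = FALSE]))
      vl <- batch_loss_grad(fw, val_idx)$loss
      hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss / n_b,
                                     val_loss = vl))
      if (verbose && ep %% 10 == 0)
        message(sprintf("epoch %d: train %.4f val %.4f", ep, ep_loss / n_b, vl))
      # snapshot weights together with their batch-norm running statistics
      if (vl < best_val) { best_val <- vl; best_params <- model$params }
    }
    model$params <- best_params
    model$trained <- TRUE
    model$history <- hist
    model$class_weights <- list(murmur = wm, outcome = wo)
    model
  })
}

#' Predict murmur and outcome for patients
#'
#' @param object a trained `stage2` model.
#' @param X feature matrix (rows = patients) or a single feature vector.
#' @param ... unused.
#' @return list with `murmur_probs` (n x 3), `outcome_probs` (n x 2),
#'   `murmur` and `outcome` (argmax decisions).
#' @export
predict.stage2 <- function(object, X, ...) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  Xs <- t((t(X) - object$center) / object$scale)
  fw <- stage2_fwd(object, t(Xs))
  mp <- t(fw$murmur_probs); op <- t(fw$outcome_probs)
  colnames(mp) <- MURMUR_CLASSES; colnames(op) <- OUTCOME_CLASSES
  list(murmur_probs = mp, outcome_probs = op,
       murmur = MURMUR_CLASSES[apply(mp, 1, which.max)],
       outcome = OUTCOME_CLASSES[apply(op, 1, which.max)])
}

#' @export
print.stage2 <- function(x, ...) {
  cat(sprintf("Stage-2 multitask MLP: %d inputs -> %s -> (3 murmur + 2 outcome)%s\n",
              length(x$center), paste(x$config$hidden, collapse = " -> "),
              if (x$trained) ", trained" else ", untrained"))
  invisible(x)
}
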