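# Minimal neural-network primitives on base-R matrices (BLAS-backed GEMM).
# Activations are stored channels-by-columns: a batch of B signals of length
# L with C channels is a C x (L*B) matrix, sample-major in the columns.
# Every layer returns its output plus the cache its backward pass needs.
# These are internal building blocks for the MIL U-Net, the PANN encoder and
# the stage-2 MLP.

nn_init_conv <- function(c_in, c_out, k, rng_sd = NULL) {
  sd <- if (is.null(rng_sd)) sqrt(2 / (c_in * k)) else rng_sd
  list(W = array(stats::rnorm(c_out * c_in * k, 0, sd), c(c_out, c_in, k)),
       b = numeric(c_out))
}

nn_init_dense <- function(f_in, f_out) {
  list(W = matrix(stats::rnorm(f_out * f_in, 0, sqrt(2 / f_in)), f_out, f_in),
       b = numeric(f_out))
}

nn_init_bn <- function(c) {
  list(gamma = rep(1, c), beta = numeric(c),
       run_mean = numeric(c), run_var = rep(1, c))
}

# 1D convolution, stride 1, same padding, kernel size K (odd); compiled
# kernels carry the GEMM work.
conv1d_fwd <- function(X, par, L, B) {
  Y <- cpp_conv1d_fwd(X, par$W, par$b, as.integer(L), as.integer(B))
  list(Y = Y, cache = list(X = X, L = as.integer(L), B = as.integer(B)))
}

conv1d_bwd <- function(dY, par, cache) {
  cpp_conv1d_bwd(cache$X, par$W, dY, cache$L, cache$B)
}

relu_fwd <- function(X) {
  mask <- X > 0
  list(Y = X * mask, cache = mask)
}
relu_bwd <- function(dY, mask) dY * mask

leaky_relu_fwd <- function(X, alpha = 0.01) {
  mask <- X > 0
  list(Y = ifelse(mask, X, alpha * X), cache = list(mask = mask, alpha = alpha))
}
leaky_relu_bwd <- function(dY, cache)
  dY * ifelse(cache$mask, 1, cache$alpha)

# max pool, window 2 stride 2 (L must be even)
maxpool2_fwd <- function(X, L, B) {
  stopifnot(L %% 2L == 0L)
  odd <- X[, seq(1L, ncol(X), by = 2L), drop = FALSE]
  even <- X[, seq(2L, ncol(X), by = 2L), drop = FALSE]
  mask <- odd >= even
  list(Y = pmax(odd, even), cache = list(mask = mask, L = L, B = B))
}
maxpool2_bwd <- function(dY, cache) {
  C <- nrow(dY)
  dX <- matrix(0, C, 2L * ncol(dY))
  dX[, seq(1L, ncol(dX), by = 2L)] <- dY * cache$mask
  dX[, seq(2L, ncol(dX), by = 2L)] <- dY * (!cache$mask)
  dX
}

# nearest-neighbour x2 upsampling
upsample2_fwd <- function(X) X[, rep(seq_len(ncol(X)), each = 2L), drop = FALSE]
upsample2_bwd <- function(dY) {
  dY[, seq(1L, ncol(dY), by = 2L), drop = FALSE] +
    dY[, seq(2L, ncol(dY), by = 2L), drop = FALSE]
}

dense_fwd <- function(X, par) {
  list(Y = par$W %*% X + par$b, cache = X)
}
dense_bwd <- function(dY, par, X) {
  list(dX = t(par$W) %*% dY, dW = dY %*% t(X), db = rowSums(dY))
}

# batch normalization over columns, per row (channel)
bn_fwd <- function(X, par, train = TRUE, momentum = 0.1, eps = 1e-5) {
  if (train && ncol(X) > 1L) {
    mu <- rowMeans(X)
    v <- rowMeans((X - mu)^2)
    par$run_mean <- (1 - momentum) * par$run_mean + momentum * mu
    par$run_var <- (1 - momentum) * par$run_var + momentum * v
  } else {
    mu <- par$run_mean
    v <- par$run_var
  }
  ivar <- 1 / sqrt(v + eps)
  xhat <- (X - mu) * ivar
  list(Y = par$gamma * xhat + par$beta, par = par,
       cache = list(xhat = xhat, ivar = ivar, gamma = par$gamma))
}
bn_bwd <- function(dY, cache) {
  N <- ncol(dY)
  dgamma <- rowSums(dY * cache$xhat)
  dbeta <- rowSums(dY)
  dX <- (cache$gamma * cache$ivar / N) *
    (N * dY - dbeta - cache$xhat * dgamma)
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

dropout_fwd <- function(X, rate, train = TRUE) {
  if (!train || rate <= 0) return(list(Y = X, cache = NULL))
  mask <- matrix(stats::runif(length(X)) >= rate, nrow(X)) / (1 - rate)
  list(Y = X * mask, cache = mask)
}
dropout_bwd <- function(dY, mask) if (is.null(mask)) dY else dY * mask

# Adaptive pooling of each sample's L columns into m segments
# (floor/ceiling boundaries). type in max/avg/min. Output C x (m*B).
adaptive_pool_fwd <- function(X, L, B, m, type = c("max", "avg", "min")) {
  type <- match.arg(type)
  C <- nrow(X)
  Y <- matrix(0, C, m * B)
  arg <- if (type != "avg") matrix(0L, C, m * B) else NULL
  widths <- integer(m)
  base <- (0:(B - 1L)) * L
  for (i in seq_len(m)) {
    s <- floor((i - 1L) * L / m) + 1L
    e <- ceiling(i * L / m)
    widths[i] <- e - s + 1L
    outc <- seq(i, m * B, by = m)  # column i of each sample
    if (type == "avg") {
      acc <- matrix(0, C, B)
      for (j in s:e) acc <- acc + X[, base + j, drop = FALSE]
      Y[, outc] <- acc / (e - s + 1L)
    } else {
      best <- X[, base + s, drop = FALSE]
      bidx <- matrix(s, C, B)
      if (e > s) for (j in (s + 1L):e) {
        cand <- X[, base + j, drop = FALSE]
        upd <- if (type == "max") cand > best else cand < best
        best[upd] <- cand[upd]
        bidx[upd] <- j
      }
      Y[, outc] <- best
      arg[, outc] <- bidx
    }
  }
  list(Y = Y, cache = list(L = L, B = B, m = m, type = type, arg = arg,
                           widths = widths))
}
adaptive_pool_bwd <- function(dY, cache) {
  C <- nrow(dY); L <- cache$L; B <- cache$B; m <- cache$m
  dX <- matrix(0, C, L * B)
  base <- (0:(B - 1L)) * L
  for (i in seq_len(m)) {
    s <- floor((i - 1L) * L / m) + 1L
    e <- ceiling(i * L / m)
    outc <- seq(i, m * B, by = m)
    if (cache$type == "avg") {
      g <- dY[, outc, drop = FALSE] / (e - s + 1L)
      for (j in s:e) dX[, base + j] <- dX[, base + j, drop = FALSE] + g
    } else {
      bidx <- cache$arg[, outc, drop = FALSE]      # C x B, positions in s..e
      g <- dY[, outc, drop = FALSE]
      cols <- rep(base, each = C) + as.vector(bidx) # target column per entry
      lin <- (cols - 1L) * C + rep(seq_len(C), B)
      # duplicate linear indices cannot occur (one argmax per (channel,sample,i))
      dX[lin] <- dX[lin] + as.vector(g)
    }
  }
  dX
}

softmax_cols <- function(Z) {
  Z <- Z - matrix(apply(Z, 2, max), nrow(Z), ncol(Z), byrow = TRUE)
  E <- exp(Z)
  E / matrix(colSums(E), nrow(Z), ncol(Z), byrow = TRUE)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# global-norm gradient clipping: rescale all gradients when the joint
# L2 norm exceeds max_norm (guards against the rare loss spikes of
# pooled-probability BCE when a bag probability saturates)
clip_gradients <- function(grads, max_norm) {
  if (!is.finite(max_norm)) return(grads)
  total <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (!is.finite(total)) {
    grads <- lapply(grads, function(g) { g[!is.finite(g)] <- 0; g })
    total <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  }
  if (total > max_norm) grads <- lapply(grads, function(g) g * max_norm / total)
  grads
}

# Adam optimizer over a flat named list of arrays.
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# flatten nested parameter lists ({layer}.{tensor}) for the optimizer
flatten_params <- function(nested) {
  out <- list()
  for (ln in names(nested)) {
    for (tn in names(nested[[ln]])) {
      if (tn %in% c("run_mean", "run_var")) next
      out[[paste0(ln, ".", tn)]] <- nested[[ln]][[tn]]
    }
  }
  out
}
unflatten_params <- function(flat, nested) {
  for (nm in names(flat)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    nested[[parts[1]]][[parts[2]]] <- flat[[nm]]
  }
  nested
}
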