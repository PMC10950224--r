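test_that("softmax pooling matches direct evaluation of the formula", {
  # single instance and uniform instances pool to themselves
  expect_equal(softmax_pool(0.42), 0.42)
  expect_equal(softmax_pool(rep(0.3, 100)), 0.3)
  # [0.1, 0.9] -> (0.1 e^0.1 + 0.9 e^0.9) / (e^0.1 + e^0.9)
  expect_equal(softmax_pool(c(0.1, 0.9)),
               (0.1 * exp(0.1) + 0.9 * exp(0.9)) / (exp(0.1) + exp(0.9)),
               tolerance = 1e-15)
  expect_equal(round(softmax_pool(c(0.1, 0.9)), 3), 0.652)
  expect_error(softmax_pool(numeric(0)))
  expect_error(softmax_pool(c(0.5, 1.2)))
})

test_that("softmax pooling oracle agreement on 1000 random traces", {
  set.seed(11)
  for (i in 1:1000) {
    p <- stats::runif(sample(1:50, 1))
    oracle <- sum(p * exp(p)) / sum(exp(p))   # direct formula
    expect_equal(softmax_pool(p), oracle, tolerance = 1e-12)
    # bounds: mean <= pooled <= max
    expect_gte(softmax_pool(p) + 1e-12, mean(p))
    expect_lte(softmax_pool(p) - 1e-12, max(p))
  }
})

test_that("softmax pooling is permutation-invariant and monotone", {
  set.seed(12)
  for (i in 1:50) {
    p <- stats::runif(20)
    expect_equal(softmax_pool(p), softmax_pool(sample(p)))
    j <- sample(20, 1)
    q <- p
    q[j] <- min(1, p[j] + stats::runif(1, 0, 1 - p[j]))
    expect_gte(softmax_pool(q), softmax_pool(p) - 1e-12)
  }
  # logit-scale variant shares the bounds
  z <- stats::rnorm(100, 0, 3)
  pl <- softmax_pool_logits(z)
  p <- 1 / (1 + exp(-z))
  expect_gte(pl + 1e-12, mean(p))
  expect_lte(pl - 1e-12, max(p))
})

test_that("the U-Net is fully convolutional with matched output length", {
  m <- build_mil_unet(widths = c(2, 2, 3, 3, 4, 4), seed = 1)
  for (L in c(2^14, 2^12)) {
    X <- matrix(stats::rnorm(L), 1)
    out <- murmil:::unet_fwd(m, X, L, 1L)
    expect_equal(ncol(out$logits), L)
    expect_equal(nrow(out$logits), 1)
  }
  # all-zero input with freshly initialized zero biases -> spatially
  # constant output (translation invariance of convolutions)
  X0 <- matrix(0, 1, 2^10)
  out0 <- murmil:::unet_fwd(m, X0, 2^10, 1L)$logits
  expect_lt(diff(range(out0)), 1e-12)
})

test_that("murmurness traces are probabilities of the input length", {
  m <- build_mil_unet(widths = c(2, 2, 3, 3, 4, 4), seed = 2)
  x <- stats::rnorm(5000)  # not a multiple of 32; padding handled inside
  tr <- murmurness(m, x)
  expect_length(tr, 5000)
  expect_true(all(tr >= 0 & tr <= 1))
})

test_that("training with 0 epochs returns the initial weights", {
  set.seed(3)
  sigs <- lapply(1:4, function(i) stats::rnorm(2^10))
  m0 <- build_mil_unet(seed = 9)
  m <- train_mil(sigs, c(1, 0, 1, 0),
                 mil_train_config(epochs = 0), model = m0, seed = 9)
  expect_identical(m$params, m0$params)
  expect_error(train_mil(sigs, c(1, 1, 1, 1), mil_train_config(epochs = 1)),
               "both")
})

test_that("a short training run reduces the loss and is seed-reproducible", {
  set.seed(4)
  # tiny separable task: positives carry a strong 300 Hz band burst
  mk <- function(pos) {
    x <- 0.05 * stats::rnorm(2^11)
    if (pos) x[500:900] <- x[500:900] + sin(2 * pi * 300 * (0:400) / 2000)
    x
  }
  sigs <- c(lapply(1:8, function(i) mk(TRUE)), lapply(1:8, function(i) mk(FALSE)))
  labs <- rep(c(1, 0), each = 8)
  cfg <- mil_train_config(batch_size = 8, epochs = 6, patience = 6,
                          fixed_length = 2^11)
  m1 <- train_mil(sigs, labs, cfg, seed = 5)
  expect_lt(utils::tail(m1$history$train_loss, 1), m1$history$train_loss[1])
  m2 <- train_mil(sigs, labs, cfg, seed = 5)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
})

test_that("postprocessing follows the threshold and 60 ms merge rule", {
  rate <- 2000
  expect_equal(nrow(postprocess_trace(numeric(1000), rate)), 0)
  # two peaks 30 ms apart -> one segment; 100 ms apart -> two
  mk_trace <- function(gap_ms) {
    tr <- rep(0.0, 2000)
    p1 <- 500; p2 <- 500 + round(gap_ms / 1000 * rate)
    for (p in c(p1, p2)) tr[(p - 10):(p + 10)] <-
        0.9 * (1 - abs(-10:10) / 12)
    tr
  }
  expect_equal(nrow(postprocess_trace(mk_trace(30), rate)), 1)
  expect_equal(nrow(postprocess_trace(mk_trace(100), rate)), 2)
  # triangular pulse peaking at 0.9 -> exactly one segment containing the apex
  tr <- pmax(0, 0.9 * (1 - abs(seq(-1, 1, length.out = 2001))))
  seg <- postprocess_trace(tr, rate)
  expect_equal(nrow(seg), 1)
  apex <- which.max(tr) - 1L
  expect_true(seg$start <= apex && seg$end > apex)
  expect_equal(seg$peak, max(tr))
  # threshold honored exactly: peak below 0.6 gives nothing
  expect_equal(nrow(postprocess_trace(tr * 0.6, rate)), 0)
})

test_that("postprocessing agrees with a brute-force oracle on random traces", {
  # oracle: independent O(n^2)-style scan — local maxima above threshold,
  # prominence by explicit walk, exhaustive chain merge, run extents
  oracle_pp <- function(tr, rate, thr = 0.6, merge_ms = 60, prom = 0.1) {
    n <- length(tr)
    peaks <- c()
    for (i in 2:(n - 1)) {
      if (tr[i] >= thr && tr[i] > tr[i - 1] && tr[i] >= tr[i + 1]) {
        v <- tr[i]
        l <- i; while (l > 1 && tr[l - 1] <= v) l <- l - 1
        r <- i; while (r < n && tr[r + 1] <= v) r <- r + 1
        lmin <- min(tr[l:i]); rmin <- min(tr[i:r])
        if (v - max(lmin, rmin) >= prom) peaks <- c(peaks, i)
      }
    }
    if (!length(peaks)) return(0L)
    margin <- merge_ms / 1000 * rate
    groups <- 1
    for (k in seq_along(peaks)[-1])
      groups <- c(groups, if (peaks[k] - peaks[k - 1] > margin)
        max(groups) + 1 else max(groups))
    length(unique(groups))
  }
  set.seed(13)
  for (i in 1:30) {
    tr <- stats::pnorm(cumsum(stats::rnorm(5000, 0, 0.2)) / 3)
    got <- postprocess_trace(tr, 2000)
    expect_equal(nrow(got), oracle_pp(tr, 2000))
  }
})

test_that("phase precision counts in-phase activations", {
  seg <- fix_clean_rec()$segmentation
  sys <- seg[seg$label == "systole", ]
  dia <- seg[seg$label == "diastole", ]
  mk_seg <- function(rows) data.frame(start = rows$start + 2,
                                      end = rows$start + 40,
                                      peak = 0.9)
  # 4 activations all overlapping systole -> 1.0
  s4 <- mk_seg(sys[1:4, ])
  expect_equal(phase_precision(s4, seg, "systolic")$precision, 1.0)
  # no activations -> NO_ACTIVATION
  none <- phase_precision(data.frame(start = integer(0), end = integer(0),
                                     peak = numeric(0)), seg, "systolic")
  expect_true(none$no_activation)
  expect_true(is.na(none$precision))
  # 3 of 4 in systole -> 0.75 (oracle: manual overlap count)
  s3 <- rbind(mk_seg(sys[1:3, ]), mk_seg(dia[1, ]))
  expect_equal(phase_precision(s3, seg, "systolic")$precision, 0.75)
  # pseudo precision: phase forced to systole
  expect_equal(pseudo_precision(s3, seg)$precision, 0.75)
  expect_equal(pseudo_precision(mk_seg(dia[1, ]), seg)$precision, 0.0)
  half <- rbind(mk_seg(sys[1, ]), mk_seg(dia[1, ]))
  expect_equal(pseudo_precision(half, seg)$precision, 0.5)
})
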