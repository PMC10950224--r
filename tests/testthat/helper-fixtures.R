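# Shared fixtures. Recordings are generated in code; the expensive trained
# models are built once per test run and memoized here so several test
# files can share them.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# a clean systolic-murmur recording and a murmur-free twin (same seed)
fix_murmur_rec <- function(seed = 11, snr = 6, hr = 100) {
  memo(sprintf("mur_%d_%g_%g", seed, snr, hr),
       synth_recording(sim_config(duration = 10, heart_rate = hr,
                                  murmur_present = TRUE, murmur_snr = snr,
                                  seed = seed)))
}

fix_clean_rec <- function(seed = 11, hr = 100) {
  memo(sprintf("cln_%d_%g", seed, hr),
       synth_recording(sim_config(duration = 10, heart_rate = hr,
                                  murmur_present = FALSE, seed = seed)))
}

# band-passed + globally scaled input as used for MIL training
mil_input <- function(rec) 4 * pcg_bandpass(rec$samples, rec$rate)

# recordings for MIL training experiments: n/2 murmur, n/2 clean, varied
# heart rate / SNR / noise (the study conditions of the generator defaults)
mil_training_set <- function(n, seed = 500) {
  memo(sprintf("milset_%d_%d", n, seed), {
    set.seed(seed)
    half <- n %/% 2
    recs <- c(
      lapply(seq_len(half), function(i)
        synth_recording(sim_config(
          duration = 10, heart_rate = runif(1, 70, 140),
          murmur_present = TRUE, murmur_snr = runif(1, 3, 10),
          noise_level = runif(1, 0.01, 0.05), seed = seed + i))),
      lapply(seq_len(n - half), function(i)
        synth_recording(sim_config(
          duration = 10, heart_rate = runif(1, 70, 140),
          murmur_present = FALSE, noise_level = runif(1, 0.01, 0.05),
          seed = seed + half + i))))
    list(recordings = recs,
         signals = lapply(recs, mil_input),
         labels = rep(c(1, 0), c(half, n - half)))
  })
}

# the shared trained MIL U-Net (localization fixture); built once
trained_mil <- function() {
  memo("trained_mil", {
    tr <- mil_training_set(200)
    train_mil(tr$signals, tr$labels,
              mil_train_config(batch_size = 16, epochs = 12, patience = 12,
                               lr_decay_every = 25),
              seed = 7)
  })
}
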