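# Shared fixtures. Everything is generated in code; the expensive trained
# network used by the acceptance tests is built once per test run and
# cached in this environment.

.fixtures <- new.env(parent = emptyenv())

# Reduced-scale training of the phase-coding network (the acceptance
# stated world): N = 256, rank 2, oscillatory init, linear readout, rate
# regularizer, synthetic 7-9 Hz reference, 1024 trials/epoch, 50 epochs.
acceptance_training <- function(seed = 1) {
  key <- paste0("train_", seed)
  if (!is.null(.fixtures[[key]])) return(.fixtures[[key]])
  dseed <- seed * 1000 + 17
  rec <- synthetic_lfp(240 * 4, 500, 7, 9, 0.2, 0.3, seed = dseed)
  pre <- preprocess(rec)
  segs <- segment_trials(pre, seed = dseed + 1)
  sp <- split_segments(segs, 0.9, seed = dseed + 2)
  cfg <- task_config()
  mk <- function(ss, n, s0) lapply(seq_len(n), function(i)
    make_trial(ss[[1 + (i - 1) %% length(ss)]], 1 + (i - 1) %% 2, cfg,
               seed = s0 + i))
  trials <- mk(sp$train, 1024, dseed + 10)
  vals <- mk(sp$validation, 128, dseed + 500000)
  rnn <- init_rnn(256, 2, init_spec("oscillatory"), seed = dseed + 3)
  t0 <- Sys.time()
  fit <- train_rnn(rnn, trials,
                   train_config(epochs = 50, regularize_rates = TRUE),
                   seed = dseed + 4, val_trials = vals)
  fit$minutes <- as.numeric(difftime(Sys.time(), t0, units = "mins"))
  fit$rnn <- canonicalize(fit$rnn)
  fit$task_cfg <- cfg
  .fixtures[[key]] <- fit
  fit
}

# small deterministic canonical rank-2 test network
tiny_rnn <- function(N = 32, seed = 42, mode = "oscillatory") {
  canonicalize(init_rnn(N, 2, init_spec(mode), seed = seed))
}

# pure-sine task trials on the training grid
sine_trials <- function(n, stim = NULL, cfg = task_config(), seed0 = 1000,
                        freq_hz = 8) {
  ref <- pure_sine(freq_hz, 1, 0, 2, 1000 / cfg$h)
  lapply(seq_len(n), function(i)
    make_trial(ref, if (is.null(stim)) 1 + (i - 1) %% 2 else stim, cfg,
               seed = seed0 + i))
}

# readout phase lag (units of pi) over the last two reference cycles,
# estimated by projection onto sin/cos of the reference phase
readout_lag_pi <- function(r, trial, freq_hz = 8, n_cycles = 2) {
  idx <- which(trial$mask)
  n_win <- round(n_cycles * (1000 / freq_hz) / trial$h)
  idx <- idx[(length(idx) - n_win + 1):length(idx)]
  a <- sum(r[idx] * sin(trial$theta[idx]))
  b <- sum(r[idx] * cos(trial$theta[idx]))
  atan2(-b, a) / pi
}

circ_mean_pi <- function(lags_pi) {
  (atan2(mean(sin(lags_pi * pi)), mean(cos(lags_pi * pi))) / pi) %% 2
}
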