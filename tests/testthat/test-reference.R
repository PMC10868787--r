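# Synthetic theta-band generator and the preprocessing / phase pipeline.

test_that("synthetic LFP has its spectral peak in the requested band and is
           deterministic per seed", {
  rec <- synthetic_lfp(4, 500, 7, 9, 0.2, 0.3, seed = 1)
  x <- rec$samples[1, ]
  sp <- stats::spec.pgram(ts(x, frequency = 500), plot = FALSE, taper = 0,
                          spans = 5)
  fpeak <- sp$freq[which.max(sp$spec)]
  expect_gte(fpeak, 7)
  expect_lte(fpeak, 9)
  rec2 <- synthetic_lfp(4, 500, 7, 9, 0.2, 0.3, seed = 1)
  expect_identical(rec$samples, rec2$samples)
  rec3 <- synthetic_lfp(4, 500, 7, 9, 0.2, 0.3, seed = 2)
  expect_false(identical(rec$samples, rec3$samples))
})

test_that("degenerate drift collapses to a near-pure sinusoid", {
  rec <- synthetic_lfp(4, 500, 7.999, 8.001, 0, 0, seed = 3)
  x <- rec$samples[1, ]
  t <- seq_along(x) / 500
  fit <- lm(x ~ sin(2 * pi * 8 * t) + cos(2 * pi * 8 * t))
  expect_gt(cor(fitted(fit), x), 0.99)
})

test_that("generator rejects invalid parameters", {
  expect_error(synthetic_lfp(-1, 500, 7, 9, 0.2, 0.3, seed = 1), "duration")
  expect_error(synthetic_lfp(4, 500, 9, 7, 0.2, 0.3, seed = 1), "band")
  expect_error(synthetic_lfp(4, 500, 7, 400, 0.2, 0.3, seed = 1), "band")
  expect_error(synthetic_lfp(4, 500, 7, 9, 0.2, 0.3), "seed")
})

test_that("preprocess normalizes to unit-sine RMS and is a real high-pass", {
  # unit 8 Hz sine at 1250 Hz in -> RMS 1/sqrt(2) within 2% after resampling
  t <- seq(0, 8, by = 1 / 1250)
  rec <- raw_recording(sin(2 * pi * 8 * t), 1250)
  pp <- preprocess(rec)
  expect_equal(pp$sample_rate, 500)
  rms <- sqrt(mean(pp$samples[1, ]^2))
  expect_lt(abs(rms - 1 / sqrt(2)) / (1 / sqrt(2)), 0.02)

  # DC input is annihilated (high-pass has an exact zero at DC)
  recdc <- raw_recording(rep(2, 3000), 500)
  ppdc <- preprocess(recdc)
  core <- ppdc$samples[1, 600:2400]
  expect_lt(max(abs(core)), 1e-10)

  # frequency-response oracle computed from the designed taps directly:
  # stopband (< 7 Hz) at least 20 dB below passband
  taps <- oscmem:::fir_highpass(511, 7 / 500)
  H <- function(f) abs(sum(taps * exp(-2i * pi * f / 500 * seq_along(taps))))
  pass <- mean(vapply(c(20, 40, 80), H, 0))
  stopb <- max(vapply(c(0.5, 2, 4), H, 0))
  expect_gt(20 * log10(pass / stopb), 20)

  expect_error(preprocess(raw_recording(rnorm(100), 500)), "shorter")
})

test_that("Morlet phase extraction recovers frequency and phase", {
  ps <- pure_sine(8, 1, 0, 4, 500)
  ph <- extract_phase(ps$u, 500)
  expect_equal(ph$dominant_freq, 8.0)
  slope <- mean(diff(oscmem:::unwrap_phase(ph$theta))) * 500
  expect_lt(abs(slope - 2 * pi * 8) / (2 * pi * 8), 0.01)
  # sin(theta) reconstructs the signal (phase convention)
  expect_gt(cor(sin(ph$theta), ps$u[(ph$offset + 1):length(ps$u)]), 0.999)

  ps74 <- pure_sine(7.4, 1, 0.3, 4, 500)
  expect_equal(extract_phase(ps74$u, 500)$dominant_freq, 7.4)

  expect_error(extract_phase(ps$u, 500, freq_lo = 9, freq_hi = 7), "grid")
})

test_that("end-to-end: pipeline recovers the generator's hidden phase", {
  rec <- synthetic_lfp(24, 500, 7, 9, 0.2, 0.3, seed = 7, n_channels = 2)
  pre <- preprocess(rec)
  segs <- segment_trials(pre, seed = 8)
  expect_gt(length(segs), 0)
  tp <- attr(pre, "true_phase")
  seg_n <- 4 * 500
  ccs <- vapply(seq_along(segs), function(s) {
    ref <- segs[[s]]
    idx <- (s - 1) * seg_n + (seg_n - length(ref$u) + 1):seg_n
    oscmem:::circ_cor(ref$theta, tp[idx])
  }, 0)
  expect_gt(min(ccs), 0.9)
  # invariant: unwrapped theta strictly increasing
  for (ref in segs)
    expect_true(all(diff(oscmem:::unwrap_phase(ref$theta)) > 0))
})

test_that("segmenting counts, artifact rejection, reproducible channels", {
  rec <- synthetic_lfp(40, 500, 7, 9, 0.1, 0.2, seed = 9)
  pre <- preprocess(rec)
  segs <- segment_trials(pre, seed = 10)
  expect_length(segs, 10)

  # inject an artifact into segment 4 -> one fewer segment
  bad <- pre
  bad$samples[1, 4 * 2000 - 700] <- 5
  segs_bad <- segment_trials(bad, seed = 10)
  expect_length(segs_bad, 9)

  two <- synthetic_lfp(24, 500, 7, 9, 0.1, 0.2, seed = 11, n_channels = 2)
  pre2 <- preprocess(two)
  a <- segment_trials(pre2, seed = 12)
  b <- segment_trials(pre2, seed = 12)
  expect_identical(lapply(a, `[[`, "u"), lapply(b, `[[`, "u"))
})

test_that("pure sine reference is exact", {
  ps <- pure_sine(8, 1, 0, 1, 500)
  expect_length(ps$u, 500)
  expect_equal(ps$u[1], 0)
  # 8 full cycles in 1 s: unwrapped span = 2*pi*8*(n-1)/n
  span <- max(oscmem:::unwrap_phase(ps$theta)) - ps$theta[1]
  expect_equal(span, 2 * pi * 8 * 499 / 500, tolerance = 1e-10)
  ps0 <- pure_sine(8, 0, 0.7, 1, 500)
  expect_true(all(ps0$u == 0))
  expect_gt(diff(oscmem:::unwrap_phase(ps0$theta))[1], 0)
  psq <- pure_sine(8, 2, pi / 2, 1, 500)
  expect_equal(psq$u[1], 2)
})
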