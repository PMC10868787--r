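# Reference oscillations: synthetic theta-band LFP emulation and the
# preprocessing / instantaneous-phase pipeline used to turn multichannel
# recordings into per-trial reference signals.

#' Raw multichannel recording container
#'
#' A minimal container for a multichannel continuous recording (arbitrary
#' units), as produced by [synthetic_lfp()] or supplied by the user.
#'
#' @param samples numeric matrix, channels x samples
#' @param sample_rate sampling rate in Hz (> 0)
#' @return an object of class `raw_recording`
#' @export
raw_recording <- function(samples, sample_rate) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1)
  stopifnot(is.matrix(samples), sample_rate > 0)
  structure(list(samples = samples, sample_rate = sample_rate,
                 n_channels = nrow(samples)),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d channel(s), %d samples @ %g Hz (%.1f s)\n",
              x$n_channels, ncol(x$samples), x$sample_rate,
              ncol(x$samples) / x$sample_rate))
  invisible(x)
}

#' Reference oscillation with instantaneous phase track
#'
#' @param u normalized signal samples (dimensionless)
#' @param theta instantaneous phase per sample, radians in `[0, 2*pi)`
#' @param sample_rate Hz
#' @param dominant_freq dominant frequency in Hz
#' @param source one of `"synthetic"`, `"preprocessed"`, `"pure_sine"`
#' @return an object of class `reference_signal`
#' @export
reference_signal <- function(u, theta, sample_rate, dominant_freq,
                             source = c("synthetic", "preprocessed",
                                        "pure_sine")) {
  source <- match.arg(source)
  stopifnot(length(u) == length(theta), sample_rate > 0)
  structure(list(u = as.numeric(u), theta = wrap_2pi(as.numeric(theta)),
                 sample_rate = sample_rate, dominant_freq = dominant_freq,
                 source = source),
            class = "reference_signal")
}

#' @export
print.reference_signal <- function(x, ...) {
  cat(sprintf("<reference_signal> %s, %d samples @ %g Hz, f0 = %g Hz, RMS %.3f\n",
              x$source, length(x$u), x$sample_rate, x$dominant_freq,
              sqrt(mean(x$u^2))))
  invisible(x)
}

# Exact Ornstein-Uhlenbeck discretization, stationary initial condition.
ou_process <- function(n, dt, tau, sd) {
  if (sd <= 0 || n == 0) return(numeric(n))
  a <- exp(-dt / tau)
  innov <- rnorm(n, sd = sd * sqrt(1 - a^2))
  innov[1] <- rnorm(1, sd = sd)
  as.numeric(stats::filter(innov, a, method = "recursive"))
}

#' Generate a synthetic theta-like LFP recording
#'
#' Produces a narrowband stochastic oscillation emulating the statistics of
#' hippocampal theta-band field potentials: a sinusoidal carrier whose
#' amplitude (log-normal) and frequency both drift slowly under
#' Ornstein-Uhlenbeck modulation, plus broadband measurement noise. All
#' channels share the carrier phase (stored as attribute `true_phase` for
#' validation); amplitude drift and noise are channel-specific.
#'
#' @param duration_s recording duration in seconds
#' @param sample_rate sampling rate in Hz (default 500)
#' @param band_low_hz,band_high_hz frequency band of the carrier; the carrier
#'   centre frequency is the band midpoint
#' @param amp_drift_sd standard deviation of the log-amplitude drift
#' @param freq_drift_sd standard deviation of the frequency drift (Hz)
#' @param seed integer seed (required; generation is deterministic per seed)
#' @param n_channels number of channels
#' @param drift_tau_s drift correlation time in seconds; must be slow
#'   relative to the carrier period
#' @param noise_sd white measurement-noise SD relative to carrier RMS
#' @return a [raw_recording()] with attributes `true_phase` (radians) and
#'   `true_freq` (Hz) giving the hidden generator state
#' @export
synthetic_lfp <- function(duration_s, sample_rate = 500, band_low_hz = 7,
                          band_high_hz = 9, amp_drift_sd = 0.2,
                          freq_drift_sd = 0.3, seed, n_channels = 1,
                          drift_tau_s = 2, noise_sd = 0.1) {
  if (duration_s <= 0) stop("duration_s must be positive")
  if (!(band_low_hz > 0 && band_high_hz > band_low_hz &&
        band_high_hz < sample_rate / 2))
    stop("invalid band: need 0 < low < high < sample_rate/2")
  if (missing(seed)) stop("an integer seed is required")
  set.seed(seed)
  n <- round(duration_s * sample_rate)
  dt <- 1 / sample_rate
  f0 <- (band_low_hz + band_high_hz) / 2
  f_t <- f0 + ou_process(n, dt, drift_tau_s, freq_drift_sd)
  phase0 <- runif(1, 0, 2 * pi)
  theta <- phase0 + cumsum(2 * pi * f_t * dt)
  samples <- matrix(0, n_channels, n)
  for (ch in seq_len(n_channels)) {
    la <- ou_process(n, dt, drift_tau_s, amp_drift_sd)
    amp <- exp(la - amp_drift_sd^2 / 2)       # mean-one amplitude drift
    x <- amp * sin(theta)
    if (noise_sd > 0) x <- x + rnorm(n, sd = noise_sd / sqrt(2))
    samples[ch, ] <- x
  }
  rec <- raw_recording(samples, sample_rate)
  attr(rec, "true_phase") <- wrap_2pi(theta)
  attr(rec, "true_freq") <- f_t
  rec
}

# ---- FIR design (windowed sinc, Hamming) and helpers -----------------------

# Type-I linear-phase low-pass; cutoff in cycles/sample (0, 0.5).
fir_lowpass <- function(n_taps, cutoff) {
  stopifnot(n_taps %% 2 == 1, cutoff > 0, cutoff < 0.5)
  M <- (n_taps - 1) / 2
  k <- seq(-M, M)
  hd <- 2 * cutoff * ifelse(k == 0, 1, sin(2 * pi * cutoff * k) /
                              (2 * pi * cutoff * k))
  wnd <- 0.54 + 0.46 * cos(pi * k / M)   # Hamming
  h <- hd * wnd
  h / sum(h)                              # unity DC gain
}

# High-pass by spectral inversion of the low-pass.
fir_highpass <- function(n_taps, cutoff) {
  h <- -fir_lowpass(n_taps, cutoff)
  M <- (n_taps - 1) / 2
  h[M + 1] <- h[M + 1] + 1
  h
}

# Linear-phase FIR filtering with symmetric delay compensation
# (zero-phase-equivalent single pass; edges are zero-padded).
fir_filter <- function(x, taps) {
  n <- length(x)
  nt <- length(taps)
  if (n <= nt) stop("signal shorter than the filter: need length > ", nt)
  M <- (nt - 1) / 2
  L <- nextn(n + nt - 1, 2)
  y <- Re(fft(fft(c(x, numeric(L - n))) *
              fft(c(taps, numeric(L - nt))), inverse = TRUE)) / L
  y[(M + 1):(M + n)]
}

# Polyphase-style rational resampling by p/q with anti-alias FIR.
resample_poly <- function(x, p, q) {
  if (p == q) return(x)
  g <- gcd_int(p, q)
  p <- p / g; q <- q / g
  up <- numeric(length(x) * p)
  up[seq(1, length(up), by = p)] <- x * p
  mx <- max(p, q)
  taps <- fir_lowpass(2 * 10 * mx + 1, 0.5 / mx * 0.9)
  f <- fir_filter(up, taps)
  f[seq(1, length(f), by = q)]
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Preprocess a raw recording into normalized reference material
#'
#' Mirrors the preprocessing applied to the rat CA1 recordings feeding the
#' task: resample to `target_rate`, high-pass with a Hamming-window FIR
#' filter (linear phase, delay-compensated), then normalize channel-wise so
#' the root-mean-square of each channel equals that of a unit-amplitude sine
#' wave (1/sqrt(2)).
#'
#' @param raw a [raw_recording()]
#' @param target_rate output sampling rate in Hz (default 500)
#' @param highpass_hz high-pass cutoff in Hz (default 7)
#' @param n_taps FIR length, odd (default 511)
#' @return a `raw_recording` of normalized samples at `target_rate`, with
#'   attribute `normalized = TRUE`; generator attributes (`true_phase`) are
#'   carried over, resampled to the new rate
#' @export
preprocess <- function(raw, target_rate = 500, highpass_hz = 7,
                       n_taps = 511) {
  stopifnot(inherits(raw, "raw_recording"))
  if (ncol(raw$samples) <= n_taps)
    stop("recording shorter than the FIR filter (", n_taps, " taps)")
  rs_ratio <- target_rate / raw$sample_rate
  out <- NULL
  for (ch in seq_len(raw$n_channels)) {
    x <- raw$samples[ch, ]
    if (rs_ratio != 1) {
      frac <- rational_approx(rs_ratio)
      x <- resample_poly(x, frac[1], frac[2])
    }
    taps <- fir_highpass(n_taps, highpass_hz / target_rate)
    x <- fir_filter(x, taps)
    s <- sd(x)
    if (s > 1e-10) x <- x / (sqrt(2) * s)  # RMS 1/sqrt(2), unit-sine equiv

    if (is.null(out)) out <- matrix(0, raw$n_channels, length(x))
    out[ch, ] <- x
  }
  rec <- raw_recording(out, target_rate)
  attr(rec, "normalized") <- TRUE
  tp <- attr(raw, "true_phase")
  if (!is.null(tp)) {
    idx <- seq(1, length(tp), length.out = ncol(out))
    # unwrap, interpolate on the new grid, rewrap
    attr(rec, "true_phase") <- wrap_2pi(approx(seq_along(tp), unwrap_phase(tp),
                                               xout = idx)$y)
  }
  rec
}

rational_approx <- function(r, max_den = 64) {
  best <- c(1, 1); err <- Inf
  for (q in seq_len(max_den)) {
    p <- round(r * q)
    if (p < 1) next
    e <- abs(r - p / q)
    if (e < err - 1e-15) { err <- e; best <- c(p, q) }
  }
  if (err > 1e-9) stop("sample-rate ratio ", r, " is not close to rational")
  best
}

unwrap_phase <- function(th) {
  d <- diff(th)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(th[1], d))
}

#' Extract instantaneous phase with complex Morlet wavelets
#'
#' Convolves the signal with complex Morlet wavelets (Gaussian envelope with
#' SD `cycles / (2*pi*f)`) on a frequency grid, keeps the frequency with the
#' highest mean power over the retained window (one winner per chunk), and
#' returns its phase. Phase convention: `sin(theta)` reconstructs the
#' oscillatory component, matching the task targets.
#'
#' @param x numeric signal vector (normalized)
#' @param sample_rate Hz
#' @param freq_lo,freq_hi,freq_step frequency grid in Hz (default 7..9 by 0.2)
#' @param cycles Morlet width parameter c (default 7)
#' @param discard_s initial duration discarded to avoid filter/wavelet edge
#'   effects (default 1 s)
#' @return list with `theta` (radians, `[0, 2*pi)`, retained samples),
#'   `dominant_freq` (Hz), `offset` (number of discarded leading samples),
#'   and `power` (mean wavelet power per grid frequency)
#' @export
extract_phase <- function(x, sample_rate, freq_lo = 7, freq_hi = 9,
                          freq_step = 0.2, cycles = 7, discard_s = 1.0) {
  if (freq_step <= 0 || freq_hi < freq_lo) stop("empty frequency grid")
  freqs <- seq(freq_lo, freq_hi, by = freq_step)
  n <- length(x)
  off <- round(discard_s * sample_rate)
  if (off >= n) stop("signal shorter than discard_s")
  W <- morlet_transform(x, sample_rate, freqs, cycles)
  keep <- (off + 1):n
  pw <- colMeans(Mod(W[keep, , drop = FALSE])^2)
  j <- which.max(pw)
  theta <- wrap_2pi(Arg(W[keep, j]) + pi / 2)  # sin convention
  list(theta = theta, dominant_freq = freqs[j], offset = off,
       power = stats::setNames(pw, freqs))
}

# Complex Morlet wavelet transform; returns n x n_freq complex matrix.
morlet_transform <- function(x, sample_rate, freqs, cycles) {
  n <- length(x)
  # kernel support: +/- 4 SD of the widest wavelet
  sig_max <- cycles / (2 * pi * min(freqs))
  half <- ceiling(4 * sig_max * sample_rate)
  L <- nextn(n + 2 * half + 1, 2)
  fx <- fft(c(x, numeric(L - n)))
  out <- matrix(0i, n, length(freqs))
  tt <- seq(-half, half) / sample_rate
  for (j in seq_along(freqs)) {
    f <- freqs[j]
    sig <- cycles / (2 * pi * f)
    # correlation with psi = conv with psi(-s) conjugated; the Gaussian
    # envelope is even, so this is conv with the unconjugated wavelet
    w <- exp(2i * pi * f * tt) * exp(-tt^2 / (2 * sig^2))
    w <- w / sqrt(sum(Mod(w)^2))
    conv <- fft(fx * fft(c(w, numeric(L - length(w)))), inverse = TRUE) / L
    out[, j] <- conv[(half + 1):(half + n)]
  }
  out
}

#' Split a recording into per-trial reference segments
#'
#' Splits a normalized multichannel recording into non-overlapping chunks,
#' picks one uniformly random channel per chunk, rejects chunks whose maximum
#' absolute value exceeds `artifact_thresh`, and extracts the instantaneous
#' phase of each retained chunk with [extract_phase()].
#'
#' @param rec normalized [raw_recording()] (output of [preprocess()] or
#'   [synthetic_lfp()] followed by [preprocess()])
#' @param segment_s segment duration in seconds (default 4)
#' @param artifact_thresh artifact rejection threshold on `|u|` (default 4)
#' @param seed integer seed controlling the per-chunk channel choice
#' @param ... passed to [extract_phase()]
#' @return list of [reference_signal()] objects (possibly empty)
#' @export
segment_trials <- function(rec, segment_s = 4.0, artifact_thresh = 4.0,
                           seed, ...) {
  stopifnot(inherits(rec, "raw_recording"))
  if (missing(seed)) stop("an integer seed is required")
  set.seed(seed)
  fs <- rec$sample_rate
  seg_n <- round(segment_s * fs)
  n_seg <- floor(ncol(rec$samples) / seg_n)
  out <- list()
  for (s in seq_len(n_seg)) {
    ch <- sample.int(rec$n_channels, 1)
    idx <- ((s - 1) * seg_n + 1):(s * seg_n)
    u <- rec$samples[ch, idx]
    if (max(abs(u)) > artifact_thresh) next
    ph <- extract_phase(u, fs, ...)
    keep <- (ph$offset + 1):length(u)
    out[[length(out) + 1]] <-
      reference_signal(u[keep], ph$theta, fs, ph$dominant_freq,
                       source = "preprocessed")
  }
  out
}

#' Pure sinusoidal reference signal
#'
#' The idealized reference used for all reverse-engineering analyses:
#' `u = amplitude * sin(theta)` with `theta = phase0 + 2*pi*freq*t`.
#'
#' @param freq_hz frequency in Hz (must be below Nyquist)
#' @param amplitude sine amplitude (default 1)
#' @param phase0 initial phase in radians (default 0)
#' @param duration_s duration in seconds
#' @param sample_rate Hz (default 500)
#' @return a [reference_signal()] with an exact phase track
#' @export
pure_sine <- function(freq_hz, amplitude = 1, phase0 = 0, duration_s,
                      sample_rate = 500) {
  stopifnot(freq_hz < sample_rate / 2)
  n <- round(duration_s * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  theta <- phase0 + 2 * pi * freq_hz * t
  reference_signal(amplitude * sin(theta), theta, sample_rate, freq_hz,
                   source = "pure_sine")
}
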