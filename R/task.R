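# Phase-coding working-memory trials: a transient stimulus pulse must be
# remembered as the phase offset of the output oscillation relative to the
# reference. Targets are defined from stimulus offset onward only.

#' Task configuration
#'
#' Defaults follow the two-stimulus task: trials of 0.8 s, stimulus onset
#' uniform in `[0.125, 0.25]` s, duration uniform in `[0.125, 0.175]` s,
#' rectangular pulses of amplitude 1, and target phase offsets of `0.2*pi`
#' (stimulus a, "in-phase") and `1.2*pi` (stimulus b, "anti-phase"). The
#' target on the masked region is `sin(theta - phase_offsets[stim_id])`.
#'
#' @param T_trial trial duration in seconds
#' @param onset_range stimulus onset window, seconds
#' @param dur_range stimulus duration window, seconds
#' @param amplitude stimulus pulse amplitude
#' @param phase_offsets target phase offsets phi0 in radians; the target is
#'   `sin(theta - phi0)` (one offset per stimulus)
#' @param h integration step in ms; the reference sample rate must equal
#'   `1000/h`
#' @return an object of class `task_config`
#' @export
task_config <- function(T_trial = 0.8, onset_range = c(0.125, 0.25),
                        dur_range = c(0.125, 0.175), amplitude = 1,
                        phase_offsets = c(0.2, 1.2) * pi, h = 2) {
  stopifnot(onset_range[2] + dur_range[2] < T_trial,
            length(phase_offsets) >= 1)
  d <- outer(phase_offsets, phase_offsets, circ_diff)
  if (any(abs(d[upper.tri(d)]) < 1e-9))
    stop("phase offsets must be distinct mod 2*pi")
  structure(list(T_trial = T_trial, onset_range = onset_range,
                 dur_range = dur_range, amplitude = amplitude,
                 phase_offsets = phase_offsets, h = h),
            class = "task_config")
}

#' Four-stimulus task configuration
#'
#' The extended task storing one of four stimuli with target offsets
#' `-0.2*pi, -0.7*pi, -1.4*pi, -1.7*pi` relative to the reference, i.e.
#' `phase_offsets = c(0.2, 0.7, 1.4, 1.7)*pi` in the `sin(theta - phi0)`
#' convention.
#'
#' @param ... overrides passed to [task_config()]
#' @return a `task_config` with four phase offsets
#' @export
task_config_multi <- function(...) {
  task_config(phase_offsets = c(0.2, 0.7, 1.4, 1.7) * pi, ...)
}

#' Build one task trial from a reference signal
#'
#' Slices a trial-length window from the reference (random offset when the
#' reference is longer than a trial, giving a random initial phase), draws
#' stimulus onset and duration, and assembles the input matrix (reference
#' channel plus one rectangular-pulse channel per stimulus), the target
#' `sin(theta - phi0)` and the loss mask (true from stimulus offset on).
#'
#' @param ref a [reference_signal()] at sample rate `1000/cfg$h`
#' @param stim_id which stimulus is shown, 1-based
#' @param cfg a [task_config()]
#' @param seed integer seed for onset/duration/window draws
#' @return an object of class `wm_trial` with elements `u`, `theta`,
#'   `inputs` (T x C matrix, reference first), `target`, `mask`,
#'   `t_on`/`t_off` (ms), `stim_id`, `h`
#' @export
make_trial <- function(ref, stim_id, cfg = task_config(), seed = NULL) {
  stopifnot(inherits(ref, "reference_signal"))
  fs <- 1000 / cfg$h
  if (abs(ref$sample_rate - fs) > 1e-9)
    stop("reference sample rate ", ref$sample_rate,
         " does not match the integration grid 1000/h = ", fs)
  n_stim <- length(cfg$phase_offsets)
  if (stim_id < 1 || stim_id > n_stim) stop("stim_id out of range")
  if (!is.null(seed)) set.seed(seed)
  T_n <- round(cfg$T_trial * fs)
  if (length(ref$u) < T_n) stop("reference shorter than one trial")
  start <- if (length(ref$u) > T_n)
    sample.int(length(ref$u) - T_n + 1, 1) else 1L
  idx <- start:(start + T_n - 1)
  u <- ref$u[idx]; theta <- ref$theta[idx]
  onset <- runif(1, cfg$onset_range[1], cfg$onset_range[2])
  dur <- runif(1, cfg$dur_range[1], cfg$dur_range[2])
  k_on <- floor(onset * fs) + 1          # grid-aligned (rounded down)
  k_off <- floor((onset + dur) * fs) + 1
  stim <- matrix(0, T_n, n_stim)
  stim[k_on:(k_off - 1), stim_id] <- cfg$amplitude
  mask <- seq_len(T_n) >= k_off
  target <- sin(theta - cfg$phase_offsets[stim_id])
  target[!mask] <- 0
  structure(list(u = u, theta = theta,
                 inputs = cbind(ref = u, stim),
                 target = target, mask = mask,
                 t_on = (k_on - 1) * cfg$h, t_off = (k_off - 1) * cfg$h,
                 stim_id = stim_id, h = cfg$h,
                 phase_offset = cfg$phase_offsets[stim_id]),
            class = "wm_trial")
}

#' @rdname make_trial
#' @param cfg4 a four-offset [task_config_multi()]
#' @export
make_trial_multi <- function(ref, stim_id, cfg4 = task_config_multi(),
                             seed = NULL) {
  stopifnot(length(cfg4$phase_offsets) == 4)
  make_trial(ref, stim_id, cfg4, seed)
}

#' Split reference segments into training and validation sets
#'
#' @param segments list of reference segments (or any list)
#' @param frac_train fraction assigned to training (default 0.9)
#' @param seed integer seed for the shuffle
#' @return list with elements `train` and `validation`; disjoint and
#'   exhaustive
#' @export
split_segments <- function(segments, frac_train = 0.9, seed) {
  stopifnot(length(segments) >= 2)
  if (missing(seed)) stop("an integer seed is required")
  set.seed(seed)
  n <- length(segments)
  n_train <- round(frac_train * n)
  perm <- sample.int(n)
  list(train = segments[perm[seq_len(n_train)]],
       validation = segments[perm[(n_train + 1):n]])
}

# Stack a list of equal-length trials into the cube layout the C++ batch
# kernels expect: inputs C x B x T, target/mask T x B.
stack_trials <- function(trials) {
  T_n <- length(trials[[1]]$target)
  C <- ncol(trials[[1]]$inputs)
  B <- length(trials)
  inputs <- array(0, c(C, B, T_n))
  target <- matrix(0, T_n, B)
  mask <- matrix(0, T_n, B)
  for (b in seq_len(B)) {
    tr <- trials[[b]]
    stopifnot(length(tr$target) == T_n, ncol(tr$inputs) == C)
    inputs[, b, ] <- t(tr$inputs)
    target[, b] <- tr$target
    mask[, b] <- as.numeric(tr$mask)
  }
  list(inputs = inputs, target = target, mask = mask)
}
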