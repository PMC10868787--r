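# Mixture-of-Gaussians connectivity and the mean-field (infinite-N) theory.
# When per-unit weights are drawn from a mixture of L zero-mean Gaussians,
# the kappa dynamics close on themselves:
#   tau dk_i/dt = -k_i + sum_l w_l (k1 s_m1n_i + k2 s_m2n_i + v s_In_i) G_l
# with gain G_l = E[tanh'(Delta_l z)] ~= 1/sqrt(1 + (pi/2) Delta_l^2).

#' Analytic population gain
#'
#' Closed-form approximation of the average slope `E_z[tanh'(Delta z)]`,
#' `z ~ N(0,1)`, obtained by substituting `erf(sqrt(pi)/2 x)` for `tanh(x)`:
#' `gain = 1/sqrt(1 + (pi/2) delta_sq)`. Decreases from 1 (at 0) toward 0 as
#' the population saturates.
#'
#' @param delta_sq squared saturation argument `Delta^2` (>= 0)
#' @return gain in (0, 1]
#' @export
mf_gain <- function(delta_sq) {
  if (any(delta_sq < 0)) stop("delta_sq must be nonnegative")
  1 / sqrt(1 + (pi / 2) * delta_sq)
}

#' Gaussian-mixture connectivity description
#'
#' Describes network connectivity as `L` subpopulations; units in
#' population `l` (proportion `weights[l]`) draw their joint weight vector
#' (input weights, n-vectors, m-vectors, readout) from a zero-mean Gaussian
#' with covariance `covs[[l]]`.
#'
#' @param weights population proportions (positive, sum 1)
#' @param covs list of per-population covariance matrices over the joint
#'   vector `(inputs..., n_1..n_R, m_1..m_R, w)`, with dimnames
#' @param channels data.frame with columns `name`, `kind` (`"osc"` or
#'   `"stim"`) and optionally `phase` (radians), one row per input channel
#' @param rank connectivity rank R
#' @param tau time constant, ms
#' @param readout_mode `"linear"` or `"tanh"`
#' @param labels optional population labels
#' @return object of class `mixture_connectivity`
#' @export
mixture_connectivity <- function(weights, covs, channels, rank = 2,
                                 tau = 20,
                                 readout_mode = c("linear", "tanh"),
                                 labels = NULL) {
  readout_mode <- match.arg(readout_mode)
  stopifnot(abs(sum(weights) - 1) < 1e-8, all(weights > 0),
            length(covs) == length(weights))
  C <- nrow(channels)
  V <- C + 2 * rank + 1
  vars <- c(channels$name, paste0("n", seq_len(rank)),
            paste0("m", seq_len(rank)), "w")
  for (l in seq_along(covs)) {
    S <- covs[[l]]
    stopifnot(nrow(S) == V, ncol(S) == V)
    ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      stop("covariance of component ", l, " is not positive semidefinite")
    dimnames(covs[[l]]) <- list(vars, vars)
  }
  if (is.null(channels$phase)) channels$phase <- 0
  structure(list(weights = weights, covs = covs, channels = channels,
                 rank = rank, tau = tau, readout_mode = readout_mode,
                 labels = labels %||% paste0("p", seq_along(weights)),
                 vars = vars),
            class = "mixture_connectivity")
}

#' @export
print.mixture_connectivity <- function(x, ...) {
  cat(sprintf("<mixture_connectivity> rank %d, %d population(s) [%s], %d channel(s)\n",
              x$rank, length(x$weights),
              paste(sprintf("%s:%.2f", x$labels, x$weights), collapse = ", "),
              nrow(x$channels)))
  invisible(x)
}

# index helpers into the joint variable vector
mix_idx <- function(mix) {
  C <- nrow(mix$channels); R <- mix$rank
  list(I = seq_len(C), n = C + seq_len(R), m = C + R + seq_len(R),
       w = C + 2 * R + 1)
}

# cubes consumed by cpp_mf_flow
mix_cubes <- function(mix) {
  ix <- mix_idx(mix)
  L <- length(mix$weights); R <- mix$rank; C <- nrow(mix$channels)
  Smn <- array(0, c(R, R, L)); Sin <- array(0, c(C, R, L))
  var_m <- matrix(0, R, L); var_I <- matrix(0, C, L)
  for (l in seq_len(L)) {
    S <- mix$covs[[l]]
    Smn[, , l] <- S[ix$m, ix$n, drop = FALSE]        # [j,i] = cov(m_j, n_i)
    Sin[, , l] <- S[ix$I, ix$n, drop = FALSE]
    var_m[, l] <- diag(S)[ix$m]
    var_I[, l] <- diag(S)[ix$I]
  }
  list(Smn = Smn, Sin = Sin, var_m = var_m, var_I = var_I)
}

#' Mean-field right-hand side with per-population decomposition
#'
#' Reference implementation of the mean-field equations: returns
#' `tau * dkappa/dt` contributions per population (their sum plus `-kappa`
#' is the total drift), together with the per-population gains. Useful for
#' verifying that the total phase velocity is the weighted sum of
#' per-population phase velocities.
#'
#' @param mix a [mixture_connectivity()]
#' @param kappa state vector (length = rank)
#' @param v filtered input values per channel (length = channels)
#' @return list with `dkappa` (dkappa/dt, per ms), `per_pop`
#'   (rank x L matrix of population drive contributions), `gains`
#' @export
meanfield_rhs <- function(mix, kappa, v) {
  cb <- mix_cubes(mix)
  L <- length(mix$weights); R <- mix$rank
  per <- matrix(0, R, L); gains <- numeric(L)
  C <- nrow(mix$channels)
  for (l in seq_len(L)) {
    d2 <- sum(cb$var_m[, l] * kappa^2) + sum(cb$var_I[, l] * v^2)
    G <- mf_gain(d2)
    gains[l] <- G
    Smn_l <- matrix(cb$Smn[, , l], R, R)     # [j, i] = cov(m_j, n_i)
    Sin_l <- matrix(cb$Sin[, , l], C, R)
    lin <- as.numeric(crossprod(Smn_l, kappa)) +
      as.numeric(crossprod(Sin_l, v))
    per[, l] <- mix$weights[l] * G * lin
  }
  list(dkappa = (-kappa + rowSums(per)) / mix$tau, per_pop = per,
       gains = gains)
}

#' Mean-field flow field (driven)
#'
#' Packages a mixture with a reference drive into a field object on which
#' the same Poincare machinery as for network fields operates
#' ([find_fixed_points()], [floquet_multipliers()], ...). The Jacobian for
#' the variational equation is analytic.
#'
#' @param mix a [mixture_connectivity()]
#' @param A reference amplitude (applied to all oscillatory channels)
#' @param freq_hz reference frequency, Hz
#' @param stim tonic values for the stimulus channels (default 0)
#' @param h default step, ms
#' @return object of class `mf_field`
#' @export
mf_field <- function(mix, A = 1, freq_hz = 8, stim = NULL, h = 0.5) {
  kinds <- mix$channels$kind
  n_stim <- sum(kinds == "stim")
  stim <- stim %||% numeric(n_stim)
  stopifnot(length(stim) == n_stim)
  ch_kind <- ifelse(kinds == "osc", 0L, 1L)
  ch_amp <- numeric(length(kinds))
  ch_amp[kinds == "osc"] <- A
  ch_amp[kinds == "stim"] <- stim
  cb <- mix_cubes(mix)
  structure(c(cb, list(mix = mix, ch_kind = ch_kind, ch_amp = ch_amp,
                       ch_phase = mix$channels$phase, A = A,
                       freq_hz = freq_hz, omega = hz_to_radms(freq_hz),
                       tau = mix$tau, stim = stim, h = h,
                       rank = mix$rank)),
            class = "mf_field")
}

mf_flow <- function(field, kappa, theta0 = 0, n_periods = 1, h = NULL,
                    method = c("rk4", "euler"), monodromy = FALSE,
                    traj_stride = 0L) {
  method <- match.arg(method)
  ps <- period_steps(field, h)
  kappa <- as.matrix(kappa)
  if (nrow(kappa) != field$rank) kappa <- t(kappa)
  cpp_mf_flow(field$rank, field$mix$weights, field$Smn, field$Sin,
              field$var_m, field$var_I, field$ch_kind, field$ch_amp,
              field$ch_phase, field$omega, field$tau, kappa, theta0, ps$h,
              as.integer(round(ps$n * n_periods)),
              if (method == "euler") 0L else 1L, monodromy,
              as.integer(traj_stride))
}

mf_map <- function(field, kappa, n_periods = 1, h = NULL, method = "rk4") {
  vecin <- is.null(dim(kappa))
  out <- mf_flow(field, kappa, 0, n_periods, h, method)
  k <- out$kappa
  if (vecin) k <- drop(k)
  attr(k, "winding") <- out$winding
  k
}

mf_jacobian <- function(field, kappa, n_periods = 1, h = NULL) {
  out <- mf_flow(field, matrix(kappa, field$rank), 0, n_periods, h,
                 monodromy = TRUE)
  list(P = drop(out$kappa), M = out$M[, , 1], winding = out$winding[1])
}

#' Sample a finite network from a mixture
#'
#' Unit `j`'s joint weight vector is drawn from the Gaussian of its
#' population; population sizes are deterministic blocks of
#' `round(weights * N)` units (exact reproducibility; no multinomial
#' scatter).
#'
#' @param mix a [mixture_connectivity()]
#' @param N number of units (`N * min(weights)` must be at least 10)
#' @param seed integer seed
#' @return a `lowrank_rnn` with population labels in attribute
#'   `population`
#' @export
sample_network <- function(mix, N, seed) {
  if (missing(seed)) stop("an integer seed is required")
  if (N * min(mix$weights) < 10)
    stop("N too small for the smallest mixture component")
  set.seed(seed)
  ix <- mix_idx(mix)
  sizes <- floor(mix$weights * N)
  rem <- N - sum(sizes)
  if (rem > 0) {
    o <- order(mix$weights * N - sizes, decreasing = TRUE)
    sizes[o[seq_len(rem)]] <- sizes[o[seq_len(rem)]] + 1
  }
  V <- length(mix$vars)
  Y <- matrix(0, N, V)
  pop <- integer(N)
  at <- 0
  for (l in seq_along(sizes)) {
    if (sizes[l] == 0) next
    S <- mix$covs[[l]]
    ch <- chol(S + diag(1e-10, V))
    rows <- at + seq_len(sizes[l])
    Y[rows, ] <- matrix(rnorm(sizes[l] * V), sizes[l], V) %*% ch
    pop[rows] <- l
    at <- at + sizes[l]
  }
  rnn <- structure(list(N = N, rank = mix$rank,
                        m = Y[, ix$m, drop = FALSE],
                        n = Y[, ix$n, drop = FALSE], J = NULL,
                        I = Y[, ix$I, drop = FALSE],
                        channels = mix$channels, w = Y[, ix$w],
                        readout_scale = 1, readout_mode = mix$readout_mode,
                        tau = mix$tau, sigma_noise = 0),
                   class = "lowrank_rnn")
  attr(rnn, "population") <- pop
  rnn
}

#' Mean-field readout
#'
#' Infinite-N readout `E[w x]/1` (linear) or `E[w tanh(x)]` (tanh; by
#' Gaussian integration by parts the population covariance is multiplied by
#' the gain).
#'
#' @param mix a [mixture_connectivity()]
#' @param kappa state (length rank)
#' @param v filtered input values per channel
#' @return scalar readout
#' @export
mf_readout <- function(mix, kappa, v) {
  ix <- mix_idx(mix)
  out <- 0
  cb <- mix_cubes(mix)
  for (l in seq_along(mix$weights)) {
    S <- mix$covs[[l]]
    lin <- sum(S[ix$w, ix$m] * kappa) + sum(S[ix$w, ix$I] * v)
    if (mix$readout_mode == "tanh") {
      d2 <- sum(cb$var_m[, l] * kappa^2) + sum(cb$var_I[, l] * v^2)
      lin <- lin * mf_gain(d2)
    }
    out <- out + mix$weights[l] * lin
  }
  out
}

# filtered channel values at phase theta (steady state)
mf_v_at <- function(field, theta) {
  fg <- 1 / sqrt((field$omega * field$tau)^2 + 1)
  lag <- atan(field$omega * field$tau)
  ifelse(field$ch_kind == 0,
         field$ch_amp * fg * sin(theta + field$ch_phase - lag),
         field$ch_amp)
}

#' Mean-field coupling function on the (theta, phi) grid
#'
#' Noise-free analogue of [extract_coupling()] for a rank-2 mixture:
#' evaluates the mean-field phase velocity on the circle of radius `r` and
#' returns `g = dphi/dt - omega` as a `coupling_grid`, directly comparable
#' with (and usable by) the phase-model machinery.
#'
#' @param mix rank-2 [mixture_connectivity()]
#' @param A,freq_hz reference drive
#' @param stim tonic stimulus values
#' @param n_grid grid resolution
#' @param r kappa radius (default: radius of the stable cycles found by
#'   forward iteration)
#' @return a `coupling_grid`
#' @export
mf_coupling <- function(mix, A = 1, freq_hz = 8, stim = NULL, n_grid = 64,
                        r = NULL) {
  stopifnot(mix$rank == 2)
  field <- mf_field(mix, A, freq_hz, stim)
  if (is.null(r)) {
    f0 <- mf_field(mix, A, freq_hz)
    ang <- seq(0, 2 * pi, length.out = 9)[-9]
    out <- mf_flow(f0, rbind(cos(ang), sin(ang)), 0, 60)
    r <- mean(sqrt(colSums(out$kappa^2)))
  }
  th <- seq(0, 2 * pi, length.out = n_grid + 1)[-(n_grid + 1)]
  g <- matrix(0, n_grid, n_grid)
  for (i in seq_len(n_grid)) {
    v <- mf_v_at(field, th[i])
    for (j in seq_len(n_grid)) {
      kap <- r * c(cos(th[j]), sin(th[j]))
      dk <- meanfield_rhs(mix, kap, v)$dkappa
      g[i, j] <- (kap[1] * dk[2] - kap[2] * dk[1]) / r^2 - field$omega
    }
  }
  structure(list(theta_grid = th, phi_grid = th, g = g,
                 omega = field$omega, r = r, stim = field$stim, A = A,
                 freq_hz = freq_hz, tau = mix$tau),
            class = "coupling_grid")
}

#' Zeros of the autonomous 1-D mean-field flow
#'
#' For rank-1 mixtures: evaluates `dkappa/dt` with all inputs off on a
#' kappa grid, locates zeros by sign change + bisection, and classifies
#' their stability by the local slope.
#'
#' @param mix rank-1 [mixture_connectivity()]
#' @param kappa_max grid half-width (default 3)
#' @param n_grid grid points
#' @return data.frame with `kappa`, `stable`
#' @export
mf_zeros_1d <- function(mix, kappa_max = 3, n_grid = 601) {
  stopifnot(mix$rank == 1)
  v0 <- numeric(nrow(mix$channels))
  f <- function(k) meanfield_rhs(mix, k, v0)$dkappa
  ks <- seq(-kappa_max, kappa_max, length.out = n_grid)
  fs <- vapply(ks, f, 0)
  zeros <- list()
  for (i in seq_len(n_grid - 1)) {
    if (fs[i] == 0 || fs[i] * fs[i + 1] < 0) {
      root <- stats::uniroot(f, c(ks[i], ks[i + 1]), tol = 1e-10)$root
      slope <- (f(root + 1e-5) - f(root - 1e-5)) / 2e-5
      zeros[[length(zeros) + 1]] <- data.frame(kappa = root,
                                               stable = slope < 0)
    }
  }
  out <- do.call(rbind, zeros)
  out[!duplicated(round(out$kappa, 6)), ]
}

# ---------------------------------------------------------------------------
# Designed presets. Magnitudes below were tuned numerically (see the
# methods vignette) under the sign/zero patterns of the three-population
# construction: one autonomously oscillating population unconnected to the
# input, plus coupling populations whose input covariances implement the
# coupling function and whose stimulus variances implement saturation.
# ---------------------------------------------------------------------------

empty_cov <- function(vars) {
  S <- matrix(0, length(vars), length(vars), dimnames = list(vars, vars))
  S
}

set_sym <- function(S, a, b, val) { S[a, b] <- S[b, a] <- val; S }

# oscillator population: skew overlap -> rigid rotation at +eta*G, radial
# fixed point where J0 * G(sigma_m^2 r^2) balances the leak.
osc_cov <- function(vars, J0, eta, var_m = 1, var_n) {
  S <- empty_cov(vars)
  diag(S) <- 0
  S["m1", "m1"] <- S["m2", "m2"] <- var_m
  S["n1", "n1"] <- S["n2", "n2"] <- var_n
  S["w", "w"] <- 16
  S <- set_sym(S, "m1", "n1", J0)
  S <- set_sym(S, "m2", "n2", J0)
  S <- set_sym(S, "m1", "n2", eta)
  S <- set_sym(S, "m2", "n1", -eta)
  S
}

#' Designed two-stimulus mixture (3 populations)
#'
#' One oscillator population (unconnected to the input; skew-symmetric
#' m-n overlaps generate rotation at the reference frequency) and two
#' coupling populations whose `cos(2*phi)`-type overlaps lock the internal
#' phase to the reference at two stable phase differences ~pi apart. Each
#' coupling population carries a large variance on one stimulus channel, so
#' a tonic stimulus saturates it (gain -> 0) and the surviving population's
#' input-phase term steers the network to the corresponding cycle.
#'
#' @param freq_hz target autonomous/reference frequency (default 8)
#' @param tau time constant, ms
#' @param eta_scale oscillator detuning factor compensating the
#'   rotation-rate reduction caused by the strong `cos(2*phi)` coupling
#'   (the mean angular velocity of `a + b*cos(2*phi)` modulated rotation is
#'   `sqrt(a^2-b^2)`, not `a`); tuned numerically for 1:1 locking at the
#'   reference frequency
#' @param readout_rho covariances `cov(w, m1)`, `cov(w, m2)` of the
#'   oscillator population, fixing the output phase of the two memory
#'   cycles (tuned so the cycle selected by stimulus a reads out at
#'   `sin(theta - 0.2*pi)` with unit amplitude)
#' @return a [mixture_connectivity()] with populations
#'   `oscillator`, `coupling_a`, `coupling_b`
#' @export
design_two_stim <- function(freq_hz = 8, tau = 20, eta_scale = 1.25,
                            readout_rho = c(-0.1843, 1.4215)) {
  wts <- c(0.5, 0.25, 0.25)
  omega_tau <- hz_to_radms(freq_hz) * tau
  channels <- data.frame(name = c("osc", "stim_a", "stim_b"),
                         kind = c("osc", "stim", "stim"),
                         phase = 0, stringsAsFactors = FALSE)
  vars <- c(channels$name, "n1", "n2", "m1", "m2", "w")
  # oscillator: radius ~1 (G(r=1) = 0.624); J0 balances leak, eta sets omega
  G1 <- mf_gain(1)
  J0 <- 1 / (wts[1] * G1)
  eta <- eta_scale * omega_tau / (wts[1] * G1)
  p1 <- osc_cov(vars, J0, eta, var_m = 1, var_n = 45)
  p1 <- set_sym(p1, "w", "m1", readout_rho[1])
  p1 <- set_sym(p1, "w", "m2", readout_rho[2])
  # coupling populations: cos(2 phi) overlaps + input-phase terms
  cpl <- function(stim_name, sgn) {
    S <- empty_cov(vars)
    S["m1", "m1"] <- S["m2", "m2"] <- 1
    S["n1", "n1"] <- S["n2", "n2"] <- 30
    S["osc", "osc"] <- 4
    S[stim_name, stim_name] <- 64
    S["w", "w"] <- 16
    S <- set_sym(S, "m1", "n2", 3)     # cos(2 phi) pattern
    S <- set_sym(S, "m2", "n1", 3)
    S <- set_sym(S, "osc", "n1", sgn * 4)
    S <- set_sym(S, "osc", "n2", -sgn * 4)
    S
  }
  mixture_connectivity(wts, list(p1, cpl("stim_a", 1), cpl("stim_b", -1)),
                       channels, rank = 2, tau = tau,
                       labels = c("oscillator", "coupling_a", "coupling_b"))
}

#' Designed four-stimulus mixture (5 populations)
#'
#' Extends [design_two_stim()] to four memories: one oscillator population
#' plus four coupling populations arranged in two anisotropy classes whose
#' gains saturate at opposite internal phases. Their `cos(2*phi)` overlap
#' terms cancel pairwise while the gain anisotropy converts the residual
#' into a `cos(4*phi)`-type coupling with four stable locked phases. Each
#' stimulus carries large variance into all coupling populations except
#' one, so a tonic stimulus leaves a single population active, whose
#' input-phase term selects a unique cycle.
#'
#' @param freq_hz target frequency (default 8)
#' @param tau time constant, ms
#' @param eta_scale relative detuning of the oscillator population,
#'   compensating the mean drift contributed by the coupling populations;
#'   tuned numerically to the centre of the four-attractor locking window
#' @return a [mixture_connectivity()] with 5 populations
#' @export
design_four_stim <- function(freq_hz = 8, tau = 20, eta_scale = 1.17) {
  wts <- c(0.4, 0.15, 0.15, 0.15, 0.15)
  omega_tau <- hz_to_radms(freq_hz) * tau
  channels <- data.frame(name = c("osc", paste0("stim_", letters[1:4])),
                         kind = c("osc", rep("stim", 4)),
                         phase = 0, stringsAsFactors = FALSE)
  vars <- c(channels$name, "n1", "n2", "m1", "m2", "w")
  G1 <- mf_gain(1)
  J0 <- 1 / (wts[1] * G1)
  eta <- eta_scale * omega_tau / (wts[1] * G1)
  p1 <- osc_cov(vars, J0, eta, var_m = 1,
                var_n = (J0^2 + eta^2) * 1.15)
  # coupling population k: gain anisotropy class X (m1-heavy) or Y
  # (m2-heavy); the classes saturate at internal phases a quarter period
  # apart, and their cos(2 phi) overlaps carry opposite signs, so the
  # leading 2-phi coupling cancels and the gain anisotropy converts the
  # residual into cos(4 phi). gamma rotates the input-phase term; stimulus
  # k is the only one *not* feeding this population.
  vb <- 3.2; vs <- 0.3; c4 <- 5; beta <- 5; sI <- 2.4
  cpl <- function(k, class_x, gamma, csgn) {
    S <- empty_cov(vars)
    vm <- if (class_x) c(vb, vs) else c(vs, vb)
    S["m1", "m1"] <- vm[1]; S["m2", "m2"] <- vm[2]
    S["n1", "n1"] <- S["n2", "n2"] <-
      (c4^2 / min(vm) + 2 * beta^2 / sI^2) * 1.15
    S["osc", "osc"] <- sI^2
    for (j in 1:4) if (j != k)
      S[paste0("stim_", letters[j]), paste0("stim_", letters[j])] <- 64
    S["w", "w"] <- 16
    S <- set_sym(S, "m1", "n2", csgn * c4)
    S <- set_sym(S, "m2", "n1", csgn * c4)
    S <- set_sym(S, "osc", "n1", beta * cos(gamma))
    S <- set_sym(S, "osc", "n2", beta * sin(gamma))
    S
  }
  covs <- list(p1,
               cpl(1, TRUE, 0, +1),
               cpl(2, FALSE, pi / 2, -1),
               cpl(3, TRUE, pi, +1),
               cpl(4, FALSE, 3 * pi / 2, -1))
  mixture_connectivity(wts, covs, channels, rank = 2, tau = tau,
                       labels = c("oscillator", paste0("coupling_", letters[1:4])))
}

#' Designed rank-1 rate-coding mixture (2 populations)
#'
#' The alternative, rate-coding solution: a 1-D mean-field flow with three
#' stable zeros (0 and +/- kappa*). Population 1 (negative m-n coupling,
#' large m-variance) creates the stable zero at 0 and transmits the
#' reference in phase (positive `cov(I_osc, w)`); it saturates away from 0.
#' Population 2 (positive coupling, small m-variance) creates the outer
#' zeros and an anti-phase output. Stimulus a saturates population 2
#' (steering kappa to 0), stimulus b saturates population 1 (steering to
#' +/- kappa*). The readout is of rates (tanh), so a saturated population
#' drops out of the output.
#'
#' @param tau time constant, ms
#' @return a rank-1 [mixture_connectivity()] with `tanh` readout
#' @export
design_rate_coding_rank1 <- function(tau = 20) {
  channels <- data.frame(name = c("osc", "stim_a", "stim_b"),
                         kind = c("osc", "stim", "stim"),
                         phase = 0, stringsAsFactors = FALSE)
  vars <- c(channels$name, "n1", "m1", "w")
  p1 <- empty_cov(vars)                       # in-phase / zero-at-0 pop
  p1["osc", "osc"] <- 0.25
  p1["stim_b", "stim_b"] <- 64
  p1["n1", "n1"] <- 16; p1["m1", "m1"] <- 16; p1["w", "w"] <- 16
  p1 <- set_sym(p1, "m1", "n1", -3)
  p1 <- set_sym(p1, "osc", "w", 1.8)
  p2 <- empty_cov(vars)                       # anti-phase / outer zeros
  p2["osc", "osc"] <- 0.25
  p2["stim_a", "stim_a"] <- 64
  p2["n1", "n1"] <- 64; p2["m1", "m1"] <- 0.25; p2["w", "w"] <- 16
  p2 <- set_sym(p2, "m1", "n1", 3.8)
  p2 <- set_sym(p2, "osc", "w", -0.9)
  mixture_connectivity(c(0.5, 0.5), list(p1, p2), channels, rank = 1,
                       tau = tau, readout_mode = "tanh",
                       labels = c("inphase", "antiphase"))
}

#' Designed phase-precession mixture (continuous input)
#'
#' The reference enters through two channels (`sin(theta)`, `cos(theta)`);
#' a continuous position `s` in `[0, 1)` enters as
#' `(sin(s*pi/2), cos(s*pi/2))`. Two coupling populations implement
#' sin- and cos-type coupling functions; the position input saturates them
#' complementarily, so the effective coupling function — and with it the
#' locked phase difference — translates continuously (by a quarter period
#' from `s = 0` to `s = 1`).
#'
#' @param freq_hz target frequency (default 8)
#' @param tau time constant, ms
#' @return a [mixture_connectivity()]; build driven fields with
#'   [precession_field()]
#' @export
design_phase_precession <- function(freq_hz = 8, tau = 20) {
  wts <- c(0.5, 0.25, 0.25)
  omega_tau <- hz_to_radms(freq_hz) * tau
  channels <- data.frame(name = c("osc_a", "osc_b", "pos_a", "pos_b"),
                         kind = c("osc", "osc", "stim", "stim"),
                         phase = c(0, pi / 2, 0, 0),
                         stringsAsFactors = FALSE)
  vars <- c(channels$name, "n1", "n2", "m1", "m2", "w")
  G1 <- mf_gain(1)
  p1 <- osc_cov(vars, 1 / (wts[1] * G1), omega_tau / (wts[1] * G1),
                var_m = 1, var_n = 30)
  cpl <- function(sin_type) {
    S <- empty_cov(vars)
    S["m1", "m1"] <- S["m2", "m2"] <- 1
    S["n1", "n1"] <- S["n2", "n2"] <- 30
    S["osc_a", "osc_a"] <- S["osc_b", "osc_b"] <- 1
    S["w", "w"] <- 16
    if (sin_type) {
      # g ~ sin(theta - phi): cov(osc_a, n2) = q, cov(osc_b, n1) = q
      S <- set_sym(S, "osc_a", "n2", 3)
      S <- set_sym(S, "osc_b", "n1", 3)
      S["pos_b", "pos_b"] <- 100    # strongly suppressed near s = 0
    } else {
      # g ~ cos(theta - phi): cov(osc_b, n2) = q, cov(osc_a, n1) = -q
      S <- set_sym(S, "osc_b", "n2", 3)
      S <- set_sym(S, "osc_a", "n1", -3)
      S["pos_a", "pos_a"] <- 100    # strongly suppressed near s = 1
    }
    S
  }
  mixture_connectivity(wts, list(p1, cpl(TRUE), cpl(FALSE)), channels,
                       rank = 2, tau = tau,
                       labels = c("oscillator", "coupling_sin",
                                  "coupling_cos"))
}

#' Driven field for the phase-precession mixture at position s
#'
#' @param mix output of [design_phase_precession()]
#' @param s position in `[0, 1)`
#' @param A reference amplitude
#' @param freq_hz reference frequency
#' @param h step, ms
#' @return an `mf_field` with position encoded as
#'   `(sin(s*pi/2), cos(s*pi/2))` on the tonic channels
#' @export
precession_field <- function(mix, s, A = 1, freq_hz = 8, h = 0.5) {
  mf_field(mix, A, freq_hz, stim = c(sin(pi * s / 2), cos(pi * s / 2)),
           h = h)
}

# ---------------------------------------------------------------------------
# Mixture fitting (MAP-EM with a strong zero-mean prior on component means)
# ---------------------------------------------------------------------------

log_dmvnorm <- function(X, mu, S) {
  d <- ncol(X)
  ch <- chol(S)
  z <- forwardsolve(t(ch), t(X) - mu)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * d * log(2 * pi)
}

gmm_fit_zero_mean <- function(X, L, seed, prior_precision = 1e6,
                              max_iter = 300, tol = 1e-7, ridge = 1e-6) {
  set.seed(seed)
  N <- nrow(X); d <- ncol(X)
  km <- suppressWarnings(stats::kmeans(X, centers = min(L, N - 1),
                                       nstart = 3, iter.max = 50))
  Rz <- matrix(1e-3, N, L)
  Rz[cbind(seq_len(N), km$cluster)] <- 1
  Rz <- Rz / rowSums(Rz)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    Nk <- colSums(Rz)
    if (any(Nk < d + 2)) return(NULL)   # degenerate component
    wk <- Nk / N
    mus <- t(Rz) %*% X / (Nk + prior_precision)   # MAP-shrunk means
    Ss <- vector("list", L)
    logp <- matrix(0, N, L)
    for (k in seq_len(L)) {
      Xc <- sweep(X, 2, mus[k, ])
      Ss[[k]] <- crossprod(Xc * Rz[, k], Xc) / Nk[k] + diag(ridge, d)
      logp[, k] <- log(wk[k]) + log_dmvnorm(X, mus[k, ], Ss[[k]])
    }
    mx <- apply(logp, 1, max)
    lse <- mx + log(rowSums(exp(logp - mx)))
    ll <- sum(lse)
    Rz <- exp(logp - lse)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll)) break
    ll_old <- ll
  }
  list(weights = colSums(Rz) / N, means = mus, covs = Ss, loglik = ll,
       resp = Rz)
}

#' Fit a Gaussian mixture to trained connectivity and evaluate by resampling
#'
#' Fits mixtures of `1..L` zero-mean (MAP, mean prior precision `1e6`)
#' Gaussians to the joint per-unit weight vectors
#' `(inputs, n's, m's, w)` of a trained network, then resamples finite
#' networks from each fit and scores them on a batch of pure-sine trials,
#' comparing with the original network's loss.
#'
#' @param rnn trained `lowrank_rnn`
#' @param L_range component counts to fit (default 1:7)
#' @param seed integer seed
#' @param n_resample resampled networks per fit (default 30)
#' @param n_trials evaluation batch size (default 128)
#' @param cfg task configuration for the evaluation trials
#' @param freq_hz evaluation reference frequency
#' @param max_restarts refits on degenerate components
#' @return list per L with `mixture`, `loglik`, `resample_loss` (vector),
#'   plus `orig_loss` at the top level
#' @export
fit_mixture <- function(rnn, L_range = 1:7, seed, n_resample = 30,
                        n_trials = 128, cfg = task_config(),
                        freq_hz = 8, max_restarts = 5) {
  if (missing(seed)) stop("an integer seed is required")
  X <- cbind(rnn$I, rnn$n, rnn$m, rnn$w)
  n_stim <- sum(rnn$channels$kind == "stim")
  set.seed(seed)
  ref <- pure_sine(freq_hz, 1, 0, cfg$T_trial + 1, 1000 / cfg$h)
  trials <- lapply(seq_len(n_trials), function(i)
    make_trial(ref, 1 + (i %% n_stim), cfg, seed = seed * 1000 + i))
  orig_loss <- batch_objective(rnn, trials, cfg$h, 0)[["loss"]]
  res <- list()
  for (L in L_range) {
    fit <- NULL
    for (rs in seq_len(max_restarts)) {
      fit <- gmm_fit_zero_mean(X, L, seed + 101 * L + rs)
      if (!is.null(fit)) break
    }
    if (is.null(fit)) { res[[as.character(L)]] <- NULL; next }
    chans <- rnn$channels
    mix <- mixture_connectivity(pmax(fit$weights, 1e-9) /
                                  sum(pmax(fit$weights, 1e-9)),
                                lapply(fit$covs, function(S)
                                  (S + t(S)) / 2 + diag(1e-8, ncol(S))),
                                chans, rank = rnn$rank, tau = rnn$tau,
                                readout_mode = rnn$readout_mode)
    losses <- vapply(seq_len(n_resample), function(i) {
      net <- sample_network(mix, rnn$N, seed = seed + 7919 * L + i)
      net$readout_scale <- rnn$readout_scale
      batch_objective(net, trials, cfg$h, 0)[["loss"]]
    }, 0)
    res[[as.character(L)]] <- list(mixture = mix, loglik = fit$loglik,
                                   means = fit$means,
                                   resample_loss = losses)
  }
  res$orig_loss <- orig_loss
  res
}
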