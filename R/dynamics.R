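# Reverse engineering the driven dynamics: the rank-2 network with a
# sinusoidal reference reduces to an autonomous flow on the solid torus
# (kappa1, kappa2, theta). Limit cycles are fixed points of the Poincare
# return map on the section {theta = 0 mod 2pi}; their orbital stability is
# given by the Floquet multipliers, the eigenvalues of the monodromy matrix.

#' Autonomous vector field on the (kappa1, kappa2, theta) torus
#'
#' Builds the reduced field for a canonicalized rank-2 network driven by
#' `u(theta) = A sin(theta)` at angular velocity `omega = 2*pi*freq_hz`
#' (plus optional tonic stimuli). The filtered input is available in closed
#' form, `v(theta) = A/sqrt((omega*tau)^2+1) * sin(theta - atan(omega*tau))`
#' (transient constant set to zero).
#'
#' @param rnn a rank-2 `lowrank_rnn` (canonicalized automatically)
#' @param A reference oscillation amplitude
#' @param freq_hz reference frequency in Hz
#' @param stim tonic stimulus amplitudes, one per stimulus channel
#'   (default all zero)
#' @param h default integration step in ms
#' @return an object of class `kappa_field`
#' @export
kappa_field <- function(rnn, A = 1, freq_hz = 8, stim = NULL, h = 0.5) {
  if (is_fullrank(rnn)) stop("kappa_field() requires a low-rank network")
  if (rnn$rank != 2) stop("kappa_field() requires a rank-2 network")
  if (!isTRUE(attr(rnn, "canonical"))) rnn <- canonicalize(rnn)
  kinds <- rnn$channels$kind
  n_stim <- sum(kinds == "stim")
  stim <- stim %||% numeric(n_stim)
  stopifnot(length(stim) == n_stim)
  ch_phase <- rnn$channels$phase %||% numeric(length(kinds))
  ch_kind <- ifelse(kinds == "osc", 0L, 1L)
  ch_amp <- numeric(length(kinds))
  ch_amp[kinds == "osc"] <- A
  ch_amp[kinds == "stim"] <- stim
  structure(list(rnn = rnn, m = rnn$m, n = rnn$n,
                 I_perp = attr(rnn, "I_perp"), alpha = attr(rnn, "alpha"),
                 ch_kind = ch_kind, ch_amp = ch_amp, ch_phase = ch_phase,
                 A = A, freq_hz = freq_hz, omega = hz_to_radms(freq_hz),
                 tau = rnn$tau, stim = stim, h = h),
            class = "kappa_field")
}

#' @export
print.kappa_field <- function(x, ...) {
  cat(sprintf("<kappa_field> A = %g, f = %g Hz, stim = (%s), tau = %g ms\n",
              x$A, x$freq_hz, paste(signif(x$stim, 3), collapse = ", "),
              x$tau))
  invisible(x)
}

# Integer number of fixed steps per reference period; the step is shrunk so
# theta advances exactly 2*pi per period (keeps the section exact).
period_steps <- function(field, h = NULL) {
  h <- h %||% field$h
  T_per <- 2 * pi / field$omega
  n <- max(1L, as.integer(ceiling(T_per / h - 1e-9)))
  list(n = n, h = T_per / n, T = T_per)
}

field_flow <- function(field, kappa, theta0 = 0, n_periods = 1, h = NULL,
                       method = c("rk4", "euler"), monodromy = FALSE,
                       traj_stride = 0L) {
  method <- match.arg(method)
  ps <- period_steps(field, h)
  kappa <- as.matrix(kappa)
  if (nrow(kappa) != 2) kappa <- t(kappa)
  cpp_kappa_flow(field$m, field$n, field$I_perp, field$alpha,
                 field$ch_kind, field$ch_amp, field$ch_phase, field$omega,
                 field$tau, kappa, theta0, ps$h,
                 as.integer(round(ps$n * n_periods)),
                 if (method == "euler") 0L else 1L, monodromy,
                 as.integer(traj_stride))
}

#' Poincare return map on the section theta = 0
#'
#' Integrates the reduced dynamics for `n_periods` reference periods from
#' the section `{theta = 0 mod 2pi}` with a fixed-step deterministic
#' integrator (RK4 by default; Euler available for strict replication).
#'
#' @param field a [kappa_field()]
#' @param kappa section point(s): length-2 vector or 2 x K matrix
#' @param n_periods reference periods per application (default 1)
#' @param h step override, ms
#' @param method `"rk4"` or `"euler"`
#' @return mapped point(s), same shape as `kappa`; attribute `winding` gives
#'   the unwrapped internal phase advance (radians) over the return
#' @export
poincare_map <- function(field, kappa, n_periods = 1, h = NULL,
                         method = "rk4") {
  vecin <- is.null(dim(kappa))
  out <- field_flow(field, kappa, 0, n_periods, h, method)
  k <- out$kappa
  if (vecin) k <- drop(k)
  attr(k, "winding") <- out$winding
  k
}

# Jacobian of the n-period return map via the variational equation.
poincare_jacobian <- function(field, kappa, n_periods = 1, h = NULL,
                              method = "rk4") {
  out <- field_flow(field, matrix(kappa, 2), 0, n_periods, h, method,
                    monodromy = TRUE)
  list(P = drop(out$kappa), M = out$M[, , 1], winding = out$winding[1])
}

#' Floquet multipliers of a limit cycle
#'
#' Integrates the variational (monodromy) equation `dM/dt = D_kappa F M`,
#' `M(0) = I`, along the orbit for one return and returns the eigenvalues
#' of `M(T)` — the Floquet multipliers of the cycle. The cycle is orbitally
#' stable iff all multipliers have magnitude below one.
#'
#' @param field a [kappa_field()] (or mean-field equivalent)
#' @param kappa_star fixed point of the return map on the section
#' @param n_periods period of the orbit in reference cycles
#' @param h step override
#' @return complex vector of multipliers (length 2)
#' @export
floquet_multipliers <- function(field, kappa_star, n_periods = 1, h = NULL) {
  pj <- field_jacobian(field, kappa_star, n_periods, h)
  eigen(pj$M, only.values = TRUE)$values
}

# dispatcher so the same Newton/Floquet machinery serves network fields and
# mean-field mixtures
field_jacobian <- function(field, kappa, n_periods = 1, h = NULL) {
  if (inherits(field, "kappa_field"))
    poincare_jacobian(field, kappa, n_periods, h)
  else mf_jacobian(field, kappa, n_periods, h)
}

field_map <- function(field, kappa, n_periods = 1, h = NULL, ...) {
  if (inherits(field, "kappa_field"))
    poincare_map(field, kappa, n_periods, h, ...)
  else mf_map(field, kappa, n_periods, h, ...)
}

# damped Newton iteration on P(kappa) - kappa
newton_fixed_point <- function(field, kappa0, n_periods = 1, tol = 1e-9,
                               max_iter = 40, h = NULL) {
  kap <- as.numeric(kappa0)
  dim_k <- length(kap)
  res_prev <- Inf
  for (it in seq_len(max_iter)) {
    pj <- field_jacobian(field, kap, n_periods, h)
    res <- pj$P - kap
    rn <- sqrt(sum(res^2))
    if (!is.finite(rn)) return(NULL)
    if (rn < tol)
      return(list(kappa = kap, residual = rn, M = pj$M,
                  winding = pj$winding, iterations = it))
    step <- tryCatch(solve(pj$M - diag(dim_k), -res),
                     error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lam <- 1
    for (d in 1:6) {   # damping: do not accept a worse residual blindly
      cand <- kap + lam * step
      pr <- field_map(field, cand, n_periods, h)
      rn2 <- sqrt(sum((as.numeric(pr) - cand)^2))
      if (is.finite(rn2) && (rn2 < rn || rn2 < tol)) break
      lam <- lam / 2
    }
    kap <- kap + lam * step
    if (rn > res_prev * 10) return(NULL)   # diverging
    res_prev <- rn
  }
  # did not reach tol
  pj <- field_jacobian(field, kap, n_periods, h)
  rn <- sqrt(sum(pj$P - kap)^2)
  if (rn < tol * 100)
    list(kappa = kap, residual = rn, M = pj$M, winding = pj$winding,
         iterations = max_iter)
  else NULL
}

default_seed_ring <- function(radii = c(0.5, 1, 2), n_angles = 8) {
  ang <- seq(0, 2 * pi, length.out = n_angles + 1)[-(n_angles + 1)]
  do.call(cbind, lapply(radii, function(r) rbind(r * cos(ang), r * sin(ang))))
}

#' Locate fixed points of the Poincare map (limit cycles)
#'
#' Candidate points are generated by forward iteration of the map from a
#' seed grid (which finds the attracting cycles), then polished by damped
#' Newton iteration using the variational-equation Jacobian; unconverged
#' seeds are dropped and duplicates merged by distance. Each fixed point is
#' annotated with its Floquet multipliers and winding number (internal
#' cycles per return, from the unwrapped phase advance).
#'
#' @param field a [kappa_field()] or mean-field flow
#' @param seed_grid optional 2 x K matrix of section seeds (default: rings
#'   of initial conditions)
#' @param tol Newton residual tolerance (default 1e-9)
#' @param n_periods period of the sought orbits in reference cycles
#' @param forward_periods forward-iteration burn-in before polishing
#' @param merge_tol merge radius for duplicate fixed points
#' @param h step override
#' @param include_seeds also polish directly from the raw seeds (finds
#'   unstable fixed points)
#' @return list of fixed points, each a list with `kappa`, `multipliers`,
#'   `max_mult`, `stable`, `residual`, `winding_m`, `period_n`
#' @export
find_fixed_points <- function(field, seed_grid = NULL, tol = 1e-9,
                              n_periods = 1, forward_periods = 30,
                              merge_tol = 1e-3, h = NULL,
                              include_seeds = FALSE) {
  seeds <- seed_grid %||% default_seed_ring()
  burn <- field_map(field, seeds, n_periods = forward_periods * n_periods,
                    h = h)
  cand <- as.matrix(burn)
  if (include_seeds) cand <- cbind(cand, as.matrix(seeds))
  # deduplicate candidates before polishing
  keep <- rep(TRUE, ncol(cand))
  for (j in seq_len(ncol(cand))) {
    if (!keep[j]) next
    if (j < ncol(cand))
      for (k in (j + 1):ncol(cand))
        if (sqrt(sum((cand[, j] - cand[, k])^2)) < merge_tol) keep[k] <- FALSE
  }
  cand <- cand[, keep, drop = FALSE]
  fps <- list()
  for (j in seq_len(ncol(cand))) {
    nr <- newton_fixed_point(field, cand[, j], n_periods, tol, h = h)
    if (is.null(nr)) next
    dup <- FALSE
    for (f in fps)
      if (sqrt(sum((f$kappa - nr$kappa)^2)) < merge_tol) { dup <- TRUE; break }
    if (dup) next
    mult <- eigen(nr$M, only.values = TRUE)$values
    fps[[length(fps) + 1]] <-
      list(kappa = nr$kappa, multipliers = mult,
           max_mult = max(Mod(mult)), stable = max(Mod(mult)) < 1,
           residual = nr$residual,
           winding_m = as.integer(round(nr$winding / (2 * pi))),
           period_n = n_periods)
  }
  fps
}

#' Stability of the memory cycles under tonic stimulus input
#'
#' Sweeps a tonic stimulus amplitude, tracking both no-stimulus limit cycles
#' by continuation (Newton polishing seeded from the previous amplitude) and
#' recomputing their Floquet multipliers. The critical amplitude `crit` is
#' where the disfavored cycle loses stability (max multiplier norm crossing
#' 1, linearly interpolated) or disappears in the saddle-node.
#'
#' @param rnn rank-2 network (or a [kappa_field()] whose stimulus will be
#'   swept)
#' @param stim_id which stimulus channel to drive (1-based)
#' @param amplitudes increasing vector of tonic amplitudes (first should
#'   be 0)
#' @param A,freq_hz reference drive (defaults 1, 8 Hz)
#' @param ... passed to [find_fixed_points()] for the initial census
#' @return list with `table` (data.frame: amplitude, cycle, kappa, max
#'   multiplier norm, stable, n_stable) and `crit`
#' @export
stimulus_bifurcation <- function(rnn, stim_id, amplitudes, A = 1,
                                 freq_hz = 8, ...) {
  if (inherits(rnn, "kappa_field")) rnn <- rnn$rnn
  n_stim <- sum(rnn$channels$kind == "stim")
  base_stim <- numeric(n_stim)
  f0 <- kappa_field(rnn, A, freq_hz, base_stim)
  fps <- find_fixed_points(f0, ...)
  fps <- fps[order(vapply(fps, function(f) atan2(f$kappa[2], f$kappa[1]),
                          0))]
  if (length(fps) == 0) stop("no limit cycles found at zero stimulus")
  rows <- list()
  current <- lapply(fps, function(f) f$kappa)
  alive <- rep(TRUE, length(fps))
  for (s in amplitudes) {
    st <- base_stim; st[stim_id] <- s
    fs <- kappa_field(rnn, A, freq_hz, st)
    for (ci in seq_along(current)) {
      if (!alive[ci]) next
      nr <- newton_fixed_point(fs, current[[ci]], 1, 1e-9)
      if (is.null(nr)) { alive[ci] <- FALSE; next }
      # continuation must stay on the same branch: reject large jumps
      if (sqrt(sum((nr$kappa - current[[ci]])^2)) >
          1 + sqrt(sum(current[[ci]]^2))) { alive[ci] <- FALSE; next }
      current[[ci]] <- nr$kappa
      mult <- eigen(nr$M, only.values = TRUE)$values
      rows[[length(rows) + 1]] <-
        data.frame(amplitude = s, cycle = ci, kappa1 = nr$kappa[1],
                   kappa2 = nr$kappa[2], max_mult = max(Mod(mult)),
                   stable = max(Mod(mult)) < 1)
    }
  }
  tab <- do.call(rbind, rows)
  ns <- stats::aggregate(stable ~ amplitude, tab, sum)
  names(ns)[2] <- "n_stable"
  tab <- merge(tab, ns, by = "amplitude")
  tab <- tab[order(tab$amplitude, tab$cycle), ]
  crit <- NA_real_
  for (ci in unique(tab$cycle)) {
    sub <- tab[tab$cycle == ci, ]
    cross <- which(sub$max_mult >= 1)
    if (length(cross) > 0) {
      i <- min(cross)
      crit_ci <- if (i == 1) sub$amplitude[1] else {
        s0 <- sub$amplitude[i - 1]; s1 <- sub$amplitude[i]
        m0 <- sub$max_mult[i - 1]; m1 <- sub$max_mult[i]
        s0 + (1 - m0) / (m1 - m0) * (s1 - s0)
      }
      crit <- min(crit, crit_ci, na.rm = TRUE)
    } else if (nrow(sub) < length(unique(tab$amplitude))) {
      # branch annihilated (saddle-node): take the last surviving amplitude
      crit <- min(crit, max(sub$amplitude), na.rm = TRUE)
    }
  }
  list(table = tab, crit = crit)
}

reduce_ratio <- function(m, n) {
  if (m == 0) return(c(0, n))
  g <- gcd_int(abs(m), n)
  c(m / g, n / g)
}

#' Amplitude-frequency stability scan with m:n locking classification
#'
#' For every grid cell, iterates the Poincare map from a ring of initial
#' conditions until convergence, detects the period `n` of each attracting
#' orbit of the map (up to `max_n`), computes its winding number `m`
#' (internal cycles per `n` reference periods), and labels the cell
#' (`bistable 1:1`, `bistable m:n`, `monostable`, `other`).
#'
#' @param rnn rank-2 network
#' @param amps amplitude grid
#' @param freqs frequency grid (Hz)
#' @param max_n maximum map period considered
#' @param n_ring initial conditions on the seeding ring
#' @param burn_periods forward-iteration burn-in (reference periods)
#' @param settle_tol distance threshold for period detection / orbit
#'   identity
#' @param h integration step, ms
#' @return data.frame with one row per cell: amplitude, frequency,
#'   n_stable, m, n, label
#' @export
freq_amp_scan <- function(rnn, amps, freqs, max_n = 4, n_ring = 16,
                          burn_periods = 40, settle_tol = 1e-2, h = 0.5) {
  if (!isTRUE(attr(rnn, "canonical"))) rnn <- canonicalize(rnn)
  rows <- list()
  for (f in freqs) {
    for (A in amps) {
      field <- kappa_field(rnn, A, f, h = h)
      cell <- scan_cell(field, max_n, n_ring, burn_periods, settle_tol, h)
      rows[[length(rows) + 1]] <-
        data.frame(amplitude = A, frequency = f, n_stable = cell$n_stable,
                   m = cell$m, n = cell$n, label = cell$label)
    }
  }
  do.call(rbind, rows)
}

scan_cell <- function(field, max_n, n_ring, burn_periods, settle_tol, h) {
  ang <- seq(0, 2 * pi, length.out = n_ring + 1)[-(n_ring + 1)]
  seeds <- rbind(cos(ang), sin(ang)) * 1.2
  # fixed-step Euler throughout: classification works at settle_tol 1e-2,
  # far above the integration error at h = 0.5 ms
  burn <- field_flow(field, seeds, 0, burn_periods, h, method = "euler")
  ps <- period_steps(field, h)
  n_rec <- max_n + 4
  rec <- field_flow(field, burn$kappa, 0, n_rec, h, method = "euler",
                    traj_stride = ps$n)
  pts <- rec$traj           # 2 x K x (n_rec+1) section points
  wind <- rec$winding       # total winding over n_rec periods
  orbits <- list()
  for (j in seq_len(ncol(seeds))) {
    traj_j <- pts[, j, , drop = TRUE]   # 2 x (n_rec+1)
    last <- traj_j[, ncol(traj_j)]
    if (!all(is.finite(last))) next
    per <- NA_integer_
    for (nn in 1:max_n) {
      if (sqrt(sum((last - traj_j[, ncol(traj_j) - nn])^2)) < settle_tol) {
        per <- nn; break
      }
    }
    if (is.na(per)) next                # not settled within max_n
    wm <- as.integer(round(wind[j] * per / n_rec / (2 * pi)))
    orb_pts <- traj_j[, ncol(traj_j) - seq_len(per) + 1, drop = FALSE]
    dup <- FALSE
    for (o in orbits) {
      if (o$per == per &&
          min(apply(o$pts, 2, function(p)
            min(colSums((orb_pts - p)^2)))) < settle_tol^2) {
        dup <- TRUE; break
      }
    }
    if (!dup)
      orbits[[length(orbits) + 1]] <- list(per = per, wm = wm, pts = orb_pts)
  }
  if (length(orbits) == 0)
    return(list(n_stable = 0L, m = NA_integer_, n = NA_integer_,
                label = "other"))
  ratios <- unique(t(vapply(orbits, function(o) reduce_ratio(o$wm, o$per),
                            c(0, 0))))
  if (nrow(ratios) == 1) {
    m <- ratios[1, 1]; n <- ratios[1, 2]
    label <- if (length(orbits) == 2 && m == 1 && n == 1) "bistable 1:1"
    else if (length(orbits) == 2) sprintf("bistable %d:%d", m, n)
    else if (length(orbits) == 1) "monostable"
    else "other"
    list(n_stable = length(orbits), m = as.integer(m), n = as.integer(n),
         label = label)
  } else {
    list(n_stable = length(orbits), m = NA_integer_, n = NA_integer_,
         label = "other")
  }
}

#' Torus embedding for phase-space visualization
#'
#' Maps `(kappa1, kappa2, theta)` to 3-D coordinates
#' `(cos(theta) (r_tilde - kappa1), sin(theta) (r_tilde - kappa1), kappa2)`.
#' The map is injective when `r_tilde` exceeds every `kappa1` in the data.
#'
#' @param kappa 2 x T matrix (rows kappa1, kappa2) or length-2 vector
#' @param theta phase per column of `kappa`
#' @param r_tilde tube-center radius
#' @return T x 3 matrix of embedded coordinates
#' @export
torus_embed <- function(kappa, theta, r_tilde) {
  kappa <- as.matrix(kappa)
  if (nrow(kappa) != 2) kappa <- t(kappa)
  if (r_tilde <= max(kappa[1, ]))
    warning("r_tilde <= max(kappa1): embedding may self-intersect")
  cbind(x = cos(theta) * (r_tilde - kappa[1, ]),
        y = sin(theta) * (r_tilde - kappa[1, ]),
        z = kappa[2, ])
}

#' Rate-coding vs phase-coding metrics from rate traces
#'
#' Per unit: the absolute difference of min-max-normalized time-mean rates
#' between the two stimulus conditions, and the absolute circular difference
#' of the unit's oscillation phase (projection of its rate trace onto
#' `exp(1i*theta)`). Model-level metrics are means over units.
#'
#' @param rates_a,rates_b N x T rate matrices (steady-state windows)
#' @param theta_a,theta_b reference phase per time bin
#' @return list with `rate_metric`, `phase_metric` and per-unit vectors
#' @export
coding_metrics_rates <- function(rates_a, rates_b, theta_a, theta_b) {
  un <- unwrap_phase(theta_a)
  n_cyc <- (max(un) - min(un)) / (2 * pi)
  if (n_cyc < 2) stop("steady-state window shorter than two reference cycles")
  mu_a <- rowMeans(rates_a); mu_b <- rowMeans(rates_b)
  lo <- pmin(apply(rates_a, 1, min), apply(rates_b, 1, min))
  hi <- pmax(apply(rates_a, 1, max), apply(rates_b, 1, max))
  rng <- pmax(hi - lo, 1e-12)
  rate_diff <- abs(mu_a - mu_b) / rng
  ph_a <- Arg((rates_a - mu_a) %*% exp(-1i * theta_a))
  ph_b <- Arg((rates_b - mu_b) %*% exp(-1i * theta_b))
  phase_diff <- abs(circ_diff(ph_a, ph_b))
  list(rate_metric = mean(rate_diff), phase_metric = mean(phase_diff),
       rate_per_unit = rate_diff, phase_per_unit = phase_diff)
}

#' @rdname coding_metrics_rates
#' @param rnn a `lowrank_rnn`
#' @param trials_a,trials_b lists of trials for the two conditions
#' @param window_cycles steady-state window length in reference cycles,
#'   taken from the trial end
#' @details `coding_metrics()` simulates the network (noise-free) on both
#'   trial sets and evaluates the metrics on the trailing
#'   `window_cycles` reference cycles, averaging rates across trials.
#' @export
coding_metrics <- function(rnn, trials_a, trials_b, window_cycles = 2) {
  avg_rates <- function(trials) {
    f <- attr(trials[[1]], "freq_hz") %||% trials[[1]]$freq_hz %||% 8
    n_win <- round(window_cycles * (1000 / f) / trials[[1]]$h)
    idx <- (length(trials[[1]]$target) - n_win + 1):length(trials[[1]]$target)
    acc <- NULL
    for (tr in trials) {
      sim <- simulate_rnn(rnn, tr)
      r <- tanh(sim$x[, idx, drop = FALSE])
      acc <- if (is.null(acc)) r else acc + r
    }
    list(rates = acc / length(trials), theta = trials[[1]]$theta[idx])
  }
  a <- avg_rates(trials_a); b <- avg_rates(trials_b)
  coding_metrics_rates(a$rates, b$rates, a$theta, b$theta)
}

#' Low-dimensional basis for full-rank networks
#'
#' Recovers an analysis basis for unconstrained networks: the first two left
#' singular vectors of the recurrent drive `J tanh(x(t))` collected over the
#' supplied trajectories, plus the oscillatory input vector orthogonalized
#' against them. Reports the fraction of state variance captured by the
#' 3-D basis and of drive variance captured by the two singular vectors.
#'
#' @param rnn a full-rank (or low-rank) network
#' @param trials trials whose simulated activity defines the basis (one
#'   reference period of each trial type suffices)
#' @return list with `u1`, `u2`, `i_perp` (orthonormal basis vectors),
#'   `var_explained` (r^2 of the 3-D basis on x), `var_drive` (r^2 of
#'   u1, u2 on the drive)
#' @export
pca_basis_fullrank <- function(rnn, trials) {
  X <- do.call(cbind, lapply(trials, function(tr) simulate_rnn(rnn, tr)$x))
  D <- rnn_J(rnn) %*% tanh(X)
  sv <- svd(D, nu = 2, nv = 0)
  if (sv$d[2] < 1e-10 * sv$d[1])
    warning("rank-deficient trajectory matrix")
  u1 <- sv$u[, 1]; u2 <- sv$u[, 2]
  iosc <- rnn$I[, which(rnn$channels$kind == "osc")[1]]
  ip <- iosc - u1 * sum(u1 * iosc) - u2 * sum(u2 * iosc)
  ip <- ip / sqrt(sum(ip^2))
  B <- cbind(u1, u2, ip)
  var_explained <- sum((crossprod(B, X))^2) / sum(X^2)
  var_drive <- sum(sv$d[1:2]^2) / sum(D^2)
  list(u1 = u1, u2 = u2, i_perp = ip, var_explained = var_explained,
       var_drive = var_drive)
}
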