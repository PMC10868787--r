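# Reduction of the converged rank-2 dynamics to two phase-coupled
# oscillators: theta' = omega (reference), phi' = omega + g(phi, theta)
# (internal phase), with the coupling function g extracted from the network
# equations in polar coordinates under a constant-radius approximation.

#' Extract the coupling function of a rank-2 network
#'
#' Rewrites the reduced dynamics in polar coordinates
#' `kappa = r (cos phi, sin phi)`, approximating the kappa-radius as
#' constant (the mean orbit radius over the two stable cycles unless given),
#' and evaluates
#' `tau dphi/dt = (1/r^2) [ (1/N)(kappa1 n2 - kappa2 n1)' tanh(x) +
#' (kappa1 alpha2 - kappa2 alpha1) u(theta) ]` on a (theta, phi) grid;
#' the coupling function is `g = dphi/dt - omega`.
#'
#' @param rnn rank-2 network
#' @param A,freq_hz reference amplitude and frequency
#' @param stim tonic stimulus amplitudes under which to extract g
#' @param n_grid grid resolution per axis (default 64)
#' @param r radius override; default: mean orbit radius over the stable
#'   no-stimulus cycles
#' @param h integration step for the radius computation
#' @return object of class `coupling_grid`: `theta_grid`, `phi_grid`
#'   (radians), `g` (rad/ms, theta in rows), `omega`, `r`, `stim`
#' @export
extract_coupling <- function(rnn, A = 1, freq_hz = 8, stim = NULL,
                             n_grid = 64, r = NULL, h = 0.5) {
  field <- kappa_field(rnn, A, freq_hz, stim, h = h)
  if (is.null(r)) {
    f0 <- kappa_field(field$rnn, A, freq_hz, h = h)
    fps <- find_fixed_points(f0, h = h)
    fps <- Filter(function(f) f$stable, fps)
    if (length(fps) == 0) stop("no stable cycles found to set the radius")
    r <- mean(vapply(fps, function(f) orbit_radius(f0, f$kappa, h), 0))
  }
  if (r <= 0) stop("nonpositive radius")
  theta_grid <- seq(0, 2 * pi, length.out = n_grid + 1)[-(n_grid + 1)]
  phi_grid <- theta_grid
  dphi <- cpp_coupling_grid(field$m, field$n, field$I_perp, field$alpha,
                            field$ch_kind, field$ch_amp, field$ch_phase,
                            field$omega, field$tau, r, theta_grid, phi_grid)
  structure(list(theta_grid = theta_grid, phi_grid = phi_grid,
                 g = dphi - field$omega, omega = field$omega, r = r,
                 stim = field$stim, A = A, freq_hz = freq_hz,
                 tau = field$tau),
            class = "coupling_grid")
}

#' @export
print.coupling_grid <- function(x, ...) {
  cat(sprintf("<coupling_grid> %dx%d, omega = %.4f rad/ms, r = %.3f, |g| up to %.4f\n",
              length(x$theta_grid), length(x$phi_grid), x$omega, x$r,
              max(abs(x$g))))
  invisible(x)
}

# mean orbit radius of the limit cycle through kappa_star
orbit_radius <- function(field, kappa_star, h = NULL, n_periods = 1) {
  flowfun <- if (inherits(field, "kappa_field")) field_flow else mf_flow
  out <- flowfun(field, matrix(kappa_star, 2), 0, n_periods, h,
                 traj_stride = 1L)
  tr <- out$traj[, 1, ]
  mean(sqrt(colSums(tr^2)))
}

#' Simulate the two coupled phase oscillators
#'
#' Integrates `theta' = omega` (exact) and `phi' = omega + g(phi, theta)`
#' with the coupling function bilinearly interpolated on its periodic grid
#' (fixed-step RK4).
#'
#' @param coupling a `coupling_grid`
#' @param phi0 initial internal phase(s), vector
#' @param theta0 initial reference phase
#' @param n_periods duration in reference periods
#' @param h step in ms
#' @param keep_traj record phi once per reference period
#' @return list with `phi` (final), `theta` (final), and optionally
#'   `traj` (K x periods matrix of per-period phi) and `theta_traj`
#' @export
simulate_phase_model <- function(coupling, phi0, theta0 = 0, n_periods = 20,
                                 h = 0.5, keep_traj = FALSE) {
  T_per <- 2 * pi / coupling$omega
  n_per_period <- max(1L, as.integer(ceiling(T_per / h - 1e-9)))
  h_eff <- T_per / n_per_period
  out <- cpp_phase_sim(coupling$g, coupling$omega, coupling$tau, theta0,
                       as.numeric(phi0), h_eff,
                       as.integer(n_per_period * n_periods),
                       if (keep_traj) as.integer(n_per_period) else 0L)
  res <- list(phi = out$phi, theta = out$theta)
  if (keep_traj) {
    res$traj <- out$traj
    res$theta_traj <- theta0 + 2 * pi * (0:n_periods)
  }
  res
}

#' Census of locked solutions of the phase model
#'
#' Integrates the phase model from a ring of initial internal phases and
#' counts the distinct locked phase differences `phi - theta`. A trajectory
#' counts as locked when its per-reference-cycle change of `phi - theta`
#' stays below `lock_tol` radians over the last five cycles.
#'
#' @param coupling a `coupling_grid`
#' @param n_init number of initial phases (default 16)
#' @param n_periods integration length in reference periods
#' @param lock_tol per-cycle drift tolerance (rad)
#' @param merge_tol circular distance below which locked phases are merged
#' @return list with `n_attractors`, `locked_phases` (circular positions of
#'   phi - theta), `converged` (logical per initial condition)
#' @export
phase_attractor_census <- function(coupling, n_init = 16, n_periods = 80,
                                   lock_tol = 1e-3, merge_tol = 0.2) {
  phi0 <- seq(0, 2 * pi, length.out = n_init + 1)[-(n_init + 1)]
  sim <- simulate_phase_model(coupling, phi0, n_periods = n_periods,
                              keep_traj = TRUE)
  psi <- sweep(sim$traj, 2, sim$theta_traj)   # phi - theta per period
  nc <- ncol(psi)
  drift <- abs(psi[, nc] - psi[, nc - 5])/5
  conv <- drift < lock_tol
  locked <- wrap_2pi(psi[conv, nc])
  phases <- c()
  for (p in locked) {
    if (length(phases) == 0 ||
        min(abs(circ_diff(p, phases))) > merge_tol)
      phases <- c(phases, p)
  }
  list(n_attractors = length(phases), locked_phases = phases,
       converged = conv)
}

#' Compare the phase-model reduction with the full network
#'
#' Initializes the full network on the kappa-circle of radius `r` at a set
#' of internal phases, simulates both the network (noise-free, pure-sine
#' reference) and the coupled-oscillator model from matched initial
#' conditions, and reports the circular discrepancy between the phase-model
#' `phi` and the network's `atan2(kappa2, kappa1)` after convergence.
#'
#' @param rnn rank-2 network
#' @param coupling a `coupling_grid` extracted from it
#' @param inits initial internal phases (default 8 spread over the circle)
#' @param n_periods simulation length in reference periods
#' @param h step, ms
#' @return list with `discrepancy` (per init, rad), `max_discrepancy`,
#'   `n_attractors_full`, `n_attractors_phase`, `converged`
#' @export
compare_phase_to_full <- function(rnn, coupling, inits = NULL,
                                  n_periods = 60, h = 0.5) {
  if (!isTRUE(attr(rnn, "canonical"))) rnn <- canonicalize(rnn)
  inits <- inits %||% seq(0, 2 * pi, length.out = 9)[-9]
  field <- kappa_field(rnn, coupling$A, coupling$freq_hz, coupling$stim,
                       h = h)
  # full-network end phases, starting on the radius-r circle at theta = 0
  kap0 <- rbind(coupling$r * cos(inits), coupling$r * sin(inits))
  full <- field_flow(field, kap0, 0, n_periods, h)
  phi_full <- atan2(full$kappa[2, ], full$kappa[1, ])
  sim <- simulate_phase_model(coupling, inits, n_periods = n_periods,
                              keep_traj = TRUE)
  phi_red <- sim$phi
  nc <- ncol(sim$traj)
  conv <- abs((sim$traj[, nc] - sim$traj[, nc - 5]) -
              (sim$theta_traj[nc] - sim$theta_traj[nc - 5])) / 5 < 1e-3
  if (!all(conv)) warning(sum(!conv), " non-convergent trajectories excluded")
  disc <- abs(circ_diff(phi_red, phi_full))
  # initial conditions near a basin boundary can land on different
  # attractors in the two systems; they say nothing about how well the
  # attractors themselves match, so they are flagged and excluded from the
  # headline discrepancy (but counted in basin_agreement).
  same_attr <- disc < pi / 2
  if (any(conv & !same_attr))
    warning(sum(conv & !same_attr),
            " initial condition(s) converged to different attractors",
            " (basin-boundary sensitivity); excluded")
  use <- conv & same_attr
  census_full <- cluster_phases(phi_full[conv])
  census_red <- cluster_phases(wrap_2pi(phi_red[conv]))
  # attractor-set discrepancy: match each full-network locked phase to the
  # nearest phase-model locked phase
  ph_f <- unique_phases(phi_full[conv])
  ph_r <- unique_phases(wrap_2pi(phi_red[conv]))
  set_disc <- if (length(ph_f) && length(ph_r))
    max(vapply(ph_f, function(p) min(abs(circ_diff(p, ph_r))), 0)) else NA
  list(discrepancy = disc, max_discrepancy = max(disc[use]),
       phase_set_discrepancy = set_disc,
       n_attractors_full = census_full, n_attractors_phase = census_red,
       basin_agreement = mean(same_attr[conv]), converged = conv)
}

unique_phases <- function(ph, merge_tol = 0.2) {
  cl <- c()
  for (p in wrap_2pi(ph))
    if (length(cl) == 0 || min(abs(circ_diff(p, cl))) > merge_tol)
      cl <- c(cl, p)
  cl
}

cluster_phases <- function(ph, merge_tol = 0.2) {
  cl <- c()
  for (p in wrap_2pi(ph))
    if (length(cl) == 0 || min(abs(circ_diff(p, cl))) > merge_tol)
      cl <- c(cl, p)
  length(cl)
}

#' Coupling function under a tonic stimulus, with attractor census
#'
#' @param rnn rank-2 network
#' @param stim_id stimulus channel (1-based)
#' @param s tonic amplitude
#' @param ... passed to [extract_coupling()]
#' @return a `coupling_grid` with an attached `census` element (from
#'   [phase_attractor_census()])
#' @export
coupling_under_stimulus <- function(rnn, stim_id, s, ...) {
  n_stim <- sum(rnn$channels$kind == "stim")
  stim <- numeric(n_stim); stim[stim_id] <- s
  cg <- extract_coupling(rnn, stim = stim, ...)
  cg$census <- phase_attractor_census(cg)
  cg
}
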