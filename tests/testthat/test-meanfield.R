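# Gaussian-mixture connectivity: gain, mean-field equations, sampling,
# designed presets, mixture fitting.

test_that("analytic gain: exact endpoints, monotone, Monte-Carlo oracle", {
  expect_equal(mf_gain(0), 1)
  expect_lt(mf_gain(4), mf_gain(1))
  expect_error(mf_gain(-1), "nonnegative")
  set.seed(123)
  z <- rnorm(1e6)
  # exact approximation error of the closed form peaks at 0.0209
  # (delta = 0.5, by quadrature); allow that plus Monte-Carlo noise
  for (delta in c(0.5, 1, 2, 5)) {
    mc <- mean(1 / cosh(delta * z)^2)     # E[tanh'(delta z)]
    expect_lt(abs(mf_gain(delta^2) - mc), 0.022)
  }
  # and the closed form is exact against quadrature to its known bias
  for (delta in c(0.5, 1, 2, 5)) {
    ex <- integrate(function(z) (1 / cosh(delta * z)^2) * dnorm(z),
                    -Inf, Inf, rel.tol = 1e-10)$value
    expect_lt(abs(mf_gain(delta^2) - ex), 0.021)
  }
})

test_that("mean-field RHS: pure decay and rigid rotation oracles", {
  channels <- data.frame(name = "osc", kind = "osc", phase = 0)
  vars <- c("osc", "n1", "n2", "m1", "m2", "w")
  S0 <- matrix(0, 6, 6, dimnames = list(vars, vars))
  diag(S0) <- c(1, 1, 1, 1, 1, 1)
  mix0 <- mixture_connectivity(1, list(S0), channels, rank = 2)
  r0 <- meanfield_rhs(mix0, c(0.7, -0.3), 0)
  expect_equal(r0$dkappa, -c(0.7, -0.3) / 20, tolerance = 1e-12)

  # skew-symmetric single population: angular velocity = sigma_n1m2 * gain
  S <- S0
  S["m1", "n1"] <- S["n1", "m1"] <- 2
  S["m2", "n2"] <- S["n2", "m2"] <- 2
  S["m1", "n2"] <- S["n2", "m1"] <- 1.5
  S["m2", "n1"] <- S["n1", "m2"] <- -1.5
  S["n1", "n1"] <- S["n2", "n2"] <- 12
  mix <- mixture_connectivity(1, list(S), channels, rank = 2)
  r <- 0.8
  kap <- r * c(cos(0.4), sin(0.4))
  rhs <- meanfield_rhs(mix, kap, 0)
  G <- mf_gain(r^2)   # Delta^2 = sigma_m^2 r^2 with sigma_m^2 = 1
  # tau * dphi/dt = (k1 dk2 - k2 dk1) tau / r^2 = sigma_m1n2 * gain
  tau_dphi <- (kap[1] * rhs$dkappa[2] - kap[2] * rhs$dkappa[1]) * 20 / r^2
  expect_equal(tau_dphi, 1.5 * G, tolerance = 1e-12)
  # radial part: tau r'/r = -1 + sigma_mn * gain
  tau_dr <- (kap[1] * rhs$dkappa[1] + kap[2] * rhs$dkappa[2]) * 20 / r^2
  expect_equal(tau_dr, -1 + 2 * G, tolerance = 1e-12)
})

test_that("total phase velocity is the weighted sum of population
           contributions", {
  mix <- design_two_stim()
  kap <- c(0.9, -0.4)
  v <- c(0.5, 0, 0)
  rhs <- meanfield_rhs(mix, kap, v)
  total <- -kap + rowSums(rhs$per_pop)
  expect_equal(rhs$dkappa, total / 20, tolerance = 1e-12)
  r2 <- sum(kap^2)
  dphi_total <- (kap[1] * rhs$dkappa[2] - kap[2] * rhs$dkappa[1]) / r2
  per <- apply(rhs$per_pop, 2, function(p)
    (kap[1] * p[2] - kap[2] * p[1]) / r2 / 20)
  leak <- 0  # -kappa contributes nothing to the phase velocity
  expect_equal(dphi_total, sum(per) + leak, tolerance = 1e-12)
})

test_that("sampled networks reproduce the component covariances", {
  mix <- design_two_stim()
  net <- sample_network(mix, 4096, seed = 31)
  pop <- attr(net, "population")
  expect_equal(as.numeric(table(pop)), round(mix$weights * 4096))
  Y <- cbind(net$I, net$n, net$m, net$w)
  ix <- oscmem:::mix_idx(mix)
  for (l in seq_along(mix$weights)) {
    sub <- Y[pop == l, ]
    emp <- cov(sub)
    S <- mix$covs[[l]]
    npop <- nrow(sub)
    # every entry within ~3 standard errors of its target; the absolute
    # floor absorbs the 1e-10 jitter used for Cholesky of singular blocks
    se <- sqrt((outer(diag(S), diag(S)) + S^2) / npop)
    expect_true(all(abs(emp - S) <= 3.5 * se + 1e-4))
  }
  expect_error(sample_network(mix, 20, seed = 1), "too small")
  # single-population edge case
  single <- mixture_connectivity(1, mix$covs[1], mix$channels, rank = 2)
  net1 <- sample_network(single, 256, seed = 32)
  expect_equal(attr(net1, "population"), rep(1L, 256))
})

test_that("two-stimulus design: bistable pi-apart cycles, saturation,
           steering", {
  mix <- design_two_stim()
  f1 <- mf_field(mix, A = 1)
  fps <- Filter(function(f) f$stable, find_fixed_points(f1,
                                                        forward_periods = 80))
  expect_length(fps, 2)
  phs <- vapply(fps, function(f) atan2(f$kappa[2], f$kappa[1]), 0)
  expect_lt(abs(abs(oscmem:::circ_diff(phs[1], phs[2])) - pi), 0.05)
  expect_true(all(vapply(fps, function(f) f$max_mult, 0) < 1))

  # saturating stimulus: coupling population gain < 0.1, one attractor
  fa <- mf_field(mix, A = 1, stim = c(1, 0))
  va <- oscmem:::mf_v_at(fa, pi / 3)
  gains <- meanfield_rhs(mix, fps[[1]]$kappa, va)$gains
  expect_lt(gains[2], 0.1)
  fpa <- Filter(function(f) f$stable,
                find_fixed_points(fa, forward_periods = 80))
  expect_length(fpa, 1)

  # steering: tonic a (b) then release ends in the a- (b-) cycle from all
  # of 8 initial phases
  r0 <- sqrt(sum(fps[[1]]$kappa^2))
  ang <- seq(0, 2 * pi, length.out = 9)[-9]
  starts <- rbind(r0 * cos(ang), r0 * sin(ang))
  fb <- mf_field(mix, A = 1, stim = c(0, 1))
  mid_a <- oscmem:::mf_flow(fa, starts, 0, 20)$kappa
  fin_a <- oscmem:::mf_flow(f1, mid_a, 0, 60)$kappa
  mid_b <- oscmem:::mf_flow(fb, starts, 0, 20)$kappa
  fin_b <- oscmem:::mf_flow(f1, mid_b, 0, 60)$kappa
  ph_a <- atan2(fin_a[2, ], fin_a[1, ])
  ph_b <- atan2(fin_b[2, ], fin_b[1, ])
  expect_lt(max(abs(oscmem:::circ_diff(ph_a, ph_a[1]))), 0.02)
  expect_lt(max(abs(oscmem:::circ_diff(ph_b, ph_b[1]))), 0.02)
  expect_gt(abs(oscmem:::circ_diff(ph_a[1], ph_b[1])), 2.5)
})

test_that("rank-1 rate-coding design: three stable zeros, steering,
           anti-phase output", {
  mix <- design_rate_coding_rank1()
  z <- mf_zeros_1d(mix)
  expect_equal(sum(z$stable), 3)
  expect_equal(sum(!z$stable), 2)
  expect_lt(min(abs(z$kappa[z$stable])), 1e-8)   # one stable zero at 0
  kstar <- max(z$kappa[z$stable])
  expect_gt(kstar, 0.5)

  f0 <- mf_field(mix, A = 1)
  # the reference drive shifts the outer fixed point slightly; settle it
  kstar_drv <- abs(oscmem:::mf_flow(f0, matrix(kstar, 1), 0, 20)$kappa)
  fa <- mf_field(mix, A = 1, stim = c(1, 0))
  fb <- mf_field(mix, A = 1, stim = c(0, 1))
  for (k0 in c(0.3, kstar, -kstar, 0.05)) {
    # 0.15 s stimulus (1.2 reference periods) then free evolution
    fin_a <- oscmem:::mf_flow(f0, oscmem:::mf_flow(fa, matrix(k0, 1), 0,
                                                   1.2)$kappa, 0, 20)$kappa
    fin_b <- oscmem:::mf_flow(f0, oscmem:::mf_flow(fb, matrix(k0, 1), 0,
                                                   1.2)$kappa, 0, 20)$kappa
    expect_lt(abs(fin_a), 1e-3)
    expect_lt(abs(abs(fin_b) - kstar_drv), 1e-3)  # either outer zero
  }
  # in-phase at 0 vs anti-phase at kappa*: tanh readout flips sign
  th <- seq(0, 2 * pi, length.out = 33)[-33]
  v_at <- function(t) oscmem:::mf_v_at(f0, t)
  rr0 <- vapply(th, function(t) mf_readout(mix, 0, v_at(t)), 0)
  rr1 <- vapply(th, function(t) mf_readout(mix, kstar, v_at(t)), 0)
  expect_lt(cor(rr0, rr1), -0.99)
})

test_that("four-stimulus design: four cycles, stimulus-selective collapse,
           cos(4 phi)-type coupling", {
  mix <- design_four_stim()
  f1 <- mf_field(mix, A = 1)
  ang <- seq(0, 2 * pi, length.out = 17)[-17]
  out <- oscmem:::mf_flow(f1, rbind(cos(ang), sin(ang)), 0, 80)
  k2 <- oscmem:::mf_flow(f1, out$kappa, 0, 1)$kappa
  expect_lt(max(sqrt(colSums((k2 - out$kappa)^2))), 1e-2)
  ph <- atan2(out$kappa[2, ], out$kappa[1, ])
  cl <- oscmem:::unique_phases(ph, merge_tol = 0.3)
  expect_length(cl, 4)
  seps <- sort(diff(sort(cl)))
  expect_lt(max(abs(seps - pi / 2)), 0.1)   # quarter-spaced

  # stimulus k collapses to a single attractor, selecting cycle k
  r0 <- mean(sqrt(colSums(out$kappa^2)))
  sel <- numeric(4)
  for (k in 1:4) {
    st <- numeric(4); st[k] <- 1
    fk <- mf_field(mix, A = 1, stim = st)
    mid <- oscmem:::mf_flow(fk, rbind(r0 * cos(ang[c(1, 5, 9, 13)]),
                                      r0 * sin(ang[c(1, 5, 9, 13)])),
                            0, 25)$kappa
    fin <- oscmem:::mf_flow(f1, mid, 0, 60)$kappa
    phk <- atan2(fin[2, ], fin[1, ])
    expect_lt(max(abs(oscmem:::circ_diff(phk, phk[1]))), 0.05)
    sel[k] <- phk[1]
  }
  expect_length(oscmem:::unique_phases(sel, 0.3), 4)  # all four selectable

  # higher-frequency coupling: 4-phi harmonic of the averaged coupling
  # exceeds the 2-phi harmonic (the cos(2 phi) terms cancel by design)
  net <- canonicalize(sample_network(mix, 4096, seed = 33))
  cg <- extract_coupling(net, r = r0)
  gphi <- colMeans(cg$g)         # g averaged over theta, as function of phi
  ph_grid <- cg$phi_grid
  h2 <- Mod(mean(gphi * exp(-2i * ph_grid)))
  h4 <- Mod(mean(gphi * exp(-4i * ph_grid)))
  expect_gt(h4, h2)
})

test_that("phase-precession design: locked phase moves monotonically and
           continuously with position, quarter-period overall", {
  mix <- design_phase_precession()
  svals <- seq(0, 1, by = 0.25)
  locked <- vapply(svals, function(s) {
    fs <- precession_field(mix, s)
    ang <- seq(0, 2 * pi, length.out = 9)[-9]
    burn <- oscmem:::mf_flow(fs, rbind(cos(ang), sin(ang)), 0, 60)
    post <- oscmem:::mf_flow(fs, burn$kappa, 0, 10)
    expect_lt(max(abs(post$winding / (2 * pi) / 10 - 1)), 5e-3)  # locked
    ph <- atan2(post$kappa[2, ], post$kappa[1, ])
    expect_lt(max(abs(oscmem:::circ_diff(ph, ph[1]))), 0.05)     # unique
    ph[1]
  }, 0)
  d <- oscmem:::circ_diff(locked[-1], locked[-5])
  expect_true(all(d < 0) || all(d > 0))          # monotone
  expect_lt(max(abs(d)), 0.5)                    # continuous steps
  total <- abs(sum(d))
  expect_lt(abs(total - pi / 2), 0.6)            # ~quarter period overall

  # s = 0 and s = 1 coupling functions are quarter-period translates of
  # each other in the phase difference psi = phi - theta (the resonant,
  # theta-averaged profile Gamma(psi))
  n0 <- canonicalize(sample_network(mix, 4096, seed = 34))
  cg0 <- extract_coupling(n0, stim = c(sin(0), cos(0)), r = 1)
  cg1 <- extract_coupling(n0, stim = c(sin(pi / 2), cos(pi / 2)), r = 1)
  gamma_profile <- function(cg) {
    n <- length(cg$theta_grid)
    vapply(seq_len(n), function(j)
      mean(cg$g[cbind(seq_len(n), 1 + (seq_len(n) + j - 2) %% n)]), 0)
  }
  g0 <- gamma_profile(cg0); g1 <- gamma_profile(cg1)
  # the per-network extraction noise is common to both conditions, so the
  # translation is read off the fundamental harmonic's phase
  psi <- cg0$phi_grid
  shift <- oscmem:::circ_diff(Arg(mean(g1 * exp(-1i * psi))),
                              Arg(mean(g0 * exp(-1i * psi))))
  expect_lt(abs(abs(shift) - pi / 2), 0.6)
})

test_that("mixture fitting recovers a known mixture and shrinks means", {
  mix <- design_two_stim()
  net <- sample_network(mix, 3000, seed = 35)
  fits <- fit_mixture(net, L_range = 3, seed = 36, n_resample = 3,
                      n_trials = 16)
  fit <- fits[["3"]]
  expect_false(is.null(fit))
  # strong zero-mean prior: component means nearly zero
  expect_lt(max(abs(fit$means)), 1e-2)
  # weights recovered up to permutation
  expect_equal(sort(fit$mixture$weights), sort(mix$weights),
               tolerance = 0.05)
  # covariances recovered up to permutation: greedy matching by Frobenius
  # distance (the two coupling populations share the same weight)
  taken <- logical(3)
  for (i in 1:3) {
    S_t <- mix$covs[[i]]
    d <- vapply(1:3, function(j)
      if (taken[j]) Inf else norm(fit$mixture$covs[[j]] - S_t, "F"), 0)
    j <- which.min(d)
    taken[j] <- TRUE
    expect_lt(max(abs(fit$mixture$covs[[j]] - S_t)) / max(abs(S_t)), 0.25)
    expect_lt(abs(fit$mixture$weights[j] - mix$weights[i]), 0.05)
  }
  expect_true(all(is.finite(fit$resample_loss)))
  expect_true(is.finite(fits$orig_loss))
})
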