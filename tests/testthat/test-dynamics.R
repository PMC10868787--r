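# Poincare maps, Floquet multipliers, scans, embeddings, coding metrics.

# field with the recurrence switched off: tau k' = -k + alpha A sin(theta),
# whose return map and monodromy are known in closed form
linear_field <- function(N = 32, seed = 42, A = 1, freq = 8) {
  rnn <- tiny_rnn(N, seed)
  rnn$n[] <- 0
  kappa_field(rnn, A, freq)  # tiny_rnn is already canonical
}

test_that("Poincare map matches the closed-form affine solution of the
           driven linear system", {
  f <- linear_field()
  al <- f$alpha[, 1]
  tau <- f$tau; om <- f$omega
  Tp <- 2 * pi / om
  kp0 <- al / sqrt(1 + (om * tau)^2) * sin(0 - atan(om * tau))
  k0 <- c(0.3, -0.2)
  P <- poincare_map(f, k0)
  P_exact <- kp0 + exp(-Tp / tau) * (k0 - kp0)
  expect_lt(max(abs(P - P_exact)), 1e-6)
  # flow composition: applying the map twice = one two-period map
  P2a <- poincare_map(f, poincare_map(f, k0))
  P2b <- poincare_map(f, k0, n_periods = 2)
  expect_lt(max(abs(P2a - P2b)), 1e-10)
})

test_that("monodromy multipliers: exact linear value and FD cross-check", {
  f <- linear_field()
  tau <- f$tau; Tp <- 2 * pi / f$omega
  al <- f$alpha[, 1]
  kp0 <- al / sqrt(1 + (f$omega * tau)^2) * sin(0 - atan(f$omega * tau))
  lam <- floquet_multipliers(f, kp0)
  expect_lt(max(abs(Mod(lam) - exp(-Tp / tau))), 1e-9)

  # nonlinear field: variational equation vs finite differences of the map
  fn <- kappa_field(tiny_rnn(48, 15), 1, 8)
  kap <- c(0.4, 0.1)
  pj <- oscmem:::poincare_jacobian(fn, kap)
  eps <- 1e-6
  Mfd <- matrix(0, 2, 2)
  for (j in 1:2) {
    e <- c(0, 0); e[j] <- eps
    Mfd[, j] <- (poincare_map(fn, kap + e) - poincare_map(fn, kap - e)) /
      (2 * eps)
  }
  expect_lt(max(abs(pj$M - Mfd)) / max(abs(Mfd)), 1e-3)
  lam1 <- eigen(pj$M, only.values = TRUE)$values
  lam2 <- eigen(Mfd, only.values = TRUE)$values
  expect_lt(max(abs(sort(Mod(lam1)) - sort(Mod(lam2)))), 1e-3)
})

test_that("pure-decay field has a single fixed point at the origin", {
  f <- linear_field(A = 0)
  fps <- find_fixed_points(f, forward_periods = 20)
  expect_length(fps, 1)
  expect_lt(sqrt(sum(fps[[1]]$kappa^2)), 1e-6)
  expect_true(fps[[1]]$stable)
  # fixed points drift < tol under step refinement
  f2 <- f; f2$h <- 0.25
  fps2 <- find_fixed_points(f2, forward_periods = 20)
  expect_lt(sqrt(sum((fps2[[1]]$kappa - fps[[1]]$kappa)^2)), 1e-6)
})

test_that("stability labels agree with forward iteration", {
  # designed mean-field two-stimulus model: both labelled-stable cycles are
  # recovered by forward iteration from a 1e-3 perturbation
  mix <- design_two_stim()
  f1 <- mf_field(mix, A = 1)
  fps <- find_fixed_points(f1, forward_periods = 60)
  st <- Filter(function(f) f$stable, fps)
  expect_gte(length(st), 2)
  for (fp in st) {
    pert <- fp$kappa + c(1e-3, -1e-3) / sqrt(2)
    back <- oscmem:::mf_map(f1, pert, n_periods = 20)
    expect_lt(sqrt(sum((as.numeric(back) - fp$kappa)^2)), 1e-4)
  }
})

test_that("torus embedding is correct and injective when the bound holds", {
  th <- seq(0, 2 * pi, length.out = 40)
  z <- torus_embed(rbind(0 * th, 0 * th), th, r_tilde = 2)
  expect_true(all(abs(sqrt(z[, 1]^2 + z[, 2]^2) - 2) < 1e-12))
  expect_true(all(z[, 3] == 0))
  # z-coordinate is always kappa2
  kap <- rbind(runif(40, -1, 1), runif(40, -1, 1))
  z2 <- torus_embed(kap, th, r_tilde = 2)
  expect_equal(z2[, 3], kap[2, ])
  # brute-force injectivity on a sampled grid
  g <- as.matrix(expand.grid(k1 = seq(-1, 1, 0.5), k2 = seq(-1, 1, 0.5),
                             th = seq(0, 2 * pi - 0.4, 0.4)))
  zz <- torus_embed(t(g[, 1:2]), g[, 3], r_tilde = 1.5)
  d <- as.matrix(dist(zz))
  diag(d) <- Inf
  expect_gt(min(d), 1e-6)
  expect_warning(torus_embed(rbind(2, 0), 0, r_tilde = 1.5), "self-intersect")
})

test_that("coding metrics separate phase codes from rate codes", {
  th <- seq(0, 6 * pi, length.out = 300)  # 3 cycles
  base <- outer(seq(0.2, 1, length.out = 10), th, function(a, t) a * sin(t))
  # identical oscillations shifted by pi between conditions
  shifted <- outer(seq(0.2, 1, length.out = 10), th,
                   function(a, t) a * sin(t + pi))
  cm <- coding_metrics_rates(base, shifted, th, th)
  expect_equal(cm$phase_metric, pi, tolerance = 1e-6)
  expect_lt(cm$rate_metric, 1e-10)
  # condition-dependent offsets, same phase
  cm2 <- coding_metrics_rates(base + 1, base - 1, th, th)
  expect_lt(cm2$phase_metric, 1e-6)
  expect_gt(cm2$rate_metric, 0.3)
  expect_error(coding_metrics_rates(base[, 1:50], shifted[, 1:50],
                                    th[1:50], th[1:50]), "cycles")
})

test_that("PCA basis: exact for rank-2 input, orthonormal in general", {
  rnn <- tiny_rnn(48, 16)
  trials <- sine_trials(2, seed0 = 31)
  pb <- pca_basis_fullrank(rnn, trials)
  expect_gt(pb$var_drive, 1 - 1e-10)       # drive lies in span(m1, m2)
  B <- cbind(pb$u1, pb$u2, pb$i_perp)
  expect_lt(max(abs(crossprod(B) - diag(3))), 1e-10)
  # full-rank network: basis still orthonormal, variance in (0, 1]
  fr <- init_rnn(48, "full", init_spec("fullrank"), seed = 17)
  pb2 <- pca_basis_fullrank(fr, trials)
  B2 <- cbind(pb2$u1, pb2$u2, pb2$i_perp)
  expect_lt(max(abs(crossprod(B2) - diag(3))), 1e-10)
  expect_gt(pb2$var_explained, 0)
  expect_lte(pb2$var_explained, 1)
})

test_that("full-rank training runs and reduces the loss", {
  fr <- init_rnn(32, "full", init_spec("fullrank"), seed = 18)
  trials <- sine_trials(16, seed0 = 41)
  fit <- train_rnn(fr, trials,
                   train_config(epochs = 4, batch = 8, lr = 0.001,
                                regularize_rates = TRUE), seed = 19)
  expect_lt(tail(fit$history$train, 1), fit$history$train[1])
  expect_true(is_fullrank <- identical(fit$rnn$rank, "full"))
})
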