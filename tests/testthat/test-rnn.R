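# Network initialization, integration, loss, training machinery.

test_that("initial covariances match the specification", {
  rnn <- init_rnn(4096, 2, init_spec(), seed = 3)
  # sample covariance within 3 standard errors (SE ~ 1/sqrt(N) here)
  se <- sqrt((1 + 0.6^2) / 4096)
  expect_lt(abs(cov(rnn$m[, 1], rnn$n[, 1]) - 0.6), 3 * se)
  expect_lt(abs(cov(rnn$m[, 2], rnn$n[, 2]) - 0.6), 3 * se)
  expect_lt(abs(cov(rnn$m[, 1], rnn$n[, 2])), 3 / sqrt(4096))
  se_w <- 16 * sqrt(2 / 4095)
  expect_lt(abs(var(rnn$w) - 16), 3 * se_w)
})

test_that("oscillatory initialization yields an unstable complex pair", {
  rnn <- init_rnn(512, 2, init_spec("oscillatory"), seed = 4)
  ev <- eigen(rnn_J(rnn), only.values = TRUE)$values
  lead <- ev[which.max(Re(ev))]
  expect_gt(Re(lead), 1)
  expect_gt(abs(Im(lead)), 0.1)
})

test_that("init validates covariance structure", {
  expect_error(init_rnn(32, 2, init_spec(cov_mn = 1.5), seed = 1), "PSD")
  expect_error(init_rnn(32, 1, init_spec("oscillatory"), seed = 1),
               "rank >= 2")
})

test_that("zero input and zero state is a fixed point of the update", {
  rnn <- tiny_rnn()
  trial <- list(inputs = matrix(0, 100, 3), h = 2)
  sim <- simulate_rnn(rnn, trial)
  expect_true(all(sim$x == 0))
  expect_true(all(sim$r == 0))
})

test_that("factored low-rank recurrence equals the dense-J simulation", {
  rnn <- tiny_rnn(N = 16, seed = 5)
  dense <- rnn
  dense$rank <- "full"
  dense$J <- rnn_J(rnn)
  tr <- sine_trials(1, stim = 1, seed0 = 7)[[1]]
  s1 <- simulate_rnn(rnn, tr)
  s2 <- simulate_rnn(dense, tr)
  expect_lt(max(abs(s1$x - s2$x)), 1e-8)
  expect_lt(max(abs(s1$r - s2$r)), 1e-8)
})

test_that("kappa projections match direct integration of the reduced
           2-D system (same discretization, dynamic filtered input)", {
  # independent oracle: Euler-integrate the nonautonomous reduced system
  # (kappa1, kappa2 and the filtered input v as its own leaky state) in R
  rnn <- tiny_rnn(N = 48, seed = 6)
  h <- 2; tau <- rnn$tau
  ref <- pure_sine(8, 1, 0, 1, 500)
  u <- ref$u
  Ti <- length(u)
  inputs <- cbind(u, 0, 0)
  sim <- simulate_rnn(rnn, list(inputs = inputs, h = h))
  kap_full <- oscmem:::kappa_project(rnn, sim$x)
  al <- attr(rnn, "alpha")[, 1]
  Ip <- attr(rnn, "I_perp")[, 1]
  kap <- c(0, 0); v <- 0
  kap_red <- matrix(0, 2, Ti)
  for (k in seq_len(Ti - 1)) {
    kap_red[, k] <- kap
    x <- rnn$m %*% kap + Ip * v
    dk <- (-kap + crossprod(rnn$n, tanh(x)) / rnn$N + al * u[k]) / tau
    v <- v + (h / tau) * (u[k] - v)
    kap <- kap + h * dk
  }
  kap_red[, Ti] <- kap
  expect_lt(max(abs(kap_full - kap_red)), 1e-6)
})

test_that("halving the step shrinks the Euler error roughly linearly", {
  rnn <- tiny_rnn(N = 24, seed = 8)
  mk <- function(h) {
    ref <- pure_sine(8, 1, 0, 0.4, 1000 / h)
    list(inputs = cbind(ref$u, 0, 0), h = h)
  }
  xf <- function(h) simulate_rnn(rnn, mk(h))$x_final
  e1 <- sqrt(sum((xf(2) - xf(0.125))^2))
  e2 <- sqrt(sum((xf(1) - xf(0.125))^2))
  e3 <- sqrt(sum((xf(0.5) - xf(0.125))^2))
  expect_gt(e1 / e2, 1.6); expect_lt(e1 / e2, 2.6)
  expect_gt(e2 / e3, 1.5); expect_lt(e2 / e3, 3.5)
})

test_that("loss and regularizer definitions", {
  tr <- sine_trials(1, stim = 1, seed0 = 11)[[1]]
  expect_equal(rnn_loss(tr$target, tr), 0)
  expect_equal(rnn_loss(tr$target + 1, tr), 1)
  x <- matrix(rnorm(5 * length(tr$target)), 5)
  x0 <- x - rowMeans(x[, tr$mask, drop = FALSE])  # zero masked-mean rows
  expect_equal(rnn_regularizer(x0, tr), 0)
  expect_gt(rnn_regularizer(x + 2, tr), 0)
  bad <- tr; bad$mask[] <- FALSE
  expect_error(rnn_loss(tr$target, bad), "mask")
})

test_that("analytic BPTT gradients match central finite differences", {
  set.seed(2)
  N <- 8; Tn <- 20; B <- 3
  rnn <- init_rnn(N, 2, init_spec(), seed = 7)
  inputs <- array(rnorm(3 * B * Tn), c(3, B, Tn))
  target <- matrix(rnorm(Tn * B), Tn, B)
  mask <- matrix(0, Tn, B); mask[8:Tn, ] <- 1
  args <- function(r) list(r$m, r$n, matrix(0, 1, 1), FALSE, r$I, r$w,
                           r$readout_scale, 0L, inputs, target, mask,
                           2, 20, 0.7, 0, 0L)
  obj <- function(r) do.call(oscmem:::cpp_rnn_bptt, c(args(r), FALSE))$objective
  out <- do.call(oscmem:::cpp_rnn_bptt, c(args(rnn), TRUE))
  eps <- 1e-6
  worst <- 0
  for (k in 1:12) {
    p <- sample(c("m", "n", "I"), 1)
    i <- sample(length(rnn[[p]]), 1)
    rp <- rnn; rp[[p]][i] <- rp[[p]][i] + eps
    rm_ <- rnn; rm_[[p]][i] <- rm_[[p]][i] - eps
    fd <- (obj(rp) - obj(rm_)) / (2 * eps)
    g <- out[[paste0("g", p)]][i]
    worst <- max(worst, abs(fd - g) / max(abs(fd), 1e-8))
  }
  expect_lt(worst, 1e-4)
  # readout-scale gradient
  rp <- rnn; rp$readout_scale <- rp$readout_scale + eps
  rm_ <- rnn; rm_$readout_scale <- rm_$readout_scale - eps
  fd <- (obj(rp) - obj(rm_)) / (2 * eps)
  expect_lt(abs(fd - out$gscale) / abs(fd), 1e-4)
})

test_that("zero epochs leaves parameters unchanged; training is
           reproducible and only trains what it should", {
  rnn <- init_rnn(24, 2, init_spec(), seed = 9)
  trials <- sine_trials(8, seed0 = 21)
  f0 <- train_rnn(rnn, trials, train_config(epochs = 0), seed = 1)
  expect_identical(f0$rnn$m, rnn$m)
  expect_identical(f0$rnn$I, rnn$I)
  f1 <- train_rnn(rnn, trials, train_config(epochs = 2, batch = 4), seed = 3)
  f2 <- train_rnn(rnn, trials, train_config(epochs = 2, batch = 4), seed = 3)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$rnn$m, f2$rnn$m)
  # readout weights themselves are frozen; their scalar moves
  expect_identical(f1$rnn$w, rnn$w)
  expect_false(identical(f1$rnn$readout_scale, rnn$readout_scale))
  # loss decreases over epochs on this easy problem
  f3 <- train_rnn(rnn, trials, train_config(epochs = 6, batch = 4), seed = 3)
  expect_lt(tail(f3$history$train, 1), f3$history$train[1])
})

test_that("canonicalize orthogonalizes m, preserves J, splits the input", {
  rnn <- init_rnn(64, 2, init_spec(), seed = 10)
  J0 <- rnn_J(rnn)
  can <- canonicalize(rnn)
  expect_lt(abs(sum(can$m[, 1] * can$m[, 2])), 1e-9 * sqrt(sum(can$m^2)))
  expect_lt(norm(rnn_J(can) - J0, "F") / norm(J0, "F"), 1e-10)
  al <- attr(can, "alpha"); Ip <- attr(can, "I_perp")
  expect_lt(max(abs(crossprod(can$m, Ip))), 1e-9)
  expect_lt(max(abs(can$m %*% al + Ip - rnn$I)), 1e-9)
  # idempotent up to sign convention: J unchanged again
  can2 <- canonicalize(can)
  expect_lt(norm(rnn_J(can2) - J0, "F") / norm(J0, "F"), 1e-10)
})
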