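# Low-rank (and full-rank) rate networks:
#   tau dx/dt = -x + J tanh(x) + I u(t) + xi(t),  J = (1/N) sum_i m_i n_i'
# with Euler-Maruyama integration, backpropagation-through-time training,
# and canonicalization (orthogonal m's, input split into parallel and
# orthogonal parts).

#' Initialization specification for network weights
#'
#' Entries of the connectivity vectors are drawn jointly Gaussian with zero
#' mean. The default mode uses identity covariance except
#' `cov(m_i, n_i) = 0.6` and `var(w) = 16`. The oscillatory mode additionally
#' correlates the m/n pairs so that the 2x2 overlap matrix
#' `[cov(n_i, m_j)]` has a complex-conjugate eigenvalue pair with real part
#' above 1, giving spontaneous oscillations at initialization (rank >= 2
#' only). The full-rank mode draws dense `J` entries i.i.d. `N(0, g^2/N)`.
#'
#' @param mode `"default"`, `"oscillatory"` or `"fullrank"`
#' @param cov_mn covariance between `m_i` and `n_i` (default 0.6)
#' @param var_w variance of the readout weights (default 16)
#' @param g full-rank coupling strength (default 0.6)
#' @param osc_eig complex target eigenvalue for oscillatory mode
#'   (default `1.2 + 1i`); its conjugate partner is implied
#' @param var_n_osc variance of the n-vectors in oscillatory mode (must be
#'   large enough to keep the joint covariance positive semidefinite)
#' @return an object of class `init_spec`
#' @export
init_spec <- function(mode = c("default", "oscillatory", "fullrank"),
                      cov_mn = 0.6, var_w = 16, g = 0.6,
                      osc_eig = complex(real = 1.2, imaginary = 1.0),
                      var_n_osc = 2.5) {
  mode <- match.arg(mode)
  structure(list(mode = mode, cov_mn = cov_mn, var_w = var_w, g = g,
                 osc_eig = osc_eig, var_n_osc = var_n_osc),
            class = "init_spec")
}

# Joint covariance of (m_1..m_R, n_1..n_R) under the spec.
init_cov_mn <- function(spec, rank) {
  S <- diag(2 * rank)
  for (i in seq_len(rank)) S[i, rank + i] <- S[rank + i, i] <- spec$cov_mn
  if (spec$mode == "oscillatory") {
    if (rank < 2) stop("oscillatory initialization requires rank >= 2")
    a <- Re(spec$osc_eig); b <- Im(spec$osc_eig)
    for (i in 1:2) S[rank + i, rank + i] <- spec$var_n_osc
    # overlap matrix [cov(n_i, m_j)]_{ij} = [[a, -b], [b, a]]
    S[rank + 1, 1] <- S[1, rank + 1] <- a
    S[rank + 2, 2] <- S[2, rank + 2] <- a
    S[rank + 1, 2] <- S[2, rank + 1] <- -b
    S[rank + 2, 1] <- S[1, rank + 2] <- b
  }
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) stop("initialization covariance is not PSD")
  S
}

#' Initialize a network
#'
#' @param N number of units
#' @param rank connectivity rank: an integer (1, 2, 3, ...) or `"full"`
#' @param spec an [init_spec()]
#' @param seed integer seed
#' @param n_stim number of stimulus input channels (default 2)
#' @param osc_channels number of oscillatory reference channels (default 1)
#' @param readout_mode `"linear"` (readout of x) or `"tanh"` (readout of
#'   rates)
#' @param tau unit time constant in ms (default 20)
#' @param sigma_noise state noise SD (default 0)
#' @return an object of class `lowrank_rnn`
#' @export
init_rnn <- function(N, rank = 2, spec = init_spec(), seed, n_stim = 2,
                     osc_channels = 1, readout_mode = c("linear", "tanh"),
                     tau = 20, sigma_noise = 0) {
  readout_mode <- match.arg(readout_mode)
  if (missing(seed)) stop("an integer seed is required")
  set.seed(seed)
  fullrank <- identical(rank, "full") || (spec$mode == "fullrank")
  C <- osc_channels + n_stim
  I <- matrix(rnorm(N * C), N, C)
  w <- rnorm(N, sd = sqrt(spec$var_w))
  channels <- data.frame(
    name = c(paste0("osc", if (osc_channels > 1) seq_len(osc_channels) else ""),
             paste0("stim_", letters[seq_len(n_stim)])),
    kind = c(rep("osc", osc_channels), rep("stim", n_stim)),
    stringsAsFactors = FALSE)
  if (fullrank) {
    J <- matrix(rnorm(N * N, sd = spec$g / sqrt(N)), N, N)
    rnn <- list(N = N, rank = "full", m = NULL, n = NULL, J = J,
                I = I, channels = channels, w = w, readout_scale = 1,
                readout_mode = readout_mode, tau = tau,
                sigma_noise = sigma_noise)
  } else {
    S <- init_cov_mn(spec, rank)
    Z <- matrix(rnorm(N * 2 * rank), N, 2 * rank) %*%
      chol(S + diag(1e-12, nrow(S)))
    rnn <- list(N = N, rank = rank, m = Z[, seq_len(rank), drop = FALSE],
                n = Z[, rank + seq_len(rank), drop = FALSE], J = NULL,
                I = I, channels = channels, w = w, readout_scale = 1,
                readout_mode = readout_mode, tau = tau,
                sigma_noise = sigma_noise)
  }
  structure(rnn, class = "lowrank_rnn")
}

#' @export
print.lowrank_rnn <- function(x, ...) {
  cat(sprintf("<lowrank_rnn> N = %d, rank = %s, %d input channel(s), %s readout%s\n",
              x$N, as.character(x$rank), ncol(x$I), x$readout_mode,
              if (isTRUE(attr(x, "canonical"))) ", canonical" else ""))
  invisible(x)
}

is_fullrank <- function(rnn) identical(rnn$rank, "full")

#' Recurrent weight matrix of a network
#'
#' @param rnn a `lowrank_rnn`
#' @return the dense `N x N` matrix `J = (1/N) sum_i m_i n_i'` (or the stored
#'   dense matrix for full-rank networks)
#' @export
rnn_J <- function(rnn) {
  if (is_fullrank(rnn)) rnn$J else tcrossprod(rnn$m, rnn$n) / rnn$N
}

readout_mode_code <- function(rnn) if (rnn$readout_mode == "tanh") 1L else 0L

#' Simulate a network on one trial
#'
#' Euler-Maruyama integration of the network equations on the trial's input
#' time courses. The low-rank recurrence is evaluated in factored form
#' (two inner products, then an outer expansion); the dense matrix is never
#' materialized.
#'
#' @param rnn a `lowrank_rnn`
#' @param trial a `wm_trial` (or a list with an `inputs` matrix T x C)
#' @param h integration step ms (default: the trial's grid step)
#' @param x0 initial state (default 0)
#' @param noise_seed integer seed for the state noise; `NULL` disables noise
#'   regardless of `sigma_noise`
#' @param return_state keep the full state trajectory (N x T)
#' @return list with `x` (N x T or empty), `r` (readout), `x_final`
#' @export
simulate_rnn <- function(rnn, trial, h = NULL, x0 = NULL, noise_seed = NULL,
                         return_state = TRUE) {
  h <- h %||% trial$h %||% 2
  inputs <- t(trial$inputs)
  stopifnot(nrow(inputs) == ncol(rnn$I))
  x0 <- x0 %||% numeric(rnn$N)
  sigma <- if (is.null(noise_seed)) 0 else rnn$sigma_noise
  cpp_rnn_sim(rnn$m %||% matrix(0, rnn$N, 1), rnn$n %||% matrix(0, rnn$N, 1),
              rnn$J %||% matrix(0, 1, 1), is_fullrank(rnn),
              rnn$I, rnn$w, rnn$readout_scale, readout_mode_code(rnn),
              inputs, x0, h, rnn$tau, sigma, noise_seed %||% 0L,
              return_state)
}

#' Masked mean-squared-error task loss
#'
#' @param r readout time series
#' @param trial trial providing `target` and `mask`
#' @return mean over masked samples of `(r - target)^2`
#' @export
rnn_loss <- function(r, trial) {
  if (!any(trial$mask)) stop("empty loss mask")
  mean((r[trial$mask] - trial$target[trial$mask])^2)
}

#' Mean-rate regularizer
#'
#' Penalizes nonzero time-averaged activations over the masked (post-offset)
#' region: `(1/N) sum_i (mean_t x_i)^2`.
#'
#' @param x state trajectory, N x T
#' @param trial trial providing `mask`
#' @return scalar penalty
#' @export
rnn_regularizer <- function(x, trial) {
  if (!any(trial$mask)) stop("empty loss mask")
  xbar <- rowMeans(x[, trial$mask, drop = FALSE])
  sum(xbar^2) / nrow(x)
}

#' Training configuration
#'
#' @param epochs passes through the training set (default 50)
#' @param batch batch size (default 128)
#' @param lr Adam learning rate (default 0.01; use 0.001 for full-rank)
#' @param betas Adam decay rates (default `c(0.9, 0.999)`)
#' @param h integration step during training, ms (default 2)
#' @param regularize_rates add the mean-rate regularizer to the loss
#' @param reg_coef weight of the regularizer (default 1)
#' @param train_inputs,train_recurrent,train_scale which parameter groups to
#'   update (readout weights `w` themselves are always frozen; only the
#'   scalar multiplying them is trainable)
#' @return an object of class `train_config`
#' @export
train_config <- function(epochs = 50, batch = 128, lr = 0.01,
                         betas = c(0.9, 0.999), h = 2,
                         regularize_rates = FALSE, reg_coef = 1,
                         train_inputs = TRUE, train_recurrent = TRUE,
                         train_scale = TRUE) {
  structure(list(epochs = epochs, batch = batch, lr = lr, betas = betas,
                 eps = 1e-8, h = h, regularize_rates = regularize_rates,
                 reg_coef = reg_coef, train_inputs = train_inputs,
                 train_recurrent = train_recurrent,
                 train_scale = train_scale),
            class = "train_config")
}

# forward-only batched objective (no gradients)
batch_objective <- function(rnn, trials, h, reg_coef) {
  st <- stack_trials(trials)
  out <- cpp_rnn_bptt(rnn$m %||% matrix(0, rnn$N, 1),
                      rnn$n %||% matrix(0, rnn$N, 1),
                      rnn$J %||% matrix(0, 1, 1), is_fullrank(rnn),
                      rnn$I, rnn$w, rnn$readout_scale,
                      readout_mode_code(rnn), st$inputs, st$target, st$mask,
                      h, rnn$tau, reg_coef, 0, 0L, FALSE)
  c(loss = out$loss, reg = out$reg)
}

#' Train a network with backpropagation through time
#'
#' Minimizes the masked MSE (plus, optionally, the mean-rate regularizer)
#' with Adam over the input vectors, the connectivity vectors (or dense
#' `J`), and a scalar multiplying the frozen readout weights. Gradients are
#' obtained by backpropagation through the unrolled Euler-Maruyama update.
#'
#' @param rnn a `lowrank_rnn`
#' @param trials list of training trials (equal length)
#' @param cfg a [train_config()]
#' @param seed integer seed (batch shuffling and state noise)
#' @param val_trials optional validation trials; the validation loss is
#'   recorded each epoch
#' @param verbose print per-epoch losses
#' @return list with `rnn` (trained), `history` (data.frame epoch/train
#'   loss/val loss)
#' @export
train_rnn <- function(rnn, trials, cfg = train_config(), seed,
                      val_trials = NULL, verbose = FALSE) {
  if (missing(seed)) stop("an integer seed is required")
  set.seed(seed)
  fullrank <- is_fullrank(rnn)
  reg <- if (cfg$regularize_rates) cfg$reg_coef else 0
  pnames <- c("I", if (fullrank) "J" else c("m", "n"), "scale")
  adam <- lapply(pnames, function(p) list(m = 0, v = 0))
  names(adam) <- pnames
  t_step <- 0
  history <- data.frame(epoch = integer(), train = numeric(),
                        val = numeric())
  n <- length(trials)
  for (ep in seq_len(cfg$epochs)) {
    perm <- sample.int(n)
    nb <- ceiling(n / cfg$batch)
    ep_loss <- 0; ep_n <- 0
    for (bi in seq_len(nb)) {
      idx <- perm[((bi - 1) * cfg$batch + 1):min(bi * cfg$batch, n)]
      st <- stack_trials(trials[idx])
      noise_seed <- sample.int(.Machine$integer.max, 1)
      out <- cpp_rnn_bptt(rnn$m %||% matrix(0, rnn$N, 1),
                          rnn$n %||% matrix(0, rnn$N, 1),
                          rnn$J %||% matrix(0, 1, 1), fullrank,
                          rnn$I, rnn$w, rnn$readout_scale,
                          readout_mode_code(rnn), st$inputs, st$target,
                          st$mask, cfg$h, rnn$tau, reg, rnn$sigma_noise,
                          noise_seed, TRUE)
      if (!is.finite(out$objective)) stop("training diverged (non-finite loss)")
      grads <- list(I = out$gI,
                    scale = out$gscale)
      if (fullrank) grads$J <- out$gJ else { grads$m <- out$gm; grads$n <- out$gn }
      if (!cfg$train_inputs) grads$I[] <- 0
      if (!cfg$train_recurrent) {
        if (fullrank) grads$J[] <- 0 else { grads$m[] <- 0; grads$n[] <- 0 }
      }
      if (!cfg$train_scale) grads$scale <- 0
      t_step <- t_step + 1
      for (p in pnames) {
        g <- grads[[p]]
        a <- adam[[p]]
        a$m <- cfg$betas[1] * a$m + (1 - cfg$betas[1]) * g
        a$v <- cfg$betas[2] * a$v + (1 - cfg$betas[2]) * g^2
        adam[[p]] <- a
        mhat <- a$m / (1 - cfg$betas[1]^t_step)
        vhat <- a$v / (1 - cfg$betas[2]^t_step)
        step <- cfg$lr * mhat / (sqrt(vhat) + cfg$eps)
        if (p == "I") rnn$I <- rnn$I - step
        else if (p == "m") rnn$m <- rnn$m - step
        else if (p == "n") rnn$n <- rnn$n - step
        else if (p == "J") rnn$J <- rnn$J - step
        else rnn$readout_scale <- rnn$readout_scale - step
      }
      ep_loss <- ep_loss + out$loss * length(idx)
      ep_n <- ep_n + length(idx)
    }
    val <- NA_real_
    if (!is.null(val_trials))
      val <- batch_objective(rnn, val_trials, cfg$h, 0)[["loss"]]
    history <- rbind(history,
                     data.frame(epoch = ep, train = ep_loss / ep_n, val = val))
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %s", ep, ep_loss / ep_n,
                      ifelse(is.na(val), "-", sprintf("%.4f", val))))
  }
  attr(rnn, "canonical") <- NULL
  list(rnn = rnn, history = history)
}

#' Canonicalize a trained low-rank network
#'
#' Rewrites the connectivity so the m-vectors are mutually orthogonal
#' (balanced SVD factorization of `J`, which leaves `J` numerically
#' unchanged) and splits every input vector into components parallel and
#' orthogonal to the m-vectors:
#' `I_c = I_perp_c + sum_i m_i alpha_{i,c}` with `m_i' I_perp_c = 0`.
#'
#' @param rnn a `lowrank_rnn` with rank >= 1
#' @return the network with orthogonalized `m`, `n` and attributes `alpha`
#'   (rank x C), `I_perp` (N x C), `svals` (singular values of the factored
#'   core) and `canonical = TRUE`
#' @export
canonicalize <- function(rnn) {
  if (is_fullrank(rnn)) stop("canonicalize() requires a low-rank network")
  R <- rnn$rank
  qm <- qr(rnn$m); qn <- qr(rnn$n)
  core <- qr.R(qm) %*% t(qr.R(qn))
  sv <- svd(core)
  zero <- sv$d < 1e-12 * max(sv$d, 1)
  if (any(zero))
    warning("rank-deficient connectivity: near-zero singular value")
  # balanced factor scales; a zero singular direction keeps an orthonormal
  # m-column (so kappa coordinates stay defined) with a zero n-column
  scale_m <- sqrt(sv$d); scale_m[zero] <- 1
  scale_n <- sqrt(sv$d); scale_n[zero] <- 0
  m_new <- qr.Q(qm) %*% sv$u %*% diag(scale_m, R)
  n_new <- qr.Q(qn) %*% sv$v %*% diag(scale_n, R)
  # deterministic sign convention: align each new m-column with the old ones
  for (i in seq_len(R)) {
    s <- sign(sum(m_new[, i] * rnn$m[, min(i, ncol(rnn$m))]))
    if (s < 0) { m_new[, i] <- -m_new[, i]; n_new[, i] <- -n_new[, i] }
  }
  mm <- colSums(m_new^2)
  alpha <- crossprod(m_new, rnn$I) / mm          # R x C
  I_perp <- rnn$I - m_new %*% alpha
  rnn$m <- m_new; rnn$n <- n_new
  attr(rnn, "alpha") <- alpha
  attr(rnn, "I_perp") <- I_perp
  attr(rnn, "svals") <- sv$d
  attr(rnn, "canonical") <- TRUE
  rnn
}

# kappa projection of a state trajectory: kappa_i = m_i' x / (m_i' m_i)
kappa_project <- function(rnn, x) {
  stopifnot(isTRUE(attr(rnn, "canonical")))
  crossprod(rnn$m, x) / colSums(rnn$m^2)
}
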