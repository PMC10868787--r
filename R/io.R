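# Serialization: HDF5 for numeric artifacts (checkpoints, reference
# signals, trial batches), YAML for configurations, JSON manifests.

h5_write_list <- function(path, values) {
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  for (nm in names(values)) {
    v <- values[[nm]]
    if (is.null(v)) next
    rhdf5::h5write(v, path, nm)
  }
  rhdf5::h5closeAll()
  invisible(path)
}

#' Save / load a network checkpoint (HDF5)
#'
#' Stores connectivity vectors (or the dense matrix), input weights,
#' readout, channel metadata and scalars as named HDF5 datasets.
#'
#' @param rnn a `lowrank_rnn`
#' @param path file path
#' @return `save_rnn_h5`: the path, invisibly; `load_rnn_h5`: the network
#' @export
save_rnn_h5 <- function(rnn, path) {
  vals <- list(N = rnn$N,
               rank = if (is_fullrank(rnn)) -1L else as.integer(rnn$rank),
               m = rnn$m, n = rnn$n, J = rnn$J, I = rnn$I, w = rnn$w,
               readout_scale = rnn$readout_scale,
               readout_mode = rnn$readout_mode, tau = rnn$tau,
               sigma_noise = rnn$sigma_noise,
               channel_name = rnn$channels$name,
               channel_kind = rnn$channels$kind,
               channel_phase = rnn$channels$phase %||%
                 numeric(nrow(rnn$channels)))
  h5_write_list(path, vals)
}

#' @rdname save_rnn_h5
#' @export
load_rnn_h5 <- function(path) {
  g <- rhdf5::h5dump(path)
  rhdf5::h5closeAll()
  rank <- as.integer(g$rank)
  channels <- data.frame(name = as.character(g$channel_name),
                         kind = as.character(g$channel_kind),
                         phase = as.numeric(g$channel_phase),
                         stringsAsFactors = FALSE)
  structure(list(N = as.integer(g$N),
                 rank = if (rank < 0) "full" else rank,
                 m = g$m, n = g$n, J = g$J, I = g$I,
                 channels = channels, w = as.numeric(g$w),
                 readout_scale = as.numeric(g$readout_scale),
                 readout_mode = as.character(g$readout_mode),
                 tau = as.numeric(g$tau),
                 sigma_noise = as.numeric(g$sigma_noise)),
            class = "lowrank_rnn")
}

#' Save / load reference signals (HDF5)
#'
#' @param refs a [reference_signal()] or list of them
#' @param path file path
#' @return the path / list of `reference_signal`
#' @export
save_references_h5 <- function(refs, path) {
  if (inherits(refs, "reference_signal")) refs <- list(refs)
  vals <- list(n = length(refs))
  for (i in seq_along(refs)) {
    r <- refs[[i]]
    vals[[sprintf("ref%04d/u", i)]] <- r$u
    vals[[sprintf("ref%04d/theta", i)]] <- r$theta
    vals[[sprintf("ref%04d/sample_rate", i)]] <- r$sample_rate
    vals[[sprintf("ref%04d/dominant_freq", i)]] <- r$dominant_freq
    vals[[sprintf("ref%04d/source", i)]] <- r$source
  }
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(length(refs), path, "n")
  for (i in seq_along(refs)) {
    grp <- sprintf("ref%04d", i)
    rhdf5::h5createGroup(path, grp)
    r <- refs[[i]]
    for (f in c("u", "theta", "sample_rate", "dominant_freq", "source"))
      rhdf5::h5write(r[[f]], path, paste0(grp, "/", f))
  }
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname save_references_h5
#' @export
load_references_h5 <- function(path) {
  g <- rhdf5::h5dump(path)
  rhdf5::h5closeAll()
  n <- as.integer(g$n)
  lapply(seq_len(n), function(i) {
    r <- g[[sprintf("ref%04d", i)]]
    reference_signal(as.numeric(r$u), as.numeric(r$theta),
                     as.numeric(r$sample_rate),
                     as.numeric(r$dominant_freq), as.character(r$source))
  })
}

#' Save / load a raw multichannel recording (HDF5)
#'
#' Dataset `/lfp` (channels x samples) plus `/sample_rate`.
#'
#' @param rec a [raw_recording()]
#' @param path file path
#' @return the path / the recording
#' @export
save_raw_h5 <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  h5_write_list(path, list(lfp = rec$samples,
                           sample_rate = rec$sample_rate))
}

#' @rdname save_raw_h5
#' @export
load_raw_h5 <- function(path) {
  g <- rhdf5::h5dump(path)
  rhdf5::h5closeAll()
  raw_recording(g$lfp, as.numeric(g$sample_rate))
}

#' Save / load trial batches (HDF5)
#'
#' One group per trial with datasets `u`, `theta`, `inputs`, `target`,
#' `mask` and scalar metadata.
#'
#' @param trials list of `wm_trial` objects
#' @param path file path
#' @return the path / list of trials
#' @export
save_trials_h5 <- function(trials, path) {
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(length(trials), path, "n")
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    grp <- sprintf("trial%05d", i)
    rhdf5::h5createGroup(path, grp)
    rhdf5::h5write(tr$u, path, paste0(grp, "/u"))
    rhdf5::h5write(tr$theta, path, paste0(grp, "/theta"))
    rhdf5::h5write(tr$inputs, path, paste0(grp, "/inputs"))
    rhdf5::h5write(tr$target, path, paste0(grp, "/target"))
    rhdf5::h5write(as.integer(tr$mask), path, paste0(grp, "/mask"))
    rhdf5::h5write(c(tr$t_on, tr$t_off, tr$stim_id, tr$h),
                   path, paste0(grp, "/meta"))
  }
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname save_trials_h5
#' @export
load_trials_h5 <- function(path) {
  g <- rhdf5::h5dump(path)
  rhdf5::h5closeAll()
  lapply(seq_len(as.integer(g$n)), function(i) {
    tr <- g[[sprintf("trial%05d", i)]]
    meta <- as.numeric(tr$meta)
    structure(list(u = as.numeric(tr$u), theta = as.numeric(tr$theta),
                   inputs = as.matrix(tr$inputs),
                   target = as.numeric(tr$target),
                   mask = as.logical(as.integer(tr$mask)),
                   t_on = meta[1], t_off = meta[2],
                   stim_id = as.integer(meta[3]), h = meta[4]),
              class = "wm_trial")
  })
}

#' Save / load a mixture-connectivity description (YAML)
#'
#' Weights, channel table and labelled covariance matrices, round-tripping
#' losslessly through plain text.
#'
#' @param mix a [mixture_connectivity()]
#' @param path file path
#' @return the path / the mixture
#' @export
save_mixture_yaml <- function(mix, path) {
  yaml::write_yaml(precision = 17L, x = list(
    rank = mix$rank, tau = mix$tau, readout_mode = mix$readout_mode,
    weights = mix$weights, labels = mix$labels,
    channels = as.list(mix$channels),
    vars = mix$vars,
    covs = lapply(mix$covs, function(S) apply(S, 1, as.numeric,
                                              simplify = FALSE))),
    file = path)
  invisible(path)
}

#' @rdname save_mixture_yaml
#' @export
load_mixture_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  V <- length(y$vars)
  covs <- lapply(y$covs, function(rows) {
    S <- do.call(rbind, lapply(rows, as.numeric))
    dimnames(S) <- list(y$vars, y$vars)
    (S + t(S)) / 2
  })
  channels <- as.data.frame(y$channels, stringsAsFactors = FALSE)
  mixture_connectivity(as.numeric(y$weights), covs, channels,
                       rank = y$rank, tau = y$tau,
                       readout_mode = y$readout_mode, labels = y$labels)
}

#' Read / write an experiment configuration (YAML)
#'
#' @param path YAML file
#' @return nested configuration list
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  modifyList(default_config(), cfg)
}

#' @rdname read_experiment_config
#' @param cfg configuration list
#' @export
write_experiment_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Default experiment configuration
#'
#' Desk-scale defaults for the end-to-end pipeline; all fields can be
#' overridden from a YAML file.
#'
#' @return nested list
#' @export
default_config <- function() {
  list(
    seed = 1L,
    data = list(n_segments = 600, segment_s = 4, sample_rate = 500,
                band = c(7, 9), amp_drift_sd = 0.2, freq_drift_sd = 0.3,
                frac_train = 0.9),
    task = list(n_stim = 2),
    network = list(N = 256, rank = 2, init = "oscillatory",
                   readout = "linear"),
    train = list(epochs = 30, batch = 128, lr = 0.01,
                 regularize_rates = TRUE, trials_per_epoch = 512),
    analysis = list(A = 1, freq_hz = 8, scan_amps = 21, scan_freqs = 21,
                    amp_range = c(0.05, 2), freq_range = c(2, 16)))
}

#' Write a run manifest
#'
#' Records the configuration, its hash, the seed and the artifact list next
#' to the artifacts, sufficient to regenerate them.
#'
#' @param out_dir output directory
#' @param stage subcommand name
#' @param cfg configuration list
#' @param artifacts character vector of file names produced
#' @return manifest path, invisibly
#' @export
write_manifest <- function(out_dir, stage, cfg, artifacts) {
  cfg_path <- file.path(out_dir, paste0(stage, "-config.yaml"))
  write_experiment_config(cfg, cfg_path)
  man <- list(stage = stage, seed = cfg$seed,
              config = basename(cfg_path),
              config_md5 = unname(tools::md5sum(cfg_path)),
              package_version = as.character(utils::packageVersion("oscmem")),
              artifacts = artifacts)
  path <- file.path(out_dir, paste0(stage, "-manifest.json"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
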