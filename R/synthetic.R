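#' Softmax reinforcement-learning agent
#'
#' A stateful choice policy for [run_session()]: values start at 0.5,
#' the previous trial's outcome updates the chosen symbol's value by the
#' requested model's learning rule, and choices are drawn from the softmax
#' probability with inverse temperature beta and indecision offset phi.
#'
#' @param params List with `alpha`, `beta`, `phi` (plus `gamma`,
#'   `smooth_const` for the dynamic model).
#' @param model One of "mf", "dyn", "mb".
#' @return An agent function.
#' @export
rl_agent <- function(params, model = c("mf", "dyn", "mb")) {
  model <- match.arg(model)
  v <- c()
  SO <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("0", "1")))
  alpha <- params$alpha
  sc <- if (is.null(params$smooth_const)) 0.1 else params$smooth_const
  s_smooth <- NA_real_
  first <- TRUE

  ensure <- function(syms) {
    new <- setdiff(syms, names(v))
    if (length(new) > 0) {
      v[new] <<- 0.5
      SO <<- rbind(SO, matrix(0.5, length(new), 2,
                              dimnames = list(new, c("0", "1"))))
    }
  }

  function(pair, info) {
    ensure(pair)
    prev <- info$prev
    if (!is.null(prev)) {
      ch <- prev$choice; r <- prev$outcome
      d <- r - v[[ch]]
      if (model == "dyn") {
        if (first) {
          s_smooth <<- abs(d); m <- 0; first <<- FALSE
        } else {
          s_new <- s_smooth + sc * (abs(d) - s_smooth)
          m <- s_new - s_smooth
          s_smooth <<- s_new
        }
        alpha <<- update_dynamic_alpha(alpha, m, params$gamma)
      }
      if (model == "mb") {
        SO <<- update_so_mb(SO, ch, r, alpha)
        v[[ch]] <<- SO[ch, "1"]
      } else {
        v[[ch]] <<- v[[ch]] + alpha * d
      }
    }
    p1 <- choice_prob(v[[pair[1]]], v[[pair[2]]], params$beta, params$phi)
    if (stats::runif(1) < p1) pair[1] else pair[2]
  }
}

#' Generate reversal-learning behavior with known ground truth
#'
#' Plays the task with a softmax RL agent at the supplied generating
#' parameters and records the latent traces (values, RPE, surprise,
#' learning rate, value update) computed at those same parameters, plus
#' synthetic reaction times in which surprising positive RPEs speed up and
#' surprising negative RPEs slow down the next response.
#'
#' @param params Generating RL parameters (`alpha`, `beta`, `phi`, ...).
#' @param config A [task_config()].
#' @param model RL model variant.
#' @param rt_base,rt_coef,rt_sd Reaction-time model: RT(t+1) = rt_base -
#'   rt_coef * delta(t) + noise.
#' @param seed Optional integer seed.
#' @return List with `session` (a `session_data`), `trace` (a
#'   [latent_trace()] at the generating parameters), `rts`, and `params`.
#' @export
gen_behavior <- function(params, config = task_config(),
                         model = c("mf", "dyn", "mb"),
                         rt_base = 0.6, rt_coef = 0.15, rt_sd = 0.05,
                         seed = NULL) {
  model <- match.arg(model)
  with_seed(seed, {
    session <- run_session(config, rl_agent(params, model))
    trace <- latent_trace(params, session, model)
    n <- nrow(session$trials)
    rts <- rt_base + rt_sd * stats::rnorm(n)
    if (n > 1)
      rts[-1] <- rts[-1] - rt_coef * trace$delta[-n]
    rts <- pmax(rts, 0.15)
    list(session = session, trace = trace, rts = rts, params = params)
  })
}

#' Configuration of the synthetic EEG generator
#'
#' @param n_channels Number of sensors (default 64).
#' @param sfreq Sampling rate in Hz (default 250).
#' @param epoch_span Epoch limits in ms relative to outcome (default -200
#'   to 700).
#' @param valence_latency,surprise_latency Peak latencies (ms) of the
#'   planted categorical valence component (308) and parametric surprise
#'   component (320).
#' @param component_width Temporal Gaussian SD of both components in ms.
#' @param snr Component amplitude relative to unit-SD sensor noise.
#' @param noise_spatial_corr Strength of first-order neighbor mixing of
#'   the sensor noise, in \[0, 1).
#' @param valence_jitter SD of the multiplicative amplitude jitter on the
#'   categorical valence latent.
#' @param surprise_jitter SD of the additive endogenous variability on the
#'   surprise component amplitude.  The neural surprise response is not a
#'   deterministic function of the model-derived |RPE|: trial-to-trial
#'   amplitude fluctuations beyond the model estimate are what give an
#'   EEG-derived surprise regressor explanatory power over and above the
#'   model-based one (empirically the two correlate only moderately).
#' @return List of class `eeg_gen_config`.
#' @export
eeg_gen_config <- function(n_channels = 64, sfreq = 250,
                           epoch_span = c(-200, 700),
                           valence_latency = 308, surprise_latency = 320,
                           component_width = 40, snr = 1,
                           noise_spatial_corr = 0.5, valence_jitter = 0.2,
                           surprise_jitter = 0.4) {
  stopifnot(valence_latency > epoch_span[1], valence_latency < epoch_span[2],
            surprise_latency > epoch_span[1], surprise_latency < epoch_span[2],
            noise_spatial_corr >= 0, noise_spatial_corr < 1)
  structure(list(n_channels = n_channels, sfreq = sfreq,
                 epoch_span = epoch_span,
                 valence_latency = valence_latency,
                 surprise_latency = surprise_latency,
                 component_width = component_width, snr = snr,
                 noise_spatial_corr = noise_spatial_corr,
                 valence_jitter = valence_jitter,
                 surprise_jitter = surprise_jitter),
            class = "eeg_gen_config")
}

# Orthonormal pair of random channel patterns (correlation 0 by
# construction, satisfying the near-orthogonality requirement).
random_patterns <- function(D) {
  p1 <- stats::rnorm(D); p1 <- p1 / sqrt(sum(p1^2))
  p2 <- stats::rnorm(D); p2 <- p2 - sum(p2 * p1) * p1
  p2 <- p2 / sqrt(sum(p2^2))
  cbind(valence = p1, surprise = p2)
}

#' Generate synthetic outcome-locked EEG epochs
#'
#' Plants two components with distinct random (orthogonal) scalp patterns:
#' a categorical valence component whose per-trial amplitude is sign(RPE)
#' times a jittered unit amplitude, peaking at 308 ms, and a parametric
#' surprise component whose amplitude is the mean-centered |RPE| plus
#' endogenous trial-to-trial variability, peaking at 320 ms.  Both have
#' Gaussian temporal envelopes and are embedded in spatially correlated
#' Gaussian sensor noise.  By construction the valence amplitudes are
#' uncorrelated with |RPE| (the two latents are decoupled).
#'
#' @param trace A [latent_trace()] (or any list/data.frame with a `delta`
#'   vector).
#' @param config An [eeg_gen_config()].
#' @param seed Optional integer seed.
#' @return List with `epochs` (an [epoch_array()]), `latents` (data.frame:
#'   planted `valence` and `surprise` amplitudes, `delta`, `surprise_bin`),
#'   `patterns` (channels x 2), `config`.
#' @export
gen_eeg <- function(trace, config = eeg_gen_config(), seed = NULL) {
  delta <- trace$delta
  n <- length(delta)
  with_seed(seed, {
    D <- config$n_channels
    tms <- seq(config$epoch_span[1], config$epoch_span[2],
               by = 1000 / config$sfreq)        # ms
    S <- length(tms)
    pat <- random_patterns(D)
    g_val <- exp(-(tms - config$valence_latency)^2 /
                   (2 * config$component_width^2))
    g_sur <- exp(-(tms - config$surprise_latency)^2 /
                   (2 * config$component_width^2))
    amp_val <- sign(delta) * (1 + config$valence_jitter * stats::rnorm(n))
    amp_sur <- abs(delta) - mean(abs(delta)) +
      config$surprise_jitter * stats::rnorm(n)

    rho <- config$noise_spatial_corr
    arr <- array(0, c(n, D, S))
    for (i in seq_len(n)) {
      E <- matrix(stats::rnorm(D * S), D, S)
      if (rho > 0 && D > 1) {
        up <- rbind(E[-1, , drop = FALSE], E[1, , drop = FALSE])
        dn <- rbind(E[D, , drop = FALSE], E[-D, , drop = FALSE])
        E <- (E + rho * (up + dn) / 2) / sqrt(1 + rho^2 / 2)
      }
      sig <- config$snr *
        (amp_val[i] * outer(pat[, "valence"], g_val) +
         amp_sur[i] * outer(pat[, "surprise"], g_sur))
      arr[i, , ] <- sig + E
    }
    epochs <- epoch_array(arr, config$sfreq, config$epoch_span[1] / 1000)
    latents <- data.frame(valence = amp_val, surprise = amp_sur,
                          delta = delta,
                          surprise_bin = surprise_bins(abs(delta)))
    list(epochs = epochs, latents = latents, patterns = pat, config = config)
  })
}

#' Configuration of the synthetic BOLD generator
#'
#' Lays out four disjoint cuboid regions on the grid: voxels loading only
#' on the valence latent, only on the surprise latent, on their sum
#' (linear superposition), and on nothing.
#'
#' @param grid Volume dimensions (default 32 x 32 x 12).
#' @param TR Repetition time in seconds (default 2.5).
#' @param n_volumes Volumes per run (default 463); extended automatically
#'   if the session outlasts it.
#' @param effect_amplitudes Named amplitudes for valence_only,
#'   surprise_only and overlap regions.
#' @param noise_sd Gaussian noise SD.
#' @param roi_size Cuboid edge lengths of each region.
#' @return List of class `bold_gen_config`.
#' @export
bold_gen_config <- function(grid = c(32, 32, 12), TR = 2.5, n_volumes = 463,
                            effect_amplitudes = c(valence_only = 1,
                                                  surprise_only = 1,
                                                  overlap = 1),
                            noise_sd = 1, roi_size = c(4, 4, 3)) {
  structure(list(grid = grid, TR = TR, n_volumes = n_volumes,
                 effect_amplitudes = effect_amplitudes,
                 noise_sd = noise_sd, roi_size = roi_size),
            class = "bold_gen_config")
}

block_mask <- function(grid, corner, size) {
  m <- array(FALSE, grid)
  m[corner[1] + seq_len(size[1]) - 1,
    corner[2] + seq_len(size[2]) - 1,
    corner[3] + seq_len(size[3]) - 1] <- TRUE
  m
}

#' Generate synthetic BOLD volumes with planted valence/surprise regions
#'
#' Builds HRF-convolved regressors from the mean-centered valence and
#' surprise latents at the session's outcome onsets and plants them in
#' disjoint regions: valence-only, surprise-only, an overlap region
#' loading on their sum (linear superposition), and a null region.  White
#' Gaussian noise is added everywhere.
#'
#' @param session A `session_data` (outcome onsets).
#' @param valence,surprise Per-trial latent amplitudes (e.g. the planted
#'   EEG latents or the model trace).
#' @param config A [bold_gen_config()].
#' @param seed Optional integer seed.
#' @return List with `volumes` (a [volume_series()]), `rois` (named list
#'   of logical masks incl. `null`), `truth` (centered latents and the
#'   convolved regressors), `config`.
#' @export
gen_bold <- function(session, valence, surprise,
                     config = bold_gen_config(), seed = NULL) {
  trials <- session$trials
  n <- nrow(trials)
  stopifnot(length(valence) == n, length(surprise) == n)
  with_seed(seed, {
    g <- config$grid
    TR <- config$TR
    n_vol <- max(config$n_volumes,
                 ceiling((max(trials$onset_s) + 20) / TR))
    val_c <- valence - mean(valence)
    sur_c <- surprise - mean(surprise)
    reg_val <- build_regressor(
      event_regressor(trials$onset_s, 0.1, val_c, "val"), TR, n_vol)
    reg_sur <- build_regressor(
      event_regressor(trials$onset_s, 0.1, sur_c, "sur"), TR, n_vol)

    sz <- config$roi_size
    gap <- sz + 2L
    rois <- list(
      valence_only = block_mask(g, c(2, 2, 2), sz),
      surprise_only = block_mask(g, c(2 + gap[1], 2, 2), sz),
      overlap = block_mask(g, c(2, 2 + gap[2], 2), sz))
    rois$null <- !(rois$valence_only | rois$surprise_only | rois$overlap)

    amp <- config$effect_amplitudes
    data <- array(stats::rnorm(prod(g) * n_vol, sd = config$noise_sd),
                  c(g, n_vol))
    add_signal <- function(data, mask, ts) {
      vox <- which(mask)
      flat <- matrix(data, prod(g), n_vol)
      flat[vox, ] <- flat[vox, ] + rep(ts, each = length(vox))
      array(flat, c(g, n_vol))
    }
    data <- add_signal(data, rois$valence_only, amp["valence_only"] * reg_val)
    data <- add_signal(data, rois$surprise_only, amp["surprise_only"] * reg_sur)
    data <- add_signal(data, rois$overlap, amp["overlap"] * (reg_val + reg_sur))

    list(volumes = volume_series(data, TR),
         rois = rois,
         truth = list(valence = val_c, surprise = sur_c,
                      reg_valence = reg_val, reg_surprise = reg_sur),
         config = config)
  })
}

#' Write a small deterministic synthetic fixture bundle
#'
#' Generates, at reduced size, one subject's behavior, EEG epochs and BOLD
#' volumes with their ground-truth latents, and writes them in the
#' package's interchange formats (trial TSV, epoch TSV + JSON sidecar,
#' NIfTI volumes, truth TSV).  Identical seeds give identical bundles.
#'
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @param n_trials Trials in the (single-block) session.
#' @param n_channels EEG channels.
#' @param grid BOLD grid.
#' @return Invisibly, the named vector of file paths.
#' @export
gen_fixture_suite <- function(seed, dir = tempfile("fixtures"),
                              n_trials = 40, n_channels = 8,
                              grid = c(12, 12, 5)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- task_config(n_blocks = 1, trials_per_block = n_trials)
  beh <- gen_behavior(list(alpha = 0.3, beta = 5, phi = 0), cfg,
                      seed = seed)
  eeg <- gen_eeg(beh$trace, eeg_gen_config(n_channels = n_channels,
                                           sfreq = 125, snr = 1.5),
                 seed = seed + 1)
  bold <- gen_bold(beh$session, eeg$latents$valence, eeg$latents$surprise,
                   bold_gen_config(grid = grid, n_volumes = 10),
                   seed = seed + 2)
  paths <- c(session = file.path(dir, "session.tsv"),
             epochs = file.path(dir, "epochs"),
             volumes = file.path(dir, "bold.nii.gz"),
             truth = file.path(dir, "truth.tsv"))
  write_session(beh$session, paths["session"])
  write_epochs(eeg$epochs, paths["epochs"])
  write_volume_series(bold$volumes, paths["volumes"])
  truth <- cbind(eeg$latents,
                 value_update = beh$trace$value_update,
                 alpha_t = beh$trace$alpha_t)
  utils::write.table(truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
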