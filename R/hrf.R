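#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities: a positive lobe peaking near 5 s and
#' a later undershoot, normalized to unit peak.  These are the canonical
#' defaults (peak delay 6, undershoot delay 16, undershoot ratio 1/6,
#' 32 s support).
#'
#' @param dt Sampling step in seconds.
#' @param peak_delay,undershoot_delay Gamma shape parameters (scale 1).
#' @param ratio Undershoot amplitude relative to the positive lobe.
#' @param duration Kernel length in seconds.
#' @return Numeric kernel sampled at `dt`, starting at t = 0.
#' @export
double_gamma_hrf <- function(dt, peak_delay = 6, undershoot_delay = 16,
                             ratio = 1 / 6, duration = 32) {
  stopifnot(dt > 0)
  t <- seq(0, duration, by = dt)
  h <- stats::dgamma(t, shape = peak_delay, scale = 1) -
    ratio * stats::dgamma(t, shape = undershoot_delay, scale = 1)
  h / max(h)
}

#' Event regressor specification
#'
#' A set of brief boxcar events (default 100 ms) with per-event amplitudes;
#' unmodulated regressors have all amplitudes equal to one, parametric
#' regressors carry trial-varying amplitudes.
#'
#' @param onsets Event onsets in seconds (sorted).
#' @param durations Event durations in seconds (recycled; default 0.1).
#' @param amplitudes Per-event amplitudes (recycled; default 1).
#' @param name Regressor name.
#' @return An object of class `event_regressor`.
#' @export
event_regressor <- function(onsets, durations = 0.1, amplitudes = 1,
                            name = "reg") {
  stopifnot(!is.unsorted(onsets), all(durations > 0))
  n <- length(onsets)
  structure(list(onsets = onsets,
                 durations = rep_len(durations, n),
                 amplitudes = rep_len(amplitudes, n),
                 name = name),
            class = "event_regressor")
}

#' HRF-convolved regressor column
#'
#' Places amplitude-scaled boxcars on a fine time grid, convolves with the
#' HRF kernel, and resamples at the volume acquisition times t = k * TR.
#'
#' @param events An [event_regressor()].
#' @param TR Repetition time in seconds.
#' @param n_volumes Number of volumes.
#' @param dt Fine-grid step in seconds (default 0.1).
#' @param hrf Kernel sampled at `dt`; default [double_gamma_hrf()].
#' @return Numeric vector of length `n_volumes`.
#' @export
build_regressor <- function(events, TR, n_volumes, dt = 0.1, hrf = NULL) {
  if (is.null(hrf)) hrf <- double_gamma_hrf(dt)
  run_len <- n_volumes * TR
  if (length(events$onsets) > 0 && any(events$onsets >= run_len))
    stop("event onsets fall beyond the scanned run")
  n_fine <- ceiling(run_len / dt) + 1L
  x <- numeric(n_fine)
  for (j in seq_along(events$onsets)) {
    i0 <- floor(events$onsets[j] / dt) + 1L
    i1 <- min(n_fine, ceiling((events$onsets[j] + events$durations[j]) / dt))
    x[i0:i1] <- x[i0:i1] + events$amplitudes[j]
  }
  conv <- stats::convolve(x, rev(hrf), type = "open")[seq_len(n_fine)]
  conv[round((seq_len(n_volumes) - 1L) * TR / dt) + 1L]
}

#' Assemble a design matrix from event regressors
#'
#' Convolves each event regressor with the canonical HRF and appends
#' nuisance (e.g. motion) columns unconvolved.
#'
#' @param regressors List of [event_regressor()] objects.
#' @param TR,n_volumes Acquisition grid.
#' @param nuisance Optional numeric matrix of nuisance columns (n_volumes
#'   rows).
#' @param dt Fine-grid step for convolution.
#' @return An object of class `design_matrix`: list with `X` (volumes x
#'   regressors), `names`, `TR`, `n_volumes`, `task_cols`, `nuisance_cols`.
#' @export
build_design <- function(regressors, TR, n_volumes, nuisance = NULL,
                         dt = 0.1) {
  cols <- lapply(regressors, build_regressor, TR = TR,
                 n_volumes = n_volumes, dt = dt)
  X <- do.call(cbind, cols)
  nms <- vapply(regressors, function(r) r$name, character(1))
  task_cols <- seq_along(nms)
  nuisance_cols <- integer(0)
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    stopifnot(nrow(nuisance) == n_volumes)
    if (is.null(colnames(nuisance)))
      colnames(nuisance) <- paste0("nuis", seq_len(ncol(nuisance)))
    nuisance_cols <- ncol(X) + seq_len(ncol(nuisance))
    X <- cbind(X, nuisance)
    nms <- c(nms, colnames(nuisance))
  }
  colnames(X) <- nms
  structure(list(X = X, names = nms, TR = TR, n_volumes = n_volumes,
                 task_cols = task_cols, nuisance_cols = nuisance_cols),
            class = "design_matrix")
}

#' EEG-informed outcome-phase design (main GLM)
#'
#' Builds the seven task regressors of the main outcome-locked GLM: an
#' unmodulated outcome regressor (UM), three fully parametric outcome
#' regressors carrying the EEG single-trial variability of the late
#' valence component (EEG_LateVal), the model-derived surprise
#' (MODEL_Sur), the EEG surprise component (EEG_LateSur), a parametric
#' regressor for the early valence component (EEG_EarlyVal), an
#' unmodulated regressor for lost trials (LOST; dropped with a warning if
#' no lost trials), and an unmodulated decision-phase regressor (DEC) at
#' stimulus onset.  Parametric amplitude vectors are mean-centered before
#' convolution so that the mean evoked response loads on UM.
#'
#' @param session A `session_data` (provides outcome and decision onsets).
#' @param y_late_val,model_surprise,y_late_sur,y_early_val Per-trial
#'   amplitude vectors aligned with the session's valid trials.
#' @param motion Optional nuisance matrix (e.g. six motion parameters).
#' @param lost_onsets Onsets of lost trials (seconds; may be empty).
#' @param TR,n_volumes Acquisition grid.
#' @param dt Fine-grid step for convolution.
#' @param duration Event duration in seconds (default 0.1).
#' @return A `design_matrix`.
#' @export
build_design_glm1 <- function(session, y_late_val, model_surprise, y_late_sur,
                              y_early_val, motion = NULL,
                              lost_onsets = numeric(0), TR = 2.5, n_volumes,
                              dt = 0.1, duration = 0.1) {
  trials <- session$trials
  n <- nrow(trials)
  amps <- list(EEG_LateVal = y_late_val, MODEL_Sur = model_surprise,
               EEG_LateSur = y_late_sur, EEG_EarlyVal = y_early_val)
  for (nm in names(amps)) {
    if (length(amps[[nm]]) != n)
      stop("amplitude vector '", nm, "' has length ", length(amps[[nm]]),
           " but the session has ", n, " trials")
    amps[[nm]] <- amps[[nm]] - mean(amps[[nm]])
    if (all(abs(amps[[nm]]) < 1e-12))
      warning("parametric regressor '", nm,
              "' is constant; after centering it is all zero (collinear)")
  }
  onset <- trials$onset_s
  regs <- c(list(event_regressor(onset, duration, 1, "UM")),
            lapply(names(amps), function(nm)
              event_regressor(onset, duration, amps[[nm]], nm)))
  if (length(lost_onsets) > 0) {
    regs <- c(regs, list(event_regressor(sort(lost_onsets), duration, 1,
                                         "LOST")))
  } else {
    warning("no lost trials; LOST regressor dropped")
  }
  regs <- c(regs, list(event_regressor(trials$dec_onset_s, duration, 1,
                                       "DEC")))
  build_design(regs, TR, n_volumes, nuisance = motion, dt = dt)
}
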