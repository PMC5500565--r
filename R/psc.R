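#' Outcome-locked percent signal change
#'
#' Extracts, for each outcome onset, the 7-volume trace spanning 2 volumes
#' (5 s) before to 4 volumes (10 s) after the first volume acquired at or
#' after the outcome, and converts it to percent signal change:
#' PSC_i(t) = 100 * (X_i(t) - X_i^b) / Xbar, where X_i^b is the mean of
#' the 2 volumes preceding the outcome and Xbar the run mean.  Trials too
#' close to a run edge are skipped with a warning.
#'
#' @param ts Numeric voxel/ROI time series (one run).
#' @param onsets Outcome onsets in seconds.
#' @param TR Repetition time in seconds.
#' @param pre,post Number of volumes before/after the outcome volume
#'   (defaults 2 and 4, i.e. -5 s to +10 s at TR = 2.5).
#' @return An object of class `psc_trace`: `psc` (trials x volumes matrix),
#'   `rel_volumes` (-pre..post), `baseline` (per trial), `run_mean`,
#'   `kept` (indices of retained trials).
#' @export
psc <- function(ts, onsets, TR, pre = 2L, post = 4L) {
  n_vol <- length(ts)
  run_mean <- mean(ts)
  rel <- seq.int(-pre, post)
  rows <- list(); base <- numeric(0); kept <- integer(0)
  for (i in seq_along(onsets)) {
    iv0 <- ceiling(onsets[i] / TR) + 1L    # first volume at/after outcome
    idx <- iv0 + rel
    if (idx[1] < 1L || idx[length(idx)] > n_vol) {
      warning("trial ", i, " too close to the run edge; skipped")
      next
    }
    b <- mean(ts[iv0 - seq_len(pre)])
    rows[[length(rows) + 1L]] <- 100 * (ts[idx] - b) / run_mean
    base <- c(base, b)
    kept <- c(kept, i)
  }
  m <- if (length(rows) > 0) do.call(rbind, rows)
       else matrix(numeric(0), 0, length(rel))
  colnames(m) <- paste0("vol", rel)
  structure(list(psc = m, rel_volumes = rel, baseline = base,
                 run_mean = run_mean, kept = kept),
            class = "psc_trace")
}

#' Per-trial PSC summary around the response peak
#'
#' Averages the PSC trace over volumes 2--4 after the outcome (5--10 s,
#' around the hemodynamic peak).
#'
#' @param trace A [psc()] result.
#' @param volumes Relative volumes to average (default 2:4).
#' @return Numeric vector, one value per retained trial.
#' @export
psc_summary <- function(trace, volumes = 2:4) {
  cols <- match(volumes, trace$rel_volumes)
  if (anyNA(cols)) stop("requested volumes outside the PSC window")
  rowMeans(trace$psc[, cols, drop = FALSE])
}

#' Regression of value updates on percent signal change
#'
#' Per subject, regresses the trial-wise value update (the change of the
#' chosen option's expected value) on the trial-wise PSC summary; across
#' subjects, tests whether the slopes come from a distribution with mean
#' greater than zero (one-tailed t test).
#'
#' @param psc_list List of per-subject numeric vectors (per-trial PSC
#'   summaries), or a single numeric vector.
#' @param update_list Matching list (or vector) of per-trial value
#'   updates.
#' @return List with `slopes` (per-subject beta_1, NA when the PSC has
#'   zero variance), and -- when more than one subject is supplied --
#'   `t`, `df`, `p` of the one-tailed group test.
#' @export
psc_value_update_regression <- function(psc_list, update_list) {
  if (is.numeric(psc_list)) psc_list <- list(psc_list)
  if (is.numeric(update_list)) update_list <- list(update_list)
  stopifnot(length(psc_list) == length(update_list))
  slopes <- mapply(function(x, y) {
    stopifnot(length(x) == length(y))
    if (stats::var(x) == 0) return(NA_real_)
    unname(stats::coef(stats::lm(y ~ x))[2])
  }, psc_list, update_list)
  out <- list(slopes = slopes)
  if (length(slopes) > 1) {
    ok <- slopes[!is.na(slopes)]
    if (stats::sd(ok) < 1e-10 * max(1, abs(mean(ok)))) {  # identical slopes
      out$t <- if (mean(ok) > 0) Inf else -Inf
      out$df <- length(ok) - 1
      out$p <- if (mean(ok) > 0) 0 else 1
    } else {
      tt <- stats::t.test(ok, alternative = "greater")
      out$t <- unname(tt$statistic)
      out$df <- unname(tt$parameter)
      out$p <- tt$p.value
    }
  }
  out
}

#' Six-bin ROI response profile (valence x surprise terciles)
#'
#' Bins outcome events into positive/negative RPE crossed with
#' low/medium/high surprise, where the surprise terciles are the 0-33\%,
#' 33-66\% and 66-100\% percentiles of the EEG surprise-component
#' amplitudes computed within each valence class.  A GLM with one
#' unmodulated regressor per bin (plus a decision-phase regressor and any
#' nuisance columns) is fitted and the mean beta over each ROI reported
#' per bin.  In a region superposing both RPE dimensions the profile shows
#' pos > neg overall and a monotone increase with surprise within each
#' valence.
#'
#' @param session A `session_data`.
#' @param y_surprise Per-trial EEG surprise amplitudes (STV).
#' @param valence Per-trial logical (TRUE = positive RPE) or sign vector.
#' @param Y A [volume_series()].
#' @param roi_masks Named list of logical 3-D ROI masks.
#' @param motion Optional nuisance matrix.
#' @param duration,dt Event duration and convolution grid (seconds).
#' @return List with `beta` (ROIs x 6 matrix, columns neg_low..pos_high;
#'   NA for empty bins), `bins` (per-trial bin labels), `edges` (tercile
#'   edges per valence class).
#' @export
roi_bin_profile <- function(session, y_surprise, valence, Y, roi_masks,
                            motion = NULL, duration = 0.1, dt = 0.1) {
  trials <- session$trials
  n <- nrow(trials)
  stopifnot(length(y_surprise) == n, length(valence) == n)
  pos <- if (is.logical(valence)) valence else valence > 0
  lev <- c("neg_low", "neg_medium", "neg_high",
           "pos_low", "pos_medium", "pos_high")
  bins <- character(n)
  edges <- list()
  for (cls in c(FALSE, TRUE)) {
    idx <- which(pos == cls)
    if (length(idx) == 0) next
    q <- stats::quantile(y_surprise[idx], c(1 / 3, 2 / 3), names = FALSE)
    edges[[if (cls) "pos" else "neg"]] <- q
    tier <- cut(y_surprise[idx], c(-Inf, q, Inf),
                labels = c("low", "medium", "high"))
    bins[idx] <- paste0(if (cls) "pos_" else "neg_", as.character(tier))
  }
  bins <- factor(bins, levels = lev)

  present <- lev[table(bins)[lev] > 0]
  if (length(present) < length(lev))
    warning("empty bin(s): ", paste(setdiff(lev, present), collapse = ", "))
  regs <- lapply(present, function(b)
    event_regressor(sort(trials$onset_s[bins == b]), duration, 1, b))
  regs <- c(regs, list(event_regressor(trials$dec_onset_s, duration, 1,
                                       "DEC")))
  des <- build_design(regs, Y$TR, dim(Y$data)[4], nuisance = motion, dt = dt)
  fit <- bold_glm(Y, des)

  out <- matrix(NA_real_, length(roi_masks), length(lev),
                dimnames = list(names(roi_masks), lev))
  for (r in seq_along(roi_masks)) {
    roi_vox <- which(roi_masks[[r]])
    rows <- match(roi_vox, fit$voxels)
    rows <- rows[!is.na(rows)]
    for (b in present)
      out[r, b] <- mean(fit$beta[rows, match(b, fit$names)])
  }
  list(beta = out, bins = bins, edges = edges, fit = fit)
}
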