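#' Sliding-window single-trial discrimination of epoched EEG
#'
#' Trains a shrinkage-regularized Fisher discriminant in each 60 ms window
#' sliding across the epoch (centers -100 to 600 ms in 10 ms steps by
#' default), and scores each window by leave-one-out cross-validated ROC
#' area (Az).  The window with the highest Az (earliest on ties) defines
#' the component's peak latency; its full-data weights, single-trial
#' amplitudes and forward model characterize the discriminating component.
#'
#' @param epochs An [epoch_array()].
#' @param labels Binary condition labels, one per trial (TRUE/1 = positive
#'   class: positive RPE, or high surprise).
#' @param windows A [window_spec()].
#' @param lambda Covariance regularization in \[0, 1\], or `"auto"` to
#'   select it with [optimize_lambda()] before training.
#' @param lambda_grid Candidate grid used when `lambda = "auto"`.
#' @return An object of class `sliding_lda`: per-window weights `w`
#'   (channels x windows), full-data amplitudes `y` (trials x windows),
#'   held-out amplitudes `y_loo`, `az` per window, `forward` (channels x
#'   windows forward models), `peak_window` (center ms of max Az),
#'   `lambda`, `windows`, `labels`.
#' @examples
#' \donttest{
#' eeg <- gen_eeg(data.frame(delta = rnorm(60)), eeg_gen_config(n_channels = 8),
#'                seed = 1)
#' fit <- sliding_lda(eeg$epochs, eeg$latents$valence > 0,
#'                    window_spec(seq(0, 400, 50)))
#' fit$peak_window
#' }
#' @seealso [loo_az()], [permutation_threshold()], [predict.sliding_lda()]
#' @export
sliding_lda <- function(epochs, labels, windows = window_spec(), lambda = 0,
                        lambda_grid = c(0, 0.001, 0.01, 0.028, 0.05,
                                        0.1, 0.3, 1)) {
  labels <- as.logical(labels)
  if (identical(lambda, "auto"))
    lambda <- optimize_lambda(epochs, labels, windows, lambda_grid)$lambda
  centers <- windows$centers
  nW <- length(centers)
  D <- dim(epochs$data)[2]
  n <- dim(epochs$data)[1]
  stopifnot(length(labels) == n)

  w <- matrix(NA_real_, D, nW)
  fwd <- matrix(NA_real_, D, nW)
  y <- matrix(NA_real_, n, nW)
  y_loo <- matrix(NA_real_, n, nW)
  az <- numeric(nW)
  for (k in seq_len(nW)) {
    M <- window_average(epochs, centers[k], windows$width)
    w[, k] <- fisher_weights(M[!labels, , drop = FALSE],
                             M[labels, , drop = FALSE], lambda)
    y[, k] <- drop(M %*% w[, k])
    y_loo[, k] <- loo_amplitudes(M, labels, lambda)
    az[k] <- az_score(y_loo[, k], labels)
    fwd[, k] <- drop(crossprod(M, y[, k])) / sum(y[, k]^2)
  }
  peak <- centers[which.max(az)]       # which.max returns the earliest tie
  structure(list(w = w, y = y, y_loo = y_loo, az = az, forward = fwd,
                 peak_window = peak, lambda = lambda, windows = windows,
                 labels = labels, channel_names = epochs$channel_names),
            class = "sliding_lda")
}

#' @export
print.sliding_lda <- function(x, ...) {
  cat("Sliding-window Fisher discrimination:",
      length(x$windows$centers), "windows of", x$windows$width, "ms\n")
  cat("  lambda =", x$lambda, "| peak Az =", round(max(x$az), 3),
      "at", x$peak_window, "ms\n")
  invisible(x)
}

#' @export
summary.sliding_lda <- function(object, ...) {
  out <- data.frame(center_ms = object$windows$centers, az = object$az)
  attr(out, "peak_window") <- object$peak_window
  attr(out, "lambda") <- object$lambda
  out
}

#' Plot the cross-validated Az time course
#'
#' @param x A `sliding_lda`.
#' @param threshold Optional Az significance threshold to draw (e.g. from
#'   [permutation_threshold()]).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.sliding_lda <- function(x, threshold = NULL, ...) {
  graphics::plot(x$windows$centers, x$az, type = "l",
                 xlab = "window center (ms)", ylab = "LOO Az", ...)
  graphics::abline(h = 0.5, lty = 3)
  if (!is.null(threshold)) graphics::abline(h = threshold, lty = 2)
  graphics::abline(v = x$peak_window, col = "grey60")
  invisible(x)
}

#' Project new epochs through trained discriminant weights
#'
#' Applies the weights of one training window (the peak window by default)
#' to epochs that were not used for training, yielding single-trial
#' amplitudes on the same scale as the training projection.
#'
#' @param object A `sliding_lda`.
#' @param newepochs An [epoch_array()] with the same channels.
#' @param center Window center in ms (default the peak window).
#' @param ... Unused.
#' @return Numeric vector of per-trial amplitudes.
#' @export
predict.sliding_lda <- function(object, newepochs, center = NULL, ...) {
  if (is.null(center)) center <- object$peak_window
  k <- match(center, object$windows$centers)
  if (is.na(k)) stop("no training window centered at ", center, " ms")
  discriminant_amplitudes(newepochs, object$w[, k], center,
                          object$windows$width)
}

#' Select the covariance regularization by cross-validation
#'
#' Scores each candidate lambda by the mean leave-one-out Az over all
#' post-outcome windows (centers > 0 ms) and returns the maximizer;
#' ties go to the smaller lambda.
#'
#' @inheritParams sliding_lda
#' @param grid Candidate lambda values in \[0, 1\].
#' @return List with `lambda` (the selected value) and `az_mean` (mean Az
#'   per candidate).
#' @export
optimize_lambda <- function(epochs, labels, windows = window_spec(),
                            grid = c(0, 0.001, 0.01, 0.028, 0.05, 0.1,
                                     0.3, 1)) {
  stopifnot(all(grid >= 0), all(grid <= 1))
  grid <- sort(grid)
  post <- windows$centers[windows$centers > 0]
  Ms <- lapply(post, function(cc) window_average(epochs, cc, windows$width))
  az_mean <- vapply(grid, function(lam) {
    mean(vapply(Ms, function(M) {
      y <- tryCatch(loo_amplitudes(M, labels, lam), error = function(e) NULL)
      if (is.null(y)) return(NA_real_)
      az_score(y, labels)
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  az_mean[is.nan(az_mean)] <- -Inf
  list(lambda = grid[which.max(az_mean)], az_mean = az_mean, grid = grid)
}

#' Mean projected amplitude per surprise bin for unseen trials
#'
#' Applies trained spatial weights to trials that were held out of
#' training (e.g. intermediate-surprise trials) and averages the resulting
#' amplitudes within each surprise bin, ordered very_low to very_high.  A
#' parametric surprise component should yield strictly increasing bin
#' means.
#'
#' @param epochs_unseen [epoch_array()] of held-out trials.
#' @param w Trained weight vector.
#' @param center,width Training window of `w` (ms).
#' @param bins Factor of surprise-bin labels for the unseen trials (levels
#'   very_low, low, medium, high, very_high; see [surprise_bins()]).
#' @return Named numeric vector of bin means (NA for empty bins).
#' @export
project_unseen <- function(epochs_unseen, w, center, width = 60, bins) {
  y <- discriminant_amplitudes(epochs_unseen, w, center, width)
  lev <- c("very_low", "low", "medium", "high", "very_high")
  bins <- factor(bins, levels = lev)
  vapply(lev, function(b) {
    if (any(bins == b, na.rm = TRUE)) mean(y[which(bins == b)]) else NA_real_
  }, numeric(1))
}
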