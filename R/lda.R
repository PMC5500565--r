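#' Shrinkage-regularized covariance estimate
#'
#' Blends the sample covariance toward a spherical target with the same
#' trace: S_reg = (1 - lambda) S + lambda nu I, where nu = trace(S)/D is
#' the average eigenvalue.  lambda = 0 is the unregularized estimate,
#' lambda = 1 the spherical one; the trace is preserved for every lambda.
#'
#' @param X Trials x channels matrix (>= 2 rows).
#' @param lambda Regularization weight in \[0, 1\].
#' @return Channels x channels matrix.
#' @export
regularized_cov <- function(X, lambda = 0) {
  stopifnot(nrow(X) >= 2, lambda >= 0, lambda <= 1)
  S <- stats::cov(X)
  nu <- mean(diag(S))
  (1 - lambda) * S + lambda * nu * diag(ncol(X))
}

#' Regularized Fisher discriminant weights
#'
#' Computes the spatial weight vector w = Sc^-1 (m2 - m1), where m1, m2
#' are the class means and Sc the average of the two shrinkage-regularized
#' class covariances.  The second (positive) class projects to positive
#' amplitudes.  `invert = FALSE` gives the uninverted variant w = Sc (m2 -
#' m1) for comparison.
#'
#' @param Xa Class-1 (negative class) trials x channels matrix.
#' @param Xb Class-2 (positive class) trials x channels matrix.
#' @param lambda Covariance regularization in \[0, 1\].
#' @param invert Apply the matrix inverse (default TRUE).
#' @return Numeric weight vector of length channels.
#' @export
fisher_weights <- function(Xa, Xb, lambda = 0, invert = TRUE) {
  stopifnot(ncol(Xa) == ncol(Xb), nrow(Xa) >= 2, nrow(Xb) >= 2)
  Sc <- 0.5 * (regularized_cov(Xa, lambda) + regularized_cov(Xb, lambda))
  md <- colMeans(Xb) - colMeans(Xa)
  if (!invert) return(drop(Sc %*% md))
  w <- tryCatch(solve(Sc, md), error = function(e)
    stop("common covariance is singular; increase 'lambda' above 0 ",
         "(rank-deficient data)", call. = FALSE))
  drop(w)
}

#' Single-trial discriminator amplitudes
#'
#' Projects each trial's window-averaged sensor vector onto the
#' discriminant: y_i = w' x_i.  These amplitudes measure the distance of
#' individual trials from the discriminating hyperplane and form the
#' single-trial variability (STV) used as fMRI regressor amplitudes.
#'
#' @param epochs An [epoch_array()].
#' @param w Weight vector (length = channels).
#' @param center,width Training window (ms).
#' @return Numeric vector, one amplitude per trial.
#' @export
discriminant_amplitudes <- function(epochs, w, center, width = 60) {
  M <- window_average(epochs, center, width)
  stopifnot(length(w) == ncol(M))
  drop(M %*% w)
}

#' Area under the ROC curve
#'
#' Rank-based (Wilcoxon) Az of a score vector against binary labels; ties
#' count one half.
#'
#' @param y Numeric scores.
#' @param labels Logical or 0/1 vector; TRUE/1 is the positive class.
#' @return Az in \[0, 1\].
#' @export
az_score <- function(y, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  stopifnot(n1 > 0, n0 > 0)
  r <- rank(y)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Leave-one-out discriminator amplitudes for one window's data matrix.
loo_amplitudes <- function(M, labels, lambda = 0) {
  labels <- as.logical(labels)
  if (sum(labels) < 2 || sum(!labels) < 2)
    stop("leave-one-out requires at least 2 trials per class")
  n <- nrow(M)
  y <- numeric(n)
  for (i in seq_len(n)) {
    keep <- setdiff(seq_len(n), i)
    w <- fisher_weights(M[keep[!labels[keep]], , drop = FALSE],
                        M[keep[labels[keep]], , drop = FALSE], lambda)
    y[i] <- drop(M[i, ] %*% w)
  }
  y
}

#' Leave-one-out cross-validated Az for one training window
#'
#' For each trial, trains the regularized Fisher discriminant on all other
#' trials and scores the held-out trial; Az is the ROC area of the
#' held-out amplitudes against the labels.
#'
#' @inheritParams discriminant_amplitudes
#' @param labels Binary condition labels (TRUE/1 = positive class).
#' @param lambda Covariance regularization.
#' @return List with `az` and the held-out amplitudes `y`.
#' @export
loo_az <- function(epochs, labels, center, width = 60, lambda = 0) {
  M <- window_average(epochs, center, width)
  y <- loo_amplitudes(M, labels, lambda)
  list(az = az_score(y, labels), y = y)
}

#' Forward model (scalp pattern) of a discriminating component
#'
#' a = X y / (y'y), with X the channels x trials window-averaged data and
#' y the single-trial amplitudes.  The forward model expresses how the
#' component couples into the observed sensors and, unlike the backward
#' weights, is directly interpretable as a scalp topography.
#'
#' @inheritParams discriminant_amplitudes
#' @param y Per-trial discriminator amplitudes.
#' @return Numeric channel vector.
#' @export
forward_model <- function(epochs, y, center, width = 60) {
  M <- window_average(epochs, center, width)
  stopifnot(length(y) == nrow(M))
  ss <- sum(y^2)
  if (ss == 0) stop("amplitudes are all zero; forward model undefined")
  drop(crossprod(M, y)) / ss
}

#' Permutation null distribution for the LOO Az
#'
#' Repeats the leave-one-out discrimination after randomly permuting the
#' trial labels, building the null distribution of Az and the value
#' exceeded with probability `p` under the null.
#'
#' @inheritParams loo_az
#' @param n_perm Number of label permutations (default 1000).
#' @param p Significance level (default 0.01).
#' @param seed Optional integer seed.
#' @return An object of class `permutation_null`: list with `az_samples`,
#'   `threshold` (the empirical (1-p) quantile), `n_perm`, `p`.
#' @export
permutation_threshold <- function(epochs, labels, center, width = 60,
                                  lambda = 0, n_perm = 1000, p = 0.01,
                                  seed = NULL) {
  M <- window_average(epochs, center, width)
  with_seed(seed, {
    az <- vapply(seq_len(n_perm), function(k) {
      perm <- sample(labels)
      az_score(loo_amplitudes(M, perm, lambda), perm)
    }, numeric(1))
    structure(list(az_samples = az,
                   threshold = stats::quantile(az, 1 - p, type = 1,
                                               names = FALSE),
                   n_perm = n_perm, p = p),
              class = "permutation_null")
  })
}

#' @export
print.permutation_null <- function(x, ...) {
  cat("Permutation null of LOO Az:", x$n_perm, "permutations\n")
  cat("  Az threshold at P <", x$p, ":", round(x$threshold, 4), "\n")
  invisible(x)
}
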