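test_that("window averaging selects and averages the right samples", {
  # constant-in-time epochs: the average is that constant per channel
  arr <- array(rep(1:6, times = 10), c(2, 3, 10))
  ep <- epoch_array(arr, sfreq = 100, t0 = -0.05)
  M <- window_average(ep, center = 0, width = 60)
  expect_equal(M, matrix(1:6, 2, 3), ignore_attr = TRUE)
  # width of one sample period returns the single sample
  M1 <- window_average(ep, center = 0, width = 10)
  expect_equal(M1, arr[, , 6], ignore_attr = TRUE)
  # linear ramp over a symmetric window averages to the midpoint
  ramp <- array(rep(seq(0, 1, length.out = 101), each = 1), c(1, 1, 101))
  epr <- epoch_array(ramp, sfreq = 1000, t0 = -0.05)
  Mr <- window_average(epr, center = 0, width = 20)
  mid <- ramp[1, 1, 51]
  expect_equal(drop(Mr), mid - 0.005, tolerance = 1e-9)  # half-open bound
  expect_error(window_average(ep, center = 200, width = 60), "outside")
})

test_that("covariance shrinkage hits both endpoints and preserves trace", {
  set.seed(3)
  X <- matrix(rnorm(40), 10, 4) %*% matrix(rnorm(16), 4, 4)
  S0 <- regularized_cov(X, 0)
  expect_equal(S0, cov(X))
  S1 <- regularized_cov(X, 1)
  nu <- sum(diag(cov(X))) / 4
  expect_equal(S1, nu * diag(4))
  for (lam in c(0.1, 0.5, 0.9))
    expect_equal(sum(diag(regularized_cov(X, lam))), sum(diag(cov(X))))
})

test_that("Fisher weights match the explicit matrix-inverse oracle", {
  toy <- toy_clusters(n_per_class = 15, D = 2, sep = 2, seed = 4)
  lam <- 0.1
  w <- fisher_weights(toy$Xa, toy$Xb, lam)
  # brute-force 2x2 oracle: regularize each class covariance by hand,
  # average, invert with the closed-form 2x2 inverse
  reg <- function(X) {
    S <- cov(X); (1 - lam) * S + lam * mean(diag(S)) * diag(2)
  }
  Sc <- (reg(toy$Xa) + reg(toy$Xb)) / 2
  md <- colMeans(toy$Xb) - colMeans(toy$Xa)
  inv <- matrix(c(Sc[2, 2], -Sc[2, 1], -Sc[1, 2], Sc[1, 1]), 2, 2) /
    (Sc[1, 1] * Sc[2, 2] - Sc[1, 2] * Sc[2, 1])
  expect_equal(w, drop(inv %*% md), tolerance = 1e-10, ignore_attr = TRUE)

  # identical class means give a zero weight vector
  expect_equal(fisher_weights(toy$Xa, toy$Xa, 0.5), c(0, 0),
               ignore_attr = TRUE)
  # lambda = 1: w is proportional to the mean difference over nu
  w1 <- fisher_weights(toy$Xa, toy$Xb, 1)
  S1 <- cov(toy$Xa); S2 <- cov(toy$Xb)
  nu_c <- (mean(diag(S1)) + mean(diag(S2))) / 2
  expect_equal(w1, md / nu_c, tolerance = 1e-10, ignore_attr = TRUE)
  # rank-deficient data at lambda = 0 errors with advice
  set.seed(5)
  Xa <- matrix(rnorm(8), 2, 4); Xb <- matrix(rnorm(8), 2, 4) + 1
  expect_error(fisher_weights(Xa, Xb, 0), "lambda")
  # literal (uninverted) variant available behind the flag
  wl <- fisher_weights(toy$Xa, toy$Xb, lam, invert = FALSE)
  expect_equal(wl, drop(Sc %*% md), ignore_attr = TRUE)
})

test_that("discriminator amplitudes are linear in the weights", {
  toy <- toy_clusters(seed = 6)
  w <- fisher_weights(toy$Xa, toy$Xb, 0.1)
  y <- discriminant_amplitudes(toy$epochs, w, center = 0, width = 10)
  expect_equal(discriminant_amplitudes(toy$epochs, 2 * w, 0, 10), 2 * y)
  expect_equal(discriminant_amplitudes(toy$epochs, 0 * w, 0, 10),
               rep(0, length(y)))
  # positive class projects to larger amplitudes
  expect_gt(mean(y[toy$labels]), mean(y[!toy$labels]))
})

test_that("rank-based Az agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  y <- rnorm(60)
  lab <- rep(c(TRUE, FALSE), 30)
  expect_equal(az_score(y, lab),
               as.numeric(pROC::auc(pROC::roc(lab, y, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("leave-one-out Az separates planted clusters and rejects tiny classes", {
  toy <- toy_clusters(n_per_class = 12, D = 3, sep = 6, seed = 9)
  res <- loo_az(toy$epochs, toy$labels, center = 0, width = 10, lambda = 0.1)
  expect_equal(res$az, 1.0)
  expect_error(loo_az(toy$epochs, c(rep(FALSE, 23), TRUE), 0, 10, 0.1),
               "2 trials per class")
})

test_that("forward model inverts noise-free rank-one data exactly", {
  set.seed(10)
  a_true <- rnorm(6)
  y <- rnorm(20)
  arr <- array(0, c(20, 6, 1))
  arr[, , 1] <- outer(y, a_true)
  ep <- epoch_array(arr, 100, 0)
  a <- forward_model(ep, y, center = 0, width = 10)
  expect_equal(a, a_true, tolerance = 1e-12, ignore_attr = TRUE)
  # scaling y by c scales the pattern by 1/c
  expect_equal(forward_model(ep, 2 * y, 0, 10), a_true / 2,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(forward_model(ep, rep(0, 20), 0, 10), "all zero")
})

test_that("permutation null threshold exceeds chance and is reproducible", {
  toy <- toy_clusters(n_per_class = 10, D = 2, sep = 0, seed = 11)
  pn1 <- permutation_threshold(toy$epochs, toy$labels, 0, 10, lambda = 0.2,
                               n_perm = 60, p = 0.05, seed = 4)
  pn2 <- permutation_threshold(toy$epochs, toy$labels, 0, 10, lambda = 0.2,
                               n_perm = 60, p = 0.05, seed = 4)
  expect_identical(pn1$az_samples, pn2$az_samples)
  expect_gt(pn1$threshold, 0.5)
  expect_length(pn1$az_samples, 60)
  expect_gte(mean(pn1$az_samples <= pn1$threshold), 0.95)
})

test_that("lambda selection prefers regularization on rank-deficient data", {
  expect_equal(optimize_lambda(toy_clusters(seed = 1)$epochs,
                               toy_clusters(seed = 1)$labels,
                               window_spec(centers = 1, width = 10),
                               grid = 0.5)$lambda, 0.5)
  # channels > trials: lambda = 0 is singular, so a positive lambda wins
  set.seed(12)
  arr <- array(rnorm(14 * 20 * 3), c(14, 20, 3))
  arr[8:14, 1:3, ] <- arr[8:14, 1:3, ] + 1.5
  ep <- epoch_array(arr, 100, 0)
  lab <- rep(c(FALSE, TRUE), each = 7)
  sel <- optimize_lambda(ep, lab, window_spec(centers = 1, width = 10),
                         grid = c(0, 0.1, 0.5))
  expect_gt(sel$lambda, 0)
})

test_that("sliding discrimination reports per-window metrics and peak", {
  set.seed(13)
  b <- list(delta = runif(40, -1, 1) * rep(c(1, -1), 20))
  eeg <- gen_eeg(b, eeg_gen_config(n_channels = 8, sfreq = 100,
                                   valence_latency = 300, snr = 2),
                 seed = 14)
  lab <- eeg$latents$valence > 0
  sl <- sliding_lda(eeg$epochs, lab, window_spec(seq(100, 500, 50)),
                    lambda = 0.1)
  expect_s3_class(sl, "sliding_lda")
  expect_length(sl$az, 9)
  expect_equal(dim(sl$w), c(8, 9))
  expect_equal(sl$peak_window,
               sl$windows$centers[which.max(sl$az)])
  # predict on the training epochs at the peak reproduces stored y
  k <- match(sl$peak_window, sl$windows$centers)
  expect_equal(predict(sl, eeg$epochs), sl$y[, k])
  s <- summary(sl)
  expect_equal(names(s), c("center_ms", "az"))
})

test_that("unseen-trial projection averages amplitudes by surprise bin", {
  toy <- toy_clusters(n_per_class = 10, D = 2, sep = 4, seed = 15)
  w <- fisher_weights(toy$Xa, toy$Xb, 0.1)
  y_train <- discriminant_amplitudes(toy$epochs, w, 0, 10)
  bins <- rep(c("very_low", "very_high"), each = 10)
  m <- project_unseen(toy$epochs, w, 0, 10, bins)
  expect_equal(m[["very_high"]], mean(y_train[toy$labels]))
  expect_true(all(is.na(m[c("low", "medium", "high")])))
  # zero-signal unseen data projects to roughly zero
  set.seed(16)
  arr0 <- array(rnorm(30 * 2), c(30, 2, 1))
  m0 <- project_unseen(epoch_array(arr0, 100, 0), w, 0, 10,
                       rep("medium", 30))
  # near zero relative to the training class separation
  sep <- mean(y_train[toy$labels]) - mean(y_train[!toy$labels])
  expect_lt(abs(m0[["medium"]]) / sep, 0.25)
})

test_that("epoch arrays round-trip through the text serialization", {
  set.seed(17)
  ep <- epoch_array(array(rnorm(4 * 3 * 5), c(4, 3, 5)), 250, -0.2,
                    c("Fz", "Cz", "Pz"))
  base <- tempfile()
  write_epochs(ep, base)
  back <- read_epochs(base)
  expect_equal(back$data, ep$data, tolerance = 1e-9)
  expect_equal(back$channel_names, ep$channel_names)
  expect_equal(back$sfreq, ep$sfreq)
  unlink(paste0(base, c(".tsv", ".json")))
})
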