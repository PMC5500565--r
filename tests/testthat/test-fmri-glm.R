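test_that("double-gamma HRF has the canonical shape", {
  h <- double_gamma_hrf(0.01)
  t <- seq(0, 32, by = 0.01)
  expect_equal(h[1], 0)
  expect_lt(abs(t[which.max(h)] - 5), 0.02)  # peak of gamma(6,1) is at 5 s
  expect_equal(max(h), 1)
  # exactly one sign change: positive lobe then undershoot
  s <- sign(h[abs(h) > 1e-8])
  expect_equal(sum(diff(s) != 0), 1)
})

test_that("regressor construction is linear and peaks at the HRF lag", {
  empty <- event_regressor(numeric(0), name = "none")
  expect_equal(build_regressor(empty, TR = 2, n_volumes = 20), rep(0, 20))
  ev <- event_regressor(c(3, 11), amplitudes = c(1, 2))
  r1 <- build_regressor(ev, TR = 2, n_volumes = 30)
  ev2 <- event_regressor(c(3, 11), amplitudes = c(2, 4))
  expect_equal(build_regressor(ev2, TR = 2, n_volumes = 30), 2 * r1)
  # single event at t = 0: sampled peak sits at the volume nearest the
  # HRF peak, verified against a direct dense convolution
  single <- event_regressor(0)
  col <- build_regressor(single, TR = 1, n_volumes = 30, dt = 0.01)
  dense_t <- seq(0, 29, by = 0.01)
  box <- as.numeric(dense_t < 0.1)
  dense <- stats::convolve(box, rev(double_gamma_hrf(0.01)), type = "open")
  peak_t <- dense_t[which.max(dense[seq_along(dense_t)])]
  expect_equal(which.max(col) - 1, round(peak_t))
  expect_error(build_regressor(event_regressor(100), TR = 1, n_volumes = 20),
               "beyond")
})

test_that("the outcome-phase design has the documented columns", {
  b <- small_session(n_trials = 24, seed = 31)
  n_vol <- ceiling(max(b$session$trials$onset_s) / 2.5) + 10
  set.seed(1)
  des <- build_design_glm1(b$session,
                           y_late_val = sign(b$trace$delta),
                           model_surprise = b$trace$surprise,
                           y_late_sur = b$trace$surprise + rnorm(24, 0, 0.3),
                           y_early_val = rnorm(24),
                           motion = matrix(rnorm(n_vol * 6), n_vol, 6),
                           lost_onsets = c(40, 90),
                           TR = 2.5, n_volumes = n_vol)
  expect_equal(ncol(des$X), 13)  # 7 task + 6 motion
  expect_equal(des$names[1:7],
               c("UM", "EEG_LateVal", "MODEL_Sur", "EEG_LateSur",
                 "EEG_EarlyVal", "LOST", "DEC"))
  # parametric columns are mean-centered before convolution
  expect_warning(
    build_design_glm1(b$session, rep(1, 24), b$trace$surprise,
                      b$trace$surprise + rnorm(24, 0, 0.3), rnorm(24),
                      lost_onsets = 1, TR = 2.5, n_volumes = n_vol),
    "collinear")
  expect_warning(
    build_design_glm1(b$session, sign(b$trace$delta), b$trace$surprise,
                      b$trace$surprise + rnorm(24, 0, 0.3), rnorm(24),
                      TR = 2.5, n_volumes = n_vol),
    "LOST")
})

test_that("voxelwise OLS recovers noise-free betas and calibrated Z", {
  set.seed(32)
  n_vol <- 80
  X <- cbind(UM = 1, a = rnorm(n_vol), b = rnorm(n_vol))
  beta_true <- c(2, -1.5, 0.5)
  grid <- c(6, 6, 4)
  clean <- array(rep(as.numeric(X %*% beta_true), each = prod(grid)),
                 c(grid, n_vol))
  fit <- bold_glm(volume_series(clean, 2), X)
  expect_lt(max(abs(sweep(fit$beta, 2, beta_true))), 1e-8)

  # pure-noise voxels: Z is standard normal across voxels
  noise <- array(rnorm(prod(grid) * n_vol * 9), c(grid * c(3, 3, 1), n_vol))
  fitn <- bold_glm(volume_series(noise, 2), X)
  expect_gt(length(fitn$voxels), 1000)
  expect_lt(abs(sd(fitn$z[, "a"]) - 1), 0.05)
  expect_lt(abs(mean(fitn$z[, "a"])), 0.05)

  # orthonormal design: beta equals X'Y
  Q <- qr.Q(qr(matrix(rnorm(n_vol * 2), n_vol, 2)))
  colnames(Q) <- c("q1", "q2")
  y1 <- array(rnorm(8 * n_vol), c(2, 2, 2, n_vol))
  fq <- bold_glm(volume_series(y1, 2), Q)
  Ymat <- t(matrix(y1, 8, n_vol))
  expect_equal(fq$beta, t(crossprod(Q, Ymat)), tolerance = 1e-10,
               ignore_attr = TRUE)

  Xbad <- cbind(UM = 1, dup = rep(1, n_vol))
  expect_error(bold_glm(volume_series(y1, 2), Xbad), "dup")
})

test_that("GLM beta scales inversely with amplitude rescaling", {
  b <- small_session(n_trials = 24, seed = 33)
  n_vol <- ceiling(max(b$session$trials$onset_s) / 2.5) + 8
  amp <- b$trace$surprise - mean(b$trace$surprise)
  mk <- function(a) build_design(list(
    event_regressor(b$session$trials$onset_s, 0.1, 1, "UM"),
    event_regressor(b$session$trials$onset_s, 0.1, a, "par")),
    TR = 2.5, n_volumes = n_vol)
  set.seed(2)
  Y <- volume_series(array(rnorm(8 * n_vol), c(2, 2, 2, n_vol)), 2.5)
  b1 <- bold_glm(Y, mk(amp))$beta[, "par"]
  b3 <- bold_glm(Y, mk(3 * amp))$beta[, "par"]
  expect_equal(b3, b1 / 3, tolerance = 1e-10)
})

test_that("group-level one-sample Z behaves at the extremes", {
  d <- c(4, 4, 2)
  same <- lapply(1:5, function(i) array(0.8, d))
  zg <- group_level(same)
  expect_true(all(zg > 10))
  set.seed(34)
  null <- lapply(1:40, function(i) array(rnorm(prod(d)), d))
  zn <- group_level(null)
  expect_lt(abs(sd(zn) - 1), 0.15)
  expect_error(group_level(null[1]), "2 subjects")
})

test_that("cluster extraction respects threshold and connectivity", {
  z <- array(0, c(8, 8, 4))
  expect_length(extract_clusters(z, 2.57), 0)
  z[3:5, 3:5, 2:4] <- 5
  cl <- extract_clusters(z, 2.57)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$size, 27)
  expect_equal(cl[[1]]$sign, 1)
  # two blocks touching only at a corner: one cluster under 26-connectivity,
  # two under 6-connectivity
  z2 <- array(0, c(8, 8, 4))
  z2[1:2, 1:2, 1:2] <- -4
  z2[3:4, 3:4, 3:4] <- -4
  expect_length(extract_clusters(z2, 2.57, 26), 1)
  expect_length(extract_clusters(z2, 2.57, 6), 2)
  expect_equal(extract_clusters(z2, 2.57, 6)[[1]]$sign, -1)
})

test_that("conjunction is a voxelwise intersection", {
  m1 <- array(FALSE, c(4, 4, 2)); m2 <- m1
  m1[1:2, 1, 1] <- TRUE
  m2[3:4, 1, 1] <- TRUE
  expect_false(any(conjunction(list(m1, m2))))
  expect_equal(conjunction(list(m1, m1)), m1)
  m2[1:2, 1, 1] <- TRUE
  expect_equal(sum(conjunction(list(m1, m2))), 2)
  expect_error(conjunction(list(m1, array(TRUE, c(2, 2, 2)))), "grid")
})

test_that("percent signal change identities hold exactly", {
  expect_true(all(psc(rep(7, 60), c(30, 60), TR = 2.5)$psc == 0))
  set.seed(35)
  ts <- 100 + rnorm(80)
  p1 <- psc(ts, c(40, 100), TR = 2.5)
  p2 <- psc(5 * ts, c(40, 100), TR = 2.5)
  expect_equal(p1$psc, p2$psc, tolerance = 1e-12)
  expect_equal(dim(p1$psc), c(2, 7))
  # direct substitution: Xbar = 100, baseline 100, value 102 -> PSC = 2
  ts3 <- rep(100, 40)
  onset <- 10 * 2.5  # exactly at volume 11
  ts3[11 + 2] <- 102
  ts3 <- ts3 + (100 - mean(ts3))  # keep the run mean at 100
  p3 <- psc(ts3, onset, TR = 2.5)
  expect_equal(p3$psc[1, "vol2"], 2, tolerance = 1e-6, ignore_attr = TRUE)
  expect_warning(psc(ts, 1, TR = 2.5), "edge")
  expect_length(psc_summary(p1), 2)
})

test_that("value-update regression recovers slopes and tests direction", {
  set.seed(36)
  x <- lapply(1:6, function(i) rnorm(50))
  y2 <- lapply(x, function(xi) 2 * xi)
  res <- psc_value_update_regression(x, y2)
  expect_equal(unname(res$slopes), rep(2, 6), tolerance = 1e-10)
  expect_lt(res$p, 1e-6)
  # wrong-direction effect is not detected by the one-tailed test
  yneg <- lapply(x, function(xi) -xi)
  expect_gt(psc_value_update_regression(x, yneg)$p, 0.99)
  # independent data: slopes near zero
  yind <- lapply(x, function(xi) rnorm(50))
  expect_lt(abs(mean(psc_value_update_regression(x, yind)$slopes)), 0.2)
  expect_true(is.na(
    psc_value_update_regression(rep(1, 10), rnorm(10))$slopes))
})
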