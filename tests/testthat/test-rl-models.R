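test_that("RPE and the model-free update follow the delta rule", {
  expect_equal(rpe(0, 1), 1)
  expect_equal(rpe(1, 1), 0)
  expect_equal(rpe(0.5, 0), -0.5)
  expect_error(rpe(0.5, 2), "must be 0 or 1")
  expect_equal(update_value_mf(0.5, 0.5, 0.3), 0.65)
  expect_equal(update_value_mf(0.7, -0.2, 0), 0.7)
  expect_equal(update_value_mf(0.3, rpe(0.3, 1), 1), 1)
})

test_that("smoothed surprise slope behaves like an exponential smoother", {
  const <- smoothed_surprise_slope(rep(0.4, 50), 0.2)
  expect_equal(const$m[50], 0)
  x <- c(rep(0.1, 10), rep(0.9, 5))
  expect_gt(smoothed_surprise_slope(x, 0.3)$m[11], 0)
  # smoothing constant 1 reduces the slope to first differences
  y <- runif(10)
  expect_equal(smoothed_surprise_slope(y, 1)$m, c(0, diff(y)))
})

test_that("dynamic learning-rate updates move alpha the right way", {
  expect_gte(update_dynamic_alpha(0.3, 0.2, 1), 0.3)
  expect_lte(update_dynamic_alpha(0.3, -0.2, 1), 0.3)
  expect_equal(update_dynamic_alpha(0.3, 0, 1), 0.3)
  # large stiffness freezes the rate
  expect_equal(update_dynamic_alpha(0.3, 0.5, 50), 0.3, tolerance = 1e-12)
  # rate stays inside (0, 1) for arbitrary slopes
  set.seed(1)
  for (k in 1:200) {
    a <- update_dynamic_alpha(runif(1), runif(1, -2, 2), runif(1, -2, 4))
    expect_true(a > 0 && a < 1)
  }
})

test_that("stimulus-outcome contingency updates only the chosen entry", {
  SO <- matrix(0.5, 3, 2, dimnames = list(c("A", "B", "C"), c("0", "1")))
  SO1 <- update_so_mb(SO, "A", 1, 0.2)
  expect_equal(SO1["A", "1"], 0.6)
  expect_equal(SO1[-1, ], SO[-1, ])
  SO["B", "0"] <- 0
  expect_equal(update_so_mb(SO, "B", 0, 1)["B", "0"], 1)
  SO["C", "1"] <- 1
  expect_equal(update_so_mb(SO, "C", 1, 0.5)["C", "1"], 1)
})

test_that("softmax choice probabilities are complementary and saturate", {
  expect_equal(choice_prob(0.5, 0.5, 3, 0), 0.5)
  expect_equal(choice_prob(0.9, 0.1, 0, 0), 0.5)
  expect_gt(choice_prob(1, 0, 50, 0), 0.999)
  p <- choice_prob(0.62, 0.31, 4.2, 0.3)
  expect_equal(p + (1 - p), 1)
})

test_that("class-normalized likelihood matches hand-computed cases", {
  tt <- toy_trials()
  # beta = 0: every choice probability is 0.5; three classes each
  # contribute log 0.5
  nll <- neg_log_likelihood(list(alpha = 0.3, beta = 0, phi = 0), tt, "mf")
  expect_equal(-nll, 3 * log(0.5), tolerance = 1e-12)
  # a symbol never chosen contributes nothing
  tt2 <- tt[tt$choice != "C", ]
  nll2 <- neg_log_likelihood(list(alpha = 0.3, beta = 0, phi = 0), tt2, "mf")
  expect_equal(-nll2, 2 * log(0.5), tolerance = 1e-12)
  # near-deterministic data evaluated at its generating parameters has
  # near-zero normalized log-likelihood
  b <- gen_behavior(list(alpha = 0.5, beta = 60, phi = 0),
                    task_config(n_blocks = 1), seed = 8)
  nll3 <- neg_log_likelihood(list(alpha = 0.5, beta = 60, phi = 0),
                             b$session, "mf")
  expect_lt(nll3, 0.6)       # far below the chance value of 3 log 2
  expect_lt(nll3, nll / 3)
})

test_that("values and RPEs stay bounded for arbitrary sessions", {
  set.seed(33)
  for (k in 1:5) {
    params <- list(alpha = runif(1), beta = runif(1, 0, 10),
                   phi = rnorm(1, 0, 0.5), gamma = runif(1, 0, 4),
                   smooth_const = 0.1)
    model <- sample(c("mf", "dyn", "mb"), 1)
    b <- gen_behavior(params, task_config(n_blocks = 1,
                                          trials_per_block = 80),
                      model = model)
    tr <- latent_trace(params, b$session, model)
    expect_true(all(tr$v >= 0 & tr$v <= 1))
    expect_true(all(abs(tr$delta) <= 1))
    expect_true(all(tr$alpha_t >= 0 & tr$alpha_t <= 1))
  }
})

test_that("latent traces match the closed-form special cases", {
  b <- small_session(seed = 4)
  tr0 <- latent_trace(list(alpha = 0, beta = 5, phi = 0), b$session, "mf")
  expect_true(all(tr0$v == 0.5))
  expect_equal(tr0$delta, b$session$trials$outcome - 0.5)
  trf <- latent_trace(gen_params(), b$session, "mf")
  expect_equal(trf$value_update, trf$alpha_t * trf$delta, tolerance = 1e-12)
  expect_true(all(trf$alpha_t == 0.3))
})

test_that("very stiff dynamic model reproduces the fixed-rate trajectory", {
  b <- small_session(n_trials = 120, seed = 5)
  fixed <- latent_trace(gen_params(), b$session, "mf")
  dyn <- latent_trace(c(gen_params(), gamma = 30, smooth_const = 0.1),
                      b$session, "dyn")
  expect_lt(max(abs(fixed$v - dyn$v)), 1e-6)
  expect_lt(max(abs(fixed$delta - dyn$delta)), 1e-6)
})

test_that("surprise bins use the canonical ranges with lower-bound ties", {
  expect_equal(as.character(surprise_bins(c(0.9, 0.1, 0.5))),
               c("very_high", "very_low", "medium"))
  expect_equal(as.character(surprise_bins(c(0, 0.2, 1))),
               c("very_low", "very_low", "very_high"))
  expect_true(is.ordered(surprise_bins(0.3)))
})

test_that("BIC penalizes complexity on the printed scale", {
  expect_equal(bic_score(0, 0, 10), 0)
  expect_equal(bic_score(-2.079, 3, 340), 4.158 + 3 * log(340))
})

test_that("behavioral table flags stays and reaction-time changes", {
  b <- small_session(n_trials = 30, seed = 6)
  tab <- build_behavioral_table(b$session, b$trace, rts = b$rts)
  n <- nrow(tab)
  expect_equal(n, 30)
  expect_true(is.na(tab$stay[n]))
  # stay is defined exactly when this trial's choice is offered next trial
  tr <- b$session$trials
  offered_next <- vapply(seq_len(n - 1), function(i)
    tr$choice[i] %in% strsplit(tr$pair[i + 1], "")[[1]], logical(1))
  expect_equal(!is.na(tab$stay[-n]), offered_next)
  expect_equal(tab$delta_rt[-n], diff(tab$rt))
  tab2 <- build_behavioral_table(b$session, b$trace)
  expect_false("delta_rt" %in% names(tab2))
})
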