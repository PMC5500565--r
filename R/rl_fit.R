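#' Fit a reinforcement-learning model by maximum likelihood
#'
#' Fits one of three observer models to a session of reversal-learning
#' choices: `"mf"` -- model-free Rescorla-Wagner with a fixed learning rate
#' (parameters alpha, beta, phi); `"dyn"` -- the same with a dynamically
#' updating learning rate driven by the slope of the smoothed unsigned RPE
#' (adds the stiffness gamma); `"mb"` -- a model-based variant learning a
#' stimulus-outcome contingency matrix (alpha, beta, phi).
#'
#' Optimization runs in unconstrained space (logit alpha, log beta, raw
#' phi, log gamma) with Nelder-Mead from `n_starts` random initializations;
#' the best of the converged starts is returned.
#'
#' @param data A `session_data` object or trial data.frame (columns `pair`,
#'   `choice`, `outcome`).
#' @param model One of "mf", "dyn", "mb".
#' @param n_starts Number of random restarts (>= 1).
#' @param seed Optional integer seed for the starting points.
#' @param smooth_const Smoothing constant of the surprise trace (dynamic
#'   model only).
#' @return An object of class `rl_fit` with components `params` (fitted
#'   parameters on the natural scale), `logL` (normalized log-likelihood),
#'   `bic`, `n_trials`, `model_name`, `n_starts`, `converged`.
#' @examples
#' sess <- gen_behavior(list(alpha = 0.3, beta = 5, phi = 0), seed = 1)
#' fit <- rl_fit(sess$session, "mf", n_starts = 4, seed = 2)
#' coef(fit)
#' @seealso [latent_trace()], [compare_rl_models()]
#' @export
rl_fit <- function(data, model = c("mf", "dyn", "mb"), n_starts = 10L,
                   seed = NULL, smooth_const = 0.1) {
  model <- match.arg(model)
  trials <- if (inherits(data, "session_data")) data$trials else data
  if (nrow(trials) == 0) stop("empty trial table")
  d <- if (model == "dyn") 4L else 3L
  enc <- encode_trials(trials)

  obj <- function(theta) {
    p <- theta_to_params(theta, model, smooth_const)
    val <- nll_enc(p, enc, model)
    if (!is.finite(val)) 1e10 else val
  }

  with_seed(seed, {
    starts <- lapply(seq_len(n_starts), function(k) {
      if (k == 1L) {
        th <- c(a = stats::qlogis(0.3), b = log(3), phi = 0)
        if (model == "dyn") th <- c(th, g = log(3))
        th
      } else {
        th <- c(a = stats::rnorm(1, 0, 1.5), b = stats::rnorm(1, 0.8, 1),
                phi = stats::rnorm(1, 0, 0.5))
        if (model == "dyn") th <- c(th, g = stats::rnorm(1, 1, 1))
        th
      }
    })
    fits <- lapply(starts, function(th) {
      tryCatch(stats::optim(th, obj, method = "Nelder-Mead",
                            control = list(maxit = 1000)),
               error = function(e) NULL)
    })
    ok <- !vapply(fits, is.null, logical(1))
    if (!any(ok)) stop("all ", n_starts, " optimization starts failed for model '",
                       model, "'")
    fits <- fits[ok]
    vals <- vapply(fits, function(f) f$value, numeric(1))
    best <- fits[[which.min(vals)]]

    params <- theta_to_params(best$par, model, smooth_const)
    logL <- -best$value
    n <- nrow(trials)
    out <- list(params = params, logL = logL,
                bic = bic_score(logL, d, n),
                n_trials = n, model_name = model, n_starts = n_starts,
                converged = best$convergence == 0,
                n_free = d, trials = trials, optim = best)
    class(out) <- "rl_fit"
    out
  })
}

theta_to_params <- function(theta, model, smooth_const = 0.1) {
  p <- list(alpha = stats::plogis(theta[["a"]]),
            beta = exp(theta[["b"]]),
            phi = theta[["phi"]])
  if (model == "dyn") {
    p$gamma <- exp(theta[["g"]])
    p$smooth_const <- smooth_const
  }
  p
}

#' @export
print.rl_fit <- function(x, ...) {
  cat("RL model fit (", x$model_name, "), ", x$n_trials, " trials\n", sep = "")
  print(round(unlist(x$params), 4))
  cat("logL =", round(x$logL, 4), "  BIC =", round(x$bic, 3),
      if (!x$converged) " (not converged)" else "", "\n")
  invisible(x)
}

#' @export
summary.rl_fit <- function(object, ...) {
  tr <- latent_trace(object$params, object$trials, object$model_name)
  out <- list(fit = object,
              mean_p_choice = mean(tr$p_choice),
              mean_surprise = mean(tr$surprise),
              frac_positive_rpe = mean(tr$delta > 0))
  class(out) <- "summary.rl_fit"
  out
}

#' @export
print.summary.rl_fit <- function(x, ...) {
  print(x$fit)
  cat("mean P(chosen) =", round(x$mean_p_choice, 3),
      "| mean |RPE| =", round(x$mean_surprise, 3),
      "| frac positive RPE =", round(x$frac_positive_rpe, 3), "\n")
  invisible(x)
}

#' @export
coef.rl_fit <- function(object, ...) {
  unlist(object$params[setdiff(names(object$params), "smooth_const")])
}

#' @export
logLik.rl_fit <- function(object, ...) {
  structure(object$logL, df = object$n_free, nobs = object$n_trials,
            class = "logLik")
}

#' Per-trial choice probabilities of a fitted RL model
#'
#' @param object An `rl_fit`.
#' @param newdata Optional trial table; defaults to the fitting data.
#' @param type `"choice"` for the probability of the observed choice,
#'   `"first"` for the probability of the first-listed symbol of each pair.
#' @param ... Unused.
#' @return Numeric vector, one probability per trial.
#' @export
predict.rl_fit <- function(object, newdata = NULL, type = c("choice", "first"),
                           ...) {
  type <- match.arg(type)
  trials <- if (is.null(newdata)) object$trials
            else if (inherits(newdata, "session_data")) newdata$trials
            else newdata
  fw <- rl_forward(object$params, trials, object$model_name)
  if (type == "choice") fw$p_choice else fw$p_first
}

#' @export
residuals.rl_fit <- function(object, ...) {
  # observed choice of the first-listed symbol minus its model probability
  fw <- rl_forward(object$params, object$trials, object$model_name)
  first <- substr(object$trials$pair, 1, 1)
  as.numeric(object$trials$choice == first) - fw$p_first
}

#' Simulate sessions from a fitted RL model
#'
#' Generates new reversal-learning sessions in which a softmax agent with
#' the fitted parameters plays the task.
#'
#' @param object An `rl_fit`.
#' @param nsim Number of sessions.
#' @param seed Optional integer seed.
#' @param config A [task_config()].
#' @param ... Unused.
#' @return A list of `session_data` objects (length `nsim`).
#' @export
simulate.rl_fit <- function(object, nsim = 1, seed = NULL,
                            config = task_config(), ...) {
  with_seed(seed, {
    lapply(seq_len(nsim), function(k)
      gen_behavior(object$params, config, model = object$model_name)$session)
  })
}

#' Calibration plot of a fitted RL model
#'
#' Bins the model's predicted choice probabilities (for the first-listed
#' symbol of each pair) into deciles and plots the observed choice
#' frequency in each bin against the mean predicted probability; a
#' well-calibrated model lies on the diagonal.
#'
#' @param x An `rl_fit`.
#' @param bins Number of probability bins.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.rl_fit <- function(x, bins = 10, ...) {
  p <- predict(x, type = "first")
  obs <- as.numeric(x$trials$choice == substr(x$trials$pair, 1, 1))
  cut_idx <- cut(p, seq(0, 1, length.out = bins + 1), include.lowest = TRUE)
  px <- tapply(p, cut_idx, mean)
  ox <- tapply(obs, cut_idx, mean)
  graphics::plot(px, ox, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "predicted choice probability",
                 ylab = "observed choice frequency", ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Write a subject-by-model fit table
#'
#' Serializes a [compare_rl_models()] result as a tab-delimited table with
#' one row per subject and model (parameters, log-likelihood, BIC).
#'
#' @param cmp A [compare_rl_models()] result.
#' @param path Output file.
#' @return Invisibly, the written data.frame.
#' @export
write_fit_table <- function(cmp, path) {
  rows <- list()
  for (s in seq_along(cmp$fits)) {
    for (m in names(cmp$fits[[s]])) {
      f <- cmp$fits[[s]][[m]]
      pars <- unlist(f$params[setdiff(names(f$params), "smooth_const")])
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s, model = m,
        t(pars), logL = f$logL, bic = f$bic,
        n_trials = f$n_trials, converged = f$converged)
    }
  }
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    r[setdiff(all_cols, names(r))] <- NA
    r[all_cols]
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' Fit and compare RL models across subjects by summed BIC
#'
#' Fits each requested model to each subject's session and ranks models by
#' the sum of subject-wise BIC scores (lower is better).
#'
#' @param data_list List of `session_data` objects (or trial data.frames),
#'   one per subject.
#' @param models Character vector of model names.
#' @param n_starts Random restarts per fit.
#' @param seed Optional integer seed.
#' @return A list with `bic` (subjects x models matrix), `total` (named
#'   summed BIC), `best` (name of the lowest-total model), and `fits`.
#' @export
compare_rl_models <- function(data_list, models = c("mf", "dyn", "mb"),
                              n_starts = 5L, seed = NULL) {
  with_seed(seed, {
    fits <- lapply(data_list, function(d)
      lapply(stats::setNames(models, models), function(m)
        rl_fit(d, m, n_starts = n_starts)))
    bic <- t(vapply(fits, function(fs)
      vapply(fs, function(f) f$bic, numeric(1)), numeric(length(models))))
    colnames(bic) <- models
    total <- colSums(bic)
    list(bic = bic, total = total, best = names(which.min(total)), fits = fits)
  })
}
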