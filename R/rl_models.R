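#' Reward prediction error
#'
#' The signed RPE is the difference between the observed binary outcome and
#' the expected value of the chosen option: delta = r - v.  Its sign is the
#' outcome "valence", its magnitude |delta| the outcome "surprise".
#'
#' @param v Expected value in \[0, 1\].
#' @param r Observed outcome, 0 or 1.
#' @return Signed prediction error in \[-1, 1\].
#' @export
rpe <- function(v, r) {
  if (!all(r %in% c(0, 1))) stop("outcome 'r' must be 0 or 1")
  r - v
}

#' Model-free (Rescorla-Wagner) value update
#'
#' v' = v + alpha * delta.  Only the chosen symbol's value is updated by the
#' caller; unchosen and unshown symbols keep their values.
#'
#' @param v Current value.
#' @param delta Signed RPE.
#' @param alpha Learning rate in \[0, 1\].
#' @return Updated value.
#' @export
update_value_mf <- function(v, delta, alpha) {
  stopifnot(alpha >= 0, alpha <= 1)
  v + alpha * delta
}

#' Exponentially smoothed surprise trace and its slope
#'
#' Smooths the unsigned-RPE sequence with s(i) = s(i-1) + c * (|d(i)| -
#' s(i-1)), initialized at the first |d|, and returns the per-trial slope
#' m(i) = s(i) - s(i-1) that drives the dynamic learning rate.
#'
#' @param surprise_history Numeric vector of |delta| values.
#' @param smooth_const Smoothing constant c in (0, 1].
#' @return List with components `s` (smoothed trace) and `m` (slope; 0 on
#'   the first trial).
#' @export
smoothed_surprise_slope <- function(surprise_history, smooth_const = 0.1) {
  stopifnot(length(surprise_history) >= 1,
            smooth_const > 0, smooth_const <= 1)
  n <- length(surprise_history)
  s <- numeric(n); m <- numeric(n)
  s[1] <- surprise_history[1]
  if (n > 1) for (i in 2:n) {
    s[i] <- s[i - 1] + smooth_const * (surprise_history[i] - s[i - 1])
    m[i] <- s[i] - s[i - 1]
  }
  list(s = s, m = m)
}

#' Slope-to-rate transfer function of the dynamic learning-rate model
#'
#' Maps the smoothed-surprise slope m into \[0, 1); the stiffness gamma sets
#' how large a slope is needed before the learning rate moves.  f(0) = 0 and
#' f becomes negligible for large gamma, in which case the dynamic model
#' collapses onto the fixed-rate model.
#'
#' @param m Slope of the smoothed unsigned RPE.
#' @param gamma Stiffness parameter (> 0; fitted on the log scale).
#' @return Value in \[0, 1).
#' @export
rate_transfer <- function(m, gamma) {
  am <- abs(m)
  am / (am + exp(gamma))
}

#' Dynamic learning-rate update
#'
#' Positive slopes of the smoothed surprise trace push the learning rate up
#' toward 1 (recent outcomes have been more surprising, so learn faster);
#' negative slopes shrink it toward 0.  The magnitude of the move is
#' f(m) = |m| / (|m| + exp(gamma)).
#'
#' @param alpha_prev Learning rate before the update, in (0, 1).
#' @param m Slope of the smoothed unsigned RPE.
#' @param gamma Stiffness parameter.
#' @return Updated learning rate in (0, 1).
#' @export
update_dynamic_alpha <- function(alpha_prev, m, gamma) {
  f <- rate_transfer(m, gamma)
  if (m > 0) alpha_prev + f * (1 - alpha_prev)
  else if (m < 0) alpha_prev - f * alpha_prev
  else alpha_prev
}

#' Stimulus-outcome contingency update (model-based variant)
#'
#' Only the entry for the chosen symbol and observed outcome type is moved
#' toward 1: SO'(s, r) = SO(s, r) + alpha * (1 - SO(s, r)).  The chosen
#' symbol's value is then read out as v = SO'(s, 1).
#'
#' @param SO Contingency matrix (symbols x outcome types, columns "0","1").
#' @param s Chosen symbol (row name or index).
#' @param r Observed outcome, 0 or 1.
#' @param alpha Learning rate.
#' @return Updated matrix.
#' @export
update_so_mb <- function(SO, s, r, alpha) {
  col <- as.character(r)
  delta_so <- 1 - SO[s, col]
  SO[s, col] <- SO[s, col] + alpha * delta_so
  SO
}

#' Softmax choice probability
#'
#' P(choose a) = logistic(beta * (v_a - v_b) - phi), where beta is the
#' inverse temperature (exploration/exploitation) and phi the indecision
#' offset applied to the first-listed symbol of the pair.
#'
#' @param v_a,v_b Values of the two offered symbols.
#' @param beta Inverse temperature (>= 0).
#' @param phi Indecision offset.
#' @return Probability of choosing the first symbol.
#' @export
choice_prob <- function(v_a, v_b, beta, phi = 0) {
  stopifnot(beta >= 0)
  stats::plogis(beta * (v_a - v_b) - phi)
}

# Integer-encode a trial table once so that repeated likelihood
# evaluations inside the optimizer avoid string matching.
encode_trials <- function(trials) {
  s1c <- substr(trials$pair, 1, 1)
  s2c <- substr(trials$pair, 2, 2)
  symbols <- sort(unique(c(s1c, s2c)))
  list(s1 = match(s1c, symbols), s2 = match(s2c, symbols),
       ch = match(trials$choice, symbols),
       r = as.numeric(trials$outcome),
       chose_first = trials$choice == s1c,
       symbols = symbols, n = nrow(trials))
}

# Forward pass of an RL observer model over an encoded trial table.
# Returns per-trial values (before update), RPE, surprise, learning rate,
# value update, choice probabilities, and the final SO matrix (mb only).
rl_forward_enc <- function(params, enc, model) {
  n <- enc$n
  nS <- length(enc$symbols)
  v <- rep(0.5, nS)
  SO <- if (model == "mb")
    matrix(0.5, nS, 2, dimnames = list(enc$symbols, c("0", "1"))) else NULL
  alpha <- params$alpha
  beta <- params$beta; phi <- params$phi
  sc <- if (is.null(params$smooth_const)) 0.1 else params$smooth_const
  v_mat <- matrix(NA_real_, n, nS, dimnames = list(NULL, enc$symbols))
  delta <- numeric(n); alpha_t <- numeric(n); dv <- numeric(n)
  p_first <- numeric(n)
  s_smooth <- 0
  dyn <- model == "dyn"; mb <- model == "mb"

  for (i in seq_len(n)) {
    v_mat[i, ] <- v
    ch <- enc$ch[i]
    p_first[i] <- 1 / (1 + exp(-(beta * (v[enc$s1[i]] - v[enc$s2[i]]) - phi)))
    d <- enc$r[i] - v[ch]
    delta[i] <- d

    if (dyn) {
      if (i == 1L) {
        s_smooth <- abs(d); m <- 0
      } else {
        s_new <- s_smooth + sc * (abs(d) - s_smooth)
        m <- s_new - s_smooth
        s_smooth <- s_new
      }
      alpha <- update_dynamic_alpha(alpha, m, params$gamma)
    }
    alpha_t[i] <- alpha

    v_old <- v[ch]
    if (mb) {
      col <- enc$r[i] + 1
      SO[ch, col] <- SO[ch, col] + alpha * (1 - SO[ch, col])
      v[ch] <- SO[ch, 2]
    } else {
      v[ch] <- v[ch] + alpha * d
    }
    dv[i] <- v[ch] - v_old
  }
  p_choice <- ifelse(enc$chose_first, p_first, 1 - p_first)
  list(v = v_mat, delta = delta, surprise = abs(delta), alpha_t = alpha_t,
       value_update = dv, p_first = p_first, p_choice = p_choice, SO = SO)
}

rl_forward <- function(params, trials, model = c("mf", "dyn", "mb")) {
  model <- match.arg(model)
  rl_forward_enc(params, encode_trials(trials), model)
}

# Class-normalized negative log-likelihood on an encoded trial table.
nll_enc <- function(params, enc, model) {
  fw <- rl_forward_enc(params, enc, model)
  lp <- log(clamp_prob(fw$p_choice))
  ll <- 0
  for (k in unique(enc$ch)) {
    idx <- enc$ch == k
    ll <- ll + sum(lp[idx]) / sum(idx)
  }
  -ll
}

#' Class-normalized log-likelihood of an RL model
#'
#' The log-likelihood sums, over the three choice classes (the three
#' symbols), the summed log choice probabilities of that class divided by
#' the class's choice count; a symbol never chosen contributes 0.  Choice
#' probabilities are floored at 1e-12 before taking logs.
#'
#' @param params List with elements `alpha`, `beta`, `phi` (and `gamma`,
#'   `smooth_const` for the dynamic model).
#' @param data A `session_data` object or trial data.frame with columns
#'   `pair`, `choice`, `outcome`.
#' @param model One of "mf", "dyn", "mb".
#' @return Negative normalized log-likelihood (scalar).
#' @export
neg_log_likelihood <- function(params, data, model = c("mf", "dyn", "mb")) {
  model <- match.arg(model)
  trials <- if (inherits(data, "session_data")) data$trials else data
  if (nrow(trials) == 0) stop("empty trial table")
  nll_enc(params, encode_trials(trials), model)
}

#' Bayesian information criterion
#'
#' BIC = -2 logL + d log(n), with d free parameters and n trials.  Lower is
#' better.
#'
#' @param logL (Normalized) log-likelihood.
#' @param d Number of free parameters.
#' @param n Number of trials.
#' @return Scalar BIC.
#' @export
bic_score <- function(logL, d, n) {
  stopifnot(n >= 1)
  -2 * logL + d * log(n)
}

#' Latent trial-by-trial traces of an RL model
#'
#' Runs the model forward through a session at fixed parameters and records
#' the per-trial expected values, signed RPE, surprise (|RPE|), learning
#' rate and value update of the chosen symbol.
#'
#' @inheritParams neg_log_likelihood
#' @return An object of class `latent_trace`: list with `v` (trials x
#'   symbols value matrix, values before each trial's update), `delta`,
#'   `surprise`, `alpha_t`, `value_update`, `p_choice` and, for the
#'   model-based variant, the final `SO` matrix.
#' @export
latent_trace <- function(params, data, model = c("mf", "dyn", "mb")) {
  model <- match.arg(model)
  trials <- if (inherits(data, "session_data")) data$trials else data
  fw <- rl_forward(params, trials, model)
  fw$model <- model
  fw$params <- params
  class(fw) <- "latent_trace"
  fw
}

#' Assign surprise values to the five canonical bins
#'
#' Bins |RPE| into very_low \[0-0.2\], low (0.2-0.4\], medium (0.4-0.6\],
#' high (0.6-0.8\] and very_high (0.8-1\]; boundary values fall in the
#' lower bin (0.2 is "very_low"), except that 1.0 is "very_high".
#'
#' @param surprise Numeric vector in \[0, 1\].
#' @param edges Bin edges (default the canonical five bins).
#' @return Ordered factor with levels very_low < low < medium < high <
#'   very_high.
#' @export
surprise_bins <- function(surprise, edges = c(0, 0.2, 0.4, 0.6, 0.8, 1)) {
  stopifnot(all(surprise >= 0), all(surprise <= 1))
  cut(surprise, breaks = edges,
      labels = c("very_low", "low", "medium", "high", "very_high"),
      include.lowest = TRUE, right = TRUE, ordered_result = TRUE)
}

#' Trial-level behavioral table
#'
#' Builds the per-trial predictors used in stay/switch and reaction-time
#' analyses: `stay` (the next trial repeats this trial's choice, defined
#' when that choice is offered again; NA otherwise and on the last trial),
#' `valence` (sign of the RPE), `surprise` (|RPE|), and `delta_rt` =
#' RT(t+1) - RT(t) when reaction times are supplied.
#'
#' @param data `session_data` or trial data.frame.
#' @param trace A [latent_trace()] aligned to the trials.
#' @param rts Optional numeric vector of per-trial reaction times (s).
#' @return A data.frame with one row per trial.
#' @export
build_behavioral_table <- function(data, trace, rts = NULL) {
  trials <- if (inherits(data, "session_data")) data$trials else data
  n <- nrow(trials)
  stopifnot(length(trace$delta) == n)
  stay <- rep(NA, n)
  for (i in seq_len(n - 1)) {
    nxt <- c(substr(trials$pair[i + 1], 1, 1), substr(trials$pair[i + 1], 2, 2))
    if (trials$choice[i] %in% nxt)
      stay[i] <- trials$choice[i + 1] == trials$choice[i]
  }
  out <- data.frame(trial_index = trials$trial_index,
                    stay = stay,
                    valence = sign(trace$delta),
                    surprise = abs(trace$delta))
  if (!is.null(rts)) {
    stopifnot(length(rts) == n)
    out$rt <- rts
    out$delta_rt <- c(rts[-1] - rts[-n], NA)
  }
  out
}
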