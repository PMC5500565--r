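#' Configuration for the probabilistic reversal-learning task
#'
#' Builds the parameter set that drives [run_session()].  The defaults
#' reproduce the study design: two blocks of 170 trials, one of three symbols
#' carrying a 70\% reward probability against 30\% for the other two, a
#' learning criterion of 5 correct choices in the last 6 trials, and a
#' criterion-triggered reversal preceded by 1--8 buffer trials whose length
#' follows a truncated geometric hazard of 0.3 per trial.
#'
#' @param n_blocks Number of blocks per session.
#' @param trials_per_block Trials in each block.
#' @param p_high Reward probability of the currently "high" symbol.
#' @param p_low Reward probability of each "low" symbol.
#' @param criterion_hits,criterion_window Learning criterion: at least
#'   `criterion_hits` correct choices within the last `criterion_window`
#'   trials since the previous reversal.
#' @param buffer_hazard Per-trial probability that the buffer ends (and a
#'   reversal occurs) on each buffer trial.
#' @param buffer_min,buffer_max Bounds on the number of buffer trials.
#' @param pair_cycle List of two-symbol character vectors presented in fixed
#'   rotation.
#' @param iti_range,outcome_delay_range Uniform ranges (seconds) for the
#'   pre-stimulus and pre-outcome delays.
#' @param stim_duration,feedback_duration Stimulus and feedback durations in
#'   seconds.
#'
#' @return An object of class `task_config` (a named list).
#' @seealso [run_session()]
#' @export
task_config <- function(n_blocks = 2L, trials_per_block = 170L,
                        p_high = 0.7, p_low = 0.3,
                        criterion_hits = 5L, criterion_window = 6L,
                        buffer_hazard = 0.3, buffer_min = 1L, buffer_max = 8L,
                        pair_cycle = list(c("A", "B"), c("B", "C"), c("C", "A")),
                        iti_range = c(1, 4), outcome_delay_range = c(1, 4),
                        stim_duration = 1.25, feedback_duration = 0.65) {
  stopifnot(p_low >= 0, p_low < p_high, p_high <= 1,
            criterion_hits <= criterion_window,
            buffer_min >= 1, buffer_min <= buffer_max,
            n_blocks >= 1, trials_per_block >= 1)
  if (length(pair_cycle) == 0)
    stop("'pair_cycle' must contain at least one symbol pair")
  cfg <- list(n_blocks = as.integer(n_blocks),
              trials_per_block = as.integer(trials_per_block),
              p_high = p_high, p_low = p_low,
              criterion_hits = as.integer(criterion_hits),
              criterion_window = as.integer(criterion_window),
              buffer_hazard = buffer_hazard,
              buffer_min = as.integer(buffer_min),
              buffer_max = as.integer(buffer_max),
              pair_cycle = pair_cycle,
              iti_range = iti_range,
              outcome_delay_range = outcome_delay_range,
              stim_duration = stim_duration,
              feedback_duration = feedback_duration)
  class(cfg) <- "task_config"
  cfg
}

#' Symbol pair shown on a given trial
#'
#' Pairs rotate in a fixed order (AB, BC, CA by default) so that subjects
#' cannot exploit pair-order structure; the rotation is indexed by the
#' 0-based session-wide trial index.
#'
#' @param trial_index 0-based trial index.
#' @param cycle List of symbol pairs.
#' @return Character vector of length 2.
#' @export
next_pair <- function(trial_index, cycle) {
  if (length(cycle) == 0) stop("empty pair cycle")
  stopifnot(trial_index >= 0)
  cycle[[(trial_index %% length(cycle)) + 1L]]
}

#' Learning-criterion test
#'
#' TRUE when the choice history since the last reversal is at least `window`
#' trials long and at least `hits` of its last `window` entries are correct
#' (i.e. the current high-probability symbol was chosen).
#'
#' @param recent_correct Logical vector of correct/incorrect choices since
#'   the last reversal, oldest first.
#' @param hits,window Criterion definition (default 5 of 6).
#' @return Logical scalar.
#' @export
check_learning_criterion <- function(recent_correct, hits = 5L, window = 6L) {
  n <- length(recent_correct)
  if (n < window) return(FALSE)
  sum(recent_correct[(n - window + 1L):n]) >= hits
}

#' Draw a buffer length from the truncated geometric hazard process
#'
#' After the learning criterion is met, each subsequent trial ends the
#' buffer (triggering a reversal) with probability `hazard`, subject to a
#' minimum and maximum buffer length: P(L = k) = hazard * (1 - hazard)^(k -
#' min) for min <= k < max, with the remaining mass on `max`.
#'
#' @param hazard Per-trial stopping probability in (0, 1].
#' @param min,max Buffer-length bounds.
#' @param n Number of draws.
#' @return Integer vector of length `n`.
#' @export
draw_buffer_length <- function(hazard = 0.3, min = 1L, max = 8L, n = 1L) {
  if (hazard <= 0) stop("'hazard' must be positive (hazard = 0 never terminates)")
  stopifnot(hazard <= 1, min >= 1, min <= max)
  p <- buffer_length_pmf(hazard, min, max)
  ks <- min:max
  ks[sample.int(length(ks), n, replace = TRUE, prob = p)]
}

#' Probability mass function of the buffer length
#'
#' @inheritParams draw_buffer_length
#' @return Numeric vector of probabilities over `min:max`.
#' @export
buffer_length_pmf <- function(hazard = 0.3, min = 1L, max = 8L) {
  ks <- min:max
  p <- hazard * (1 - hazard)^(ks - min)
  p[length(p)] <- 1 - sum(p[-length(p)])
  p
}

#' Reassign the high-reward symbol at a reversal
#'
#' Chooses uniformly among the symbols other than the current high one.
#'
#' @param current Current high-probability symbol.
#' @param symbols Full symbol set.
#' @return A single symbol distinct from `current`.
#' @export
reassign_high_symbol <- function(current, symbols) {
  others <- setdiff(symbols, current)
  others[sample.int(length(others), 1L)]
}

#' Simulate a full reversal-learning session
#'
#' Runs the task state machine against an arbitrary choice-making agent.  An
#' agent is a function `agent(pair, info)` returning one element of `pair`;
#' `info` is a list with elements `trial` (0-based index), `high_symbol`
#' (the current high-probability symbol, available to oracle-style testing
#' agents), and `prev` (the previous trial's `list(pair, choice, outcome)`,
#' or `NULL` on the first trial).
#'
#' Each block starts a fresh learning phase with a randomly chosen high
#' symbol.  Once the agent reaches the learning criterion, buffer trials are
#' played under the unchanged contingency; the reversal takes effect on the
#' first trial after the buffer, which is flagged `reversal_flag = TRUE`.
#' The criterion window resets at every reversal and block start, and counts
#' only trials on which the high symbol was offered (on a low-low pair the
#' high symbol cannot be selected; with the fixed three-pair cycle such
#' trials occur every third trial, so scoring them as incorrect would make
#' a 5-of-6 criterion unattainable).
#'
#' @param config A [task_config()].
#' @param agent Choice policy, see Details.
#' @param seed Optional integer seed applied locally for reproducibility.
#' @return An object of class `session_data`: a list with `trials` (a
#'   data.frame, one row per trial) and `config`.
#' @examples
#' sess <- run_session(task_config(), oracle_agent(), seed = 1)
#' mean(sess$trials$outcome)  # close to p_high for an oracle
#' @export
run_session <- function(config = task_config(), agent, seed = NULL) {
  with_seed(seed, {
    symbols <- sort(unique(unlist(config$pair_cycle)))
    n_total <- config$n_blocks * config$trials_per_block
    col_pair <- character(n_total); col_choice <- character(n_total)
    col_outcome <- integer(n_total); col_high <- character(n_total)
    col_phase <- character(n_total); col_rev <- logical(n_total)
    col_block <- integer(n_total)
    col_onset <- numeric(n_total); col_dec <- numeric(n_total)
    high <- symbols[sample.int(length(symbols), 1L)]
    history <- logical(0)       # correct/incorrect since last reversal
    phase <- "learning"
    buffer_left <- NA_integer_
    pending_reversal <- FALSE
    t_cursor <- 0
    prev <- NULL

    for (i in seq_len(n_total)) {
      idx0 <- i - 1L
      block <- idx0 %/% config$trials_per_block + 1L
      if (idx0 %% config$trials_per_block == 0L && i > 1L) {
        # new block: fresh learning phase, new random high symbol
        high <- symbols[sample.int(length(symbols), 1L)]
        history <- logical(0)
        phase <- "learning"
        pending_reversal <- FALSE
        buffer_left <- NA_integer_
      }
      reversal_flag <- FALSE
      if (pending_reversal) {
        high <- reassign_high_symbol(high, symbols)
        history <- logical(0)
        phase <- "learning"
        pending_reversal <- FALSE
        reversal_flag <- TRUE
      }

      pair <- next_pair(idx0, config$pair_cycle)
      choice <- agent(pair, list(trial = idx0, high_symbol = high, prev = prev))
      if (!(length(choice) == 1L && choice %in% pair))
        stop("agent returned a symbol not in the offered pair at trial ", idx0)
      p_r <- if (choice == high) config$p_high else config$p_low
      outcome <- as.integer(stats::runif(1) < p_r)

      iti <- stats::runif(1, config$iti_range[1], config$iti_range[2])
      stim_onset <- t_cursor + iti
      out_delay <- stats::runif(1, config$outcome_delay_range[1],
                                config$outcome_delay_range[2])
      outcome_onset <- stim_onset + config$stim_duration + out_delay
      t_cursor <- outcome_onset + config$feedback_duration

      col_block[i] <- block
      col_pair[i] <- paste(pair, collapse = "")
      col_choice[i] <- choice
      col_outcome[i] <- outcome
      col_high[i] <- high
      col_phase[i] <- phase
      col_rev[i] <- reversal_flag
      col_onset[i] <- outcome_onset
      col_dec[i] <- stim_onset

      # Only trials offering the high symbol enter the criterion window:
      # on a low-low pair "selecting the high-probability symbol" is not
      # defined, and with the fixed 3-pair cycle a 5-of-6 criterion that
      # scored such pairs as incorrect could never be met.
      if (high %in% pair) history <- c(history, choice == high)
      if (phase == "learning") {
        if (check_learning_criterion(history, config$criterion_hits,
                                     config$criterion_window)) {
          phase <- "buffer"
          buffer_left <- draw_buffer_length(config$buffer_hazard,
                                            config$buffer_min,
                                            config$buffer_max)
        }
      } else {                              # buffer
        buffer_left <- buffer_left - 1L
        if (buffer_left == 0L) pending_reversal <- TRUE
      }
      prev <- list(pair = pair, choice = choice, outcome = outcome)
    }

    trials <- data.frame(trial_index = seq_len(n_total) - 1L,
                         block = col_block, pair = col_pair,
                         choice = col_choice, outcome = col_outcome,
                         high_symbol = col_high, phase = col_phase,
                         reversal_flag = col_rev, onset_s = col_onset,
                         dec_onset_s = col_dec,
                         stringsAsFactors = FALSE)
    structure(list(trials = trials, config = config), class = "session_data")
  })
}

#' @export
print.session_data <- function(x, ...) {
  tr <- x$trials
  cat("Reversal-learning session:", nrow(tr), "trials in",
      x$config$n_blocks, "block(s)\n")
  cat("  reward rate:", round(mean(tr$outcome), 3),
      "| reversals:", sum(tr$reversal_flag), "\n")
  invisible(x)
}

#' Reward rates conditional on the chosen symbol's status
#'
#' Because the pair cycle omits the high symbol on one third of trials, an
#' agent's unconditional reward fraction mixes the high and low reward
#' probabilities.  This helper reports the empirical reward rate separately
#' for trials where the chosen symbol was the currently designated high
#' symbol and for trials where a low symbol was chosen; the former estimates
#' `p_high`, the latter `p_low`.
#'
#' @param session A `session_data`.
#' @return Named numeric vector `c(high = , low = )` of empirical reward
#'   rates (NA if no qualifying trials).
#' @export
reward_rates <- function(session) {
  tr <- session$trials
  is_high <- tr$choice == tr$high_symbol
  c(high = if (any(is_high)) mean(tr$outcome[is_high]) else NA_real_,
    low = if (any(!is_high)) mean(tr$outcome[!is_high]) else NA_real_)
}

#' Built-in testing agents
#'
#' `oracle_agent()` always chooses the current high-probability symbol if it
#' is offered (first pair element otherwise); `anti_oracle_agent()` always
#' avoids it; `random_agent()` chooses uniformly.
#'
#' @return A function usable as the `agent` argument of [run_session()].
#' @rdname agents
#' @export
oracle_agent <- function() {
  function(pair, info) {
    if (info$high_symbol %in% pair) info$high_symbol
    else pair[sample.int(2L, 1L)]
  }
}

#' @rdname agents
#' @export
anti_oracle_agent <- function() {
  function(pair, info) {
    low <- setdiff(pair, info$high_symbol)
    low[sample.int(length(low), 1L)]
  }
}

#' @rdname agents
#' @export
random_agent <- function() {
  function(pair, info) pair[sample.int(2L, 1L)]
}

#' Read/write a session trial table
#'
#' Sessions are serialized as UTF-8 tab-delimited text with a header row,
#' one row per trial.
#'
#' @param session A `session_data` object.
#' @param path File path.
#' @return `read_session()` returns a data.frame of trials.
#' @export
write_session <- function(session, path) {
  utils::write.table(session$trials, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
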