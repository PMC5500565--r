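# Shared small-scale generators for the test suite.

# Canonical generating parameters used throughout the tests.
gen_params <- function() list(alpha = 0.3, beta = 5, phi = 0)

small_session <- function(n_trials = 60, seed = 1, params = gen_params()) {
  gen_behavior(params, task_config(n_blocks = 1, trials_per_block = n_trials),
               seed = seed)
}

# Hand-built trial table where every symbol is chosen at least once.
toy_trials <- function() {
  data.frame(trial_index = 0:5,
             block = 1L,
             pair = c("AB", "BC", "CA", "AB", "BC", "CA"),
             choice = c("A", "B", "C", "B", "C", "A"),
             outcome = c(1L, 0L, 1L, 1L, 0L, 0L),
             high_symbol = "A", phase = "learning",
             reversal_flag = FALSE,
             onset_s = seq(5, 55, by = 10),
             dec_onset_s = seq(2, 52, by = 10),
             stringsAsFactors = FALSE)
}

# Two well-separated Gaussian clusters as an epoch array with a single
# sample, so window averaging is the identity.
toy_clusters <- function(n_per_class = 10, D = 2, sep = 5, seed = 1) {
  set.seed(seed)
  Xa <- matrix(rnorm(n_per_class * D), n_per_class, D)
  Xb <- matrix(rnorm(n_per_class * D), n_per_class, D) + sep
  arr <- array(NA_real_, c(2 * n_per_class, D, 1))
  arr[, , 1] <- rbind(Xa, Xb)
  list(epochs = epoch_array(arr, sfreq = 100, t0 = 0),
       labels = rep(c(FALSE, TRUE), each = n_per_class),
       Xa = Xa, Xb = Xb)
}
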