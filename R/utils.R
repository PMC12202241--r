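# internal helpers shared across modules

# stop with a classed condition so tests can target error classes
stop_trialcea <- function(msg, class) {
  rlang::abort(msg, class = c(class, "trialcea_error"))
}

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          class = "trialcea_validation_error") {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_trialcea(sprintf("`%s` must be a single finite number.", name), class)
  }
  if (x < lower || x > upper) {
    stop_trialcea(
      sprintf("`%s` = %s is outside [%s, %s].", name, format(x), format(lower), format(upper)),
      class
    )
  }
  invisible(x)
}

# per-participant substream: the master seed and the participant index map to
# one 31-bit seed, so participant i's draws do not change when n changes
participant_seed <- function(master_seed, index) {
  (as.double(master_seed) * 48271 + as.double(index) * 16807) %% 2147483647
}

utility_floor <- function() -0.661

round_half_up <- function(x, digits = 0) {
  # the reliable-change literature rounds thresholds half-up (5.4563 -> 5.46);
  # base round() is banker's rounding, so do it explicitly
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
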