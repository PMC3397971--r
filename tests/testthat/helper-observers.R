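# Shared fixtures for the test suite: all synthetic, built in code.

# Per-level binomial data drawn from a known logistic psychometric function.
gen_pf_counts <- function(levels = c(5, 20, 50, 100), n = 100,
                          alpha = 30, beta = 0.12, gamma = 0.25, lambda = 0) {
  tibble::tibble(
    coherence = levels,
    n = n,
    k = rbinom(length(levels), n, psi_logistic(levels, alpha, beta, gamma, lambda))
  )
}

# Observer whose accuracy and certainty functions are identical (equal attention
# shifts, no lapse): the null configuration for dissociation calibration.
equal_shift_observer <- function() {
  observer_params(
    acc_threshold_valid = 20, acc_threshold_invalid = 30, acc_slope = 0.12,
    lapse = 0,
    cert_threshold_valid = 20, cert_threshold_invalid = 30, cert_slope = 0.12
  )
}

# Minimal hand-built trial table: one subject, one level, explicit outcomes.
toy_trials <- function(correct, certainty_index = rep(1, length(correct)),
                       cue_valid = rep(TRUE, length(correct)),
                       coherence = rep(20, length(correct)),
                       subject_id = "s1", variant = "SN") {
  raw <- as.character((certainty_index - 0.25) / 0.25)
  tibble::tibble(
    subject_id = subject_id, variant = variant,
    trial_index = seq_along(correct), cue_valid = cue_valid,
    coherence = coherence, true_direction = "up", other_direction = "down",
    congruent = FALSE, choice = ifelse(correct, "up", "left"),
    correct = correct, confidence_raw = raw, certainty_index = certainty_index
  )
}
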