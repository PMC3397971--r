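test_that("p_correct follows the 4AFC logistic with chance floor and lapse ceiling", {
  obs <- observer_params(
    acc_threshold_valid = 40, acc_threshold_invalid = 50,
    acc_slope = 0.2, lapse = 0
  )
  # at the threshold the function sits at the midpoint of chance and perfect
  expect_equal(p_correct(40, TRUE, obs), 0.625)
  expect_equal(p_correct(50, FALSE, obs), 0.625)

  # zero-signal limit: chance plus the small residual of the logistic tail
  obs2 <- observer_params(
    acc_threshold_valid = 40, acc_threshold_invalid = 50,
    acc_slope = 0.2, lapse = 0.02
  )
  expect_lt(p_correct(0, TRUE, obs2), 0.26)
  expect_gt(p_correct(0, TRUE, obs2), 0.25)

  # closed form, hand-evaluated: 0.25 + 0.73 / (1 + exp(-0.2 * (100 - 40)))
  expect_equal(
    p_correct(100, TRUE, obs2),
    0.25 + (1 - 0.25 - 0.02) / (1 + exp(-0.2 * 60))
  )

  expect_error(p_correct(101, TRUE, obs), "coherence")
  expect_error(p_correct(-1, TRUE, obs), "coherence")
})

test_that("observer_params validates its invariants", {
  expect_error(observer_params(acc_threshold_valid = 35, acc_threshold_invalid = 30), "valid")
  expect_error(observer_params(lapse = 0.2), "lapse")
  expect_error(observer_params(rating_cuts = c(0.5, 0.4, 0.8)), "rating_cuts")
  expect_error(observer_params(acc_threshold_valid = -5), "positive|thresholds")
})

test_that("simulate_trial is deterministic under a seed and saturates confidence", {
  obs <- observer_params(cert_noise_sd = 0)
  spec <- list(coherence = 100, cue_valid = TRUE, variant = "SN")
  t1 <- simulate_trial(spec, obs, seed = 42)
  t2 <- simulate_trial(spec, obs, seed = 42)
  expect_identical(t1, t2)
  # far above the certainty threshold with no noise: top rating
  expect_identical(t1$confidence_raw, "3")
  expect_identical(t1$certainty_index, 1)
  tw <- simulate_trial(list(coherence = 100, cue_valid = TRUE, variant = "SW"), obs, seed = 1)
  expect_identical(tw$confidence_raw, "high")
  expect_error(
    simulate_trial(list(coherence = 50, cue_valid = TRUE, variant = "XX"), obs),
    "variant"
  )
})

test_that("simulated accuracy matches the generative probability", {
  obs <- observer_params(
    acc_threshold_valid = 40, acc_threshold_invalid = 50,
    acc_slope = 0.2, lapse = 0, cert_noise_sd = 0
  )
  set.seed(7)
  n <- 10000
  resp <- attencert:::draw_responses(
    rep(40, n), rep(TRUE, n), rep("up", n), "SN", obs
  )
  se <- sqrt(0.625 * 0.375 / n)
  expect_lt(abs(mean(resp$correct) - 0.625), 3 * se)
  # errors land on wrong directions only, and all three are used
  expect_false(any(resp$choice[!resp$correct] == "up"))
  expect_setequal(unique(resp$choice[!resp$correct]), c("right", "down", "left"))
})

test_that("simulate_experiment honors fixed levels, counts and reproducibility", {
  tr <- simulate_experiment("SN", n_subjects = 1, n_trials = 1000, seed = 3)
  expect_equal(nrow(tr), 1000)
  expect_true(all(tr$coherence %in% c(5, 20, 50, 100)))
  expect_equal(sum(tr$cue_valid), 800)
  expect_identical(tr$congruent, tr$true_direction == tr$other_direction)
  expect_identical(tr$correct, tr$choice == tr$true_direction)
  expect_identical(tr$certainty_index, map_confidence(tr$confidence_raw, "SN"))
  tr2 <- simulate_experiment("SN", n_subjects = 1, n_trials = 1000, seed = 3)
  expect_identical(tr, tr2)
  expect_error(simulate_experiment("SN", n_subjects = 1, n_trials = 0), "n_trials")
  # subject params are recorded for recovery checks
  expect_length(attr(tr, "subject_params"), 1)
})

test_that("matched-performance design presents higher coherences on invalid cues", {
  tr <- simulate_experiment("SN",
    n_subjects = 2, n_trials = 500,
    levels = c(5, 20, 50), levels_invalid = c(20, 50, 100), seed = 4
  )
  expect_gt(
    mean(tr$coherence[!tr$cue_valid]),
    mean(tr$coherence[tr$cue_valid])
  )
})

test_that("accuracy and certainty are monotone in coherence with attention ordering", {
  obs <- observer_params(lapse = 0)
  tr <- simulate_experiment("SN",
    n_subjects = 1, n_trials = 40000,
    levels = c(0, 10, 25, 60), params = obs, subject_sd = 0, seed = 9
  )
  by_level <- tr |>
    dplyr::filter(cue_valid) |>
    dplyr::group_by(coherence) |>
    dplyr::summarise(acc = mean(correct), cert = mean(certainty_index), n = dplyr::n())
  expect_true(all(diff(by_level$acc) > 0))
  expect_true(all(diff(by_level$cert) > 0))
  # attention ordering at a shared mid coherence
  at25 <- tr |>
    dplyr::filter(coherence == 25) |>
    dplyr::group_by(cue_valid) |>
    dplyr::summarise(acc = mean(correct))
  expect_gt(at25$acc[at25$cue_valid], at25$acc[!at25$cue_valid])
})

test_that("accuracy at zero coherence converges to 4AFC chance", {
  # steep observer: the logistic tail at zero signal is negligible
  obs <- observer_params(
    acc_threshold_valid = 50, acc_threshold_invalid = 60,
    acc_slope = 0.4, lapse = 0
  )
  set.seed(10)
  n <- 20000
  resp <- attencert:::draw_responses(
    rep(0, n), rep(TRUE, n), sample(c("up", "right", "down", "left"), n, TRUE),
    "SN", obs
  )
  expect_lt(abs(mean(resp$correct) - 0.25), 3 * sqrt(0.25 * 0.75 / n))
})

test_that("trial tables round-trip through CSV", {
  tr <- simulate_experiment("SW", n_subjects = 1, n_trials = 50, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(tr, path, comment = "roundtrip check")
  back <- read_trials(path)
  expect_equal(as.data.frame(back), as.data.frame(tr), ignore_attr = TRUE)
  expect_match(readLines(path, n = 1), "^# roundtrip check")
})
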