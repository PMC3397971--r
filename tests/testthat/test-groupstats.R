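test_that("confidence maps onto the certainty index exactly as coded", {
  expect_equal(map_confidence(c(0, 1, 2, 3), "SN"), c(0.25, 0.5, 0.75, 1))
  expect_equal(map_confidence(c("0", "3"), "FN"), c(0.25, 1))
  expect_equal(map_confidence("2", "FN"), 0.75)
  expect_equal(map_confidence(c("low", "high"), "SW"), c(0.25, 1))
  expect_equal(map_confidence("low", "FW"), 0.25)
  expect_error(map_confidence(4, "SN"), "0..3")
  expect_error(map_confidence("medium", "SW"), "low")
})

test_that("cell means honor the minimum-trial boundary exactly", {
  mk <- function(n_valid, n_invalid) {
    dplyr::bind_rows(
      toy_trials(rep(TRUE, n_valid)),
      toy_trials(rep(c(TRUE, FALSE), length.out = n_invalid),
        cue_valid = rep(FALSE, n_invalid)
      )
    )
  }
  # level scope (default): valid + invalid trials at the level count together
  cells89 <- cell_means(mk(60, 29), min_trials = 90)
  expect_true(all(!cells89$included))
  cells90 <- cell_means(mk(60, 30), min_trials = 90)
  expect_true(all(cells90$included))
  # cell scope: each condition cell needs the count on its own
  cc <- cell_means(mk(90, 89), min_trials = 90, filter_scope = "cell")
  expect_true(all(cc$included[cc$condition == "valid"]))
  expect_false(any(cc$included[cc$condition == "invalid"]))
  # empty input: empty output, no error
  expect_equal(nrow(cell_means(toy_trials(TRUE)[0, ])), 0)
  # toy means
  cm <- cell_means(toy_trials(c(TRUE, TRUE, TRUE, TRUE)), min_trials = 1)
  expect_equal(cm$mean_value[cm$measure == "accuracy"], 1)
})

test_that("z-standardization yields mean 0 / SD 1 pools and is affine invariant", {
  cells <- cell_means(
    simulate_experiment("SN", n_subjects = 3, n_trials = 400, seed = 21),
    min_trials = 10
  )
  z <- zstandardize(cells)
  pools <- z |>
    dplyr::filter(included) |>
    dplyr::group_by(subject_id, measure) |>
    dplyr::summarise(m = mean(z_value), s = sd(z_value), .groups = "drop")
  expect_true(all(abs(pools$m) < 1e-12))
  expect_true(all(abs(pools$s - 1) < 1e-12))
  # affine recoding of the raw means leaves z untouched
  cells_affine <- dplyr::mutate(cells, mean_value = 3 * mean_value - 0.7)
  expect_equal(zstandardize(cells_affine)$z_value, z$z_value)
  # two-point pool: symmetric z with order preserved
  two <- cells[cells$subject_id == "s01" & cells$measure == "accuracy", ][1:2, ]
  two$included <- TRUE
  two$mean_value <- c(0.4, 0.6)
  z2 <- zstandardize(two)
  expect_equal(sum(z2$z_value), 0)
  expect_lt(z2$z_value[1], z2$z_value[2])
  # zero spread is flagged, not fatal
  two$mean_value <- c(0.5, 0.5)
  zz <- zstandardize(two)
  expect_true(all(is.na(zz$z_value)))
  expect_false(is.null(attr(zz, "standardization_failures")))
})

test_that("delta_z pairs matched cells and signs increases with attention", {
  cells <- tibble::tibble(
    subject_id = "s1", measure = "accuracy",
    condition = c("valid", "invalid"), coherence = 20,
    n_trials = 100, mean_value = c(0.7, 0.5), included = TRUE,
    z_value = c(0.5, -0.5)
  )
  d <- delta_z(cells)
  expect_equal(d$delta, 1.0)
  # identical conditions: all deltas zero
  cells$z_value <- c(0.3, 0.3)
  expect_equal(delta_z(cells)$delta, 0)
  # unmatched cells are skipped and counted
  lone <- cells[1, ]
  d2 <- delta_z(lone)
  expect_equal(nrow(d2), 0)
  expect_equal(attr(d2, "n_unmatched"), 1)
})

test_that("paired_t matches the textbook formula and the reference implementation", {
  x <- c(1.2, 0.8, 1.5, 0.9, 1.1, 1.4)
  y <- c(1.0, 0.9, 1.2, 1.0, 0.8, 1.1)
  ours <- paired_t(x, y)
  ref <- t.test(x, y, paired = TRUE)
  expect_equal(ours$t, unname(ref$statistic))
  expect_equal(ours$p_value, ref$p.value)
  # hand formula
  d <- x - y
  expect_equal(ours$t, mean(d) / (sd(d) / sqrt(length(d))))
  # x = y: statistic 0, p undefined
  same <- paired_t(x, x)
  expect_equal(same$t, 0)
  expect_true(is.na(same$p_value))
  # constant nonzero differences: zero-variance error
  expect_error(paired_t(c(2, 2, 2, 2), c(1, 1, 1, 1)), "variance")
  expect_error(paired_t(1, 2), "pairs")
})

test_that("modified z-scores flag a planted gross outlier and tolerate ties", {
  v <- c(1, 1.1, 0.9, 1.05, 0.95, 100)
  mask <- modified_z_outliers(v)
  expect_identical(which(!mask), 6L)
  # hand check: median 1.025, MAD 0.075 -> M = 0.6745 * 98.975 / 0.075
  m <- attr(mask, "modified_z")
  expect_equal(m[6], 0.6745 * (100 - 1.025) / 0.075)
  # all-equal input: MAD zero, warn, exclude nothing
  expect_warning(mask2 <- modified_z_outliers(rep(1, 5)), "MAD")
  expect_true(all(mask2))
  expect_error(modified_z_outliers(c(1, 2)))
  # standard normal sample: exclusion fraction stays below 1%
  set.seed(22)
  mask3 <- suppressWarnings(modified_z_outliers(rnorm(1e4)))
  expect_lt(mean(!mask3), 0.01)
})

test_that("rating frequencies around the certainty threshold are balanced for a symmetric observer", {
  obs <- observer_params(
    cert_threshold_valid = 30, cert_threshold_invalid = 30,
    cert_slope = 0.1, cert_noise_sd = 0.1, lapse = 0
  )
  # levels symmetric about the confidence threshold; windows centered on the
  # known generative thresholds, the point of symmetry of the rating mixture
  tr <- simulate_experiment("SN",
    n_subjects = 12, n_trials = 800,
    levels = c(10, 20, 30, 40, 50), params = obs, subject_sd = 0.05, seed = 23
  )
  truth <- tibble::tibble(
    subject_id = names(attr(tr, "subject_params")),
    threshold = purrr::map_dbl(attr(tr, "subject_params"), "cert_threshold_valid")
  )
  rf <- rating_frequencies(dplyr::filter(tr, cue_valid),
    window = 10, thresholds = truth
  )
  expect_gt(nrow(rf$frequencies), 5)
  expect_false(is.null(rf$tests))
  # symmetric generative confidence: no systematic low/high imbalance
  expect_gt(rf$tests$p_value[rf$tests$comparison == "0 vs 3"], 0.05)
  # frequencies are proper proportions
  sums <- with(rf$frequencies, f0 + f1 + f2 + f3)
  expect_equal(sums, rep(1, length(sums)))
  # estimated-threshold mode runs end to end on the same data
  rf2 <- rating_frequencies(dplyr::filter(tr, cue_valid), window = 10)
  expect_gt(nrow(rf2$frequencies), 5)
  # degenerate window keeps only trials exactly at the threshold level
  rf0 <- rating_frequencies(dplyr::filter(tr, cue_valid),
    window = 0, thresholds = tibble::tibble(subject_id = "s01", threshold = 30)
  )
  expect_true(all(rf0$frequencies$n_trials_window <=
    sum(tr$subject_id == "s01" & tr$coherence == 30)))
})

test_that("subjects with undefined certainty thresholds are skipped with a count", {
  # confidence saturates far above any attainable level: threshold undefined
  obs <- observer_params(
    cert_threshold_valid = 300, cert_threshold_invalid = 300,
    cert_slope = 0.01, cert_noise_sd = 0.05, lapse = 0
  )
  tr <- simulate_experiment("SN",
    n_subjects = 2, n_trials = 300,
    params = obs, subject_sd = 0, seed = 24
  )
  rf <- rating_frequencies(tr, window = 10)
  expect_equal(rf$n_skipped, 2)
  expect_equal(nrow(rf$frequencies), 0)
})

test_that("control subsets filter as specified and report manifests", {
  tr <- simulate_experiment("SN", n_subjects = 2, n_trials = 5000, seed = 25)
  nc <- control_subsets(tr, "noncongruent_only")
  expect_lt(abs(nrow(nc) / nrow(tr) - 0.75), 3 * sqrt(0.75 * 0.25 / nrow(tr)))
  expect_true(all(!nc$congruent))
  lo <- control_subsets(tr, "coherence_below_50")
  expect_setequal(unique(lo$coherence), c(5, 20))
  m <- attr(lo, "manifest")
  expect_equal(m$n_before - m$n_after, m$n_excluded)
  co <- control_subsets(tr, "correct_only")
  expect_true(all(co$correct))
  inc <- control_subsets(tr, "incorrect_only")
  expect_equal(nrow(co) + nrow(inc), nrow(tr))
  # overlapping coherences: set intersection per subject
  tr2 <- simulate_experiment("SN",
    n_subjects = 1, n_trials = 2000,
    levels = c(5, 20, 50), levels_invalid = c(20, 50, 100), seed = 26
  )
  ov <- control_subsets(tr2, "overlapping_coherences")
  expect_setequal(unique(ov$coherence), c(20, 50))
  expect_error(control_subsets(tr, "bogus"))
  # filters are idempotent
  expect_equal(nrow(control_subsets(nc, "noncongruent_only")), nrow(nc))
})
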