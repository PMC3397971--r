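test_that("certainty trials become pseudo-binomial per-level counts", {
  tr <- toy_trials(
    correct = c(TRUE, TRUE, FALSE, TRUE),
    certainty_index = c(0.25, 0.5, 0.75, 1)
  )
  d <- pf_data(tr, "certainty", "valid")
  # k = 3 (v - 0.25) / 0.75 per trial: 0 + 1 + 2 + 3 = 6 out of 12
  expect_equal(d$n, 12L)
  expect_equal(d$k, 6)
  dw <- pf_data(
    dplyr::mutate(tr, variant = "SW", certainty_index = c(0.25, 1, 1, 0.25)),
    "certainty", "valid"
  )
  expect_equal(dw$n, 4L)
  expect_equal(dw$k, 2)
  da <- pf_data(tr, "accuracy", "valid")
  expect_equal(da$k, 3L)
})

test_that("fit_pf recovers generating parameters from large samples", {
  set.seed(10)
  d <- gen_pf_counts(
    levels = c(2, 5, 10, 20, 40, 80), n = 2000,
    alpha = 30, beta = 0.25, lambda = 0.02
  )
  fit <- fit_pf(d)
  expect_lt(abs(fit$alpha - 30) / 30, 0.10)
  expect_lt(abs(fit$beta - 0.25) / 0.25, 0.25)
  expect_false(fit$degenerate)
  # self-consistency: achieved loglik is no worse than at the generating truth
  ll_truth <- attencert:::pf_loglik(c(30, 0.25, 0.02), d, 0.25, NULL)
  expect_gte(fit$loglik + 1e-6, ll_truth)
})

test_that("degenerate and flat data raise the documented flags", {
  d_flat <- tibble::tibble(coherence = c(5, 20, 50, 100), n = 200, k = 100)
  fit <- fit_pf(d_flat, lambda = 0)
  expect_true(fit$degenerate)
  # a flat confidence profile measured precisely: slope pinned at its bound,
  # threshold undefined
  d_noise <- tibble::tibble(
    coherence = c(5, 20, 50, 100), n = 50000,
    k = c(25000, 25010, 24995, 25005)
  )
  fit2 <- fit_pf(d_noise, lambda = 0)
  expect_lt(fit2$beta, 0.01) # slope collapses toward its lower bound
  expect_true(is.na(threshold_at(fit2, 0.625)))
  expect_error(fit_pf(d_flat[1, ]), "levels")
  expect_error(
    fit_pf(tibble::tibble(coherence = c(5, 20), n = 10, k = c(11, 2))),
    "counts"
  )
})

test_that("threshold_at inverts the fitted function analytically", {
  fit <- structure(
    list(
      alpha = 40, beta = 0.2, gamma = 0.25, lambda = 0, loglik = 0,
      n_trials = 0, measure = "certainty", condition = "valid",
      data = tibble::tibble(coherence = c(10, 80), n = 1, k = 1),
      degenerate = FALSE, flat = FALSE
    ),
    class = "pf_fit"
  )
  # midpoint criterion with zero lapse returns alpha exactly
  expect_equal(threshold_at(fit, 0.625), 40)
  # asymptote criteria are unreachable
  expect_true(is.na(threshold_at(fit, 0.25)))
  expect_true(is.na(threshold_at(fit, 1)))
  # nonzero lapse: analytic inversion agrees with a bisection oracle
  fit$lambda <- 0.05
  x <- threshold_at(fit, 0.8)
  oracle <- uniroot(
    function(z) psi_logistic(z, 40, 0.2, 0.25, 0.05) - 0.8,
    c(0, 100), tol = 1e-10
  )$root
  expect_equal(x, oracle, tolerance = 1e-6)
  # a criterion the function cannot reach below 100% coherence
  fit$beta <- 0.03
  expect_true(is.na(threshold_at(fit, 0.94)))
  # round-trip: threshold_at(psi(x)) is the identity on reachable criteria
  fit$beta <- 0.2
  fit$lambda <- 0
  for (x0 in c(20, 40, 70)) {
    crit <- psi_logistic(x0, 40, 0.2, 0.25, 0)
    expect_equal(threshold_at(fit, crit), x0, tolerance = 1e-8)
  }
})

test_that("the transformed likelihood ratio behaves like a deviance", {
  set.seed(12)
  d <- gen_pf_counts(n = 400)
  # identical conditions: TLR ~ 0 within optimizer tolerance
  expect_lt(abs(as.numeric(tlr(d, d, lambda = 0))), 0.01)
  # nesting: pooled loglik never beats the sum of separate logliks
  d2 <- gen_pf_counts(n = 400, alpha = 45)
  val <- tlr(d, d2, lambda = 0)
  fits <- attributes(val)
  expect_gte(
    fits$fit_A$loglik + fits$fit_B$loglik,
    fits$fit_pooled$loglik - 1e-9
  )
  expect_gte(as.numeric(val), -1e-6)
})

test_that("TLR is non-negative over many random small datasets", {
  set.seed(13)
  for (i in 1:60) {
    a <- gen_pf_counts(n = 30, alpha = runif(1, 15, 60), beta = runif(1, 0.05, 0.3))
    b <- gen_pf_counts(n = 30, alpha = runif(1, 15, 60), beta = runif(1, 0.05, 0.3))
    expect_gte(as.numeric(tlr(a, b, lambda = 0)), -1e-6)
  }
})

test_that("mc_model_comparison applies the add-one p and the 95% exceedance rule", {
  set.seed(14)
  a <- gen_pf_counts(n = 200)
  b <- gen_pf_counts(n = 200)
  cmp <- mc_model_comparison(a, b, n_sims = 200, lambda = 0, seed = 15)
  expect_equal(
    cmp$p_mc,
    (1 + sum(cmp$null_tlrs >= cmp$tlr_observed)) / (cmp$n_sims + 1)
  )
  expect_identical(cmp$significant, cmp$tlr_observed > cmp$critical)
  expect_true(all(cmp$null_tlrs >= -1e-6))
  expect_error(mc_model_comparison(a, b, n_sims = 0), "n_sims")
})

test_that("well-separated conditions are detected at modest trial counts", {
  set.seed(16)
  a <- gen_pf_counts(n = 500, alpha = 25)
  b <- gen_pf_counts(n = 500, alpha = 45)
  cmp <- mc_model_comparison(a, b, n_sims = 300, lambda = 0, seed = 17)
  expect_true(cmp$significant)
  expect_gt(cmp$tlr_observed, cmp$critical)
  expect_lt(cmp$p_mc, 0.05)
})

test_that("fitting the analysis chain to simulated trials recovers the observer", {
  obs <- observer_params(
    acc_threshold_valid = 20, acc_threshold_invalid = 30,
    acc_slope = 0.12, lapse = 0
  )
  tr <- simulate_experiment("SN",
    n_subjects = 1, n_trials = 10000,
    params = obs, subject_sd = 0, seed = 18
  )
  fit <- fit_pf(pf_data(tr, "accuracy", "valid"), lambda = 0)
  expect_lt(abs(fit$alpha - 20) / 20, 0.10)
})

test_that("tidy, glance and autoplot expose fit and comparison results", {
  set.seed(19)
  fit <- fit_pf(gen_pf_counts(n = 300), lambda = 0)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "fixed"))
  expect_equal(td$estimate[td$term == "alpha"], fit$alpha)
  gl <- glance(fit)
  expect_equal(gl$n_levels, 4L)
  expect_s3_class(autoplot(fit), "ggplot")
  cmp <- mc_model_comparison(
    gen_pf_counts(n = 100), gen_pf_counts(n = 100),
    n_sims = 50, lambda = 0, seed = 20
  )
  expect_equal(nrow(tidy(cmp)), cmp$n_sims)
  expect_s3_class(autoplot(cmp), "ggplot")
})
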