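test_that("the expected same-sex ratio follows the MZ-share formula", {
  expect_equal(expected_same_sex_ratio(2.0), 0.70)
  expect_equal(expected_same_sex_ratio(1.6), 0.75)
  expect_equal(expected_same_sex_ratio(2.0, phi_det = 0.5), 0.60)
  expect_error(expected_same_sex_ratio(0), "positive")
})

test_that("same_sex_diagnostic computes rates, inverts phi_det, and is self-consistent", {
  co <- simulate_cohort(cohort_preset("quebec", n_families = 40000, seed = 24))
  q <- suppressWarnings(same_sex_diagnostic(co))
  d <- co$deliveries
  expect_equal(q$r_t, 100 * 2 * sum(d$n_children == 2) / sum(d$n_children))
  expect_gte(q$r_ss_observed, 0)

  # inversion self-consistency: re-applying the same-sex formula at the
  # inverted phi_det reproduces the observed ratio exactly
  expect_equal(expected_same_sex_ratio(q$r_t, q$phi_det), q$r_ss_observed)

  # full detection in a simulated register implies phi_det near 1
  expect_equal(q$phi_det, 1, tolerance = 0.15)
})

test_that("an all-same-sex twin register has observed ratio 1 and a warning", {
  co <- simulate_cohort(sim_config(n_families = 3000, seed = 25,
                                   twin_base_rate = 0.02,
                                   twin_age_gradient = 0,
                                   twin_parity_gradient = 0,
                                   mz_twin_rate = 1))
  expect_warning(q <- same_sex_diagnostic(co), "exceeds 1")
  expect_equal(q$r_ss_observed, 1)
  expect_gt(q$phi_det, 1)
})

test_that("missing true twins lowers the recovered detection fraction proportionally", {
  co <- simulate_cohort(cohort_preset("quebec", n_families = 30000, seed = 26))
  bad <- corrupt_twin_labels(co, miss = 0.3, seed = 27)
  q <- suppressWarnings(same_sex_diagnostic(bad))
  expect_equal(q$phi_det, 0.7, tolerance = 0.12)
  # conservation: splitting twin deliveries never changes total children
  expect_equal(sum(bad$deliveries$n_children), sum(co$deliveries$n_children))
})

test_that("familial repetition matches the exact binomial expectation", {
  # degenerate registers
  one <- familial_repetition(rep(1L, 50), 0.5, n_reps = 200, seed = 1)
  expect_equal(one$mc_mean, 0)
  expect_equal(one$exact, 0)
  certain <- familial_repetition(c(2L, 2L), 1, n_reps = 50, seed = 1)
  expect_equal(certain$mc_mean, 2)
  expect_equal(certain$exact, 2)

  # Monte-Carlo converges on the closed form
  fr <- familial_repetition(rep(6L, 100), 0.016, n_reps = 10000, seed = 2)
  expect_equal(fr$exact, 100 * (1 - pbinom(1, 6, 0.016)))
  expect_lt(abs(fr$mc_mean - fr$exact), 3 * fr$mc_se)

  expect_error(familial_repetition(integer(0), 0.1), "non-empty")
  expect_error(familial_repetition(c(3L, -1L), 0.1), "non-negative")
})

test_that("twinning correlates recover planted gradients and match brute-force slopes", {
  # age gradient planted at 0.0004/yr with the parity channel switched off
  co <- simulate_cohort(sim_config(n_families = 40000, seed = 28,
                                   twin_base_rate = 0.012,
                                   twin_age_gradient = 0.0004,
                                   twin_parity_gradient = 0))
  tab <- build_analysis_table(co)
  res <- twinning_correlates(tab, "mother_age")
  expect_lt(abs(res$estimate - 0.0004), 2 * res$std.error)

  # a covariate unrelated to twinning stays within noise of zero
  set.seed(29)
  tab$noise <- rnorm(nrow(tab))
  res0 <- twinning_correlates(tab, "noise")
  expect_lt(abs(res0$estimate), 2 * res0$std.error)

  # 4-row hand-built check against the closed-form OLS slope
  tiny <- tibble::tibble(twin = c(0, 0, 1, 1), x = c(1, 2, 3, 5))
  slope <- cov(tiny$twin, tiny$x) / var(tiny$x)
  expect_equal(twinning_correlates(tiny, "x")$estimate, slope)

  tab$const <- 1
  expect_error(twinning_correlates(tab, "const"), "constant")
})

test_that("false twin labels dilute the same-sex ratio and shrink the twin effect", {
  co <- simulate_cohort(cohort_preset("quebec", n_families = 8000, seed = 30))
  bad <- corrupt_twin_labels(co, fake = 0.3, seed = 31)
  expect_gt(attr(bad, "n_fake"), 0)
  q_clean <- suppressWarnings(same_sex_diagnostic(co))
  q_bad <- suppressWarnings(same_sex_diagnostic(bad))
  expect_lt(q_bad$r_ss_observed, q_clean$r_ss_observed)
  a_clean <- estimate_twin_effect(build_analysis_table(co), "births")
  a_bad <- estimate_twin_effect(build_analysis_table(bad), "births")
  expect_lt(a_bad$coefficient, a_clean$coefficient)
  # children conserved under merging
  expect_equal(sum(bad$deliveries$n_children), sum(co$deliveries$n_children))
})
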