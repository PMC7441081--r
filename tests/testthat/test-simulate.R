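test_that("identical config and seed give identical cohorts", {
  cfg <- sim_config(n_families = 400, seed = 7, controller_fraction = 0.3)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$deliveries, b$deliveries)
  expect_identical(a$families, b$families)
  c2 <- simulate_cohort(cfg, seed = 8)
  expect_false(identical(a$deliveries, c2$deliveries))
})

test_that("switching twinning off yields only singleton deliveries", {
  co <- simulate_cohort(sim_config(n_families = 500, seed = 3,
                                   twin_base_rate = 0,
                                   twin_age_gradient = 0,
                                   twin_parity_gradient = 0))
  expect_true(all(co$deliveries$n_children == 1L))
  expect_true(all(is.na(co$deliveries$sex_2)))
})

test_that("with no mortality every child survives and survivors equal births", {
  co <- simulate_cohort(sim_config(n_families = 400, seed = 4,
                                   theta_s = 1, theta_t = 1,
                                   controller_fraction = 0))
  tab <- build_analysis_table(co)
  expect_equal(tab$survivors, tab$births)
})

test_that("without adult mortality and with distant sterility, exposure runs to max_wife_age", {
  co <- simulate_cohort(sim_config(n_families = 300, seed = 5,
                                   adult_annual_death_hazard = 0,
                                   sterility_age_mean = 80,
                                   sterility_age_sd = 0.1,
                                   max_wife_age = 45))
  d <- co$deliveries
  # conception stops at age 45; gestation can push a delivery slightly past
  expect_lte(max(d$mother_age), 45)
  # last deliveries cluster against the cap rather than stopping early
  last_age <- tapply(d$mother_age, d$family_id, max)
  expect_gt(mean(last_age >= 42), 0.9)
})

test_that("twin delivery rates rise in mother age and parity when gradients are positive", {
  co <- simulate_cohort(sim_config(n_families = 20000, seed = 6,
                                   twin_base_rate = 0.01,
                                   twin_age_gradient = 0.002,
                                   twin_parity_gradient = 0.004))
  d <- co$deliveries
  age_bin <- cut(d$mother_age, c(0, 25, 30, 35, 60))
  rate_by_age <- tapply(d$n_children == 2, age_bin, mean)
  expect_true(all(diff(rate_by_age) > 0))
  par_bin <- cut(d$delivery_index, c(-1, 0, 2, 4, 30))
  rate_by_parity <- tapply(d$n_children == 2, par_bin, mean)
  expect_true(all(diff(rate_by_parity) > 0))
})

test_that("controllers stop at their surviving-children target under foresight", {
  co <- simulate_cohort(sim_config(n_families = 2000, seed = 8,
                                   controller_fraction = 1,
                                   adult_annual_death_hazard = 0,
                                   wife_marriage_age_mean = 20,
                                   wife_marriage_age_sd = 1,
                                   sterility_age_mean = 45,
                                   sterility_age_sd = 1,
                                   target_mean = 2))
  d <- co$deliveries
  surv <- tapply(ifelse(is.na(d$survives_2), d$survives_1,
                        d$survives_1 + d$survives_2),
                 d$family_id, sum)
  tg <- co$families$target_n[match(as.integer(names(surv)),
                                   co$families$family_id)]
  # nearly all families end at or just above target (twin overshoot by 1)
  expect_gt(mean(surv >= tg), 0.98)
  expect_lte(max(surv - tg), 1)
})

test_that("reactive and foresight stopping coincide exactly when no child dies", {
  base <- list(n_families = 1500, seed = 12, controller_fraction = 1,
               adult_annual_death_hazard = 0, target_mean = 3,
               theta_s = 1, theta_t = 1)
  fore <- simulate_cohort(do.call(sim_config, c(base, stopping_rule = "foresight")))
  reac <- simulate_cohort(do.call(sim_config, c(base, stopping_rule = "reactive")))
  expect_identical(fore$deliveries, reac$deliveries)

  # with child mortality the two rules genuinely differ: reactive couples
  # stop on currently-alive counts (and resume after a death), foresight
  # couples stop on eventual survivors
  base$theta_s <- 0.6; base$theta_t <- 0.45
  fore2 <- simulate_cohort(do.call(sim_config, c(base, stopping_rule = "foresight")))
  reac2 <- simulate_cohort(do.call(sim_config, c(base, stopping_rule = "reactive")))
  expect_false(identical(fore2$deliveries, reac2$deliveries))
})

test_that("familial twin heterogeneity raises repeat-twin families above the random benchmark", {
  cfg <- sim_config(n_families = 30000, seed = 13, twin_base_rate = 0.015,
                    twin_age_gradient = 0, twin_parity_gradient = 0,
                    family_twin_log_sd = 1)
  co <- simulate_cohort(cfg)
  d <- co$deliveries
  twins_per_fam <- tapply(d$n_children == 2, d$family_id, sum)
  dels_per_fam <- tapply(d$n_children, d$family_id, length)
  observed_repeats <- sum(twins_per_fam >= 2)
  bench <- familial_repetition(as.integer(dels_per_fam),
                               mean(d$n_children == 2),
                               n_reps = 500, seed = 1)
  expect_gt(observed_repeats, bench$exact + 3 * sqrt(bench$exact))
})
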