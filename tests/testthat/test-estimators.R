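test_that("an exact within-cell gap of 1 is recovered with zero residual", {
  tab <- exact_table(gap = 1, interactive = TRUE)
  e <- estimate_twin_effect(tab, "births", "nonparametric")
  expect_equal(e$coefficient, 1)
  expect_equal(e$residual_scale, 0, tolerance = 1e-10)
  expect_equal(e$n_obs, nrow(tab))

  prof <- parity_profile(tab, "births")
  expect_equal(prof$gap, rep(1, nrow(prof)))
})

test_that("parametric and fully interacted estimates agree without parity-age interaction", {
  tab <- exact_table(gap = 0.7, interactive = FALSE)
  ep <- estimate_twin_effect(tab, "births", "parametric")
  en <- estimate_twin_effect(tab, "births", "nonparametric")
  expect_equal(ep$coefficient, en$coefficient, tolerance = 1e-10)
  expect_equal(ep$coefficient, 0.7, tolerance = 1e-10)

  # with interaction in the outcome the two weight cells differently
  # (unbalance the twin share across cells so the weightings diverge)
  tab2 <- exact_table(gap = 0.7, interactive = TRUE)
  tab2$births <- tab2$births + 0.3 * tab2$twin * (tab2$mother_age == 32)
  drop_idx <- which(tab2$twin == 0 & tab2$mother_age == 32 & tab2$parity <= 1)
  tab2 <- tab2[-drop_idx[seq_len(4)], ]
  ep2 <- estimate_twin_effect(tab2, "births", "parametric")
  en2 <- estimate_twin_effect(tab2, "births", "nonparametric")
  expect_false(isTRUE(all.equal(ep2$coefficient, en2$coefficient,
                                tolerance = 1e-10)))
})

test_that("both variants solve the same normal equations as a brute-force matrix solve", {
  co <- simulate_cohort(cohort_preset("quebec", n_families = 1500, seed = 19))
  tab <- build_analysis_table(co)
  for (oc in c("births", "survivors")) {
    ep <- estimate_twin_effect(tab, oc, "parametric")
    bf <- brute_ols(tab[[oc]], brute_design_parametric(tab))
    expect_equal(ep$coefficient, unname(bf["twin"]), tolerance = 1e-8)

    en <- estimate_twin_effect(tab, oc, "nonparametric")
    bf2 <- brute_ols(tab[[oc]], brute_design_cells(tab))
    expect_equal(en$coefficient, unname(bf2["twin"]), tolerance = 1e-8)
  }
  # a tiny hand-made table through the same oracle
  tiny <- exact_table(gap = 1, n_per_cell = 1)
  tiny$births <- tiny$births + rep(c(0.1, -0.2), length.out = nrow(tiny))
  et <- estimate_twin_effect(tiny, "births", "parametric")
  bft <- brute_ols(tiny$births, brute_design_parametric(tiny))
  expect_equal(et$coefficient, unname(bft["twin"]), tolerance = 1e-8)
})

test_that("a linear-in-parity twin excess is recovered exactly", {
  tab <- exact_table(gap = 0)
  tab$births <- tab$births + tab$twin * (0.4 + 0.1 * tab$parity)
  ix <- estimate_parity_interaction(tab, "births")
  expect_equal(ix$lambda$coefficient, 0.1, tolerance = 1e-10)
  expect_equal(ix$alpha$coefficient, 0.4, tolerance = 1e-10)
  bf <- brute_ols(tab$births, brute_design_parametric(tab, twin_parity = TRUE))
  expect_equal(ix$lambda$coefficient, unname(bf["twin_parity"]),
               tolerance = 1e-8)
})

test_that("post-twin interval effects are exact on constructed shifts", {
  tab <- exact_table(gap = 1)
  expect_equal(estimate_post_twin_interval(tab)$coefficient, 0,
               tolerance = 1e-10)
  tab2 <- tab
  tab2$next_interval_months <- tab2$next_interval_months + 6 * tab2$twin
  expect_equal(estimate_post_twin_interval(tab2)$coefficient, 6,
               tolerance = 1e-10)
})

test_that("estimates are invariant to row order and family relabeling", {
  co <- simulate_cohort(cohort_preset("quebec", n_families = 800, seed = 20))
  tab <- build_analysis_table(co)
  e1 <- estimate_twin_effect(tab, "births", "parametric")

  set.seed(1)
  shuffled <- tab[sample(nrow(tab)), ]
  e2 <- estimate_twin_effect(shuffled, "births", "parametric")
  expect_equal(e1$coefficient, e2$coefficient, tolerance = 1e-12)
  expect_equal(e1$std_error, e2$std_error, tolerance = 1e-12)

  relabeled <- tab
  relabeled$family_id <- relabeled$family_id + 100000L
  e3 <- estimate_twin_effect(relabeled, "births", "nonparametric")
  e0 <- estimate_twin_effect(tab, "births", "nonparametric")
  expect_equal(e0$coefficient, e3$coefficient)
})

test_that("twin-free or degenerate tables raise unidentified errors", {
  co <- simulate_cohort(sim_config(n_families = 200, seed = 21,
                                   twin_base_rate = 0, twin_age_gradient = 0,
                                   twin_parity_gradient = 0))
  tab <- build_analysis_table(co)
  expect_error(estimate_twin_effect(tab, "births"),
               class = "twinstest_unidentified")
  expect_error(estimate_parity_interaction(tab, "births"),
               class = "twinstest_unidentified")
  expect_error(estimate_post_twin_interval(tab),
               class = "twinstest_unidentified")

  # all twins at one parity: the interaction slope is unidentified
  tab2 <- exact_table(gap = 1)
  tab2 <- tab2[!(tab2$twin == 1 & tab2$parity > 0), ]
  expect_error(estimate_parity_interaction(tab2, "births"),
               class = "twinstest_unidentified")
})

test_that("cluster-robust standard errors match sandwich::vcovCL", {
  co <- simulate_cohort(cohort_preset("quebec", n_families = 600, seed = 22))
  tab <- build_analysis_table(co)
  e <- estimate_twin_effect(tab, "births", "parametric", cluster_se = TRUE)
  fit <- lm(births ~ twin + factor(parity) + factor(pool_mother_age(mother_age)),
            data = tab)
  vc <- sandwich::vcovCL(fit, cluster = tab$family_id)
  expect_equal(e$std_error, sqrt(vc["twin", "twin"]), tolerance = 1e-8)
  # clustered SEs exceed conventional ones here (positive within-family
  # correlation of the family-level outcome)
  expect_gt(e$std_error,
            estimate_twin_effect(tab, "births", "parametric")$std_error)
})

test_that("tidy and glance summarise fits in broom layout", {
  tab <- exact_table(gap = 1, n_per_cell = 4)
  set.seed(23)
  tab$births <- tab$births + rnorm(nrow(tab), sd = 0.1)
  e <- estimate_twin_effect(tab, "births")
  td <- tidy(e)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_equal(td$estimate, e$coefficient)
  gl <- glance(e)
  expect_equal(gl$n_obs, nrow(tab))
  ix <- estimate_parity_interaction(tab, "births")
  expect_equal(tidy(ix)$term, c("twin", "twin:parity"))
})
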