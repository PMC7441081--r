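make_family <- function(id, sizes, survive = NULL, months = NULL,
                        ages = NULL) {
  k <- length(sizes)
  months <- months %||% seq(12, by = 26, length.out = k)
  ages <- ages %||% (22L + seq_len(k))
  if (is.null(survive)) survive <- lapply(sizes, function(s) rep(TRUE, s))
  tibble::tibble(
    family_id = id,
    delivery_index = seq_len(k) - 1L,
    mother_age = as.integer(ages),
    months_since_marriage = as.integer(months),
    n_children = as.integer(sizes),
    sex_1 = "M",
    sex_2 = ifelse(sizes == 2, "F", NA_character_),
    survives_1 = vapply(survive, `[`, logical(1), 1),
    survives_2 = ifelse(sizes == 2,
                        vapply(survive, function(s) s[min(2, length(s))],
                               logical(1)), NA)
  )
}

make_cohort <- function(deliveries, mother_death = NA_integer_,
                        father_death = NA_integer_, unit = "union") {
  ids <- unique(deliveries$family_id)
  fam <- tibble::tibble(
    family_id = ids, unit = unit,
    is_controller = NA, target_n = NA_integer_,
    mother_age_at_death = rep_len(mother_death, length(ids)),
    father_age_at_death = rep_len(father_death, length(ids)))
  twin_cohort(fam, deliveries)
}

test_that("the analysis table counts births, parity and intervals per delivery", {
  co <- make_cohort(make_family(1L, c(1, 2, 1), months = c(12, 40, 70)))
  tab <- build_analysis_table(co)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$births, rep(4L, 3))
  expect_equal(tab$twin, c(0L, 1L, 0L))
  expect_equal(tab$parity, c(0L, 1L, 2L))
  expect_equal(tab$next_interval_months, c(28L, 30L, NA))

  # all children surviving: survivors equal births
  expect_equal(tab$survivors, tab$births)

  # one twin dying before 14 drops survivors by exactly one
  co2 <- make_cohort(make_family(
    1L, c(1, 2, 1),
    survive = list(TRUE, c(TRUE, FALSE), TRUE)))
  expect_equal(unique(build_analysis_table(co2)$survivors), 3L)
})

test_that("per-family children sum to the recorded births (conservation)", {
  co <- simulate_cohort(sim_config(n_families = 300, seed = 14))
  tab <- build_analysis_table(co)
  per_fam <- dplyr::distinct(tab, family_id, births)
  direct <- tapply(co$deliveries$n_children, co$deliveries$family_id, sum)
  expect_equal(per_fam$births,
               as.integer(direct[as.character(per_fam$family_id)]))
  expect_equal(mean(per_fam$births), cohort_mean_births(co))
})

test_that("unordered deliveries are rejected", {
  bad <- make_family(1L, c(1, 1))
  bad$months_since_marriage <- c(40L, 12L)
  expect_error(make_cohort(bad), "ordered")
})

test_that("sample filters drop only families with a disqualifying recorded death", {
  dels <- dplyr::bind_rows(
    make_family(1L, 1), make_family(2L, 1), make_family(3L, 1))
  fam <- tibble::tibble(
    family_id = 1:3, unit = "union", is_controller = NA,
    target_n = NA_integer_,
    mother_age_at_death = c(35L, NA, 60L),
    father_age_at_death = c(NA, 50L, 44L))
  co <- twin_cohort(fam, dels)

  # union unit: mother dead at 35 excludes family 1; father dead at 44
  # excludes family 3; unknown deaths are kept
  kept <- apply_filters(co, filter_policy(unit = "union"))
  expect_equal(kept$families$family_id, 2L)

  # father unit: family 2's father reached 50, family 3's died at 44
  kept_f <- apply_filters(co, filter_policy(unit = "father"))
  expect_setequal(kept_f$families$family_id, c(1L, 2L))

  # distrusting missing records empties the unknown families too
  strict <- apply_filters(co, filter_policy(
    unit = "union", treat_unknown_death_as_survival = FALSE))
  expect_equal(nrow(strict$families), 0)

  # idempotence
  twice <- apply_filters(kept, filter_policy(unit = "union"))
  expect_identical(twice$families, kept$families)
})

test_that("cohorts round-trip through CSV exactly", {
  co <- simulate_cohort(sim_config(n_families = 30, seed = 15,
                                   controller_fraction = 0.4,
                                   twin_base_rate = 0.15))
  path <- tempfile(fileext = ".csv")
  write_cohort_csv(co, path)
  back <- read_cohort_csv(path)
  expect_equal(back$deliveries, co$deliveries)
  expect_equal(back$families, co$families)
})

test_that("the CSV reader rejects malformed rows and accepts empty cohorts", {
  co <- simulate_cohort(sim_config(n_families = 5, seed = 16))
  path <- tempfile(fileext = ".csv")
  write_cohort_csv(co, path)

  lines <- readLines(path)
  # corrupt one delivery to a triplet
  row <- grep(",1,M", lines)[1]
  lines[row] <- sub("(^[0-9]+,[a-z]+,[0-9]+,[0-9]+,[0-9]+,)1,", "\\13,",
                    lines[row])
  bad <- tempfile(fileext = ".csv")
  writeLines(lines, bad)
  expect_error(read_cohort_csv(bad), "n_children")

  empty <- tempfile(fileext = ".csv")
  writeLines(lines[1], empty)
  eco <- read_cohort_csv(empty)
  expect_s3_class(eco, "twin_cohort")
  expect_equal(nrow(eco$families), 0)
  expect_equal(nrow(eco$deliveries), 0)
})

test_that("childless families survive the CSV round trip", {
  dels <- make_family(1L, c(1, 2))
  fam <- tibble::tibble(
    family_id = 1:2, unit = "union", is_controller = c(NA, NA),
    target_n = NA_integer_,
    mother_age_at_death = c(NA_integer_, 44L),
    father_age_at_death = NA_integer_)
  co <- twin_cohort(fam, dels)
  path <- tempfile(fileext = ".csv")
  write_cohort_csv(co, path)
  back <- read_cohort_csv(path)
  expect_equal(nrow(back$families), 2)
  expect_equal(back$families, co$families)
  expect_equal(back$deliveries, co$deliveries)
})

test_that("cohort_theory_params estimates survival and family size from the data", {
  co <- simulate_cohort(sim_config(n_families = 8000, seed = 17,
                                   theta_s = 0.8, theta_t = 0.5,
                                   twin_base_rate = 0.05))
  tp <- cohort_theory_params(co)
  expect_equal(tp$theta_s, 0.8, tolerance = 0.02)
  expect_equal(tp$theta_t, 0.5, tolerance = 0.05)
  expect_equal(tp$phi, 1 / cohort_mean_births(co))
})
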