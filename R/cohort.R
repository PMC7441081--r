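#' Construct a cohort of family birth histories
#'
#' A `twin_cohort` bundles two tibbles: `families` (one row per reproductive
#' unit) and `deliveries` (one row per delivery event, singleton or twin).
#' [simulate_cohort()] and [read_cohort_csv()] both return this container.
#'
#' `families` columns: `family_id`, `unit` (`"union"`, `"father"` or
#' `"mother"`), `mother_age_at_death` and `father_age_at_death` (completed
#' years, `NA` when no death record), and — for simulated cohorts — the latent
#' `is_controller` flag and `target_n` surviving-children target.
#'
#' `deliveries` columns: `family_id`, `delivery_index` (0-based order within
#' the family), `mother_age` (completed years at delivery),
#' `months_since_marriage`, `n_children` (1 or 2), `sex_1`/`sex_2` (`"M"` or
#' `"F"`, `sex_2` is `NA` for singletons) and `survives_1`/`survives_2`
#' (survival to age 14; `survives_2` is `NA` for singletons).
#'
#' @param families,deliveries Tibbles as described above.
#' @return An object of class `twin_cohort`.
#' @export
twin_cohort <- function(families, deliveries) {
  families <- tibble::as_tibble(families)
  deliveries <- tibble::as_tibble(deliveries)

  need_fam <- c("family_id", "unit", "mother_age_at_death", "father_age_at_death")
  need_del <- c("family_id", "delivery_index", "mother_age",
                "months_since_marriage", "n_children", "sex_1", "sex_2",
                "survives_1", "survives_2")
  miss <- setdiff(need_fam, names(families))
  if (length(miss)) abort(paste0("`families` is missing columns: ",
                                 paste(miss, collapse = ", ")))
  miss <- setdiff(need_del, names(deliveries))
  if (length(miss)) abort(paste0("`deliveries` is missing columns: ",
                                 paste(miss, collapse = ", ")))
  if (!"is_controller" %in% names(families)) families$is_controller <- NA
  if (!"target_n" %in% names(families)) families$target_n <- NA_integer_

  if (anyDuplicated(families$family_id)) {
    abort("`families$family_id` must be unique.")
  }
  if (!all(deliveries$family_id %in% families$family_id)) {
    abort("Every delivery must belong to a family present in `families`.")
  }
  bad <- !deliveries$n_children %in% c(1L, 2L)
  if (any(bad)) {
    abort(sprintf("`n_children` must be 1 or 2 (first offending row: %d).",
                  which(bad)[1]))
  }
  if (any(deliveries$n_children == 2 &
          (is.na(deliveries$sex_2) | is.na(deliveries$survives_2)))) {
    abort("Twin deliveries must record `sex_2` and `survives_2`.")
  }

  if (nrow(deliveries) > 1) {
    o <- order(deliveries$family_id, deliveries$delivery_index)
    fam <- deliveries$family_id[o]
    same <- fam[-1] == fam[-length(fam)]
    idx_ok <- diff(deliveries$delivery_index[o]) > 0
    mon_ok <- diff(deliveries$months_since_marriage[o]) > 0
    bad <- same & !(idx_ok & mon_ok)
    if (any(bad)) {
      abort(sprintf(
        "Deliveries must be strictly ordered in delivery_index and months_since_marriage within each family (family %s).",
        fam[-1][bad][1]))
    }
  }

  structure(list(families = families, deliveries = deliveries),
            class = "twin_cohort")
}

#' @export
print.twin_cohort <- function(x, ...) {
  nfam <- nrow(x$families)
  ndel <- nrow(x$deliveries)
  nb <- sum(x$deliveries$n_children)
  ntwin <- sum(x$deliveries$n_children == 2)
  cat(sprintf("<twin_cohort> %d families, %d deliveries, %d births\n",
              nfam, ndel, nb))
  if (ndel > 0) {
    cat(sprintf("  twin deliveries: %d (%.2f%% of births); mean births per family with births: %.2f\n",
                ntwin, 100 * 2 * ntwin / nb, cohort_mean_births(x)))
  }
  if (any(x$families$is_controller %in% TRUE)) {
    cat(sprintf("  controllers: %d of %d families\n",
                sum(x$families$is_controller %in% TRUE), nfam))
  }
  invisible(x)
}

#' Mean births per family among families with at least one birth
#'
#' Children are counted, so a twin delivery contributes 2. Families with no
#' recorded delivery are excluded, matching how average completed family size
#' is reported for historical samples.
#'
#' @param cohort A `twin_cohort`.
#' @return A single number (NaN for a cohort with no deliveries).
#' @export
cohort_mean_births <- function(cohort) {
  stopifnot(inherits(cohort, "twin_cohort"))
  per_fam <- tapply(cohort$deliveries$n_children, cohort$deliveries$family_id, sum)
  mean(as.numeric(per_fam))
}

#' Empirical theory parameters of a cohort
#'
#' Estimates the inputs of the closed-form expected twin effects directly
#' from a cohort: singleton and twin survival-to-14 rates, mean births per
#' family with births, and the last-birth fraction `phi = 1 / mean births`.
#'
#' @param cohort A `twin_cohort`.
#' @return A [theory_params()] object.
#' @export
cohort_theory_params <- function(cohort) {
  stopifnot(inherits(cohort, "twin_cohort"))
  d <- cohort$deliveries
  singles <- d$n_children == 1
  twins <- d$n_children == 2
  if (!any(singles) || !any(twins)) {
    abort("Cohort must contain both singleton and twin deliveries to estimate survival rates.")
  }
  theta_s <- mean(d$survives_1[singles])
  theta_t <- mean(c(d$survives_1[twins], d$survives_2[twins]))
  theory_params(theta_s = theta_s, theta_t = theta_t,
                mean_births = cohort_mean_births(cohort))
}
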