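#' Build the per-delivery analysis table
#'
#' Flattens a cohort into the table the twin-effect regressions consume: one
#' row per delivery, carrying the family-level outcomes on every row.
#'
#' @param cohort A [twin_cohort()].
#' @return A tibble with columns:
#' \describe{
#'   \item{family_id}{Family identifier.}
#'   \item{twin}{1 if this delivery is a twin pair, else 0.}
#'   \item{parity}{0-based count of prior deliveries (a twin pair advances
#'     parity by one, so parity indexes delivery events, not children).}
#'   \item{mother_age}{Mother's completed years at the delivery.}
#'   \item{births}{Total children ever born in the family (twins count as 2);
#'     constant within family.}
#'   \item{survivors}{Children surviving to age 14; constant within family.}
#'   \item{next_interval_months}{Months to the family's next delivery, `NA`
#'     for the last delivery.}
#' }
#' @examples
#' cohort <- simulate_cohort(sim_config(n_families = 50, seed = 3))
#' build_analysis_table(cohort)
#' @export
build_analysis_table <- function(cohort) {
  stopifnot(inherits(cohort, "twin_cohort"))
  d <- cohort$deliveries
  d |>
    dplyr::arrange(.data$family_id, .data$delivery_index) |>
    dplyr::group_by(.data$family_id) |>
    dplyr::mutate(
      twin = as.integer(.data$n_children == 2L),
      parity = dplyr::row_number() - 1L,
      births = sum(.data$n_children),
      survivors = sum(.data$survives_1, na.rm = TRUE) +
        sum(.data$survives_2, na.rm = TRUE),
      next_interval_months = dplyr::lead(.data$months_since_marriage) -
        .data$months_since_marriage
    ) |>
    dplyr::ungroup() |>
    dplyr::select("family_id", "twin", "parity", "mother_age", "births",
                  "survivors", "next_interval_months")
}

#' Sample-inclusion filter policy
#'
#' Historical family reconstitutions only approximate complete reproductive
#' histories; the standard inclusion rule keeps all families except those in
#' which the relevant parent is *known* to have died before completing the
#' reproductive span — age 40 for mothers, 45 for fathers — interpreting a
#' missing death record as survival.
#'
#' @param mother_min_age,father_min_age Minimum attained ages (years).
#' @param unit Which parent's survival matters: `"union"` (both), `"mother"`,
#'   or `"father"`.
#' @param treat_unknown_death_as_survival Keep families whose relevant death
#'   age is unrecorded (default `TRUE`).
#' @return A list of class `filter_policy`.
#' @export
filter_policy <- function(mother_min_age = 40, father_min_age = 45,
                          unit = c("union", "mother", "father"),
                          treat_unknown_death_as_survival = TRUE) {
  unit <- match.arg(unit)
  if (!is.numeric(mother_min_age) || mother_min_age <= 0 ||
      !is.numeric(father_min_age) || father_min_age <= 0) {
    abort("Minimum attained ages must be positive.")
  }
  structure(list(mother_min_age = mother_min_age,
                 father_min_age = father_min_age,
                 unit = unit,
                 treat_unknown_death_as_survival =
                   isTRUE(treat_unknown_death_as_survival)),
            class = "filter_policy")
}

#' Apply sample-inclusion filters to a cohort
#'
#' Removes families in which the policy-relevant parent is recorded as dying
#' below the policy's minimum attained age. With
#' `treat_unknown_death_as_survival` (the default) families without a death
#' record are retained. Filtering is idempotent.
#'
#' @param cohort A [twin_cohort()].
#' @param policy A [filter_policy()].
#' @return The filtered `twin_cohort` (possibly with zero families).
#' @examples
#' cohort <- simulate_cohort(sim_config(n_families = 200, seed = 9,
#'                                      adult_annual_death_hazard = 0.02))
#' filtered <- apply_filters(cohort, filter_policy())
#' nrow(filtered$families) <= nrow(cohort$families)
#' @export
apply_filters <- function(cohort, policy = filter_policy()) {
  stopifnot(inherits(cohort, "twin_cohort"), inherits(policy, "filter_policy"))
  fam <- cohort$families
  unknown_ok <- policy$treat_unknown_death_as_survival

  ok_age <- function(age, min_age) {
    ifelse(is.na(age), unknown_ok, age >= min_age)
  }
  mother_ok <- ok_age(fam$mother_age_at_death, policy$mother_min_age)
  father_ok <- ok_age(fam$father_age_at_death, policy$father_min_age)
  keep <- switch(policy$unit,
                 union = mother_ok & father_ok,
                 mother = mother_ok,
                 father = father_ok)
  fam <- fam[keep, , drop = FALSE]
  twin_cohort(fam,
              cohort$deliveries[cohort$deliveries$family_id %in% fam$family_id, ,
                                drop = FALSE])
}
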