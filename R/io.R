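#' Read and write cohorts as per-delivery CSV files
#'
#' The on-disk schema is one line per delivery with the family-level fields
#' repeated: `family_id, unit, delivery_index, mother_age,
#' months_since_marriage, n_children, sex_1, sex_2, survives_1, survives_2,
#' mother_age_at_death, father_age_at_death` plus two optional simulation-only
#' columns `is_controller, target_n`. A family with no deliveries is encoded
#' as a single line whose delivery fields are all empty, so that writing and
#' re-reading is the identity on any cohort. All dates are integer months
#' since marriage; sexes are `"M"`/`"F"`; survival flags are logical.
#'
#' @param cohort A [twin_cohort()].
#' @param path File path.
#' @return `read_cohort_csv()` returns a [twin_cohort()];
#'   `write_cohort_csv()` returns `path` invisibly.
#' @examples
#' co <- simulate_cohort(sim_config(n_families = 3, seed = 5))
#' f <- tempfile(fileext = ".csv")
#' write_cohort_csv(co, f)
#' identical(read_cohort_csv(f)$deliveries, co$deliveries)
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "twin_cohort"))
  fam <- cohort$families
  del <- cohort$deliveries
  flat <- dplyr::left_join(
    del,
    fam[, c("family_id", "unit", "mother_age_at_death", "father_age_at_death",
            "is_controller", "target_n")],
    by = "family_id")
  childless <- fam[!fam$family_id %in% del$family_id, , drop = FALSE]
  if (nrow(childless)) {
    empty <- tibble::tibble(
      family_id = childless$family_id,
      delivery_index = NA_integer_, mother_age = NA_integer_,
      months_since_marriage = NA_integer_, n_children = NA_integer_,
      sex_1 = NA_character_, sex_2 = NA_character_,
      survives_1 = NA, survives_2 = NA,
      unit = childless$unit,
      mother_age_at_death = childless$mother_age_at_death,
      father_age_at_death = childless$father_age_at_death,
      is_controller = childless$is_controller,
      target_n = childless$target_n)
    flat <- dplyr::bind_rows(flat, empty)
  }
  flat <- flat |>
    dplyr::select("family_id", "unit", "delivery_index", "mother_age",
                  "months_since_marriage", "n_children", "sex_1", "sex_2",
                  "survives_1", "survives_2", "mother_age_at_death",
                  "father_age_at_death", "is_controller", "target_n") |>
    dplyr::arrange(.data$family_id, .data$delivery_index)
  readr::write_csv(flat, path, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  header <- strsplit(readr::read_lines(path, n_max = 1), ",")[[1]]
  spec <- readr::cols(
    family_id = readr::col_integer(),
    unit = readr::col_character(),
    delivery_index = readr::col_integer(),
    mother_age = readr::col_integer(),
    months_since_marriage = readr::col_integer(),
    n_children = readr::col_integer(),
    sex_1 = readr::col_character(),
    sex_2 = readr::col_character(),
    survives_1 = readr::col_logical(),
    survives_2 = readr::col_logical(),
    mother_age_at_death = readr::col_integer(),
    father_age_at_death = readr::col_integer(),
    .default = readr::col_guess()
  )
  if ("is_controller" %in% header) {
    spec$cols$is_controller <- readr::col_logical()
  }
  if ("target_n" %in% header) {
    spec$cols$target_n <- readr::col_integer()
  }
  flat <- readr::read_csv(path, col_types = spec, na = c("", "NA"),
                          progress = FALSE)
  if (nrow(flat) == 0 && length(setdiff(
    c("family_id", "unit", "n_children"), header)) == 0) {
    # header-only file: an empty cohort
    return(twin_cohort(
      tibble::tibble(family_id = integer(0), unit = character(0),
                     is_controller = logical(0), target_n = integer(0),
                     mother_age_at_death = integer(0),
                     father_age_at_death = integer(0)),
      tibble::tibble(family_id = integer(0), delivery_index = integer(0),
                     mother_age = integer(0), months_since_marriage = integer(0),
                     n_children = integer(0), sex_1 = character(0),
                     sex_2 = character(0), survives_1 = logical(0),
                     survives_2 = logical(0))))
  }
  required <- c("family_id", "unit", "delivery_index", "mother_age",
                "months_since_marriage", "n_children", "sex_1", "sex_2",
                "survives_1", "survives_2", "mother_age_at_death",
                "father_age_at_death")
  miss <- setdiff(required, names(flat))
  if (length(miss)) {
    abort(paste0("Cohort CSV is missing columns: ", paste(miss, collapse = ", ")))
  }
  probs <- readr::problems(flat)
  if (nrow(probs)) {
    abort(paste0("Malformed cohort CSV rows (line numbers include header): ",
                 paste(sprintf("line %d (%s)", probs$row + 1, probs$expected),
                       collapse = "; ")))
  }
  if (!"is_controller" %in% names(flat)) flat$is_controller <- NA
  if (!"target_n" %in% names(flat)) flat$target_n <- NA_integer_

  is_delivery <- !is.na(flat$delivery_index)
  bad_n <- is_delivery & (is.na(flat$n_children) |
                            !flat$n_children %in% c(1L, 2L))
  if (any(bad_n)) {
    abort(sprintf("`n_children` must be 1 or 2; offending CSV line(s): %s.",
                  paste(which(bad_n) + 1, collapse = ", ")))
  }
  # a childless-family line must have all delivery fields empty
  ghost <- !is_delivery & (!is.na(flat$n_children) |
                             !is.na(flat$months_since_marriage))
  if (any(ghost)) {
    abort(sprintf("Rows with delivery fields but no delivery_index; CSV line(s): %s.",
                  paste(which(ghost) + 1, collapse = ", ")))
  }

  fam <- flat |>
    dplyr::distinct(.data$family_id, .data$unit, .data$mother_age_at_death,
                    .data$father_age_at_death, .data$is_controller,
                    .data$target_n)
  if (anyDuplicated(fam$family_id)) {
    dup <- fam$family_id[duplicated(fam$family_id)][1]
    abort(sprintf("Family %s has inconsistent family-level fields across its rows.", dup))
  }
  fam <- fam[, c("family_id", "unit", "is_controller", "target_n",
                 "mother_age_at_death", "father_age_at_death")]
  del <- flat[is_delivery,
              c("family_id", "delivery_index", "mother_age",
                "months_since_marriage", "n_children", "sex_1", "sex_2",
                "survives_1", "survives_2")]
  twin_cohort(fam, del)
}
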