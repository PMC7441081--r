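#' Same-sex ratio diagnostic for twin misclassification
#'
#' Monozygotic twin pairs are always same-sex while dizygotic pairs are
#' same-sex half the time, and the monozygotic rate is nearly constant across
#' populations (about 0.8 twin children per 100 births). At an observed
#' twinning rate of `R_t` twin children per 100 births, correctly labelled
#' twins should therefore be same-sex at rate `0.5 + 0.4 / R_t`. Same-day
#' baptisms of non-twin siblings mislabelled as twins dilute this towards
#' 0.5; the observed ratio inverts to a detection/validity fraction
#' `phi_det = (R_ss_observed - 0.5) * R_t / 0.4`.
#'
#' @param cohort A [twin_cohort()] with at least one twin delivery whose two
#'   sexes are recorded.
#' @return A list of class `twin_quality`: `r_t` (twin children per 100
#'   births), `r_ss_observed`, `r_ss_expected` (at full detection),
#'   `phi_det`, `n_twin_pairs`. `phi_det > 1` (same-sex ratio above the
#'   full-detection expectation) is reported with a warning, not clamped: it
#'   signals sampling noise or a twinning-rate mismatch.
#' @examples
#' co <- simulate_cohort(cohort_preset("quebec", n_families = 2000, seed = 4))
#' same_sex_diagnostic(co)
#' @export
same_sex_diagnostic <- function(cohort) {
  stopifnot(inherits(cohort, "twin_cohort"))
  d <- cohort$deliveries
  tw <- d[d$n_children == 2L & !is.na(d$sex_1) & !is.na(d$sex_2), ,
          drop = FALSE]
  if (nrow(tw) == 0) {
    abort("No twin deliveries with both sexes recorded.")
  }
  total_births <- sum(d$n_children)
  r_t <- 100 * 2 * nrow(tw) / total_births
  r_ss_obs <- mean(tw$sex_1 == tw$sex_2)
  r_ss_exp <- expected_same_sex_ratio(r_t, phi_det = 1)
  phi_det <- (r_ss_obs - 0.5) * r_t / 0.4
  if (phi_det > 1) {
    warn(sprintf(
      "Implied detection fraction %.2f exceeds 1: the observed same-sex ratio is above the full-detection expectation (sampling noise or twinning-rate mismatch).",
      phi_det))
  }
  structure(list(r_t = r_t, r_ss_observed = r_ss_obs,
                 r_ss_expected = r_ss_exp, phi_det = phi_det,
                 n_twin_pairs = nrow(tw)),
            class = "twin_quality")
}

#' Expected same-sex ratio among labelled twins
#'
#' @param r_t Twinning rate, twin children per 100 births (> 0).
#' @param phi_det Fraction of twin labels that are true twin events.
#' @return `0.5 + (0.4 / r_t) * phi_det`.
#' @export
expected_same_sex_ratio <- function(r_t, phi_det = 1) {
  if (!is.numeric(r_t) || length(r_t) != 1 || is.na(r_t) || r_t <= 0) {
    abort("`r_t` must be a positive twinning rate per 100 births.")
  }
  0.5 + (0.4 / r_t) * phi_det
}

#' @export
print.twin_quality <- function(x, ...) {
  cat("<twin_quality>\n")
  cat(sprintf("  twinning rate: %.2f twin children per 100 births (%d pairs)\n",
              x$r_t, x$n_twin_pairs))
  cat(sprintf("  same-sex ratio: observed %.3f, expected at full detection %.3f\n",
              x$r_ss_observed, x$r_ss_expected))
  cat(sprintf("  implied detection fraction: %.3f\n", x$phi_det))
  invisible(x)
}

#' Familial repetition of twin deliveries under random allocation
#'
#' If twin deliveries strike deliveries at random, the number of families
#' with two or more twin deliveries follows from the per-family binomial.
#' Comparing the observed count of repeat-twin families against this
#' benchmark tests for a familial twin propensity. Returns both a
#' Monte-Carlo estimate (with its standard error) and the exact expectation
#' `sum over families of P(Binomial(n_deliveries, twin_rate) >= 2)`.
#'
#' @param deliveries_per_family Integer vector of delivery counts, one per
#'   family.
#' @param twin_rate Probability a delivery is a twin delivery.
#' @param n_reps Monte-Carlo replications.
#' @param seed Optional seed.
#' @return A list of class `familial_repetition`: `mc_mean`, `mc_se`,
#'   `exact`, `n_reps`.
#' @examples
#' familial_repetition(rep(6, 100), twin_rate = 0.016, n_reps = 1000, seed = 1)
#' @export
familial_repetition <- function(deliveries_per_family, twin_rate,
                                n_reps = 10000, seed = NULL) {
  counts <- as.integer(deliveries_per_family)
  if (length(counts) == 0) abort("`deliveries_per_family` must be non-empty.")
  if (any(is.na(counts) | counts < 0)) {
    abort("`deliveries_per_family` must be non-negative counts.")
  }
  if (!is.numeric(twin_rate) || twin_rate < 0 || twin_rate > 1) {
    abort("`twin_rate` must be a probability.")
  }
  if (!is.null(seed)) set.seed(seed)
  reps <- vapply(seq_len(n_reps), function(i) {
    as.numeric(sum(rbinom(length(counts), counts, twin_rate) >= 2L))
  }, numeric(1))
  exact <- sum(pbinom(1, counts, twin_rate, lower.tail = FALSE))
  structure(list(mc_mean = mean(reps),
                 mc_se = sd(reps) / sqrt(n_reps),
                 exact = exact,
                 n_reps = n_reps),
            class = "familial_repetition")
}

#' @export
print.familial_repetition <- function(x, ...) {
  cat(sprintf("<familial_repetition> families with >= 2 twin deliveries under random allocation:\n"))
  cat(sprintf("  Monte-Carlo %.2f (SE %.3f, %d reps); exact expectation %.2f\n",
              x$mc_mean, x$mc_se, x$n_reps, x$exact))
  invisible(x)
}

#' Single-covariate twinning-correlate regression
#'
#' Linear-probability regression of the twin indicator on one covariate at a
#' time — the standard screen for whether twinning is associated with
#' observable family characteristics (it should correlate with mother's age
#' and parity, and with little else).
#'
#' @param table A per-delivery table containing a `twin` column and the
#'   covariate.
#' @param covariate Name of the covariate column.
#' @return A one-row tibble: `covariate`, `estimate`, `std.error`,
#'   `statistic`, `p.value`, `n_obs`.
#' @examples
#' co <- simulate_cohort(cohort_preset("quebec", n_families = 2000, seed = 4))
#' twinning_correlates(build_analysis_table(co), "mother_age")
#' @export
twinning_correlates <- function(table, covariate) {
  tab <- tibble::as_tibble(table)
  if (!"twin" %in% names(tab)) abort("`table` must contain a `twin` column.")
  if (!covariate %in% names(tab)) {
    abort(sprintf("Covariate `%s` not found in the table.", covariate))
  }
  x <- tab[[covariate]]
  if (var(as.numeric(x), na.rm = TRUE) == 0) {
    abort(sprintf("Covariate `%s` is constant; its twinning correlate is unidentified.", covariate))
  }
  if (sum(tab$twin == 1, na.rm = TRUE) == 0) {
    abort("The table contains no twin deliveries.")
  }
  fit <- lm(tab$twin ~ x)
  sm <- summary(fit)$coefficients
  tibble::tibble(
    covariate = covariate,
    estimate = sm["x", "Estimate"],
    std.error = sm["x", "Std. Error"],
    statistic = sm["x", "t value"],
    p.value = sm["x", "Pr(>|t|)"],
    n_obs = length(fit$residuals)
  )
}

#' Corrupt twin labels to emulate register misclassification
#'
#' Emulates the two baptism-register failure modes that distort historical
#' twin samples.
#' \describe{
#'   \item{`fake`}{Pairs of consecutive singleton deliveries are merged into
#'     one false "twin" delivery (two children with their original,
#'     independent sexes and survival draws) until false pairs make up the
#'     requested fraction of all twin labels — non-twin siblings baptised on
#'     the same day.}
#'   \item{`miss`}{A fraction of true twin deliveries is split into two
#'     singleton deliveries a month apart — twins never recognised as such.}
#' }
#' Total children per family are conserved; only the delivery structure is
#' distorted. False pairs bias the estimated twin effect towards 0 (towards
#' "finding control") and dilute the observed same-sex ratio; missed true
#' twins lower the detection fraction recovered by [same_sex_diagnostic()]
#' (`miss = 0.3` gives `phi_det` near 0.7), while false pairs leave it
#' nearly unchanged because they raise the observed twinning rate in the
#' same proportion as they dilute the same-sex ratio.
#'
#' @param cohort A [twin_cohort()].
#' @param fake Target fraction of final twin labels that are false pairs, in
#'   `[0, 1)`.
#' @param miss Fraction of true twin deliveries to split, in `[0, 1]`.
#' @param seed Optional seed for choosing the affected deliveries.
#' @return A `twin_cohort` with attributes `n_fake` and `n_missed`.
#' @examples
#' co <- simulate_cohort(cohort_preset("quebec", n_families = 500, seed = 21))
#' bad <- corrupt_twin_labels(co, fake = 0.3, seed = 1)
#' attr(bad, "n_fake")
#' @export
corrupt_twin_labels <- function(cohort, fake = 0, miss = 0, seed = NULL) {
  stopifnot(inherits(cohort, "twin_cohort"))
  if (!is.numeric(fake) || length(fake) != 1 || fake < 0 || fake >= 1) {
    abort("`fake` must lie in [0, 1).")
  }
  if (!is.numeric(miss) || length(miss) != 1 || miss < 0 || miss > 1) {
    abort("`miss` must lie in [0, 1].")
  }
  if (!is.null(seed)) set.seed(seed)
  d <- cohort$deliveries |>
    dplyr::arrange(.data$family_id, .data$delivery_index)

  # split missed true twins into two singleton deliveries a month apart
  n_missed <- 0L
  if (miss > 0) {
    twin_rows <- which(d$n_children == 2L)
    n_missed <- round(miss * length(twin_rows))
    if (n_missed > 0) {
      split <- sort(sample(twin_rows, n_missed))
      second <- d[split, , drop = FALSE]
      second$sex_1 <- second$sex_2
      second$survives_1 <- second$survives_2
      second$months_since_marriage <- second$months_since_marriage + 1L
      first_and_rest <- d
      first_and_rest$n_children[split] <- 1L
      second$n_children <- 1L
      second$sex_2 <- NA_character_
      second$survives_2 <- NA
      first_and_rest$sex_2[split] <- NA_character_
      first_and_rest$survives_2[split] <- NA
      d <- dplyr::bind_rows(first_and_rest, second) |>
        dplyr::arrange(.data$family_id, .data$months_since_marriage)
    }
  }

  # merge singleton pairs into false twin labels
  n_true <- sum(d$n_children == 2L)
  n_fake <- round(fake * n_true / (1 - fake))
  if (n_fake > 0) {
    nxt_same_family <- c(d$family_id[-1] == d$family_id[-nrow(d)], FALSE)
    cand <- which(d$n_children == 1L & nxt_same_family &
                    c(d$n_children[-1] == 1L, FALSE))
    chosen <- integer(0)
    blocked <- logical(nrow(d))
    for (i in sample(cand)) {
      if (length(chosen) >= n_fake) break
      if (blocked[i] || blocked[i + 1]) next
      chosen <- c(chosen, i)
      blocked[i] <- TRUE
      blocked[i + 1] <- TRUE
    }
    if (length(chosen) < n_fake) {
      warn(sprintf("Only %d of %d requested false twin pairs could be planted.",
                   length(chosen), n_fake))
    }
    second <- chosen + 1L
    d$n_children[chosen] <- 2L
    d$sex_2[chosen] <- d$sex_1[second]
    d$survives_2[chosen] <- d$survives_1[second]
    if (length(second)) d <- d[-second, , drop = FALSE]
    n_fake <- length(chosen)
  } else {
    n_fake <- 0L
  }

  d <- d |>
    dplyr::group_by(.data$family_id) |>
    dplyr::mutate(delivery_index = dplyr::row_number() - 1L) |>
    dplyr::ungroup()
  out <- twin_cohort(cohort$families, d)
  attr(out, "n_fake") <- n_fake
  attr(out, "n_missed") <- n_missed
  out
}
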