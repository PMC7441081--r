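#' Estimate the twin effect on completed fertility
#'
#' Least-squares estimate of the jump in a family outcome associated with a
#' delivery being a twin pair, controlling for the parity and mother age at
#' which the delivery occurs. Each delivery is one observation. Under natural
#' fertility the coefficient on the twin indicator is 1 for total births and
#' `2*theta_t - theta_s` for survivors; under complete parity-dependent
#' control it is muted towards the values given by
#' [expected_extra_births()] / [expected_extra_survivors()].
#'
#' Two variants are offered. `"parametric"` enters additive indicator blocks
#' for each parity level and each mother-age year (ages pooled into boundary
#' bins below 16 and above 49). `"nonparametric"` enters one indicator per
#' occupied parity-by-age cell, allowing arbitrary interaction; it is fitted
#' by demeaning outcome and twin indicator within cells
#' (Frisch–Waugh–Lovell), which is algebraically the same least-squares
#' problem. Cells with no twin delivery remain in the fixed-effect set; they
#' contribute nothing to the twin coefficient but are harmless.
#'
#' @param table Per-delivery analysis table from [build_analysis_table()].
#' @param outcome `"births"` or `"survivors"`.
#' @param variant `"parametric"` (additive controls) or `"nonparametric"`
#'   (fully interacted parity-by-age cells).
#' @param cluster_se If `TRUE`, report a cluster-robust standard error
#'   grouped by family (families contribute several rows); default is the
#'   conventional OLS standard error.
#' @return A `twin_effect` object: fields `coefficient`, `std_error`,
#'   `n_obs`, `outcome`, `variant`, `nuisance` (named vector of control
#'   coefficients), `residual_scale` and `df_residual`. Supports [tidy()],
#'   [glance()] and `print()`.
#' @examples
#' co <- simulate_cohort(cohort_preset("quebec", n_families = 2000, seed = 11))
#' tab <- build_analysis_table(co)
#' estimate_twin_effect(tab, "births")
#' @export
estimate_twin_effect <- function(table,
                                 outcome = c("births", "survivors"),
                                 variant = c("parametric", "nonparametric"),
                                 cluster_se = FALSE) {
  outcome <- match.arg(outcome)
  variant <- match.arg(variant)
  tab <- check_analysis_table(table)
  check_identified(tab$twin)

  y <- tab[[outcome]]
  if (variant == "parametric") {
    fit_twin_parametric(tab, y, outcome, variant, cluster_se,
                        extra = NULL)
  } else {
    fit_twin_cells(tab, y, outcome, cluster_se)
  }
}

#' Test whether the twin effect grows with parity
#'
#' Adds a twin-by-parity interaction to the parametric twin regression. Under
#' natural fertility the expected jump from a twin birth is the same at every
#' parity, so the interaction slope is 0; if families hold surviving-children
#' targets, twins at higher parities are more likely to fall at (or beyond)
#' the last planned birth and the slope is positive.
#'
#' @inheritParams estimate_twin_effect
#' @return A `twin_interaction` object holding two `twin_effect`s: `alpha`
#'   (twin main effect at parity 0) and `lambda` (slope per parity).
#' @examples
#' co <- simulate_cohort(cohort_preset("quebec", n_families = 2000, seed = 11))
#' estimate_parity_interaction(build_analysis_table(co), "births")
#' @export
estimate_parity_interaction <- function(table,
                                        outcome = c("births", "survivors"),
                                        cluster_se = FALSE) {
  outcome <- match.arg(outcome)
  tab <- check_analysis_table(table)
  check_identified(tab$twin)
  if (length(unique(tab$parity[tab$twin == 1])) < 2) {
    unidentified("the twin-by-parity slope needs twin deliveries at two or more parities")
  }
  y <- tab[[outcome]]
  fit_twin_parametric(tab, y, outcome, "parity_interaction", cluster_se,
                      extra = "twin_parity")
}

#' Estimate the post-twin birth-interval response
#'
#' Regresses the interval to the family's next delivery (months) on the twin
#' indicator with parity and mother-age controls, over deliveries that have a
#' following delivery. A positive coefficient means couples spaced longer
#' after a twin delivery than after a singleton at the same parity and mother
#' age — a spacing response to twinning. Under natural fertility the
#' coefficient is 0.
#'
#' @inheritParams estimate_twin_effect
#' @return A `twin_effect` with `outcome = "interval"` (months).
#' @examples
#' co <- simulate_cohort(cohort_preset("quebec", n_families = 2000, seed = 11))
#' estimate_post_twin_interval(build_analysis_table(co))
#' @export
estimate_post_twin_interval <- function(table, cluster_se = FALSE) {
  tab <- check_analysis_table(table, need_interval = TRUE)
  tab <- tab[!is.na(tab$next_interval_months), , drop = FALSE]
  if (nrow(tab) == 0) {
    unidentified("no deliveries with a recorded next interval")
  }
  check_identified(tab$twin,
                   what = "the post-twin interval effect needs both twin and singleton deliveries followed by another delivery")
  fit_twin_parametric(tab, tab$next_interval_months, "interval",
                      "parametric", cluster_se, extra = NULL)
}

#' Mean outcome by parity for twin versus singleton deliveries
#'
#' For each parity at which at least one twin delivery occurs, the mean
#' outcome among twin deliveries and among singleton deliveries, with counts
#' and the twin-singleton gap. Under natural fertility the births gap is flat
#' in parity at about 1.
#'
#' @inheritParams estimate_twin_effect
#' @return A tibble of class `twin_parity_profile` with columns `parity`,
#'   `n_twin`, `n_singleton`, `mean_twin`, `mean_singleton`, `gap`.
#'   [autoplot()] draws the profile.
#' @export
parity_profile <- function(table, outcome = c("births", "survivors")) {
  outcome <- match.arg(outcome)
  tab <- check_analysis_table(table)
  y <- tab[[outcome]]
  prof <- tab |>
    dplyr::mutate(.y = y) |>
    dplyr::group_by(.data$parity) |>
    dplyr::summarise(
      n_twin = sum(.data$twin == 1),
      n_singleton = sum(.data$twin == 0),
      mean_twin = mean(.data$.y[.data$twin == 1]),
      mean_singleton = mean(.data$.y[.data$twin == 0]),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_twin > 0) |>
    dplyr::mutate(gap = .data$mean_twin - .data$mean_singleton)
  attr(prof, "outcome") <- outcome
  class(prof) <- c("twin_parity_profile", class(prof))
  prof
}

# ---- internals ---------------------------------------------------------

#' Pool mother ages into single-year bins with boundary pooling
#'
#' Ages below 16 are pooled into the 16 bin and ages above 49 into the 49
#' bin, so extreme ages do not create single-observation indicator cells.
#' @param age Integer vector of mother ages.
#' @return Integer vector of pooled ages.
#' @keywords internal
#' @export
pool_mother_age <- function(age) {
  pmin(49L, pmax(16L, as.integer(age)))
}

check_analysis_table <- function(table, need_interval = FALSE) {
  tab <- tibble::as_tibble(table)
  need <- c("family_id", "twin", "parity", "mother_age", "births", "survivors")
  if (need_interval) need <- c(need, "next_interval_months")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    abort(paste0("Analysis table is missing columns: ",
                 paste(miss, collapse = ", "),
                 ". Use build_analysis_table()."))
  }
  if (nrow(tab) == 0) abort("Analysis table is empty.")
  if (!all(tab$twin %in% c(0L, 1L))) abort("`twin` must be 0/1.")
  tab
}

unidentified <- function(detail) {
  abort(paste0("Twin effect unidentified: ", detail, "."),
        class = "twinstest_unidentified")
}

check_identified <- function(twin, what = NULL) {
  if (all(twin == 0)) {
    unidentified(what %||% "the table contains no twin deliveries")
  }
  if (all(twin == 1)) {
    unidentified(what %||% "the table contains no singleton deliveries")
  }
  invisible(NULL)
}

new_twin_effect <- function(coefficient, std_error, n_obs, outcome, variant,
                            nuisance, residual_scale, df_residual,
                            clustered = FALSE) {
  structure(list(coefficient = coefficient, std_error = std_error,
                 n_obs = n_obs, outcome = outcome, variant = variant,
                 nuisance = nuisance, residual_scale = residual_scale,
                 df_residual = df_residual, clustered = clustered),
            class = "twin_effect")
}

# Parametric fit via lm(): y ~ twin [+ twin:parity] + parity dummies + age
# dummies. Returns twin_effect or twin_interaction (when extra is set).
fit_twin_parametric <- function(tab, y, outcome, variant, cluster_se, extra) {
  dat <- data.frame(
    y = y,
    twin = tab$twin,
    parity_f = factor(tab$parity),
    age_f = factor(pool_mother_age(tab$mother_age))
  )
  form <- y ~ twin + parity_f + age_f
  if (identical(extra, "twin_parity")) {
    dat$twin_parity <- tab$twin * tab$parity
    form <- y ~ twin + twin_parity + parity_f + age_f
  }
  fit <- lm(form, data = dat)
  cf <- coef(fit)
  want <- if (identical(extra, "twin_parity")) c("twin", "twin_parity") else "twin"
  if (anyNA(cf[want])) {
    unidentified("the twin regressor is collinear with the parity/mother-age indicators")
  }
  vc <- if (cluster_se) {
    sandwich::vcovCL(fit, cluster = tab$family_id)
  } else {
    vcov_ols(fit)  # conventional OLS vcov straight from the QR factors
  }
  rdf <- fit$df.residual
  sigma <- sqrt(sum(fit$residuals^2) / max(1, rdf))
  nuisance <- cf[setdiff(names(cf), want)]
  nuisance <- nuisance[!is.na(nuisance)]
  mk <- function(term) {
    new_twin_effect(unname(cf[term]), sqrt(vc[term, term]), nrow(dat),
                    outcome, variant, nuisance, sigma, rdf,
                    clustered = cluster_se)
  }
  if (identical(extra, "twin_parity")) {
    structure(list(alpha = mk("twin"), lambda = mk("twin_parity"),
                   outcome = outcome),
              class = "twin_interaction")
  } else {
    mk("twin")
  }
}

vcov_ols <- function(fit) {
  p <- fit$rank
  piv <- fit$qr$pivot[seq_len(p)]
  rinv <- chol2inv(qr.R(fit$qr)[seq_len(p), seq_len(p), drop = FALSE])
  s2 <- sum(fit$residuals^2) / fit$df.residual
  vc <- s2 * rinv
  nm <- colnames(fit$qr$qr)[seq_len(p)]
  dimnames(vc) <- list(nm, nm)
  vc
}

# Fully interacted fit by within-cell demeaning (FWL). Same least-squares
# problem as one indicator per occupied parity-by-age cell plus the twin
# regressor.
fit_twin_cells <- function(tab, y, outcome, cluster_se) {
  cell <- interaction(tab$parity, pool_mother_age(tab$mother_age), drop = TRUE)
  d <- tab$twin
  y_t <- y - ave(y, cell)
  d_t <- d - ave(d, cell)
  denom <- sum(d_t^2)
  if (denom <= .Machine$double.eps * length(d)) {
    unidentified("no parity-by-age cell contains both a twin and a singleton delivery")
  }
  alpha <- sum(d_t * y_t) / denom
  resid <- y_t - alpha * d_t
  n <- length(y)
  k <- nlevels(cell) + 1L
  rdf <- n - k
  if (rdf < 1) unidentified("more coefficients than observations")
  sigma2 <- sum(resid^2) / rdf
  se <- if (cluster_se) {
    cl <- tab$family_id
    scores <- rowsum(d_t * resid, cl)
    g <- nrow(scores)
    adj <- g / (g - 1) * (n - 1) / rdf
    sqrt(adj * sum(scores^2)) / denom
  } else {
    sqrt(sigma2 / denom)
  }
  cell_means_y <- tapply(y, cell, mean)
  cell_means_d <- tapply(d, cell, mean)
  nuisance <- setNames(as.numeric(cell_means_y - alpha * cell_means_d),
                       paste0("cell_", names(cell_means_y)))
  new_twin_effect(alpha, se, n, outcome, "nonparametric", nuisance,
                  sqrt(sigma2), rdf, clustered = cluster_se)
}

# ---- methods -----------------------------------------------------------

#' @export
print.twin_effect <- function(x, ...) {
  label <- switch(x$outcome,
                  births = "extra total births per twin delivery",
                  survivors = "extra children surviving to 14 per twin delivery",
                  interval = "post-twin change in next birth interval (months)")
  cat(sprintf("<twin_effect> %s (%s)\n", label, x$variant))
  cat(sprintf("  coefficient %.4f  (%sSE %.4f)  n = %d\n",
              x$coefficient, if (x$clustered) "cluster " else "", x$std_error,
              x$n_obs))
  invisible(x)
}

#' @export
print.twin_interaction <- function(x, ...) {
  cat(sprintf("<twin_interaction> outcome: %s\n", x$outcome))
  cat(sprintf("  alpha  (twin main effect)   %.4f (SE %.4f)\n",
              x$alpha$coefficient, x$alpha$std_error))
  cat(sprintf("  lambda (slope per parity)   %.4f (SE %.4f)  n = %d\n",
              x$lambda$coefficient, x$lambda$std_error, x$lambda$n_obs))
  invisible(x)
}

#' Tidy a twin-effect fit
#'
#' @param x A `twin_effect` or `twin_interaction`.
#' @param ... Unused.
#' @return A tibble with one row per reported coefficient: `term`,
#'   `estimate`, `std.error`, `statistic`, `p.value`.
#' @method tidy twin_effect
#' @export
tidy.twin_effect <- function(x, ...) {
  z <- x$coefficient / x$std_error
  tibble::tibble(
    term = "twin",
    estimate = x$coefficient,
    std.error = x$std_error,
    statistic = z,
    p.value = 2 * pnorm(-abs(z))
  )
}

#' @rdname tidy.twin_effect
#' @method tidy twin_interaction
#' @export
tidy.twin_interaction <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(x$alpha), term = "twin"),
    dplyr::mutate(tidy(x$lambda), term = "twin:parity")
  )
}

#' Glance at a twin-effect fit
#'
#' @param x A `twin_effect`.
#' @param ... Unused.
#' @return A one-row tibble: `n_obs`, `outcome`, `variant`,
#'   `residual_scale`, `df_residual`, `clustered`.
#' @method glance twin_effect
#' @export
glance.twin_effect <- function(x, ...) {
  tibble::tibble(
    n_obs = x$n_obs,
    outcome = x$outcome,
    variant = x$variant,
    residual_scale = x$residual_scale,
    df_residual = x$df_residual,
    clustered = x$clustered
  )
}
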