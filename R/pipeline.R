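#' Configure an end-to-end pipeline run
#'
#' @param input Path to a cohort CSV (see [read_cohort_csv()]). Exactly one
#'   of `input` and `preset` must be given.
#' @param preset Name of a simulation preset (see [cohort_preset()]).
#' @param n_families Families to simulate when `preset` is used.
#' @param controller_fraction Controller share for simulated cohorts.
#' @param filters A [filter_policy()], or `NULL` to skip filtering.
#' @param estimators Character subset of
#'   `c("births", "survivors", "interaction", "interval")`.
#' @param variant Regression variant for the main twin effects.
#' @param theory `"from-data"` (estimate `theta_s`, `theta_t`, `phi` from the
#'   analysed cohort) or a [theory_params()] override.
#' @param confidence Confidence level for controller-share bounds.
#' @param output_dir Directory for the report bundle, or `NULL` to return
#'   results without writing.
#' @param seed Integer seed controlling simulation and Monte-Carlo stages.
#' @return A list of class `run_config`.
#' @export
run_config <- function(input = NULL, preset = NULL,
                       n_families = 50000, controller_fraction = 0,
                       filters = filter_policy(),
                       estimators = c("births", "survivors", "interaction",
                                      "interval"),
                       variant = c("parametric", "nonparametric"),
                       theory = "from-data",
                       confidence = 0.95,
                       output_dir = NULL,
                       seed = 1) {
  if (is.null(input) == is.null(preset)) {
    abort("Give exactly one of `input` (a cohort CSV) or `preset` (a simulation preset).")
  }
  variant <- match.arg(variant)
  bad <- setdiff(estimators, c("births", "survivors", "interaction", "interval"))
  if (length(bad)) {
    abort(paste0("Unknown estimator selection: ", paste(bad, collapse = ", ")))
  }
  if (!identical(theory, "from-data") && !inherits(theory, "theory_params")) {
    abort('`theory` must be "from-data" or a theory_params object.')
  }
  structure(list(input = input, preset = preset, n_families = n_families,
                 controller_fraction = controller_fraction,
                 filters = filters, estimators = estimators,
                 variant = variant, theory = theory,
                 confidence = confidence, output_dir = output_dir,
                 seed = seed),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)),
          class = "twinstest_stage_error", parent = e)
  })
}

#' Run the full twins-test pipeline
#'
#' Simulates or loads a cohort, applies sample filters, builds the
#' per-delivery analysis table, estimates the selected twin effects,
#' compares them with the closed-form no-control / complete-control
#' expectations, bounds the controller share, runs data-quality diagnostics,
#' and renders a Markdown report. With `output_dir` set, writes
#' `analysis_table.csv`, `estimates.json`, `theory_comparison.csv`,
#' `diagnostics.json`, `parity_profile.csv` and `report.md`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list of class `twin_report` with elements `cohort`,
#'   `table`, `estimates`, `theory`, `diagnostics`, `profile`, `report`
#'   (Markdown text) and `config`.
#' @examples
#' res <- run_pipeline(run_config(preset = "quebec", n_families = 500,
#'                                seed = 3, estimators = "births"))
#' res$estimates$births
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))

  cohort <- if (!is.null(config$preset)) {
    stage("simulate", {
      cfg <- cohort_preset(config$preset, n_families = config$n_families,
                           seed = config$seed,
                           controller_fraction = config$controller_fraction)
      simulate_cohort(cfg)
    })
  } else {
    stage("load", read_cohort_csv(config$input))
  }

  filtered <- stage("filter", {
    out <- if (is.null(config$filters)) cohort else
      apply_filters(cohort, config$filters)
    if (nrow(out$families) == 0) {
      abort("no families remain after the sample-inclusion filters")
    }
    out
  })

  tab <- stage("analysis_table", {
    tt <- build_analysis_table(filtered)
    if (nrow(tt) == 0) abort("the filtered cohort contains no deliveries")
    tt
  })

  est <- stage("estimate", {
    out <- list()
    if ("births" %in% config$estimators) {
      out$births <- estimate_twin_effect(tab, "births", config$variant)
    }
    if ("survivors" %in% config$estimators) {
      out$survivors <- estimate_twin_effect(tab, "survivors", config$variant)
    }
    if ("interaction" %in% config$estimators) {
      out$interaction_births <- estimate_parity_interaction(tab, "births")
      out$interaction_survivors <- estimate_parity_interaction(tab, "survivors")
    }
    if ("interval" %in% config$estimators) {
      out$interval <- estimate_post_twin_interval(tab)
    }
    out
  })

  theory <- stage("theory", {
    params <- if (identical(config$theory, "from-data")) {
      cohort_theory_params(filtered)
    } else {
      config$theory
    }
    expected <- list(
      births_nc = expected_extra_births(params, "no_control"),
      births_c = expected_extra_births(params, "full_control"),
      survivors_nc = expected_extra_survivors(params, "no_control"),
      survivors_c = expected_extra_survivors(params, "full_control")
    )
    bounds <- list()
    for (oc in c("births", "survivors")) {
      e <- est[[oc]]
      if (!is.null(e)) {
        bounds[[oc]] <- controller_share_bound(
          e$coefficient, e$std_error,
          alpha_nc = expected[[paste0(oc, "_nc")]],
          alpha_c = expected[[paste0(oc, "_c")]],
          confidence = config$confidence)
      }
    }
    list(params = params, expected = expected, bounds = bounds)
  })

  diagnostics <- stage("diagnose", {
    per_fam <- as.integer(table(tab$family_id))
    twin_rate <- mean(tab$twin)
    list(
      same_sex = same_sex_diagnostic(filtered),
      repetition = familial_repetition(per_fam, twin_rate, n_reps = 2000,
                                       seed = config$seed),
      observed_repeats = sum(tapply(tab$twin, tab$family_id, sum) >= 2),
      correlates = dplyr::bind_rows(
        twinning_correlates(tab, "mother_age"),
        twinning_correlates(tab, "parity"))
    )
  })

  profile <- stage("profile", parity_profile(tab, "births"))

  report <- stage("report", make_report(est, theory, diagnostics))

  out <- structure(
    list(cohort = filtered, table = tab, estimates = est, theory = theory,
         diagnostics = diagnostics, profile = profile, report = report,
         config = config),
    class = "twin_report")

  if (!is.null(config$output_dir)) {
    stage("write", write_report_bundle(out, config$output_dir))
  }
  invisible(out)
}

write_report_bundle <- function(res, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(res$table, file.path(dir, "analysis_table.csv"))
  readr::write_csv(tibble::as_tibble(res$profile),
                   file.path(dir, "parity_profile.csv"))

  est_json <- purrr::map(res$estimates, function(e) {
    if (inherits(e, "twin_interaction")) {
      list(alpha = est_summary(e$alpha), lambda = est_summary(e$lambda))
    } else {
      est_summary(e)
    }
  })
  jsonlite::write_json(est_json, file.path(dir, "estimates.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  th <- res$theory
  cmp <- tibble::tibble(
    outcome = c("births", "survivors"),
    estimate = vapply(c("births", "survivors"), function(oc) {
      e <- res$estimates[[oc]]; if (is.null(e)) NA_real_ else e$coefficient
    }, numeric(1)),
    std_error = vapply(c("births", "survivors"), function(oc) {
      e <- res$estimates[[oc]]; if (is.null(e)) NA_real_ else e$std_error
    }, numeric(1)),
    expected_no_control = c(th$expected$births_nc, th$expected$survivors_nc),
    expected_full_control = c(th$expected$births_c, th$expected$survivors_c),
    share_upper_bound = vapply(c("births", "survivors"), function(oc) {
      b <- th$bounds[[oc]]; if (is.null(b)) NA_real_ else b$upper
    }, numeric(1))
  )
  readr::write_csv(cmp, file.path(dir, "theory_comparison.csv"))

  dg <- res$diagnostics
  jsonlite::write_json(
    list(
      same_sex = unclass(dg$same_sex),
      familial_repetition = unclass(dg$repetition),
      observed_repeat_twin_families = dg$observed_repeats,
      twinning_correlates = dg$correlates
    ),
    file.path(dir, "diagnostics.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows")

  writeLines(res$report, file.path(dir, "report.md"))
  invisible(dir)
}

est_summary <- function(e) {
  list(coefficient = e$coefficient, se = e$std_error, n = e$n_obs,
       variant = e$variant, outcome = e$outcome)
}

#' Render the Markdown summary report
#'
#' Produces a human-readable document with three tables: twin effects on
#' total births, twin effects on surviving children (each against the
#' no-control and complete-control expectations), and controller-share
#' confidence intervals. Estimates that were not computed are shown as
#' "not computed". Numbers are printed to 2 decimal places.
#'
#' @param estimates Named list of fits as produced by [run_pipeline()]
#'   (`births`, `survivors`, `interaction_*`, `interval`; any may be absent).
#' @param theory List with `params`, `expected`, `bounds` as produced by
#'   [run_pipeline()].
#' @param diagnostics List with `same_sex`, `repetition`, `correlates` as
#'   produced by [run_pipeline()].
#' @return A character vector of Markdown lines.
#' @export
make_report <- function(estimates, theory, diagnostics) {
  f2 <- function(x) ifelse(is.na(x), "--", sprintf("%.2f", x))
  nc <- "not computed"

  effect_row <- function(e, enc, ec) {
    if (is.null(e)) {
      sprintf("| %s | %s | %s | %s | %s |", nc, nc, f2(enc), f2(ec), nc)
    } else {
      sprintf("| %s | %s | %s | %s | %d |",
              f2(e$coefficient), f2(e$std_error), f2(enc), f2(ec), e$n_obs)
    }
  }
  lines <- c(
    "# Twin-birth test of parity-dependent fertility control", "",
    sprintf("Theory parameters: theta_s = %s, theta_t = %s, phi = %s (mean births %s).",
            f2(theory$params$theta_s), f2(theory$params$theta_t),
            f2(theory$params$phi), f2(theory$params$mean_births)), "",
    "## Twin effect on total births", "",
    "| Estimate | SE | Expected, no control | Expected, control | N |",
    "|---|---|---|---|---|",
    effect_row(estimates$births, theory$expected$births_nc,
               theory$expected$births_c), "",
    "## Twin effect on surviving children", "",
    "| Estimate | SE | Expected, no control | Expected, control | N |",
    "|---|---|---|---|---|",
    effect_row(estimates$survivors, theory$expected$survivors_nc,
               theory$expected$survivors_c), "",
    "## Controller-share confidence intervals", "",
    "| Outcome | Point share | Interval |",
    "|---|---|---|"
  )
  for (oc in c("births", "survivors")) {
    b <- theory$bounds[[oc]]
    lines <- c(lines, if (is.null(b)) {
      sprintf("| %s | %s | %s |", oc, nc, nc)
    } else {
      sprintf("| %s | %s | [%s, %s] (%.0f%%, %s) |", oc, f2(b$point),
              f2(b$lower), f2(b$upper), 100 * b$confidence,
              gsub("_", "-", b$side))
    })
  }
  lines <- c(lines, "")
  if (!is.null(estimates$interaction_births)) {
    ib <- estimates$interaction_births
    lines <- c(lines, sprintf(
      "Twin-by-parity slope (births): %s (SE %s) -- flat under natural fertility.",
      f2(ib$lambda$coefficient), f2(ib$lambda$std_error)), "")
  }
  if (!is.null(estimates$interval)) {
    iv <- estimates$interval
    lines <- c(lines, sprintf(
      "Post-twin change in next birth interval: %s months (SE %s).",
      f2(iv$coefficient), f2(iv$std_error)), "")
  }
  if (!is.null(diagnostics$same_sex)) {
    ss <- diagnostics$same_sex
    lines <- c(lines, sprintf(
      "Data quality: twinning rate %s per 100 births; same-sex ratio observed %s vs expected %s (implied detection fraction %s).",
      f2(ss$r_t), f2(ss$r_ss_observed), f2(ss$r_ss_expected), f2(ss$phi_det)),
      "")
  }
  lines
}

#' @export
print.twin_report <- function(x, ...) {
  cat(x$report, sep = "\n")
  invisible(x)
}
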