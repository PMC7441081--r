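#' Plot a parity profile of twin versus singleton deliveries
#'
#' Mean outcome by parity for twin and singleton deliveries. Under natural
#' fertility the two lines run parallel (a constant gap of about 1 for total
#' births); converging lines at high parity indicate parity-dependent
#' control.
#'
#' @param object A `twin_parity_profile` from [parity_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot twin_parity_profile
#' @export
autoplot.twin_parity_profile <- function(object, ...) {
  outcome <- attr(object, "outcome") %||% "births"
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("mean_twin", "mean_singleton"),
                        names_to = "delivery", values_to = "mean_outcome") |>
    dplyr::mutate(delivery = dplyr::recode(.data$delivery,
                                           mean_twin = "twin",
                                           mean_singleton = "singleton"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$parity, y = .data$mean_outcome,
                                     colour = .data$delivery,
                                     shape = .data$delivery)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "parity at delivery",
                  y = paste("mean", outcome, "per family"),
                  colour = NULL, shape = NULL,
                  title = "Completed fertility by parity at delivery") +
    ggplot2::theme_minimal()
}

#' Plot estimated twin effects against the two theoretical poles
#'
#' Point estimates with 95% intervals for the twin effect on births and
#' survivors, with the expected values under no control and complete control
#' marked, mirroring how the estimates are read against theory.
#'
#' @param object A `twin_report` from [run_pipeline()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot twin_report
#' @export
autoplot.twin_report <- function(object, ...) {
  rows <- purrr::compact(list(
    births = object$estimates$births,
    survivors = object$estimates$survivors))
  if (!length(rows)) {
    abort("The run contains no births/survivors estimates to plot.")
  }
  df <- purrr::imap_dfr(rows, function(e, oc) {
    tibble::tibble(
      outcome = oc,
      estimate = e$coefficient,
      lo = e$coefficient - 1.96 * e$std_error,
      hi = e$coefficient + 1.96 * e$std_error,
      no_control = object$theory$expected[[paste0(oc, "_nc")]],
      full_control = object$theory$expected[[paste0(oc, "_c")]])
  })
  theory_long <- tidyr::pivot_longer(df, c("no_control", "full_control"),
                                     names_to = "regime", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$outcome)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$estimate), size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                           width = 0.1) +
    ggplot2::geom_point(data = theory_long,
                        ggplot2::aes(y = .data$value, colour = .data$regime),
                        shape = 4, size = 3, stroke = 1.2) +
    ggplot2::labs(x = NULL, y = "twin effect",
                  colour = "expected under",
                  title = "Estimated twin effects vs theoretical poles") +
    ggplot2::theme_minimal()
}
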