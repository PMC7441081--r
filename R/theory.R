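#' Theory parameters for expected twin effects
#'
#' The closed-form expected effects of a twin birth depend on three
#' population quantities: the singleton survival-to-14 probability
#' `theta_s`, the per-child twin survival probability `theta_t`, and the
#' last-birth fraction `phi` — the share of births that are the family's last
#' planned birth, approximated by the reciprocal of mean completed births.
#'
#' @param theta_s,theta_t Survival-to-14 probabilities for singleton and twin
#'   children.
#' @param mean_births Mean births per family among families with at least one
#'   birth (>= 1). When given, `phi` defaults to `1 / mean_births`.
#' @param phi Last-birth fraction in (0, 1]; may be given directly.
#' @return A list of class `theory_params` with fields `theta_s`, `theta_t`,
#'   `phi`, `mean_births`.
#' @examples
#' theory_params(theta_s = 0.65, theta_t = 0.55, mean_births = 5.9)
#' @export
theory_params <- function(theta_s, theta_t, mean_births = NULL, phi = NULL) {
  for (nm in c("theta_s", "theta_t")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      abort(sprintf("`%s` must be a probability in [0, 1].", nm))
    }
  }
  if (is.null(phi)) {
    if (is.null(mean_births)) {
      abort("Provide either `mean_births` or `phi`.")
    }
    phi <- last_birth_fraction(mean_births)
  } else {
    if (!is.numeric(phi) || length(phi) != 1 || is.na(phi) || phi <= 0 || phi > 1) {
      abort("`phi` must lie in (0, 1].")
    }
    if (!is.null(mean_births) && abs(phi - 1 / mean_births) > 1e-8) {
      abort("`phi` must equal 1 / mean_births when both are given.")
    }
  }
  structure(list(theta_s = theta_s, theta_t = theta_t, phi = phi,
                 mean_births = mean_births %||% (1 / phi)),
            class = "theory_params")
}

#' @export
print.theory_params <- function(x, ...) {
  cat(sprintf("<theory_params> theta_s = %.3f, theta_t = %.3f, phi = %.3f (mean births %.2f)\n",
              x$theta_s, x$theta_t, x$phi, x$mean_births))
  invisible(x)
}

#' Last-birth fraction from mean family size
#'
#' Every completed family has exactly one last birth, so the fraction of all
#' births that are last births is the reciprocal of mean births per family.
#'
#' @param mean_births Mean births per family with at least one birth (>= 1).
#' @return `1 / mean_births`.
#' @examples
#' last_birth_fraction(5.9) # ~0.17
#' @export
last_birth_fraction <- function(mean_births) {
  if (!is.numeric(mean_births) || length(mean_births) != 1 ||
      is.na(mean_births) || mean_births < 1) {
    abort("`mean_births` must be a single number >= 1.")
  }
  1 / mean_births
}

#' Expected extra total births from a twin birth
#'
#' Under no parity-dependent control a twin birth adds exactly 1 to expected
#' total births. Under complete control (every family has a surviving-children
#' target), a twin not at the last planned birth adds `2(1 - theta_t/theta_s)`
#' births (the extra twin substitutes for later births needed to reach the
#' target), while a twin at the last planned birth — probability `phi` — adds
#' exactly 1. The average is `2(1 - theta_t/theta_s)(1 - phi) + phi`.
#'
#' @param params A [theory_params()].
#' @param regime `"no_control"` or `"full_control"`.
#' @return Expected extra births (a single number).
#' @examples
#' p <- theory_params(theta_s = 0.65, theta_t = 0.55, phi = 0.17)
#' expected_extra_births(p, "no_control")   # 1
#' expected_extra_births(p, "full_control") # ~0.43
#' @export
expected_extra_births <- function(params, regime = c("no_control", "full_control")) {
  stopifnot(inherits(params, "theory_params"))
  regime <- match.arg(regime)
  if (regime == "no_control") return(1)
  if (params$theta_s <= 0) {
    abort("`theta_s` must be positive under full control (births needed to reach a surviving target are N / theta_s).")
  }
  2 * (1 - params$theta_t / params$theta_s) * (1 - params$phi) + params$phi
}

#' Expected extra children surviving to 14 from a twin birth
#'
#' Under no control the twin delivery replaces a singleton, so survivors rise
#' by `2 theta_t - theta_s` (possibly negative when twin mortality is more
#' than twice singleton mortality). Under complete control the gain survives
#' only when the twin was the last planned birth: `phi (2 theta_t - theta_s)`.
#'
#' @inheritParams expected_extra_births
#' @return Expected extra surviving children.
#' @examples
#' p <- theory_params(theta_s = 0.65, theta_t = 0.55, phi = 0.17)
#' expected_extra_survivors(p, "no_control")   # 0.45
#' expected_extra_survivors(p, "full_control") # ~0.08
#' @export
expected_extra_survivors <- function(params, regime = c("no_control", "full_control")) {
  stopifnot(inherits(params, "theory_params"))
  regime <- match.arg(regime)
  base <- 2 * params$theta_t - params$theta_s
  if (regime == "no_control") base else params$phi * base
}

#' Expected twin effects for one or more parameter sets
#'
#' Convenience tabulation of the four closed-form expected effects for each
#' supplied parameter set — the layout used to compare estimated twin effects
#' with the no-control and complete-control poles.
#'
#' @param params A `theory_params` or a named list of them.
#' @return A tibble with one row per parameter set and columns
#'   `births_no_control`, `births_full_control`, `survivors_no_control`,
#'   `survivors_full_control`.
#' @examples
#' expected_effects_table(list(
#'   england = theory_params(0.65, 0.55, mean_births = 5.96),
#'   quebec  = theory_params(0.71, 0.52, mean_births = 5.64)))
#' @export
expected_effects_table <- function(params) {
  if (inherits(params, "theory_params")) params <- list(params)
  if (is.null(names(params))) names(params) <- paste0("set", seq_along(params))
  purrr::imap_dfr(params, function(p, nm) {
    tibble::tibble(
      population = nm,
      theta_s = p$theta_s, theta_t = p$theta_t, phi = p$phi,
      births_no_control = expected_extra_births(p, "no_control"),
      births_full_control = expected_extra_births(p, "full_control"),
      survivors_no_control = expected_extra_survivors(p, "no_control"),
      survivors_full_control = expected_extra_survivors(p, "full_control")
    )
  })
}
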