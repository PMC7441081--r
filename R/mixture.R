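#' Bound the population share of fertility controllers
#'
#' In a population that mixes a fraction `p` of controllers (families with a
#' surviving-children target) with `1 - p` natural-fertility families, the
#' expected twin-effect coefficient is the linear mixture
#' `alpha(p) = (1 - p) alpha_nc + p alpha_c`, where `alpha_nc` and `alpha_c`
#' are the regime-specific expected effects (see [expected_extra_births()]).
#' Treating the estimate `alpha_hat` as normal with standard error `se`, the
#' point share is `(alpha_nc - alpha_hat) / (alpha_nc - alpha_c)` and a
#' one-sided upper confidence bound at level `confidence` is obtained by
#' sliding `alpha_hat` down by `z * se` before inverting — a
#' normal-approximation linear-mixture bound. Shares are truncated to
#' `[0, 1]` after computation.
#'
#' @param alpha_hat Estimated twin-effect coefficient.
#' @param se Its standard error (>= 0).
#' @param alpha_nc,alpha_c Expected coefficient under no control and complete
#'   control (must differ).
#' @param confidence Confidence level (default 0.95).
#' @param side `"one_sided_upper"` (default, reported as `[0, upper]`) or
#'   `"two_sided"`.
#' @return A list of class `mixture_interval` with fields `point`, `lower`,
#'   `upper`, `confidence`, `side`.
#' @examples
#' # precise estimate right at the natural-fertility pole
#' controller_share_bound(1.03, 0.05, alpha_nc = 1, alpha_c = 0.61)
#' @export
controller_share_bound <- function(alpha_hat, se, alpha_nc, alpha_c,
                                   confidence = 0.95,
                                   side = c("one_sided_upper", "two_sided")) {
  side <- match.arg(side)
  check_mixture_args(alpha_hat, se, alpha_nc, alpha_c)
  if (!is.numeric(confidence) || length(confidence) != 1 ||
      confidence <= 0 || confidence >= 1) {
    abort("`confidence` must lie in (0, 1).")
  }
  delta <- alpha_nc - alpha_c
  clamp <- function(x) pmin(1, pmax(0, x))
  point <- clamp((alpha_nc - alpha_hat) / delta)
  if (side == "one_sided_upper") {
    z <- qnorm(confidence)
    lower <- 0
    upper <- clamp((alpha_nc - (alpha_hat - z * se)) / delta)
  } else {
    z <- qnorm(1 - (1 - confidence) / 2)
    lower <- clamp((alpha_nc - (alpha_hat + z * se)) / delta)
    upper <- clamp((alpha_nc - (alpha_hat - z * se)) / delta)
  }
  structure(list(point = point, lower = lower, upper = upper,
                 confidence = confidence, side = side),
            class = "mixture_interval")
}

#' @export
print.mixture_interval <- function(x, ...) {
  cat(sprintf("<mixture_interval> share of controllers: point %.3f, %s %.0f%% interval [%.3f, %.3f]\n",
              x$point, gsub("_", "-", x$side), 100 * x$confidence,
              x$lower, x$upper))
  invisible(x)
}

#' Probability that the controller share is below a threshold
#'
#' Normal-approximation probability that the true controller share is below
#' `threshold`, treating `alpha_hat` as normally distributed around the true
#' mixture coefficient with standard error `se` (a flat prior on the share,
#' without truncation). A share below `threshold` corresponds to a true
#' coefficient above `alpha_nc - threshold * (alpha_nc - alpha_c)`.
#'
#' @inheritParams controller_share_bound
#' @param threshold Share threshold in `[0, 1]`.
#' @return A probability.
#' @examples
#' # how sure can we be that under 10% of families had targets?
#' controller_share_probability(1.02, 0.07, alpha_nc = 1, alpha_c = 0.73,
#'                              threshold = 0.10)
#' @export
controller_share_probability <- function(alpha_hat, se, alpha_nc, alpha_c,
                                         threshold) {
  check_mixture_args(alpha_hat, se, alpha_nc, alpha_c)
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      is.na(threshold) || threshold < 0 || threshold > 1) {
    abort("`threshold` must lie in [0, 1].")
  }
  if (threshold >= 1) return(1)  # a share cannot exceed 1
  delta <- alpha_nc - alpha_c
  if (se == 0) {
    point <- (alpha_nc - alpha_hat) / delta
    return(as.numeric(point < threshold) * 1)
  }
  pnorm((alpha_hat - (alpha_nc - threshold * delta)) / se)
}

check_mixture_args <- function(alpha_hat, se, alpha_nc, alpha_c) {
  for (nm in c("alpha_hat", "se", "alpha_nc", "alpha_c")) {
    v <- get(nm, envir = parent.frame())
    if (!is.numeric(v) || length(v) != 1 || is.na(v)) {
      abort(sprintf("`%s` must be a single number.", nm))
    }
  }
  if (get("se", envir = parent.frame()) < 0) abort("`se` must be >= 0.")
  if (get("alpha_nc", envir = parent.frame()) ==
      get("alpha_c", envir = parent.frame())) {
    abort("`alpha_nc` and `alpha_c` must differ: the mixture is degenerate when the two regimes predict the same coefficient.")
  }
  invisible(NULL)
}
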