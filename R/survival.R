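# Probability/rate conversions, Weibull relapse hazards with relative-risk
# adjustment, and least-squares Weibull fitting to survival points.

#' Annual/monthly probability conversion
#'
#' Converts between annual and monthly probabilities on the constant-rate
#' scale: `annual_to_monthly_prob(p) = 1 - (1 - p)^(1/12)` and its exact
#' inverse `monthly_to_annual_prob(p) = 1 - (1 - p)^12`.
#'
#' @param p_annual,p_monthly Probability in \[0, 1\].
#' @return A probability in \[0, 1\].
#' @export
#' @examples
#' annual_to_monthly_prob(0.20)  # ~0.01845, monthly recurrence hazard
annual_to_monthly_prob <- function(p_annual) {
  if (any(p_annual < 0 | p_annual > 1))
    stop("parameter error: p_annual must lie in [0, 1]", call. = FALSE)
  1 - (1 - p_annual)^(1 / 12)
}

#' @rdname annual_to_monthly_prob
#' @export
monthly_to_annual_prob <- function(p_monthly) {
  if (any(p_monthly < 0 | p_monthly > 1))
    stop("parameter error: p_monthly must lie in [0, 1]", call. = FALSE)
  1 - (1 - p_monthly)^12
}

#' Apply a relative risk to a per-cycle probability
#'
#' Relative risks act on the rate (log-survival) scale,
#' `1 - (1 - p)^rr`, so the result stays in \[0, 1\] for any `rr > 0`
#' (unlike naive multiplication, from which it differs by O(p^2)).
#'
#' @param p Per-cycle probability in \[0, 1\].
#' @param rr Relative risk (> 0).
#' @return Adjusted probability.
#' @export
#' @examples
#' apply_rr_to_prob(0.1, 2)  # 0.19
apply_rr_to_prob <- function(p, rr) {
  if (any(p < 0 | p > 1))
    stop("parameter error: p must lie in [0, 1]", call. = FALSE)
  if (any(rr <= 0))
    stop("parameter error: rr must be > 0", call. = FALSE)
  1 - (1 - p)^rr
}

weibull_survival <- function(t, shape, scale) exp(-(t / scale)^shape)

#' Per-cycle relapse probability from a relapse specification
#'
#' For a Weibull specification the conditional per-cycle probability after
#' `t` months in remission is `1 - S(t + 1)/S(t)` with
#' `S(t) = exp(-(t/scale)^shape)`. For a relative-risk specification the
#' placebo (base) curve's conditional probability is adjusted via
#' [apply_rr_to_prob()]. The remission clock `t` resets on every new entry
#' into remission; in the cohort engine it is carried by the tunnel index.
#'
#' @param cycle_in_remission Whole months already spent in remission
#'   (>= 0); the returned probability applies to the next cycle.
#' @param spec A [relapse_spec()].
#' @param base The placebo-curve [relapse_spec()] (weibull mode); required
#'   when `spec` is in `rr_vs_placebo` mode.
#' @return Probability in \[0, 1\].
#' @export
#' @examples
#' monthly_relapse_prob(0, relapse_spec("weibull", shape = 2, scale = 10))
monthly_relapse_prob <- function(cycle_in_remission, spec, base = NULL) {
  if (any(cycle_in_remission < 0))
    stop("parameter error: cycle_in_remission must be >= 0", call. = FALSE)
  if (!inherits(spec, "relapse_spec"))
    stop("parameter error: spec must be a relapse_spec", call. = FALSE)
  if (spec$mode == "weibull") {
    t <- cycle_in_remission
    p <- 1 - weibull_survival(t + 1, spec$shape, spec$scale) /
      weibull_survival(t, spec$shape, spec$scale)
    return(pmin(pmax(p, 0), 1))
  }
  if (is.null(base) || !inherits(base, "relapse_spec") || base$mode != "weibull")
    stop("parameter error: rr_vs_placebo mode needs a weibull base curve",
         call. = FALSE)
  apply_rr_to_prob(monthly_relapse_prob(cycle_in_remission, base), spec$rr)
}

#' Fit a Weibull survival curve to relapse-free survival points
#'
#' Least-squares fit on the linearised form
#' `log(-log S) = shape * log t - shape * log scale`, using points with
#' `t > 0` and `0 < S < 1`. With exactly two usable points the fit
#' interpolates them exactly.
#'
#' @param points Data frame with columns `time_months` and `survival`
#'   (e.g. from [weibull_survival_points()]).
#' @return A weibull-mode [relapse_spec()] with attribute `"rss"` (residual
#'   sum of squares on the linearised scale).
#' @export
#' @examples
#' pts <- weibull_survival_points(1.3, 14, 1:12)
#' fit_weibull(pts)
fit_weibull <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("time_months", "survival") %in% names(points)))
  keep <- points$time_months > 0 & points$survival > 0 & points$survival < 1
  pts <- points[keep, , drop = FALSE]
  if (nrow(pts) < 2L)
    stop("fit error: need at least 2 points with t > 0 and 0 < survival < 1",
         call. = FALSE)
  x <- log(pts$time_months)
  y <- log(-log(pts$survival))
  fit <- stats::lm.fit(cbind(1, x), y)
  shape <- fit$coefficients[[2]]
  if (!is.finite(shape) || shape <= 0)
    stop("fit error: non-positive fitted shape (points not Weibull-like)",
         call. = FALSE)
  scale <- exp(-fit$coefficients[[1]] / shape)
  out <- relapse_spec("weibull", shape = shape, scale = scale)
  attr(out, "rss") <- sum(fit$residuals^2)
  out
}
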