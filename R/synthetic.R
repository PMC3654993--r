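# Synthetic-data generators: stand-in life tables, relapse-free survival
# points, and randomized valid parameter sets. These emulate inputs that are
# not published at full detail (national life table, relapse-prevention
# survival data) so every downstream stage is testable self-contained.

#' Gompertz life table
#'
#' Annual death probabilities under a Gompertz hazard
#' \eqn{h(x) = a e^{b x}}: integrating the hazard over one year of age gives
#' \eqn{q(x) = 1 - \exp[-(a/b)(e^{b(x+1)} - e^{bx})]} for `b > 0`, and the
#' constant-hazard limit \eqn{q = 1 - e^{-a}} when `b = 0`. The defaults
#' (`a = 2e-5`, `b = 0.1`) give adult mortality of realistic order
#' (about 0.002/yr at age 45).
#'
#' @param a Baseline hazard per year (> 0).
#' @param b Hazard log-slope per year of age (>= 0).
#' @param age_min,age_max Integer age range (years), `age_min < age_max`.
#' @return Named numeric vector mapping age to annual death probability,
#'   suitable for [mortality_spec()].
#' @export
#' @examples
#' gompertz_life_table(2e-5, 0.1, 40, 50)
gompertz_life_table <- function(a = 2e-5, b = 0.1, age_min = 20L, age_max = 100L) {
  if (!is.numeric(a) || a <= 0) stop("parameter error: a must be > 0", call. = FALSE)
  if (!is.numeric(b) || b < 0) stop("parameter error: b must be >= 0", call. = FALSE)
  if (age_min >= age_max) stop("parameter error: age_min must be < age_max", call. = FALSE)
  ages <- seq(as.integer(age_min), as.integer(age_max))
  H <- if (b > 0) (a / b) * (exp(b * (ages + 1)) - exp(b * ages)) else rep(a, length(ages))
  q <- 1 - exp(-H)
  setNames(pmin(pmax(q, 0), 1), as.character(ages))
}

#' Weibull relapse-free survival points
#'
#' Evaluates \eqn{S(t) = \exp[-(t/\lambda)^k]} at the requested times,
#' emulating the digitised relapse-free survival data a Weibull curve is
#' fitted to.
#'
#' @param shape Weibull shape `k` (> 0).
#' @param scale Weibull scale `lambda` in months (> 0).
#' @param times Strictly increasing non-negative times in months.
#' @return Data frame with columns `time_months`, `survival`.
#' @seealso [fit_weibull()]
#' @export
#' @examples
#' weibull_survival_points(1, 10, c(0, 5, 10))
weibull_survival_points <- function(shape, scale, times) {
  if (!is.numeric(shape) || shape <= 0) stop("parameter error: shape must be > 0", call. = FALSE)
  if (!is.numeric(scale) || scale <= 0) stop("parameter error: scale must be > 0", call. = FALSE)
  if (any(times < 0) || is.unsorted(times, strictly = TRUE))
    stop("parameter error: times must be >= 0 and strictly increasing", call. = FALSE)
  data.frame(time_months = times, survival = exp(-(times / scale)^shape))
}

#' Default parameter ranges for random scenarios
#'
#' Plausible ranges for each randomized field of [random_scenario()], chosen
#' to always satisfy configuration invariants (utility ranges are disjoint
#' and ordered, probabilities stay inside \[0, 1\]).
#'
#' @return Named list of `c(low, high)` ranges.
#' @export
default_scenario_ranges <- function() {
  list(
    utility_well = c(0.82, 0.95),
    utility_remission = c(0.70, 0.82),
    utility_episode = c(0.40, 0.70),
    direct_cost_remission = c(10, 80),
    indirect_cost_remission = c(50, 300),
    direct_cost_episode = c(100, 400),
    indirect_cost_episode = c(200, 600),
    annual_recurrence_prob = c(0.10, 0.35),
    off_treatment_remission_prob = c(0.10, 0.30),
    episode_mortality_rr = c(5, 30),
    gompertz_a = c(1e-5, 1e-4),
    gompertz_b = c(0.08, 0.11),
    placebo_shape = c(0.7, 1.5),
    placebo_scale = c(6, 24),
    monthly_remission_prob = c(0.10, 0.50),
    monthly_discontinuation_prob = c(0.05, 0.30),
    discontinuation_symptom_prob = c(0.0, 0.30),
    double_dose_fraction = c(0.0, 0.50),
    adr_freq = c(0.0, 0.15),
    monthly_drug_cost_standard = c(5, 100),
    rr = c(0.3, 1.2),
    treatment_shape = c(0.7, 1.5),
    treatment_scale = c(12, 48)
  )
}

runif1 <- function(r) runif(1, r[1], r[2])

#' Randomized valid model configuration
#'
#' Draws a full [model_config()] uniformly within the supplied ranges. The
#' first treatment arm carries its own Weibull relapse curve and hepatic
#' monitoring; the remaining arms use relative risks versus placebo. Every
#' generated configuration passes [validate_config()]; the draw is
#' reproducible given `rng_seed`. Collapsing a range to a point
#' (`low == high`) pins that field.
#'
#' @param rng_seed Integer seed.
#' @param n_treatments Number of treatment arms (>= 1).
#' @param ranges Named list of `c(low, high)` ranges; defaults from
#'   [default_scenario_ranges()], unknown names rejected.
#' @return A validated `model_config`.
#' @export
random_scenario <- function(rng_seed, n_treatments = 3L, ranges = list()) {
  stopifnot(n_treatments >= 1)
  base <- default_scenario_ranges()
  if (length(ranges)) {
    bad <- setdiff(names(ranges), names(base))
    if (length(bad))
      stop("generation error: unknown range field(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    for (nm in names(ranges)) {
      r <- ranges[[nm]]
      if (length(r) != 2L || r[1] > r[2])
        stop("generation error: range for ", nm, " must be c(low, high) with low <= high",
             call. = FALSE)
      base[[nm]] <- r
    }
  }
  r <- base
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(rng_seed)

  sv <- health_state_values(
    utility_well = runif1(r$utility_well),
    utility_remission = runif1(r$utility_remission),
    utility_episode = runif1(r$utility_episode),
    direct_cost_remission = runif1(r$direct_cost_remission),
    indirect_cost_remission = runif1(r$indirect_cost_remission),
    direct_cost_episode = runif1(r$direct_cost_episode),
    indirect_cost_episode = runif1(r$indirect_cost_episode)
  )
  mort <- mortality_spec(
    gompertz_life_table(runif1(r$gompertz_a), runif1(r$gompertz_b), 20L, 100L),
    episode_mortality_rr = runif1(r$episode_mortality_rr)
  )
  adr <- base_case_adr_table()
  trs <- lapply(seq_len(n_treatments), function(i) {
    rel <- if (i == 1L)
      relapse_spec("weibull", shape = runif1(r$treatment_shape),
                   scale = runif1(r$treatment_scale))
    else
      relapse_spec("rr_vs_placebo", rr = runif1(r$rr))
    treatment_profile(
      name = sprintf("Drug%02d", i),
      daily_dose_mg = 25,
      double_dose_fraction = runif1(r$double_dose_fraction),
      monthly_remission_prob = runif1(r$monthly_remission_prob),
      monthly_discontinuation_prob = runif1(r$monthly_discontinuation_prob),
      discontinuation_symptom_prob = runif1(r$discontinuation_symptom_prob),
      relapse = rel,
      adr_monthly_freq = setNames(runif(length(ADR_NAMES), r$adr_freq[1], r$adr_freq[2]),
                                  ADR_NAMES),
      monthly_drug_cost_standard = runif1(r$monthly_drug_cost_standard),
      hepatic_monitoring = i == 1L
    )
  })
  names(trs) <- vapply(trs, function(t) t$name, character(1))
  model_config(
    state_values = sv,
    mortality = mort,
    annual_recurrence_prob = runif1(r$annual_recurrence_prob),
    adr_table = adr,
    discontinuation_symptom_decrement = 0.065,
    discontinuation_symptom_cost = 52,
    hepatic_test_cost = 75,
    placebo_relapse = relapse_spec("weibull",
                                   shape = runif1(r$placebo_shape),
                                   scale = runif1(r$placebo_scale)),
    off_treatment_remission_prob = runif1(r$off_treatment_remission_prob),
    econ = economic_settings(),
    treatments = trs
  )
}

#' Write synthetic tables to CSV
#'
#' `write_life_table_csv()` writes `age,annual_death_prob`;
#' `write_survival_points_csv()` writes `time_months,survival`.
#'
#' @param life_table Named numeric vector as from [gompertz_life_table()].
#' @param points Data frame as from [weibull_survival_points()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_life_table_csv <- function(life_table, path) {
  write.csv(data.frame(age = as.integer(names(life_table)),
                       annual_death_prob = unname(life_table)),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_life_table_csv
#' @export
write_survival_points_csv <- function(points, path) {
  write.csv(points[, c("time_months", "survival")], path, row.names = FALSE)
  invisible(path)
}
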