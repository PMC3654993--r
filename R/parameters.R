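# Parameter containers, validation and configuration I/O.
#
# A model configuration is a plain named list with class "model_config";
# sub-objects (treatment profiles, relapse specifications) are likewise
# classed lists so that validation and serialization can dispatch on them.

stop_validation <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_validation(field, "must be a probability in [0, 1]")
  invisible(x)
}

check_nonneg <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    stop_validation(field, "must be a non-negative number")
  invisible(x)
}

check_pos <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop_validation(field, "must be a positive number")
  invisible(x)
}

#' Relapse specification
#'
#' A relapse hazard is either a Weibull relapse-free survival curve
#' (`mode = "weibull"`, on-treatment arms whose curve was fitted directly)
#' or a relative risk versus placebo applied to the base placebo curve
#' (`mode = "rr_vs_placebo"`).
#'
#' @param mode `"weibull"` or `"rr_vs_placebo"`.
#' @param shape,scale Weibull shape (dimensionless) and scale (months),
#'   required for `mode = "weibull"`.
#' @param rr Relative risk of relapse versus placebo (> 0), required for
#'   `mode = "rr_vs_placebo"`.
#' @return A classed list of class `"relapse_spec"`.
#' @export
#' @examples
#' relapse_spec("weibull", shape = 1, scale = 24)
#' relapse_spec("rr_vs_placebo", rr = 0.513)
relapse_spec <- function(mode = c("weibull", "rr_vs_placebo"),
                         shape = NULL, scale = NULL, rr = NULL) {
  mode <- match.arg(mode)
  if (mode == "weibull") {
    if (is.null(shape) || is.null(scale) || !is.null(rr))
      stop_validation("relapse", "weibull mode requires exactly shape and scale")
    check_pos(shape, "relapse$shape"); check_pos(scale, "relapse$scale")
    out <- list(mode = mode, shape = shape, scale = scale)
  } else {
    if (is.null(rr) || !is.null(shape) || !is.null(scale))
      stop_validation("relapse", "rr_vs_placebo mode requires exactly rr")
    check_pos(rr, "relapse$rr")
    out <- list(mode = mode, rr = rr)
  }
  structure(out, class = "relapse_spec")
}

#' Treatment profile
#'
#' All drug-specific inputs for one model arm: monthly transition
#' probabilities, relapse specification, adverse-drug-reaction (ADR)
#' frequencies, dosing and price.
#'
#' @param name Treatment name (unique within a configuration).
#' @param daily_dose_mg Daily dose in mg.
#' @param double_dose_fraction Fraction of patients escalated to double dose
#'   from the second on-treatment cycle onwards.
#' @param monthly_remission_prob Monthly probability of remission while on
#'   treatment during a depressive episode.
#' @param monthly_discontinuation_prob Monthly probability of discontinuing
#'   treatment.
#' @param discontinuation_symptom_prob Probability of suffering
#'   discontinuation symptoms upon stopping treatment.
#' @param relapse A [relapse_spec()].
#' @param adr_monthly_freq Named numeric vector of monthly ADR
#'   probabilities; must contain all eight names in [adr_names()].
#' @param monthly_drug_cost_standard Monthly medication cost at standard
#'   dose, in euro.
#' @param hepatic_monitoring Logical; whether periodic hepatic blood tests
#'   are required (billed at treatment months 1, 2, 3 and 6).
#' @return A classed list of class `"treatment_profile"`.
#' @export
treatment_profile <- function(name, daily_dose_mg, double_dose_fraction,
                              monthly_remission_prob,
                              monthly_discontinuation_prob,
                              discontinuation_symptom_prob,
                              relapse, adr_monthly_freq,
                              monthly_drug_cost_standard,
                              hepatic_monitoring = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  check_pos(daily_dose_mg, paste0(name, "$daily_dose_mg"))
  check_prob(double_dose_fraction, paste0(name, "$double_dose_fraction"))
  check_prob(monthly_remission_prob, paste0(name, "$monthly_remission_prob"))
  check_prob(monthly_discontinuation_prob,
             paste0(name, "$monthly_discontinuation_prob"))
  check_prob(discontinuation_symptom_prob,
             paste0(name, "$discontinuation_symptom_prob"))
  if (!inherits(relapse, "relapse_spec"))
    stop_validation(paste0(name, "$relapse"), "must be a relapse_spec")
  if (!is.numeric(adr_monthly_freq) ||
      !setequal(names(adr_monthly_freq), ADR_NAMES))
    stop_validation(paste0(name, "$adr_monthly_freq"),
                    "must be a named vector with all eight ADR names")
  adr_monthly_freq <- adr_monthly_freq[ADR_NAMES]
  for (a in ADR_NAMES)
    check_prob(adr_monthly_freq[[a]],
               paste0(name, "$adr_monthly_freq$", a))
  check_nonneg(monthly_drug_cost_standard,
               paste0(name, "$monthly_drug_cost_standard"))
  stopifnot(is.logical(hepatic_monitoring), length(hepatic_monitoring) == 1L)
  structure(list(
    name = name,
    daily_dose_mg = daily_dose_mg,
    double_dose_fraction = double_dose_fraction,
    monthly_remission_prob = monthly_remission_prob,
    monthly_discontinuation_prob = monthly_discontinuation_prob,
    discontinuation_symptom_prob = discontinuation_symptom_prob,
    relapse = relapse,
    adr_monthly_freq = adr_monthly_freq,
    monthly_drug_cost_standard = monthly_drug_cost_standard,
    hepatic_monitoring = hepatic_monitoring
  ), class = "treatment_profile")
}

#' Health-state utilities and monthly costs
#'
#' @param utility_well,utility_remission,utility_episode State utilities on
#'   the 0–1 scale. For valid base configurations
#'   `utility_episode <= utility_remission <= utility_well`; a violation
#'   (possible under sensitivity-analysis extremes) raises a warning, not an
#'   error.
#' @param direct_cost_remission,indirect_cost_remission Monthly direct and
#'   indirect (productivity) cost of the remission state, euro.
#' @param direct_cost_episode,indirect_cost_episode Monthly costs of the
#'   depressive-episode state, euro. The well and dead states accrue zero
#'   state cost.
#' @return A classed list of class `"health_state_values"`.
#' @export
health_state_values <- function(utility_well, utility_remission,
                                utility_episode,
                                direct_cost_remission, indirect_cost_remission,
                                direct_cost_episode, indirect_cost_episode) {
  check_prob(utility_well, "utility_well")
  check_prob(utility_remission, "utility_remission")
  check_prob(utility_episode, "utility_episode")
  if (utility_episode > utility_remission || utility_remission > utility_well)
    warning("state utilities are not ordered episode <= remission <= well",
            call. = FALSE)
  check_nonneg(direct_cost_remission, "direct_cost_remission")
  check_nonneg(indirect_cost_remission, "indirect_cost_remission")
  check_nonneg(direct_cost_episode, "direct_cost_episode")
  check_nonneg(indirect_cost_episode, "indirect_cost_episode")
  structure(list(
    utility_well = utility_well,
    utility_remission = utility_remission,
    utility_episode = utility_episode,
    direct_cost_remission = direct_cost_remission,
    indirect_cost_remission = indirect_cost_remission,
    direct_cost_episode = direct_cost_episode,
    indirect_cost_episode = indirect_cost_episode
  ), class = "health_state_values")
}

#' Mortality specification
#'
#' @param life_table Named numeric vector mapping integer age (years) to the
#'   annual probability of death; ages must be contiguous.
#' @param episode_mortality_rr Relative mortality multiplier (>= 1) applied
#'   on the rate scale during depressive episodes, reflecting excess suicide
#'   risk.
#' @return A classed list of class `"mortality_spec"`.
#' @export
mortality_spec <- function(life_table, episode_mortality_rr) {
  if (!is.numeric(life_table) || is.null(names(life_table)))
    stop_validation("mortality$life_table", "must be a named numeric vector")
  ages <- as.integer(names(life_table))
  if (anyNA(ages) || !identical(ages, seq(min(ages), max(ages))))
    stop_validation("mortality$life_table", "ages must be contiguous integers")
  if (any(life_table < 0 | life_table > 1))
    stop_validation("mortality$life_table", "probabilities must lie in [0, 1]")
  if (!is.numeric(episode_mortality_rr) || episode_mortality_rr < 1)
    stop_validation("mortality$episode_mortality_rr", "must be >= 1")
  structure(list(
    life_table = setNames(as.numeric(life_table), as.character(ages)),
    episode_mortality_rr = episode_mortality_rr
  ), class = "mortality_spec")
}

#' Economic settings
#'
#' @param annual_discount_rate Annual discount rate applied to costs and
#'   outcomes beyond the first year (default 0.035).
#' @param horizon_cycles Time horizon in monthly cycles (default 24).
#' @param start_age_years Cohort entry age in years (default 45).
#' @param perspective `"societal"` (includes productivity costs) or
#'   `"payer"` (direct health care costs only).
#' @param wtp_thresholds Willingness-to-pay thresholds, euro per QALY.
#' @param discontinuation_symptom_duration_days Duration of discontinuation
#'   symptoms, days (default 7).
#' @param days_per_month Days per model month (default 30).
#' @return A classed list of class `"economic_settings"`.
#' @export
economic_settings <- function(annual_discount_rate = 0.035,
                              horizon_cycles = 24L,
                              start_age_years = 45,
                              perspective = c("societal", "payer"),
                              wtp_thresholds = c(40000, 50000, 60000),
                              discontinuation_symptom_duration_days = 7,
                              days_per_month = 30) {
  perspective <- match.arg(perspective)
  check_nonneg(annual_discount_rate, "econ$annual_discount_rate")
  if (!is.numeric(horizon_cycles) || horizon_cycles < 1)
    stop_validation("econ$horizon_cycles", "must be >= 1")
  check_pos(start_age_years, "econ$start_age_years")
  if (!is.numeric(wtp_thresholds) || any(wtp_thresholds <= 0))
    stop_validation("econ$wtp_thresholds", "must be positive")
  check_pos(discontinuation_symptom_duration_days,
            "econ$discontinuation_symptom_duration_days")
  check_pos(days_per_month, "econ$days_per_month")
  structure(list(
    annual_discount_rate = annual_discount_rate,
    horizon_cycles = as.integer(horizon_cycles),
    start_age_years = start_age_years,
    perspective = perspective,
    wtp_thresholds = as.numeric(wtp_thresholds),
    discontinuation_symptom_duration_days = discontinuation_symptom_duration_days,
    days_per_month = days_per_month
  ), class = "economic_settings")
}

#' Model configuration
#'
#' The complete disease-level and treatment-level input set for the model.
#'
#' @param state_values A [health_state_values()].
#' @param mortality A [mortality_spec()].
#' @param annual_recurrence_prob Annual probability of recurrence from the
#'   well state (converted to a monthly probability internally).
#' @param adr_table Named list (one entry per ADR in [adr_names()]) of
#'   `list(utility_decrement =, monthly_cost =)`.
#' @param discontinuation_symptom_decrement Utility decrement of
#'   discontinuation symptoms (set equal to that of nausea).
#' @param discontinuation_symptom_cost Management cost of a
#'   discontinuation-symptom event, euro.
#' @param hepatic_test_cost Cost of one hepatic blood test, euro.
#' @param placebo_relapse A weibull-mode [relapse_spec()]: the placebo
#'   relapse-free survival curve that relative risks act on, and the relapse
#'   hazard used for patients off treatment.
#' @param off_treatment_remission_prob Monthly remission probability for
#'   patients in a depressive episode off treatment (untreated/spontaneous
#'   remission; an explicit assumption, default 0.20).
#' @param econ An [economic_settings()].
#' @param treatments List of [treatment_profile()]s with unique names.
#' @return A classed list of class `"model_config"`.
#' @seealso [base_case_config()], [validate_config()], [load_config()]
#' @export
model_config <- function(state_values, mortality, annual_recurrence_prob,
                         adr_table, discontinuation_symptom_decrement,
                         discontinuation_symptom_cost, hepatic_test_cost,
                         placebo_relapse, off_treatment_remission_prob,
                         econ, treatments) {
  cfg <- structure(list(
    state_values = state_values,
    mortality = mortality,
    annual_recurrence_prob = annual_recurrence_prob,
    adr_table = adr_table,
    discontinuation_symptom_decrement = discontinuation_symptom_decrement,
    discontinuation_symptom_cost = discontinuation_symptom_cost,
    hepatic_test_cost = hepatic_test_cost,
    placebo_relapse = placebo_relapse,
    off_treatment_remission_prob = off_treatment_remission_prob,
    econ = econ,
    treatments = treatments
  ), class = "model_config")
  validate_config(cfg)
  cfg
}

#' Validate a model configuration
#'
#' Checks every invariant of a [model_config()]: sub-object classes, bounds
#' on probabilities/utilities/costs, presence of all eight ADR entries,
#' uniqueness of treatment names, and that the life table covers the
#' modelled age range. Utility ordering violations
#' (`episode <= remission <= well`) warn rather than fail so that
#' sensitivity-analysis extremes remain runnable.
#'
#' @param config A `model_config`.
#' @return Invisibly `TRUE`; errors describe the offending field and bound.
#' @export
validate_config <- function(config) {
  if (!inherits(config, "model_config"))
    stop_validation("config", "must be a model_config")
  if (!inherits(config$state_values, "health_state_values"))
    stop_validation("state_values", "must be a health_state_values")
  sv <- config$state_values
  check_prob(sv$utility_well, "utility_well")
  check_prob(sv$utility_remission, "utility_remission")
  check_prob(sv$utility_episode, "utility_episode")
  if (sv$utility_episode > sv$utility_remission ||
      sv$utility_remission > sv$utility_well)
    warning("state utilities are not ordered episode <= remission <= well",
            call. = FALSE)
  if (!inherits(config$mortality, "mortality_spec"))
    stop_validation("mortality", "must be a mortality_spec")
  check_prob(config$annual_recurrence_prob, "annual_recurrence_prob")
  if (!setequal(names(config$adr_table), ADR_NAMES))
    stop_validation("adr_table", "must have one entry per ADR name")
  for (a in ADR_NAMES) {
    e <- config$adr_table[[a]]
    check_prob(e$utility_decrement, paste0("adr_table$", a, "$utility_decrement"))
    check_nonneg(e$monthly_cost, paste0("adr_table$", a, "$monthly_cost"))
  }
  check_prob(config$discontinuation_symptom_decrement,
             "discontinuation_symptom_decrement")
  check_nonneg(config$discontinuation_symptom_cost,
               "discontinuation_symptom_cost")
  check_nonneg(config$hepatic_test_cost, "hepatic_test_cost")
  if (!inherits(config$placebo_relapse, "relapse_spec") ||
      config$placebo_relapse$mode != "weibull")
    stop_validation("placebo_relapse", "must be a weibull relapse_spec")
  check_prob(config$off_treatment_remission_prob, "off_treatment_remission_prob")
  if (!inherits(config$econ, "economic_settings"))
    stop_validation("econ", "must be an economic_settings")
  nm <- vapply(config$treatments, function(x) x$name, character(1))
  if (anyDuplicated(nm))
    stop_validation("treatments", "treatment names must be unique")
  if (!identical(names(config$treatments), unname(nm)))
    stop_validation("treatments", "list names must equal profile names")
  for (tr in config$treatments) {
    if (!inherits(tr, "treatment_profile"))
      stop_validation("treatments", "entries must be treatment_profile objects")
    # re-run constructor checks (fields may have been mutated in place)
    do.call(treatment_profile, unclass(tr))
  }
  ages <- as.integer(names(config$mortality$life_table))
  need_max <- floor(config$econ$start_age_years +
                      (config$econ$horizon_cycles - 1) / 12)
  if (min(ages) > floor(config$econ$start_age_years) || max(ages) < need_max)
    stop_validation("mortality$life_table",
                    sprintf("must cover ages %d..%d",
                            floor(config$econ$start_age_years), need_max))
  invisible(TRUE)
}

#' @export
print.model_config <- function(x, ...) {
  cat("<model_config>\n")
  cat(sprintf("  treatments : %s\n", paste(names(x$treatments), collapse = ", ")))
  cat(sprintf("  horizon    : %d monthly cycles, entry age %.0f\n",
              x$econ$horizon_cycles, x$econ$start_age_years))
  cat(sprintf("  perspective: %s; discount %.1f%%/yr beyond year 1\n",
              x$econ$perspective, 100 * x$econ$annual_discount_rate))
  cat(sprintf("  utilities  : well %.2f / remission %.2f / episode %.2f\n",
              x$state_values$utility_well, x$state_values$utility_remission,
              x$state_values$utility_episode))
  invisible(x)
}

#' @export
print.treatment_profile <- function(x, ...) {
  cat(sprintf("<treatment_profile> %s: %g mg/day, remission %.3f/mo, discontinuation %.3f/mo, drug cost %.2f EUR/mo\n",
              x$name, x$daily_dose_mg, x$monthly_remission_prob,
              x$monthly_discontinuation_prob, x$monthly_drug_cost_standard))
  invisible(x)
}

# ---- serialization ---------------------------------------------------------

config_to_list <- function(config) {
  list(
    economics = unclass(config$econ),
    state_values = unclass(config$state_values),
    mortality = list(
      life_table = list(
        age = as.integer(names(config$mortality$life_table)),
        annual_death_prob = unname(config$mortality$life_table)
      ),
      episode_mortality_rr = config$mortality$episode_mortality_rr
    ),
    annual_recurrence_prob = config$annual_recurrence_prob,
    adr_table = config$adr_table,
    discontinuation_symptom_decrement = config$discontinuation_symptom_decrement,
    discontinuation_symptom_cost = config$discontinuation_symptom_cost,
    hepatic_test_cost = config$hepatic_test_cost,
    placebo_relapse = unclass(config$placebo_relapse),
    off_treatment_remission_prob = config$off_treatment_remission_prob,
    treatments = lapply(unname(config$treatments), function(tr) {
      out <- unclass(tr)
      out$relapse <- unclass(out$relapse)
      out$adr_monthly_freq <- as.list(out$adr_monthly_freq)
      out
    })
  )
}

config_from_list <- function(x) {
  need <- function(key) {
    if (is.null(x[[key]]))
      stop(sprintf("configuration format error: missing key '%s'", key),
           call. = FALSE)
    x[[key]]
  }
  econ <- do.call(economic_settings, need("economics"))
  sv <- do.call(health_state_values, need("state_values"))
  mt <- need("mortality")
  lt <- mt$life_table
  if (is.null(lt$age) || is.null(lt$annual_death_prob))
    stop("configuration format error: mortality$life_table needs 'age' and 'annual_death_prob'",
         call. = FALSE)
  mort <- mortality_spec(
    setNames(as.numeric(unlist(lt$annual_death_prob)),
             as.character(unlist(lt$age))),
    mt$episode_mortality_rr
  )
  trs <- lapply(need("treatments"), function(tr) {
    tr$relapse <- do.call(relapse_spec, tr$relapse)
    tr$adr_monthly_freq <- unlist(tr$adr_monthly_freq)
    do.call(treatment_profile, tr)
  })
  names(trs) <- vapply(trs, function(t) t$name, character(1))
  model_config(
    state_values = sv,
    mortality = mort,
    annual_recurrence_prob = need("annual_recurrence_prob"),
    adr_table = need("adr_table"),
    discontinuation_symptom_decrement = need("discontinuation_symptom_decrement"),
    discontinuation_symptom_cost = need("discontinuation_symptom_cost"),
    hepatic_test_cost = need("hepatic_test_cost"),
    placebo_relapse = do.call(relapse_spec, need("placebo_relapse")),
    off_treatment_remission_prob = need("off_treatment_remission_prob"),
    econ = econ,
    treatments = trs
  )
}

#' Read / write a model configuration as YAML
#'
#' The on-disk format is a YAML document with top-level keys `economics`,
#' `state_values`, `mortality`, `adr_table`, `treatments` plus the
#' disease-level scalars. `save_config()` followed by `load_config()` is a
#' lossless round trip at full double precision.
#'
#' @param path File path.
#' @param config A validated [model_config()].
#' @return `load_config()` returns a validated `model_config`;
#'   `save_config()` returns `path` invisibly.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  x <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop(sprintf("configuration format error in '%s': %s",
                 path, conditionMessage(e)), call. = FALSE))
  config_from_list(x)
}

#' @rdname load_config
#' @export
save_config <- function(config, path) {
  validate_config(config)
  # precision = 22 makes the double -> text -> double round trip exact
  txt <- yaml::as.yaml(config_to_list(config), precision = 22L)
  writeLines(txt, path)
  invisible(path)
}

#' Load a life table from CSV
#'
#' Expects a header `age,annual_death_prob`.
#'
#' @param path CSV file path.
#' @param episode_mortality_rr Episode mortality multiplier for the
#'   resulting [mortality_spec()].
#' @return A [mortality_spec()].
#' @export
load_life_table_csv <- function(path, episode_mortality_rr = 20.35) {
  d <- read.csv(path)
  if (!all(c("age", "annual_death_prob") %in% names(d)))
    stop("life table CSV must have columns 'age' and 'annual_death_prob'",
         call. = FALSE)
  mortality_spec(setNames(d$annual_death_prob, as.character(d$age)),
                 episode_mortality_rr)
}
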