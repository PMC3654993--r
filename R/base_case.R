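# Packaged base-case configuration: the published Greek cost-utility input
# set for agomelatine versus venlafaxine, sertraline, fluoxetine and
# escitalopram (branded and generic), year-2012 prices, societal
# perspective. Inputs the source analysis left in unavailable supplements
# (life table, relapse Weibull parameters, off-treatment remission) carry
# documented package defaults; see the methods vignette.

#' Adverse-drug-reaction utility decrements and management costs
#'
#' Published per-ADR utility decrements (Sullivan catalogue values; the
#' lower Botteman estimate, 0.08095, for sleep difficulties) and monthly
#' management costs in euro. Somnolence is not treated pharmaceutically and
#' carries zero cost.
#'
#' @return Named list, one `list(utility_decrement =, monthly_cost =)` per
#'   name in [adr_names()].
#' @export
base_case_adr_table <- function() {
  list(
    constipation       = list(utility_decrement = 0.065,   monthly_cost = 12.5),
    dyspepsia          = list(utility_decrement = 0.086,   monthly_cost = 12.0),
    diarrhoea          = list(utility_decrement = 0.044,   monthly_cost = 5.5),
    nausea             = list(utility_decrement = 0.065,   monthly_cost = 6.0),
    somnolence         = list(utility_decrement = 0.085,   monthly_cost = 0.0),
    headache           = list(utility_decrement = 0.115,   monthly_cost = 2.8),
    sexual_dysfunction = list(utility_decrement = 0.049,   monthly_cost = 44.0),
    sleep_disorder     = list(utility_decrement = 0.08095, monthly_cost = 54.0)
  )
}

# Six-month relapse-free survival anchors for the default exponential
# (shape = 1) relapse curves, matching the relapse-prevention trial the
# fitted curve derives from (~22% relapse on treatment, ~47% on placebo,
# at six months). Scale solves S(6) = exp(-6/scale).
ON_TX_RELAPSE_S6 <- 0.78
PLACEBO_RELAPSE_S6 <- 0.53

default_on_treatment_relapse <- function() {
  relapse_spec("weibull", shape = 1, scale = -6 / log(ON_TX_RELAPSE_S6))
}

default_placebo_relapse <- function() {
  relapse_spec("weibull", shape = 1, scale = -6 / log(PLACEBO_RELAPSE_S6))
}

base_case_profile <- function(name, dose, dd, rem, disc, sympt, relapse,
                              freqs, cost, hepatic = FALSE) {
  treatment_profile(
    name = name, daily_dose_mg = dose, double_dose_fraction = dd,
    monthly_remission_prob = rem, monthly_discontinuation_prob = disc,
    discontinuation_symptom_prob = sympt, relapse = relapse,
    adr_monthly_freq = setNames(freqs, ADR_NAMES),
    monthly_drug_cost_standard = cost, hepatic_monitoring = hepatic
  )
}

#' Packaged base-case configuration
#'
#' The complete published input set: five branded arms (agomelatine,
#' venlafaxine, fluoxetine, sertraline, escitalopram) plus four generic
#' arms that differ from their branded counterparts only in medication
#' price (effectiveness and safety assumed equal). Agomelatine and
#' venlafaxine share a directly fitted Weibull relapse curve; the remaining
#' arms apply relative risks versus placebo (fluoxetine 0.513, sertraline
#' 0.633, escitalopram 0.531) to the placebo curve. State utilities are
#' 0.86 (well), 0.81 (remission) and 0.57 (depressive episode); monthly
#' state costs 35/173 (remission direct/indirect) and 190/380 (episode);
#' annual recurrence 20%; episode mortality multiplier 20.35 (suicide
#' risk); hepatic monitoring for agomelatine at €75 per test.
#'
#' Venlafaxine and escitalopram remission probabilities are assumed equal
#' to agomelatine's 0.323. Escitalopram's discontinuation-symptom
#' probability is 0.07 as tabulated. The life table and the relapse-curve
#' parameters are package defaults (see the methods vignette) because the
#' original supplements are not published.
#'
#' @return A validated [model_config()] with nine treatment arms.
#' @export
#' @examples
#' cfg <- base_case_config()
#' names(cfg$treatments)
#' cfg$treatments[["Agomelatine"]]$adr_monthly_freq[["nausea"]]  # 0.066
base_case_config <- function() {
  on_tx <- default_on_treatment_relapse()
  #                 const  dysp   diarr  nausea somnol headac sexdys sleep
  freq_agom  <- c(0.027, 0.020, 0.040, 0.066, 0.035, 0.111, 0.005, 0.007)
  freq_venla <- c(0.042, 0.024, 0.018, 0.226, 0.048, 0.119, 0.018, 0.024)
  freq_fluox <- c(0.011, 0.008, 0.027, 0.114, 0.034, 0.114, 0.004, 0.019)
  freq_sert  <- c(0.006, 0.013, 0.057, 0.044, 0.013, 0.101, 0.019, 0.019)
  freq_escit <- c(0.006, 0.025, 0.069, 0.138, 0.038, 0.144, 0.013, 0.025)

  agom  <- base_case_profile("Agomelatine", 25, 0.221, 0.323, 0.117, 0.00,
                             on_tx, freq_agom, 60.27, hepatic = TRUE)
  venla <- base_case_profile("Venlafaxine", 75, 0.118, 0.323, 0.216, 0.20,
                             on_tx, freq_venla, 18.03)
  fluox <- base_case_profile("Fluoxetine", 20, 0.230, 0.284, 0.171, 0.00,
                             relapse_spec("rr_vs_placebo", rr = 0.513),
                             freq_fluox, 21.31)
  sert  <- base_case_profile("Sertraline", 50, 0.245, 0.289, 0.189, 0.00,
                             relapse_spec("rr_vs_placebo", rr = 0.633),
                             freq_sert, 17.35)
  escit <- base_case_profile("Escitalopram", 20, 0.0, 0.323, 0.144, 0.07,
                             relapse_spec("rr_vs_placebo", rr = 0.531),
                             freq_escit, 56.31)

  generic <- function(branded, name, cost) {
    p <- unclass(branded)
    p$name <- name
    p$monthly_drug_cost_standard <- cost
    do.call(treatment_profile, p)
  }
  trs <- list(
    agom, venla, sert, escit, fluox,
    generic(venla, "Generic Venlafaxine", 14.38),
    generic(sert,  "Generic Sertraline",  10.81),
    generic(escit, "Generic Escitalopram", 45.60),
    generic(fluox, "Generic Fluoxetine",  14.37)
  )
  names(trs) <- vapply(trs, function(t) t$name, character(1))

  model_config(
    state_values = health_state_values(
      utility_well = 0.86, utility_remission = 0.81, utility_episode = 0.57,
      direct_cost_remission = 35, indirect_cost_remission = 173,
      direct_cost_episode = 190, indirect_cost_episode = 380
    ),
    mortality = mortality_spec(gompertz_life_table(2e-5, 0.1, 20L, 100L),
                               episode_mortality_rr = 20.35),
    annual_recurrence_prob = 0.20,
    adr_table = base_case_adr_table(),
    discontinuation_symptom_decrement = 0.065,  # equal to nausea
    discontinuation_symptom_cost = 52,
    hepatic_test_cost = 75,
    placebo_relapse = default_placebo_relapse(),
    off_treatment_remission_prob = 0.20,        # assumption, see vignette
    econ = economic_settings(),
    treatments = trs
  )
}
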