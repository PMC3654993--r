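# Small hand-controllable configurations for engine tests.

zero_life_table <- function() {
  setNames(rep(0, 81), as.character(20:100))
}

# Relapse spec whose per-cycle probability is numerically zero (~1e-12).
no_relapse <- function() relapse_spec("weibull", shape = 1, scale = 1e12)

# A two-arm configuration with every hazard individually controllable.
toy_config <- function(p_rem = 0.5, p_disc = 0.2,
                       relapse = no_relapse(),
                       placebo_relapse = no_relapse(),
                       p_rem_off = 0,
                       recurrence = 0,
                       life_table = zero_life_table(),
                       episode_rr = 1,
                       u = c(well = 0.86, remission = 0.81, episode = 0.57),
                       adr_freq = 0,
                       sympt_prob = 0,
                       drug_cost = 10,
                       discount = 0,
                       horizon = 24L,
                       perspective = "societal",
                       second_arm = TRUE) {
  freqs <- setNames(rep(adr_freq, 8), adr_names())
  tr1 <- treatment_profile(
    name = "A", daily_dose_mg = 25, double_dose_fraction = 0,
    monthly_remission_prob = p_rem, monthly_discontinuation_prob = p_disc,
    discontinuation_symptom_prob = sympt_prob, relapse = relapse,
    adr_monthly_freq = freqs, monthly_drug_cost_standard = drug_cost)
  trs <- list(A = tr1)
  if (second_arm) {
    tr2 <- treatment_profile(
      name = "B", daily_dose_mg = 25, double_dose_fraction = 0,
      monthly_remission_prob = min(p_rem * 0.8, 1),
      monthly_discontinuation_prob = p_disc,
      discontinuation_symptom_prob = sympt_prob,
      relapse = relapse_spec("rr_vs_placebo", rr = 1),
      adr_monthly_freq = freqs, monthly_drug_cost_standard = drug_cost * 0.5)
    trs$B <- tr2
  }
  model_config(
    state_values = health_state_values(
      utility_well = u[["well"]], utility_remission = u[["remission"]],
      utility_episode = u[["episode"]],
      direct_cost_remission = 35, indirect_cost_remission = 173,
      direct_cost_episode = 190, indirect_cost_episode = 380),
    mortality = mortality_spec(life_table, episode_mortality_rr = episode_rr),
    annual_recurrence_prob = recurrence,
    adr_table = base_case_adr_table(),
    discontinuation_symptom_decrement = 0.065,
    discontinuation_symptom_cost = 52,
    hepatic_test_cost = 75,
    placebo_relapse = placebo_relapse,
    off_treatment_remission_prob = p_rem_off,
    econ = economic_settings(annual_discount_rate = discount,
                             horizon_cycles = horizon,
                             perspective = perspective),
    treatments = trs)
}
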