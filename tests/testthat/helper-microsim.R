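# Independent first-order microsimulation of the transition rules, used as
# a Monte Carlo oracle for the cohort engine. The per-state transition
# probabilities are derived here directly from the profile/configuration
# (not taken from build_transition_matrix), and individuals are tracked one
# cycle at a time.

microsim_occupancy <- function(profile, config, n, seed) {
  set.seed(seed)
  H <- config$econ$horizon_cycles
  lt <- config$mortality$life_table
  # state coding mirrors state_space(): 1 EpOn, 2:7 RemOn, 8 EpOff,
  # 9:14 RemOff, 15 Well, 16 Dead
  state <- rep(1L, n)
  occ <- matrix(0, H + 1L, 16L)
  occ[1L, 1L] <- 1
  p_rel_on <- sapply(0:5, function(t)
    monthly_relapse_prob(t, profile$relapse, config$placebo_relapse))
  p_rel_off <- sapply(0:5, function(t)
    monthly_relapse_prob(t, config$placebo_relapse))
  p_rec <- 1 - (1 - config$annual_recurrence_prob)^(1 / 12)
  for (cyc in seq_len(H)) {
    age <- floor(config$econ$start_age_years + (cyc - 1) / 12)
    q_m <- 1 - (1 - lt[[as.character(age)]])^(1 / 12)
    q_ep <- 1 - (1 - q_m)^config$mortality$episode_mortality_rr
    new <- state
    alive <- state != 16L
    in_ep <- state %in% c(1L, 8L)
    die <- runif(n) < ifelse(in_ep, q_ep, q_m)
    dies <- alive & die
    new[dies] <- 16L
    live <- alive & !die

    idx <- which(live & state == 1L)            # episode on treatment
    if (length(idx)) {
      rem <- runif(length(idx)) < profile$monthly_remission_prob
      dis <- runif(length(idx)) < profile$monthly_discontinuation_prob
      new[idx[rem & !dis]] <- 2L                # remission on tx, month 1
      new[idx[!rem & dis]] <- 8L                # episode off tx
      new[idx[rem & dis]] <- 9L                 # remit then discontinue
    }
    for (m in 1:6) {                            # remission on treatment
      idx <- which(live & state == (1L + m))
      if (!length(idx)) next
      rel <- runif(length(idx)) < p_rel_on[m]
      dis <- runif(length(idx)) < profile$monthly_discontinuation_prob
      new[idx[rel]] <- 1L
      new[idx[!rel & dis]] <- 8L + m            # same tunnel month, off tx
      new[idx[!rel & !dis]] <- if (m < 6) 2L + m else 15L
    }
    idx <- which(live & state == 8L)            # episode off treatment
    if (length(idx)) {
      rem <- runif(length(idx)) < config$off_treatment_remission_prob
      new[idx[rem]] <- 9L
    }
    for (m in 1:6) {                            # remission off treatment
      idx <- which(live & state == (8L + m))
      if (!length(idx)) next
      rel <- runif(length(idx)) < p_rel_off[m]
      new[idx[rel]] <- 1L                       # relapse resumes original drug
      new[idx[!rel]] <- if (m < 6) 9L + m else 15L
    }
    idx <- which(live & state == 15L)           # well
    if (length(idx)) {
      rec <- runif(length(idx)) < p_rec
      new[idx[rec]] <- 1L
    }
    state <- new
    occ[cyc + 1L, ] <- tabulate(state, 16L) / n
  }
  occ
}
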