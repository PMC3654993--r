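# Cohort engine: expanded 16-state space (remission split into six monthly
# tunnel states so the six-months-to-well rule and the remission-time
# relapse clock fit a memoryless chain), per-cycle transition matrices, and
# forward cohort propagation with cost/QALY accrual streams.

N_TUNNEL <- 6L
S_EP_ON <- 1L
S_REM_ON <- 2L:7L
S_EP_OFF <- 8L
S_REM_OFF <- 9L:14L
S_WELL <- 15L
S_DEAD <- 16L
S_ON_TX <- c(S_EP_ON, S_REM_ON)          # states where drug is administered
S_OFF_TX <- c(S_EP_OFF, S_REM_OFF)
S_EPISODE <- c(S_EP_ON, S_EP_OFF)        # states with excess suicide mortality

# When remission and discontinuation both occur in one episode cycle the
# joint mass is routed "remit then discontinue", i.e. to off-treatment
# remission. Pinned by a test; the alternative (on-treatment remission) is
# not decidable from the published description.
BOTH_EVENTS_TO_OFF_REMISSION <- TRUE

# Model cycles at which hepatic monitoring (agomelatine) is billed: weeks
# 3, 6, 12 and 24 mapped to months 1, 2, 3 and 6 of time on treatment.
HEPATIC_MONITORING_CYCLES <- c(1L, 2L, 3L, 6L)

#' Model state space
#'
#' The 16 expanded states, in matrix order: depressive episode on
#' treatment; remission on treatment, tunnel months 1–6; depressive episode
#' off treatment; remission off treatment, tunnel months 1–6; well; dead.
#'
#' @return Character vector of 16 state labels.
#' @export
state_space <- function() {
  c("EpisodeOnTx", paste0("RemissionOnTx", 1:N_TUNNEL),
    "EpisodeOffTx", paste0("RemissionOffTx", 1:N_TUNNEL),
    "Well", "Dead")
}

#' Per-cycle transition matrix
#'
#' Builds the row-stochastic 16x16 transition matrix for one monthly cycle.
#' Death is resolved first: the monthly background probability comes from
#' the life table at the current (integer) age, multiplied on the rate
#' scale by `episode_mortality_rr` in the two depressive-episode states.
#' Surviving mass then moves: from the on-treatment episode, remission and
#' discontinuation compete multiplicatively (both-events mass goes to
#' off-treatment remission); from on-treatment remission tunnel month `m`,
#' relapse (at the arm's curve evaluated at `m - 1` months in remission)
#' returns to the on-treatment episode, the non-relapsing mass may
#' discontinue, and the remainder advances (month 6 exits to well). The
#' off-treatment mirror uses the untreated remission probability and the
#' placebo relapse curve, with no discontinuation; relapse off treatment
#' and recurrence from well both return to the on-treatment episode state
#' (patients resume their original drug). Dead is absorbing.
#'
#' @param profile A [treatment_profile()].
#' @param config A [model_config()].
#' @param cycle Month index (0-based cycle start); retained for interface
#'   stability, the matrix depends on time only through `age`.
#' @param age Age in years at cycle start; must be covered by the life
#'   table.
#' @return A 16x16 row-stochastic matrix with dimnames [state_space()].
#' @export
build_transition_matrix <- function(profile, config, cycle, age) {
  lt <- config$mortality$life_table
  key <- as.character(floor(age))
  if (!key %in% names(lt))
    stop("coverage error: age ", floor(age), " outside the life table",
         call. = FALSE)
  q_annual <- lt[[key]]
  q_m <- annual_to_monthly_prob(q_annual)
  q_ep <- apply_rr_to_prob(q_m, config$mortality$episode_mortality_rr)

  p_rem <- profile$monthly_remission_prob
  p_disc <- profile$monthly_discontinuation_prob
  p_rem_off <- config$off_treatment_remission_prob
  p_rec <- annual_to_monthly_prob(config$annual_recurrence_prob)
  m_idx <- seq_len(N_TUNNEL)
  p_rel_on <- monthly_relapse_prob(m_idx - 1, profile$relapse,
                                   config$placebo_relapse)
  p_rel_off <- monthly_relapse_prob(m_idx - 1, config$placebo_relapse)

  M <- matrix(0, 16L, 16L, dimnames = list(state_space(), state_space()))

  s <- 1 - q_ep  # episode-state survivors
  M[S_EP_ON, S_DEAD] <- q_ep
  M[S_EP_ON, S_REM_ON[1]] <- s * p_rem * (1 - p_disc)
  M[S_EP_ON, S_EP_OFF] <- s * p_disc * (1 - p_rem)
  both <- s * p_rem * p_disc
  if (BOTH_EVENTS_TO_OFF_REMISSION) {
    M[S_EP_ON, S_REM_OFF[1]] <- both
  } else {
    M[S_EP_ON, S_REM_ON[1]] <- M[S_EP_ON, S_REM_ON[1]] + both
  }
  M[S_EP_ON, S_EP_ON] <- s * (1 - p_rem) * (1 - p_disc)

  sr <- 1 - q_m  # non-episode survivors
  for (m in m_idx) {
    from <- S_REM_ON[m]
    nxt <- if (m < N_TUNNEL) S_REM_ON[m + 1] else S_WELL
    M[from, S_DEAD] <- q_m
    M[from, S_EP_ON] <- sr * p_rel_on[m]
    M[from, S_REM_OFF[m]] <- sr * (1 - p_rel_on[m]) * p_disc
    M[from, nxt] <- M[from, nxt] + sr * (1 - p_rel_on[m]) * (1 - p_disc)
  }

  M[S_EP_OFF, S_DEAD] <- q_ep
  M[S_EP_OFF, S_REM_OFF[1]] <- s * p_rem_off
  M[S_EP_OFF, S_EP_OFF] <- s * (1 - p_rem_off)

  for (m in m_idx) {
    from <- S_REM_OFF[m]
    nxt <- if (m < N_TUNNEL) S_REM_OFF[m + 1] else S_WELL
    M[from, S_DEAD] <- q_m
    M[from, S_EP_ON] <- sr * p_rel_off[m]
    M[from, nxt] <- M[from, nxt] + sr * (1 - p_rel_off[m])
  }

  M[S_WELL, S_DEAD] <- q_m
  M[S_WELL, S_EP_ON] <- sr * p_rec
  M[S_WELL, S_WELL] <- sr * (1 - p_rec)

  M[S_DEAD, S_DEAD] <- 1

  rs <- rowSums(M)
  if (any(abs(rs - 1) > 1e-9))
    stop("internal assertion failure: transition rows do not sum to 1",
         call. = FALSE)
  M
}

state_utilities <- function(config) {
  sv <- config$state_values
  u <- numeric(16L)
  u[S_EPISODE] <- sv$utility_episode
  u[c(S_REM_ON, S_REM_OFF)] <- sv$utility_remission
  u[S_WELL] <- sv$utility_well
  u
}

#' Per-cycle accruals for one occupancy row
#'
#' Computes the QALY and cost accruals for a single cycle, given the
#' end-of-cycle occupancy row. QALYs accrue as occupancy x state utility
#' / 12, with expected adverse-drug-reaction (ADR) disutility subtracted
#' from the state utility (floored at zero with a warning) in on-treatment
#' states only; the sleep-disorder term counts only in the episode state.
#' A one-time discontinuation-symptom disutility (decrement x one week) and
#' management cost apply to the occupancy flow into off-treatment states
#' this cycle, weighted by the arm's symptom probability. Cost streams:
#' direct medical (state costs plus discontinuation-symptom management),
#' indirect/productivity (state indirect costs; included in totals only
#' under the societal perspective), medication (standard price in cycle 1,
#' dose-escalated thereafter, on-treatment occupancy), expected ADR
#' management, and hepatic monitoring (billed at treatment months 1, 2, 3
#' and 6 when the arm requires it).
#'
#' @param occupancy_row Numeric vector of 16 state fractions summing to 1.
#' @param profile A [treatment_profile()].
#' @param config A [model_config()].
#' @param cycle Cycle index (1-based month).
#' @param off_flow Fraction of the cohort flowing from on-treatment into
#'   off-treatment states during this cycle.
#' @return Named numeric vector: `qaly`, `direct_cost`, `indirect_cost`,
#'   `drug_cost`, `adr_cost`, `monitoring_cost`.
#' @export
compute_cycle_accruals <- function(occupancy_row, profile, config, cycle,
                                   off_flow = 0) {
  if (abs(sum(occupancy_row) - 1) > 1e-9)
    stop("internal assertion failure: occupancy row does not sum to 1",
         call. = FALSE)
  econ <- config$econ
  u <- state_utilities(config)
  dis <- numeric(16L)
  dis[S_EP_ON] <- expected_adr_disutility(profile, config$adr_table,
                                          include_sleep = TRUE)
  dis[S_REM_ON] <- expected_adr_disutility(profile, config$adr_table,
                                           include_sleep = FALSE)
  u_eff <- u - dis
  if (any(u_eff < 0 & occupancy_row > 0)) {
    warning("ADR disutility exceeds state utility; clamped at 0", call. = FALSE)
    u_eff <- pmax(u_eff, 0)
  }
  week_frac <- econ$discontinuation_symptom_duration_days / econ$days_per_month
  sympt_events <- off_flow * profile$discontinuation_symptom_prob
  qaly <- sum(occupancy_row * u_eff) / 12 -
    sympt_events * config$discontinuation_symptom_decrement * week_frac / 12

  sv <- config$state_values
  direct <- numeric(16L)
  direct[S_EPISODE] <- sv$direct_cost_episode
  direct[c(S_REM_ON, S_REM_OFF)] <- sv$direct_cost_remission
  indirect <- numeric(16L)
  indirect[S_EPISODE] <- sv$indirect_cost_episode
  indirect[c(S_REM_ON, S_REM_OFF)] <- sv$indirect_cost_remission

  on_tx_occ <- sum(occupancy_row[S_ON_TX])
  drug <- on_tx_occ * medication_cost(profile, cycle)
  adr <- occupancy_row[S_EP_ON] *
    expected_adr_cost(profile, config$adr_table, include_sleep = TRUE) +
    sum(occupancy_row[S_REM_ON]) *
    expected_adr_cost(profile, config$adr_table, include_sleep = FALSE)
  monitoring <- if (isTRUE(profile$hepatic_monitoring) &&
                    cycle %in% HEPATIC_MONITORING_CYCLES)
    on_tx_occ * config$hepatic_test_cost else 0

  c(qaly = qaly,
    direct_cost = sum(occupancy_row * direct) +
      sympt_events * config$discontinuation_symptom_cost,
    indirect_cost = sum(occupancy_row * indirect),
    drug_cost = drug,
    adr_cost = adr,
    monitoring_cost = monitoring)
}

#' Run the cohort model for one treatment arm
#'
#' Propagates a unit cohort, starting in the on-treatment depressive
#' episode state at the configured entry age, through `horizon_cycles`
#' monthly transitions, accruing per-cycle QALY and cost streams at cycle
#' end (no half-cycle correction). Age advances by 1/12 year per cycle;
#' transition matrices are rebuilt whenever the integer age changes.
#'
#' @param profile A [treatment_profile()].
#' @param config A [model_config()].
#' @return A `cohort_trace`: list with `occupancy`
#'   ((horizon+1) x 16 matrix, rows summing to 1), `accruals` (horizon x 6
#'   matrix of per-cycle streams), `off_flow` (per-cycle flow into
#'   off-treatment states) and `profile_name`.
#' @export
run_cohort <- function(profile, config) {
  H <- config$econ$horizon_cycles
  occ <- matrix(0, H + 1L, 16L, dimnames = list(0:H, state_space()))
  occ[1L, S_EP_ON] <- 1
  acc <- matrix(0, H, 6L, dimnames = list(
    1:H, c("qaly", "direct_cost", "indirect_cost", "drug_cost",
           "adr_cost", "monitoring_cost")))
  off_flow <- numeric(H)
  cache <- list()
  for (t in seq_len(H)) {
    age <- config$econ$start_age_years + (t - 1) / 12
    key <- as.character(floor(age))
    M <- cache[[key]]
    if (is.null(M)) {
      M <- build_transition_matrix(profile, config, t - 1L, age)
      cache[[key]] <- M
    }
    prev <- occ[t, ]
    occ[t + 1L, ] <- prev %*% M
    off_flow[t] <- sum(prev[S_ON_TX] %*% M[S_ON_TX, S_OFF_TX, drop = FALSE])
    acc[t, ] <- compute_cycle_accruals(occ[t + 1L, ], profile, config, t,
                                       off_flow = off_flow[t])
  }
  if (any(occ < -1e-12) || any(abs(rowSums(occ) - 1) > 1e-9))
    stop("internal assertion failure: occupancy not conserved", call. = FALSE)
  structure(list(occupancy = occ, accruals = acc, off_flow = off_flow,
                 profile_name = profile$name),
            class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  H <- nrow(x$accruals)
  cat(sprintf("<cohort_trace> %s: %d cycles; final occupancy well %.3f, dead %.4f\n",
              x$profile_name, H, x$occupancy[H + 1, S_WELL],
              x$occupancy[H + 1, S_DEAD]))
  invisible(x)
}

#' Export a cohort trace as CSV
#'
#' One row per cycle (cycle 0 carries the initial occupancy and zero
#' accruals); columns are `cycle`, the 16 state occupancies in
#' [state_space()] order, then the six accrual streams.
#'
#' @param trace A [run_cohort()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  H <- nrow(trace$accruals)
  acc <- rbind(matrix(0, 1, ncol(trace$accruals),
                      dimnames = list(NULL, colnames(trace$accruals))),
               trace$accruals)
  d <- data.frame(cycle = 0:H, trace$occupancy, acc, check.names = FALSE)
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}
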