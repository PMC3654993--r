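test_that("transition matrices are row-stochastic with the intended entries", {
  cfg <- base_case_config()
  ago <- cfg$treatments[["Agomelatine"]]
  M <- build_transition_matrix(ago, cfg, cycle = 0, age = 45)
  expect_equal(dim(M), c(16L, 16L))
  expect_equal(unname(rowSums(M)), rep(1, 16), tolerance = 1e-12)
  expect_true(all(M >= 0))
  expect_equal(unname(M["Dead", ]), c(rep(0, 15), 1))

  # episode death entry equals 1 - (1 - q_month)^rr, by independent arithmetic
  q_annual <- cfg$mortality$life_table[["45"]]
  q_month <- 1 - (1 - q_annual)^(1 / 12)
  expect_equal(M["EpisodeOnTx", "Dead"], 1 - (1 - q_month)^20.35,
               tolerance = 1e-14)
  expect_equal(M["EpisodeOffTx", "Dead"], 1 - (1 - q_month)^20.35,
               tolerance = 1e-14)
  expect_equal(M["Well", "Dead"], q_month, tolerance = 1e-14)

  # both-events mass (remit and discontinue) routes to off-treatment remission
  s <- (1 - q_month)^20.35  # episode-state survivors
  expect_equal(M["EpisodeOnTx", "RemissionOffTx1"],
               s * ago$monthly_remission_prob * ago$monthly_discontinuation_prob,
               tolerance = 1e-14)

  expect_error(build_transition_matrix(ago, cfg, 0, age = 300),
               "coverage error")
})

test_that("no-event configuration gives pure tunnel advancement", {
  cfg <- toy_config(p_rem = 0, p_disc = 0, recurrence = 0)
  M <- build_transition_matrix(cfg$treatments$A, cfg, 0, 45)
  expect_equal(M["EpisodeOnTx", "EpisodeOnTx"], 1, tolerance = 1e-9)
  for (m in 1:5)
    expect_equal(M[paste0("RemissionOnTx", m), paste0("RemissionOnTx", m + 1)],
                 1, tolerance = 1e-9)
  expect_equal(M["RemissionOnTx6", "Well"], 1, tolerance = 1e-9)
  expect_equal(M["Well", "Well"], 1, tolerance = 1e-9)
})

test_that("deterministic path reaches well after the six-month tunnel", {
  cfg <- toy_config(p_rem = 1, p_disc = 0)
  trace <- run_cohort(cfg$treatments$A, cfg)
  # cycle 1 enters remission month 1; month 6 completed at cycle 6; well at 7
  expect_equal(trace$occupancy["6", "RemissionOnTx6"], 1, tolerance = 1e-9)
  expect_equal(trace$occupancy["7", "Well"], 1, tolerance = 1e-9)
  expect_equal(trace$occupancy["24", "Well"], 1, tolerance = 1e-9)
})

test_that("three-cycle occupancy matches a hand forward calculation", {
  cfg <- toy_config(p_rem = 0.5, p_disc = 0.2)
  trace <- run_cohort(cfg$treatments$A, cfg)
  occ <- trace$occupancy
  # cycle 1: split of the episode mass (death-free), computed by hand
  expect_equal(unname(occ["1", c("EpisodeOnTx", "RemissionOnTx1",
                                 "EpisodeOffTx", "RemissionOffTx1")]),
               c(0.4, 0.4, 0.1, 0.1), tolerance = 1e-9)
  # cycle 2
  expect_equal(unname(occ["2", c("EpisodeOnTx", "RemissionOnTx1",
                                 "RemissionOnTx2", "EpisodeOffTx",
                                 "RemissionOffTx1", "RemissionOffTx2")]),
               c(0.16, 0.16, 0.32, 0.14, 0.12, 0.10), tolerance = 1e-9)
  # cycle 3
  expect_equal(unname(occ["3", c("EpisodeOnTx", "RemissionOnTx1",
                                 "RemissionOnTx2", "RemissionOnTx3",
                                 "EpisodeOffTx", "RemissionOffTx1",
                                 "RemissionOffTx2", "RemissionOffTx3")]),
               c(0.064, 0.064, 0.128, 0.256, 0.156, 0.048, 0.184, 0.10),
               tolerance = 1e-9)
})

test_that("occupancy is conserved and death is absorbing on the base case", {
  cfg <- base_case_config()
  for (nm in c("Agomelatine", "Venlafaxine")) {
    trace <- run_cohort(cfg$treatments[[nm]], cfg)
    expect_equal(unname(rowSums(trace$occupancy)), rep(1, 25),
                 tolerance = 1e-9)
    expect_true(all(trace$occupancy >= -1e-12))
    expect_true(all(diff(trace$occupancy[, "Dead"]) >= -1e-15))
  }
})

test_that("per-cycle accruals decompose as expected", {
  cfg <- base_case_config()
  venla <- cfg$treatments[["Venlafaxine"]]
  dead <- c(rep(0, 15), 1)
  expect_equal(unname(compute_cycle_accruals(dead, venla, cfg, 1)),
               rep(0, 6))

  well <- replace(rep(0, 16), 15, 1)
  acc <- compute_cycle_accruals(well, venla, cfg, 1)
  expect_equal(acc[["qaly"]], 0.86 / 12, tolerance = 1e-12)
  expect_equal(sum(acc[-1]), 0)

  # all mass in the on-treatment episode: hand-summed component oracle
  ep <- replace(rep(0, 16), 1, 1)
  acc <- compute_cycle_accruals(ep, venla, cfg, cycle = 1)
  expect_equal(acc[["direct_cost"]], 190)
  expect_equal(acc[["indirect_cost"]], 380)
  expect_equal(acc[["drug_cost"]], 18.03)
  adr_hand <- 0.042 * 12.5 + 0.024 * 12.0 + 0.018 * 5.5 + 0.226 * 6.0 +
    0.048 * 0.0 + 0.119 * 2.8 + 0.018 * 44.0 + 0.024 * 54.0
  expect_equal(acc[["adr_cost"]], adr_hand, tolerance = 1e-12)
  dis_hand <- 0.042 * 0.065 + 0.024 * 0.086 + 0.018 * 0.044 + 0.226 * 0.065 +
    0.048 * 0.085 + 0.119 * 0.115 + 0.018 * 0.049 + 0.024 * 0.08095
  expect_equal(acc[["qaly"]], (0.57 - dis_hand) / 12, tolerance = 1e-12)

  # dose escalation reflected from cycle 2 onwards
  acc2 <- compute_cycle_accruals(ep, venla, cfg, cycle = 2)
  expect_equal(acc2[["drug_cost"]], 18.03 * 1.118, tolerance = 1e-12)

  # hepatic monitoring billed at treatment months 1, 2, 3 and 6 only
  ago <- cfg$treatments[["Agomelatine"]]
  mon <- sapply(1:8, function(cy)
    compute_cycle_accruals(ep, ago, cfg, cy)[["monitoring_cost"]])
  expect_equal(mon, c(75, 75, 75, 0, 0, 75, 0, 0))

  # discontinuation-symptom flow terms
  accf <- compute_cycle_accruals(ep, venla, cfg, 1, off_flow = 0.3)
  expect_equal(accf[["direct_cost"]] - acc[["direct_cost"]],
               0.3 * 0.20 * 52, tolerance = 1e-12)
  expect_equal(acc[["qaly"]] - accf[["qaly"]],
               0.3 * 0.20 * 0.065 * (7 / 30) / 12, tolerance = 1e-12)
})

test_that("sleep disorder counts only in on-treatment episode accruals", {
  cfg <- base_case_config()
  venla <- cfg$treatments[["Venlafaxine"]]
  adr <- cfg$adr_table
  rem <- replace(rep(0, 16), 2, 1)   # remission on treatment, month 1
  acc <- compute_cycle_accruals(rem, venla, cfg, 1)
  d_nosleep <- expected_adr_disutility(venla, adr, include_sleep = FALSE)
  c_nosleep <- expected_adr_cost(venla, adr, include_sleep = FALSE)
  expect_equal(acc[["qaly"]], (0.81 - d_nosleep) / 12, tolerance = 1e-12)
  expect_equal(acc[["adr_cost"]], c_nosleep, tolerance = 1e-12)

  # off treatment no drug is taken: no drug or ADR costs, no ADR disutility
  ep_off <- replace(rep(0, 16), 8, 1)
  acc_off <- compute_cycle_accruals(ep_off, venla, cfg, 1)
  expect_equal(acc_off[["drug_cost"]], 0)
  expect_equal(acc_off[["adr_cost"]], 0)
  expect_equal(acc_off[["qaly"]], 0.57 / 12, tolerance = 1e-12)
})

test_that("raising the remission probability never lowers total QALYs", {
  cfg <- base_case_config()
  path <- "treatments/Fluoxetine/monthly_remission_prob"
  q <- sapply(seq(0.1, 0.9, by = 0.2), function(p) {
    c2 <- config_set(cfg, path, p)
    run_cohort(c2$treatments[["Fluoxetine"]], c2)
    summarize_arm(run_cohort(c2$treatments[["Fluoxetine"]], c2),
                  c2$treatments[["Fluoxetine"]], c2)$total_qalys
  })
  expect_true(all(diff(q) >= 0))
})

test_that("trace CSV export has the documented layout", {
  cfg <- toy_config(horizon = 6L)
  trace <- run_cohort(cfg$treatments$A, cfg)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(trace, f)
  d <- read.csv(f, check.names = FALSE)
  expect_equal(names(d), c("cycle", state_space(),
                           colnames(trace$accruals)))
  expect_equal(nrow(d), 7L)
  expect_equal(d$EpisodeOnTx[1], 1)
  expect_equal(unname(rowSums(d[, state_space()])), rep(1, 7),
               tolerance = 1e-9)
})
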