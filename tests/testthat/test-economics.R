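test_that("expected ADR burden sums frequency times decrement/cost", {
  cfg <- base_case_config()
  adr <- cfg$adr_table
  ago <- cfg$treatments[["Agomelatine"]]
  sert <- cfg$treatments[["Sertraline"]]

  expect_equal(round(expected_adr_disutility(ago, adr, FALSE), 3), 0.026)
  expect_equal(round(expected_adr_disutility(
    cfg$treatments[["Venlafaxine"]], adr, FALSE), 3), 0.039)

  # hand-summed oracle, sleep disorder included
  sert_hand <- 0.006 * 0.065 + 0.013 * 0.086 + 0.057 * 0.044 + 0.044 * 0.065 +
    0.013 * 0.085 + 0.101 * 0.115 + 0.019 * 0.049 + 0.019 * 0.08095
  expect_equal(expected_adr_disutility(sert, adr, TRUE), sert_hand,
               tolerance = 1e-12)
  sert_cost_hand <- 0.006 * 12.5 + 0.013 * 12.0 + 0.057 * 5.5 + 0.044 * 6.0 +
    0.013 * 0.0 + 0.101 * 2.8 + 0.019 * 44.0 + 0.019 * 54.0
  expect_equal(expected_adr_cost(sert, adr, TRUE), sert_cost_hand,
               tolerance = 1e-12)

  zero <- ago; zero$adr_monthly_freq[] <- 0
  expect_equal(expected_adr_disutility(zero, adr, TRUE), 0)
  expect_equal(expected_adr_cost(zero, adr, TRUE), 0)

  # somnolence is not treated: frequency contributes no cost
  som <- ago; som$adr_monthly_freq[] <- 0
  som$adr_monthly_freq[["somnolence"]] <- 1
  expect_equal(expected_adr_cost(som, adr, TRUE), 0)
  expect_equal(expected_adr_disutility(som, adr, TRUE), 0.085)

  bad <- ago; names(bad$adr_monthly_freq)[1] <- "rash"
  expect_error(expected_adr_disutility(bad, adr), "validation error")
})

test_that("medication cost escalates from the second treatment cycle", {
  cfg <- base_case_config()
  ago <- cfg$treatments[["Agomelatine"]]
  expect_equal(medication_cost(ago, 1), 60.27)
  expect_equal(round(medication_cost(ago, 2), 2), 73.59)
  expect_equal(medication_cost(ago, 24), 60.27 * 1.221, tolerance = 1e-12)
  escit <- cfg$treatments[["Escitalopram"]]
  expect_equal(medication_cost(escit, 1), 56.31)
  expect_equal(medication_cost(escit, 9), 56.31)
  expect_error(medication_cost(ago, 0), "parameter error")
})

test_that("discounting starts after the first year", {
  expect_equal(discount_factor(6, 0.035), 1)
  expect_equal(discount_factor(12, 0.035), 1)
  expect_equal(discount_factor(24, 0.035), 1 / 1.035, tolerance = 1e-12)
  expect_equal(discount_factor(18, 0.035), 1.035^(-0.5), tolerance = 1e-12)
  expect_equal(discount_factor(1:24, 0), rep(1, 24))
  # discounted totals never exceed undiscounted ones
  cfg <- base_case_config()
  ago <- cfg$treatments[["Agomelatine"]]
  trace <- run_cohort(ago, cfg)
  disc <- summarize_arm(trace, ago, cfg)
  cfg0 <- cfg; cfg0$econ$annual_discount_rate <- 0
  undisc <- summarize_arm(trace, ago, cfg0)
  expect_lt(disc$total_cost, undisc$total_cost)
  expect_lt(disc$total_qalys, undisc$total_qalys)
})

test_that("arm summaries are internally consistent", {
  cfg <- base_case_config()
  for (nm in names(cfg$treatments)[1:3]) {
    arm <- run_all_arms(cfg)[[nm]]
    expect_equal(sum(arm$components), arm$total_cost, tolerance = 1e-9)
  }
  # payer perspective drops the indirect component
  cfgp <- cfg; cfgp$econ$perspective <- "payer"
  ago <- cfgp$treatments[["Agomelatine"]]
  trace <- run_cohort(ago, cfgp)
  soc <- summarize_arm(trace, ago, cfg)
  pay <- summarize_arm(trace, ago, cfgp)
  expect_equal(pay$components[["indirect"]], 0)
  expect_equal(soc$total_cost - soc$components[["indirect"]], pay$total_cost,
               tolerance = 1e-9)
  expect_equal(soc$total_qalys, pay$total_qalys)

  # one-cycle horizon, full mass in episode, payer, no drug/ADR: state cost only
  cfg1 <- toy_config(p_rem = 0, p_disc = 0, horizon = 1L,
                     perspective = "payer", drug_cost = 0)
  a <- cfg1$treatments$A
  res <- summarize_arm(run_cohort(a, cfg1), a, cfg1)
  expect_equal(res$total_cost, 190)

  expect_error(summarize_arm(run_cohort(a, cfg1), a, base_case_config()),
               "consistency error")
})

test_that("component sums equal totals across random scenarios", {
  for (seed in 1:15) {
    cfg <- random_scenario(seed, n_treatments = 2)
    for (arm in run_all_arms(cfg))
      expect_equal(sum(arm$components), arm$total_cost, tolerance = 0.01)
  }
})

test_that("incremental analysis labels dominance and reports NMB", {
  a <- arm_result("A", 5434, 1.461)
  b <- arm_result("B", 5462, 1.447)
  ce <- incremental_analysis(a, b, thresholds = c(40000, 50000))
  expect_equal(ce$delta_cost, -28)
  expect_equal(ce$label, "dominant")
  expect_true(is.na(ce$icer))
  expect_equal(unname(ce$nmb), c(40000, 50000) * 0.014 + 28, tolerance = 1e-9)

  ce2 <- incremental_analysis(arm_result("A", 114, 1.0),
                              arm_result("B", 100, 0.974))
  expect_equal(ce2$icer, 14 / 0.026, tolerance = 1e-9)
  expect_equal(ce2$label, "icer")

  same <- incremental_analysis(a, a)
  expect_equal(same$delta_cost, 0)
  expect_equal(same$delta_qalys, 0)
  expect_true(is.na(same$icer))
  expect_equal(unname(same$nmb), rep(0, 3))

  # antisymmetry
  fwd <- incremental_analysis(a, b); rev <- incremental_analysis(b, a)
  expect_equal(fwd$delta_cost, -rev$delta_cost)
  expect_equal(fwd$delta_qalys, -rev$delta_qalys)
  expect_equal(rev$label, "dominated")

  # dominance truth table over the four quadrants
  mk <- function(dc, dq) incremental_analysis(
    arm_result("A", 100 + dc, 1 + dq), arm_result("B", 100, 1))
  expect_equal(mk(-10, 0.1)$label, "dominant")
  expect_equal(mk(10, -0.1)$label, "dominated")
  expect_equal(mk(10, 0.1)$label, "icer")
  expect_equal(mk(10, 0.1)$icer, 100)
  expect_equal(mk(-10, -0.1)$label, "icer")
  expect_equal(mk(-10, -0.1)$icer, 100)

  # NMB affine increasing in the threshold when QALYs are gained
  lam <- c(1e4, 3e4, 6e4)
  nmb <- incremental_analysis(a, b, thresholds = lam)$nmb
  expect_true(all(diff(nmb) > 0))
  expect_equal(unname(diff(nmb) / diff(lam)), rep(0.014, 2), tolerance = 1e-9)
})

test_that("base-case table compares the reference against every arm", {
  cfg <- base_case_config()
  tab <- base_case_table(cfg)
  expect_equal(nrow(tab), 9L)
  expect_equal(tab$label[1], "reference")
  expect_true(all(tab$delta_qalys[-1] != 0))
  expect_error(base_case_table(cfg, reference = "Placebo"), "unknown")
})
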