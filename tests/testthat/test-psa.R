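test_that("distribution assignment follows the nature of each parameter", {
  cfg <- base_case_config()
  d <- assign_distributions(cfg, sd_rule = 0.10)
  get <- function(p) d[d$path == p, ]

  u <- get("state_values/utility_remission")
  expect_equal(u$family, "beta")
  expect_equal(u$mean, 0.81)
  expect_equal(u$sd, 0.081)

  rr <- get("treatments/Fluoxetine/relapse/rr")
  expect_equal(rr$family, "lognormal")
  expect_equal(rr$mean, 0.513)
  expect_equal(rr$sd, 0.0513)

  # degenerate boundary means become fixed point masses
  expect_equal(get("treatments/Agomelatine/discontinuation_symptom_prob")$family,
               "fixed")
  expect_equal(get("treatments/Escitalopram/double_dose_fraction")$family,
               "fixed")
  expect_equal(get("adr_table/somnolence/monthly_cost")$family, "fixed")

  expect_equal(get("state_values/direct_cost_episode")$family, "lognormal")
  expect_equal(get("mortality/episode_mortality_rr")$family, "lognormal")
  expect_true(all(d$family %in% c("beta", "lognormal", "fixed")))
  expect_true(all(d$sd[d$family == "fixed"] == 0))
})

test_that("method-of-moments fits hit the requested moments", {
  b <- moment_match("beta", 0.5, 0.05)
  expect_equal(b$alpha, 49.5, tolerance = 1e-12)
  expect_equal(b$beta, 49.5, tolerance = 1e-12)

  ln <- moment_match("lognormal", 1, 0.1)
  expect_equal(ln$sigma^2, log(1.01), tolerance = 1e-12)
  expect_equal(ln$mu, -log(1.01) / 2, tolerance = 1e-12)

  expect_equal(moment_match("beta", 0.3, 0)$family, "fixed")
  expect_error(moment_match("beta", 0.5, 0.6), "infeasible-moments")
  expect_error(moment_match("lognormal", -1, 0.1), "infeasible-moments")

  # sampled moments approach the targets (checked tightly in acceptance)
  set.seed(4)
  x <- sample_distribution(moment_match("beta", 0.81, 0.081), 2e4)
  expect_equal(mean(x), 0.81, tolerance = 0.01)
  y <- sample_distribution(moment_match("lognormal", 18.03, 1.803), 2e4)
  expect_equal(mean(y), 18.03, tolerance = 0.02)
})

test_that("zero-variance PSA reproduces the base case bitwise", {
  cfg <- base_case_config()
  d <- assign_distributions(cfg)
  d$family <- "fixed"; d$sd <- 0
  res <- run_psa(cfg, n = 3, seed = 9, distributions = d)
  arms <- run_all_arms(cfg)
  ref <- arms[["Agomelatine"]]
  for (cm in unique(res$draws$comparator)) {
    dd <- res$draws[res$draws$comparator == cm, ]
    expect_identical(dd$delta_cost,
                     rep(ref$total_cost - arms[[cm]]$total_cost, 3))
    expect_identical(dd$delta_qaly,
                     rep(ref$total_qalys - arms[[cm]]$total_qalys, 3))
  }
})

test_that("PSA is seed-reproducible and draws stay near the base case", {
  cfg <- random_scenario(3, n_treatments = 3)
  r1 <- run_psa(cfg, n = 8, seed = 5)
  r2 <- run_psa(cfg, n = 8, seed = 5)
  expect_identical(r1$draws, r2$draws)
  r3 <- run_psa(cfg, n = 8, seed = 6)
  expect_false(identical(r1$draws, r3$draws))
  expect_equal(nrow(r1$draws), 8 * 2)

  # mean incremental QALYs over seeded draws sit within Monte Carlo error
  # of the base-case increment (mild-skew sanity check)
  cfgb <- base_case_config()
  cfgb$treatments <- cfgb$treatments[c("Agomelatine", "Venlafaxine")]
  res <- run_psa(cfgb, n = 120, seed = 21)
  base <- run_scenario(cfgb, character(0), c("Agomelatine", "Venlafaxine"))
  dq <- res$draws$delta_qaly
  se <- sd(dq) / sqrt(length(dq))
  expect_lt(abs(mean(dq) - base$delta_qalys), 3 * se)

  expect_error(run_psa(cfgb, n = 0), "parameter error")
})

test_that("acceptability curves match a brute-force recount", {
  cfg <- random_scenario(8, n_treatments = 2)
  res <- run_psa(cfg, n = 25, seed = 2)
  cm <- unique(res$draws$comparator)[1]
  grid <- seq(0, 80000, by = 10000)
  cv <- ceac(res, cm, grid)
  d <- res$draws[res$draws$comparator == cm, ]
  for (i in seq_along(grid)) {
    recount <- sum(grid[i] * d$delta_qaly - d$delta_cost >= 0) / nrow(d)
    expect_identical(cv$prob_cost_effective[i], recount)
  }
  expect_identical(attr(cv, "prob_dominant"),
                   mean(d$delta_cost < 0 & d$delta_qaly > 0))
  expect_true(all(cv$prob_cost_effective >= 0 & cv$prob_cost_effective <= 1))

  # CEAC at lambda = 0 equals P(delta_cost <= 0); monotone when all
  # draws gain QALYs
  expect_identical(ceac(res, cm, c(0, 1))$prob_cost_effective[1],
                   mean(d$delta_cost <= 0))
  if (all(d$delta_qaly >= 0))
    expect_true(all(diff(cv$prob_cost_effective) >= 0))

  # single synthetic draw: step at its own ICER
  one <- res; one$draws <- data.frame(iteration = 1L, comparator = "X",
                                      delta_cost = 100, delta_qaly = 0.01)
  step <- ceac(one, "X", c(9999, 10000, 10001))
  expect_equal(step$prob_cost_effective, c(0, 1, 1))

  expect_error(ceac(res, cm, numeric(0)), "parameter error")
  expect_error(ceac(res, "nope", c(0, 1)), "not in result")
})

test_that("dominance summary recounts stored draws", {
  cfg <- random_scenario(12, n_treatments = 3)
  res <- run_psa(cfg, n = 20, seed = 3)
  ds <- dominance_summary(res)
  expect_equal(nrow(ds), 2L)
  for (i in seq_len(nrow(ds))) {
    d <- res$draws[res$draws$comparator == ds$comparator[i], ]
    expect_equal(ds$prob_dominant[i],
                 mean(d$delta_cost < 0 & d$delta_qaly > 0))
  }
})

test_that("bootstrap intervals behave as percentile intervals", {
  mk_result <- function(dc, dq) structure(
    list(draws = data.frame(iteration = seq_along(dc), comparator = "X",
                            delta_cost = dc, delta_qaly = dq)),
    class = "psa_result")

  # constant draws: zero-width interval at the constant
  res <- mk_result(rep(120, 40), rep(0.02, 40))
  bs <- bootstrap_summary(res, n_boot = 50, seed = 1)
  expect_equal(bs$cost_lo, 120); expect_equal(bs$cost_hi, 120)
  expect_equal(bs$qaly_lo, 0.02); expect_equal(bs$qaly_hi, 0.02)

  # the interval contains the sample mean
  set.seed(33)
  for (i in 1:20) {
    res <- mk_result(rnorm(60, 50, 30), rnorm(60, 0.01, 0.02))
    bs <- bootstrap_summary(res, n_boot = 200, seed = i)
    expect_gte(bs$mean_delta_cost, bs$cost_lo)
    expect_lte(bs$mean_delta_cost, bs$cost_hi)
    expect_gte(bs$mean_delta_qaly, bs$qaly_lo)
    expect_lte(bs$mean_delta_qaly, bs$qaly_hi)
  }

  # coverage of the true mean close to nominal for a normal sample
  set.seed(99)
  hits <- 0L; reps <- 500L
  for (i in seq_len(reps)) {
    res <- mk_result(rnorm(150, 100, 40), rnorm(150, 0.01, 0.01))
    bs <- bootstrap_summary(res, n_boot = 300, seed = i)
    if (bs$cost_lo <= 100 && 100 <= bs$cost_hi) hits <- hits + 1L
  }
  expect_gt(hits / reps, 0.92)
  expect_lt(hits / reps, 0.98)

  expect_error(bootstrap_summary(mk_result(1, 0.1), n_boot = 0),
               "parameter error")
})
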