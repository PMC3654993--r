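# Second-order Monte Carlo probabilistic sensitivity analysis: beta /
# lognormal assignment by parameter nature, method-of-moments fitting,
# sampling with shared draws across arms, acceptability curves and
# bootstrap intervals.

#' Assign sampling distributions to configuration parameters
#'
#' Walks the configuration and assigns a distribution family by the nature
#' of each parameter: probabilities and utilities (remission,
#' discontinuation, symptom and ADR frequencies, double-dose fraction,
#' recurrence, state utilities, decrements) follow a beta distribution;
#' relative risks and costs (state costs, drug prices, ADR management,
#' monitoring, the episode mortality multiplier) a lognormal. The standard
#' deviation is `sd_rule` times the mean (default 10%). Means at an exact
#' boundary (0 or 1 for beta; 0 for lognormal) are held fixed. The
#' life-table and the Weibull relapse shape/scale parameters are not
#' sampled.
#'
#' @param config A [model_config()].
#' @param sd_rule Standard deviation as a fraction of the mean.
#' @return Data frame with columns `path`, `family`
#'   (`"beta"`, `"lognormal"` or `"fixed"`), `mean`, `sd`.
#' @export
assign_distributions <- function(config, sd_rule = 0.10) {
  rows <- list()
  add <- function(path, family) {
    m <- config_get(config, path)
    if (family == "beta" && (m < 0 || m > 1))
      stop("assignment error: beta mean outside [0, 1] at ", path,
           call. = FALSE)
    fam <- family
    if ((family == "beta" && (m <= 0 || m >= 1)) ||
        (family == "lognormal" && m <= 0)) fam <- "fixed"
    rows[[length(rows) + 1L]] <<- data.frame(
      path = path, family = fam, mean = m,
      sd = if (fam == "fixed") 0 else sd_rule * m,
      stringsAsFactors = FALSE)
  }
  add("state_values/utility_well", "beta")
  add("state_values/utility_remission", "beta")
  add("state_values/utility_episode", "beta")
  add("state_values/direct_cost_remission", "lognormal")
  add("state_values/indirect_cost_remission", "lognormal")
  add("state_values/direct_cost_episode", "lognormal")
  add("state_values/indirect_cost_episode", "lognormal")
  add("annual_recurrence_prob", "beta")
  add("off_treatment_remission_prob", "beta")
  add("mortality/episode_mortality_rr", "lognormal")
  add("discontinuation_symptom_decrement", "beta")
  add("discontinuation_symptom_cost", "lognormal")
  add("hepatic_test_cost", "lognormal")
  for (a in ADR_NAMES) {
    add(sprintf("adr_table/%s/utility_decrement", a), "beta")
    add(sprintf("adr_table/%s/monthly_cost", a), "lognormal")
  }
  for (nm in names(config$treatments)) {
    tr <- config$treatments[[nm]]
    add(sprintf("treatments/%s/double_dose_fraction", nm), "beta")
    add(sprintf("treatments/%s/monthly_remission_prob", nm), "beta")
    add(sprintf("treatments/%s/monthly_discontinuation_prob", nm), "beta")
    add(sprintf("treatments/%s/discontinuation_symptom_prob", nm), "beta")
    for (a in ADR_NAMES)
      add(sprintf("treatments/%s/adr_monthly_freq/%s", nm, a), "beta")
    add(sprintf("treatments/%s/monthly_drug_cost_standard", nm), "lognormal")
    if (tr$relapse$mode == "rr_vs_placebo")
      add(sprintf("treatments/%s/relapse/rr", nm), "lognormal")
  }
  do.call(rbind, rows)
}

#' Method-of-moments distribution parameters
#'
#' Beta: `alpha = m * (m(1-m)/s^2 - 1)`, `beta = (1-m) * (m(1-m)/s^2 - 1)`,
#' requiring `s^2 < m(1-m)`. Lognormal (moments of the distribution
#' itself, not of log): `sigma^2 = log(1 + s^2/m^2)`,
#' `mu = log(m) - sigma^2/2`. `s = 0` degenerates to a fixed point mass.
#'
#' @param family `"beta"`, `"lognormal"` or `"fixed"`.
#' @param mean,sd Target mean and standard deviation.
#' @return Named list of family parameters (`alpha`/`beta`, `mu`/`sigma`,
#'   or `value` for fixed).
#' @export
#' @examples
#' moment_match("beta", 0.5, 0.05)  # alpha = beta = 49.5
moment_match <- function(family, mean, sd) {
  if (sd < 0) stop("parameter error: sd must be >= 0", call. = FALSE)
  if (sd == 0 || family == "fixed") return(list(family = "fixed", value = mean))
  switch(family,
         beta = {
           if (mean <= 0 || mean >= 1)
             stop("infeasible-moments error: beta mean must lie in (0, 1)",
                  call. = FALSE)
           v <- sd^2
           if (v >= mean * (1 - mean))
             stop("infeasible-moments error: need sd^2 < mean*(1-mean)",
                  call. = FALSE)
           k <- mean * (1 - mean) / v - 1
           list(family = "beta", alpha = mean * k, beta = (1 - mean) * k)
         },
         lognormal = {
           if (mean <= 0)
             stop("infeasible-moments error: lognormal mean must be > 0",
                  call. = FALSE)
           s2 <- log(1 + sd^2 / mean^2)
           list(family = "lognormal", mu = log(mean) - s2 / 2,
                sigma = sqrt(s2))
         },
         stop("parameter error: unknown family '", family, "'", call. = FALSE))
}

#' Draw from a fitted distribution
#'
#' @param params A [moment_match()] result.
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_distribution <- function(params, n = 1L) {
  switch(params$family,
         fixed = rep(params$value, n),
         beta = rbeta(n, params$alpha, params$beta),
         lognormal = rlnorm(n, params$mu, params$sigma),
         stop("parameter error: unknown family", call. = FALSE))
}

#' Second-order Monte Carlo probabilistic sensitivity analysis
#'
#' For each iteration, draws every distributed parameter once (a single
#' shared parameter set across all arms, so common inputs such as
#' utilities move together), rebuilds and validates the configuration,
#' runs every arm, and records incremental cost and QALYs of the reference
#' arm versus each comparator. Draws that fail validation are redrawn (a
#' redraw rate above 1% triggers a warning). Fully reproducible given
#' `seed`.
#'
#' @param config A [model_config()].
#' @param n Number of iterations (default 1000).
#' @param seed Integer seed.
#' @param sd_rule Passed to [assign_distributions()].
#' @param distributions Optional distribution table overriding
#'   [assign_distributions()] (columns `path`, `family`, `mean`, `sd`).
#' @param reference Reference treatment name (default: first treatment).
#' @return A `psa_result`: list with `draws` (data frame `iteration`,
#'   `comparator`, `delta_cost`, `delta_qaly`), `arm_draws` (data frame of
#'   per-arm `cost`/`qalys` per iteration), `seed`, `n_iterations`,
#'   `n_redraws`, `reference`.
#' @export
run_psa <- function(config, n = 1000L, seed = 1L, sd_rule = 0.10,
                    distributions = NULL,
                    reference = names(config$treatments)[1]) {
  if (n < 1) stop("parameter error: n must be >= 1", call. = FALSE)
  dist <- distributions %||% assign_distributions(config, sd_rule)
  active <- dist[dist$family != "fixed", , drop = FALSE]
  params <- lapply(seq_len(nrow(active)), function(i)
    moment_match(active$family[i], active$mean[i], active$sd[i]))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  comparators <- setdiff(names(config$treatments), reference)
  n_redraws <- 0L
  draw_rows <- vector("list", n)
  arm_rows <- vector("list", n)
  for (it in seq_len(n)) {
    repeat {
      cfg_i <- config
      for (i in seq_len(nrow(active))) {
        cfg_i <- set_by_path(cfg_i, active$path[i],
                             sample_distribution(params[[i]], 1L))
      }
      ok <- tryCatch({
        suppressWarnings(validate_config(cfg_i))
        TRUE
      }, error = function(e) FALSE)
      if (ok) break
      n_redraws <- n_redraws + 1L
    }
    arms <- suppressWarnings(run_all_arms(cfg_i))
    ref <- arms[[reference]]
    arm_rows[[it]] <- data.frame(
      iteration = it, treatment = names(arms),
      cost = vapply(arms, function(a) a$total_cost, numeric(1)),
      qalys = vapply(arms, function(a) a$total_qalys, numeric(1)),
      row.names = NULL, stringsAsFactors = FALSE)
    draw_rows[[it]] <- data.frame(
      iteration = it, comparator = comparators,
      delta_cost = vapply(comparators, function(cm)
        ref$total_cost - arms[[cm]]$total_cost, numeric(1)),
      delta_qaly = vapply(comparators, function(cm)
        ref$total_qalys - arms[[cm]]$total_qalys, numeric(1)),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  if (n_redraws > 0.01 * n)
    warning(sprintf("PSA redraw rate %.1f%% exceeds 1%%", 100 * n_redraws / n),
            call. = FALSE)
  structure(list(draws = do.call(rbind, draw_rows),
                 arm_draws = do.call(rbind, arm_rows),
                 seed = seed, n_iterations = n, n_redraws = n_redraws,
                 reference = reference),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d iterations (seed %d), reference %s, %d comparator(s)\n",
              x$n_iterations, x$seed, x$reference,
              length(unique(x$draws$comparator))))
  invisible(x)
}

#' Dominance proportions from a PSA
#'
#' Fraction of iterations in which the reference arm strictly dominates
#' (cheaper and more effective than) each comparator.
#'
#' @param result A [run_psa()] result.
#' @return Data frame `comparator`, `prob_dominant`.
#' @export
dominance_summary <- function(result) {
  sp <- split(result$draws, result$draws$comparator)
  data.frame(
    comparator = names(sp),
    prob_dominant = vapply(sp, function(d)
      mean(d$delta_cost < 0 & d$delta_qaly > 0), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the probability the reference arm is
#' cost-effective versus the comparator: the fraction of PSA draws with
#' non-negative net monetary benefit, `lambda * dQ - dC >= 0`. The
#' (lambda-free) dominant fraction is attached as well.
#'
#' @param result A [run_psa()] result.
#' @param comparator Comparator name present in the result.
#' @param wtp_grid Strictly increasing willingness-to-pay grid, euro/QALY.
#' @return A `ceac_curve` data frame: `wtp`, `prob_cost_effective`,
#'   with attribute `prob_dominant`.
#' @export
ceac <- function(result, comparator, wtp_grid = seq(0, 100000, by = 2500)) {
  if (length(wtp_grid) == 0)
    stop("parameter error: wtp_grid must be non-empty", call. = FALSE)
  if (is.unsorted(wtp_grid, strictly = TRUE))
    stop("parameter error: wtp_grid must be strictly increasing", call. = FALSE)
  d <- result$draws[result$draws$comparator == comparator, , drop = FALSE]
  if (nrow(d) == 0)
    stop("parameter error: comparator '", comparator, "' not in result",
         call. = FALSE)
  p <- vapply(wtp_grid, function(l)
    mean(l * d$delta_qaly - d$delta_cost >= 0), numeric(1))
  structure(data.frame(wtp = wtp_grid, prob_cost_effective = p),
            prob_dominant = mean(d$delta_cost < 0 & d$delta_qaly > 0),
            class = c("ceac_curve", "data.frame"))
}

#' Bootstrap intervals for mean incremental cost and QALYs
#'
#' Percentile 95% intervals of the mean incremental cost and QALYs per
#' comparator, from resampling PSA draws with replacement.
#'
#' @param result A [run_psa()] result.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @param level Interval coverage (default 0.95).
#' @return Data frame: `comparator`, `mean_delta_cost`, `cost_lo`,
#'   `cost_hi`, `mean_delta_qaly`, `qaly_lo`, `qaly_hi`.
#' @export
bootstrap_summary <- function(result, n_boot = 1000L, seed = 1L, level = 0.95) {
  if (n_boot < 1) stop("parameter error: n_boot must be >= 1", call. = FALSE)
  if (nrow(result$draws) == 0)
    stop("parameter error: empty PSA result", call. = FALSE)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  alpha <- (1 - level) / 2
  sp <- split(result$draws, result$draws$comparator)
  rows <- lapply(names(sp), function(cm) {
    d <- sp[[cm]]
    ndx <- matrix(sample.int(nrow(d), nrow(d) * n_boot, replace = TRUE),
                  nrow = n_boot)
    mc <- rowMeans(matrix(d$delta_cost[ndx], nrow = n_boot))
    mq <- rowMeans(matrix(d$delta_qaly[ndx], nrow = n_boot))
    data.frame(comparator = cm,
               mean_delta_cost = mean(d$delta_cost),
               cost_lo = quantile(mc, alpha, names = FALSE),
               cost_hi = quantile(mc, 1 - alpha, names = FALSE),
               mean_delta_qaly = mean(d$delta_qaly),
               qaly_lo = quantile(mq, alpha, names = FALSE),
               qaly_hi = quantile(mq, 1 - alpha, names = FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
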