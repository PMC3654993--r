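# One-way deterministic sensitivity analysis (tornado), named scenario
# analyses, and the break-even remission-rate search.

run_pair <- function(config, arm_pair) {
  if (!all(arm_pair %in% names(config$treatments)))
    stop("parameter error: unknown treatment in arm_pair; valid choices: ",
         paste(names(config$treatments), collapse = ", "), call. = FALSE)
  a <- run_arm(config$treatments[[arm_pair[1]]], config)
  b <- run_arm(config$treatments[[arm_pair[2]]], config)
  incremental_analysis(a, b, config$econ$wtp_thresholds)
}

#' Default one-way sensitivity grid
#'
#' Builds a (path, low, high) grid for the main model drivers of an arm
#' pair: remission/discontinuation probabilities, relapse parameters, state
#' utilities and costs, drug costs, recurrence and episode mortality. Each
#' parameter is varied by `+/- rel` (default 20%) around its base value,
#' clamped to its type bounds.
#'
#' @param config A [model_config()].
#' @param arm_pair Character vector of two treatment names.
#' @param rel Relative half-width of the variation (default 0.20).
#' @return Data frame with columns `path`, `low`, `high`.
#' @export
default_dsa_grid <- function(config, arm_pair, rel = 0.20) {
  paths <- c(
    "state_values/utility_well", "state_values/utility_remission",
    "state_values/utility_episode",
    "state_values/direct_cost_remission", "state_values/indirect_cost_remission",
    "state_values/direct_cost_episode", "state_values/indirect_cost_episode",
    "annual_recurrence_prob", "off_treatment_remission_prob",
    "mortality/episode_mortality_rr",
    "placebo_relapse/scale",
    "discontinuation_symptom_cost", "hepatic_test_cost"
  )
  for (nm in arm_pair) {
    tr <- config$treatments[[nm]]
    paths <- c(paths,
               sprintf("treatments/%s/monthly_remission_prob", nm),
               sprintf("treatments/%s/monthly_discontinuation_prob", nm),
               sprintf("treatments/%s/double_dose_fraction", nm),
               sprintf("treatments/%s/monthly_drug_cost_standard", nm),
               if (tr$relapse$mode == "rr_vs_placebo")
                 sprintf("treatments/%s/relapse/rr", nm)
               else
                 sprintf("treatments/%s/relapse/scale", nm))
  }
  base <- vapply(paths, function(p) config_get(config, p), numeric(1))
  is_prob <- grepl("utility|prob", paths)
  low <- base * (1 - rel)
  high <- ifelse(is_prob, pmin(base * (1 + rel), 1), base * (1 + rel))
  low <- pmax(low, ifelse(grepl("episode_mortality_rr", paths), 1, 0))
  data.frame(path = paths, low = low, high = high,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' One-way deterministic sensitivity analysis
#'
#' Re-runs the pairwise comparison with each parameter set to its low and
#' high extreme in turn, all else held at base. Entries are returned in
#' tornado order (descending net-monetary-benefit span at the reference
#' willingness-to-pay threshold).
#'
#' @param config A [model_config()].
#' @param arm_pair Character vector `c(treatment, comparator)`.
#' @param param_grid Data frame `(path, low, high)`, e.g.
#'   [default_dsa_grid()].
#' @param reference_threshold Willingness-to-pay threshold (euro/QALY) at
#'   which the NMB span is measured; defaults to the middle configured
#'   threshold.
#' @return Data frame: `path`, `low`, `high`, `icer_low`, `label_low`,
#'   `icer_high`, `label_high`, `nmb_low`, `nmb_high`, `span`
#'   (`= abs(nmb_high - nmb_low)`), sorted by `span` descending.
#' @export
run_dsa <- function(config, arm_pair, param_grid = default_dsa_grid(config, arm_pair),
                    reference_threshold = NULL) {
  stopifnot(all(c("path", "low", "high") %in% names(param_grid)))
  if (any(param_grid$low > param_grid$high))
    stop("validation error: low > high in param_grid", call. = FALSE)
  lambda <- reference_threshold %||%
    config$econ$wtp_thresholds[ceiling(length(config$econ$wtp_thresholds) / 2)]
  eval_at <- function(path, value) {
    ce <- run_pair(config_set(config, path, value), arm_pair)
    list(icer = ce$icer, label = ce$label,
         nmb = lambda * ce$delta_qalys - ce$delta_cost)
  }
  rows <- lapply(seq_len(nrow(param_grid)), function(i) {
    lo <- eval_at(param_grid$path[i], param_grid$low[i])
    hi <- eval_at(param_grid$path[i], param_grid$high[i])
    data.frame(path = param_grid$path[i],
               low = param_grid$low[i], high = param_grid$high[i],
               icer_low = lo$icer, label_low = lo$label,
               icer_high = hi$icer, label_high = hi$label,
               nmb_low = lo$nmb, nmb_high = hi$nmb,
               span = abs(hi$nmb - lo$nmb), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$span), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

SCENARIO_NAMES <- c("payer_perspective", "exclude_adr", "exclude_sleep",
                    "exclude_discontinuation", "horizon_12")

apply_scenario <- function(config, scenario) {
  if (is.list(scenario) && !is.null(scenario$vary)) {
    for (p in names(scenario$vary))
      config <- config_set(config, p, scenario$vary[[p]])
    return(config)
  }
  stopifnot(is.character(scenario))
  for (sc in scenario) {
    config <- switch(
      sc,
      payer_perspective = { config$econ$perspective <- "payer"; config },
      exclude_adr = {
        for (nm in names(config$treatments))
          config$treatments[[nm]]$adr_monthly_freq[] <- 0
        config
      },
      exclude_sleep = {
        for (nm in names(config$treatments))
          config$treatments[[nm]]$adr_monthly_freq[["sleep_disorder"]] <- 0
        config
      },
      exclude_discontinuation = {
        for (nm in names(config$treatments)) {
          config$treatments[[nm]]$monthly_discontinuation_prob <- 0
          config$treatments[[nm]]$discontinuation_symptom_prob <- 0
        }
        config
      },
      horizon_12 = { config$econ$horizon_cycles <- 12L; config },
      stop("parameter error: unknown scenario '", sc, "'; valid: ",
           paste(SCENARIO_NAMES, collapse = ", "), call. = FALSE)
    )
  }
  validate_config(config)
  config
}

#' Run a named scenario analysis
#'
#' Applies a structural transform to the configuration and returns the
#' pairwise result. Recognised names: `payer_perspective` (direct costs
#' only), `exclude_adr` (zero all ADR frequencies), `exclude_sleep` (zero
#' the sleep-disorder frequency), `exclude_discontinuation` (zero
#' discontinuation and symptom probabilities), `horizon_12` (one-year
#' horizon). Several names may be given and compose; alternatively pass
#' `list(vary = list(path = value, ...))` for ad-hoc variation.
#'
#' @param config A [model_config()].
#' @param scenario Character vector of scenario names, or a `vary` list.
#' @param arm_pair Character vector `c(treatment, comparator)`.
#' @return A `ce_result` (see [incremental_analysis()]).
#' @export
run_scenario <- function(config, scenario, arm_pair) {
  run_pair(apply_scenario(config, scenario), arm_pair)
}

#' Break-even comparator remission rate
#'
#' Bisection search for the smallest comparator monthly remission
#' probability at which the reference arm becomes dominated
#' (`delta_qalys <= 0` and `delta_cost >= 0` for reference vs comparator),
#' holding everything else at base. Returns 1.0 (with attribute
#' `crossed = FALSE`) if even certain remission does not dominate.
#'
#' @param config A [model_config()].
#' @param comparator Comparator treatment name.
#' @param reference Reference treatment name (default: first treatment).
#' @param tolerance Bracket width at which the search stops.
#' @return The break-even probability, with attributes `bracket`
#'   (`c(low, high)`, not-dominated / dominated endpoints) and `crossed`.
#' @export
breakeven_remission <- function(config, comparator,
                                reference = names(config$treatments)[1],
                                tolerance = 1e-4) {
  if (!comparator %in% names(config$treatments))
    stop("parameter error: unknown comparator '", comparator, "'; valid: ",
         paste(names(config$treatments), collapse = ", "), call. = FALSE)
  path <- sprintf("treatments/%s/monthly_remission_prob", comparator)
  dominated_at <- function(r) {
    ce <- run_pair(config_set(config, path, r), c(reference, comparator))
    ce$delta_qalys <= 0 && ce$delta_cost >= 0
  }
  lo <- config_get(config, path)
  if (dominated_at(lo))
    stop("search failure: reference already dominated at the base remission rate",
         call. = FALSE)
  hi <- 1.0
  if (!dominated_at(hi))
    return(structure(1.0, bracket = c(lo, hi), crossed = FALSE))
  while (hi - lo > tolerance) {
    mid <- (lo + hi) / 2
    if (dominated_at(mid)) hi <- mid else lo <- mid
  }
  structure(hi, bracket = c(lo, hi), crossed = TRUE)
}
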