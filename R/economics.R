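# Expected ADR burden, medication costing with dose escalation,
# discounting, discounted per-arm totals and pairwise incremental
# cost-effectiveness analysis.

check_adr_args <- function(profile, adr_table) {
  if (!setequal(names(profile$adr_monthly_freq), ADR_NAMES))
    stop("validation error: profile must carry all eight ADR frequencies",
         call. = FALSE)
  if (!setequal(names(adr_table), ADR_NAMES))
    stop("validation error: adr_table must carry all eight ADR entries",
         call. = FALSE)
}

#' Expected per-cycle ADR disutility and management cost
#'
#' `expected_adr_disutility()` is the sum over adverse drug reactions of
#' monthly frequency times utility decrement;
#' `expected_adr_cost()` the analogous sum of frequency times monthly
#' management cost. With `include_sleep = FALSE` the sleep-disorder term is
#' omitted (sleep disturbance outside a depressive episode is attributed to
#' the depression, not the drug).
#'
#' @param profile A [treatment_profile()].
#' @param adr_table Named list of per-ADR
#'   `list(utility_decrement =, monthly_cost =)`, e.g.
#'   [base_case_adr_table()].
#' @param include_sleep Logical; include the sleep-disorder term?
#' @return A single number (utility units, or euro per month).
#' @export
#' @examples
#' cfg <- base_case_config()
#' round(expected_adr_disutility(cfg$treatments[["Agomelatine"]],
#'                               cfg$adr_table, include_sleep = FALSE), 3)
expected_adr_disutility <- function(profile, adr_table, include_sleep = TRUE) {
  check_adr_args(profile, adr_table)
  use <- if (include_sleep) ADR_NAMES else setdiff(ADR_NAMES, "sleep_disorder")
  sum(vapply(use, function(a)
    profile$adr_monthly_freq[[a]] * adr_table[[a]]$utility_decrement,
    numeric(1)))
}

#' @rdname expected_adr_disutility
#' @export
expected_adr_cost <- function(profile, adr_table, include_sleep = TRUE) {
  check_adr_args(profile, adr_table)
  use <- if (include_sleep) ADR_NAMES else setdiff(ADR_NAMES, "sleep_disorder")
  sum(vapply(use, function(a)
    profile$adr_monthly_freq[[a]] * adr_table[[a]]$monthly_cost,
    numeric(1)))
}

#' Monthly medication cost with dose escalation
#'
#' The standard monthly price applies in the first treatment cycle; from
#' the second cycle of an episode onwards (and through remission) the
#' price is uplifted by the double-dose fraction:
#' `cost * (1 + double_dose_fraction)`.
#'
#' @param profile A [treatment_profile()].
#' @param cycle_on_treatment Month of time on treatment (>= 1).
#' @return Euro per month.
#' @export
#' @examples
#' ago <- base_case_config()$treatments[["Agomelatine"]]
#' medication_cost(ago, 1)  # 60.27
#' medication_cost(ago, 2)  # 60.27 * 1.221
medication_cost <- function(profile, cycle_on_treatment) {
  if (any(cycle_on_treatment < 1))
    stop("parameter error: cycle_on_treatment must be >= 1", call. = FALSE)
  uplift <- ifelse(cycle_on_treatment >= 2, 1 + profile$double_dose_fraction, 1)
  profile$monthly_drug_cost_standard * uplift
}

#' Discount factor for a monthly cycle
#'
#' Costs and outcomes within the first year are undiscounted; cycles
#' beyond month 12 are discounted at the annual rate pro rata:
#' `(1 + rate)^(-(cycle - 12)/12)`.
#'
#' @param cycle Month index (>= 1); vectorised.
#' @param annual_rate Annual discount rate (fraction).
#' @return Dimensionless factor in (0, 1\].
#' @export
#' @examples
#' discount_factor(24, 0.035)  # 1.035^-1
discount_factor <- function(cycle, annual_rate) {
  ifelse(cycle <= 12, 1, (1 + annual_rate)^(-(cycle - 12) / 12))
}

#' Per-arm result container
#'
#' Constructs an `arm_result` directly from totals (used when tabulated
#' per-arm totals serve as inputs to incremental analysis);
#' [summarize_arm()] builds one from a cohort trace.
#'
#' @param treatment Treatment name.
#' @param total_cost Discounted total cost, euro.
#' @param total_qalys Discounted total QALYs.
#' @param components Optional named numeric vector of cost components
#'   (`drug`, `direct_medical`, `indirect`, `adr`, `monitoring`); must sum
#'   to `total_cost` within one cent when supplied.
#' @return An `arm_result`.
#' @export
arm_result <- function(treatment, total_cost, total_qalys, components = NULL) {
  check_nonneg(total_cost, "total_cost")
  check_nonneg(total_qalys, "total_qalys")
  if (!is.null(components) && abs(sum(components) - total_cost) > 0.01)
    stop("internal assertion failure: cost components do not sum to total",
         call. = FALSE)
  structure(list(treatment = treatment, total_cost = total_cost,
                 total_qalys = total_qalys, components = components),
            class = "arm_result")
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("<arm_result> %s: total cost EUR %.0f, QALYs %.3f\n",
              x$treatment, x$total_cost, x$total_qalys))
  invisible(x)
}

#' Discounted per-arm totals from a cohort trace
#'
#' Discounts each accrual stream cycle-wise by [discount_factor()] and
#' sums. Under the payer perspective the indirect (productivity) stream is
#' excluded from the cost total; under the societal perspective it is
#' included.
#'
#' @param trace A [run_cohort()] result for `profile` under `config`.
#' @param profile The matching [treatment_profile()].
#' @param config The matching [model_config()].
#' @return An [arm_result()] with cost components `drug`,
#'   `direct_medical`, `indirect`, `adr`, `monitoring`.
#' @export
summarize_arm <- function(trace, profile, config) {
  H <- config$econ$horizon_cycles
  if (nrow(trace$accruals) != H)
    stop("consistency error: trace horizon does not match configuration",
         call. = FALSE)
  df <- discount_factor(seq_len(H), config$econ$annual_discount_rate)
  disc <- colSums(trace$accruals * df)
  indirect <- if (config$econ$perspective == "societal")
    disc[["indirect_cost"]] else 0
  components <- c(drug = disc[["drug_cost"]],
                  direct_medical = disc[["direct_cost"]],
                  indirect = indirect,
                  adr = disc[["adr_cost"]],
                  monitoring = disc[["monitoring_cost"]])
  arm_result(profile$name, sum(components), disc[["qaly"]], components)
}

run_arm <- function(profile, config) {
  summarize_arm(run_cohort(profile, config), profile, config)
}

#' Run every arm of a configuration
#'
#' @param config A [model_config()].
#' @return Named list of [arm_result()]s, one per treatment.
#' @export
run_all_arms <- function(config) {
  lapply(config$treatments, run_arm, config = config)
}

#' Pairwise incremental cost-effectiveness analysis
#'
#' Computes incremental cost and QALYs of `a` versus `b`
#' (`delta = a - b`), labels dominance (`"dominant"` when `a` is cheaper
#' and more effective, `"dominated"` when costlier and less effective),
#' reports the ICER `delta_cost / delta_qalys` when both increments share a
#' sign (northeast or southwest quadrant; `NA` otherwise or when
#' `delta_qalys` is exactly zero), and the net monetary benefit
#' `NMB(lambda) = lambda * delta_qalys - delta_cost` at each
#' willingness-to-pay threshold.
#'
#' @param a,b [arm_result()]s (intervention and comparator).
#' @param thresholds Willingness-to-pay thresholds, euro per QALY.
#' @return A `ce_result`: list with `treatment`, `comparator`,
#'   `delta_cost`, `delta_qalys`, `icer`, `label`
#'   (`"dominant"`, `"dominated"` or `"icer"`), `nmb` (named by threshold).
#' @export
incremental_analysis <- function(a, b, thresholds = c(40000, 50000, 60000)) {
  stopifnot(inherits(a, "arm_result"), inherits(b, "arm_result"))
  dc <- a$total_cost - b$total_cost
  dq <- a$total_qalys - b$total_qalys
  label <- if (dc < 0 && dq > 0) "dominant"
  else if (dc > 0 && dq < 0) "dominated"
  else "icer"
  icer <- if (dq != 0 && label == "icer" &&
              ((dq > 0 && dc > 0) || (dq < 0 && dc < 0))) dc / dq else NA_real_
  nmb <- setNames(thresholds * dq - dc, as.character(thresholds))
  structure(list(treatment = a$treatment, comparator = b$treatment,
                 delta_cost = dc, delta_qalys = dq,
                 icer = icer, label = label, nmb = nmb),
            class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  icer_txt <- switch(x$label,
                     dominant = sprintf("%s dominant", x$treatment),
                     dominated = sprintf("%s dominated", x$treatment),
                     if (is.na(x$icer)) "ICER undefined"
                     else sprintf("EUR %.0f/QALY", x$icer))
  cat(sprintf("<ce_result> %s vs %s: dCost EUR %.0f, dQALY %.3f -> %s\n",
              x$treatment, x$comparator, x$delta_cost, x$delta_qalys,
              icer_txt))
  invisible(x)
}

#' Tabulate incremental results
#'
#' Runs all arms of `config` and compares the reference arm against every
#' other arm.
#'
#' @param config A [model_config()].
#' @param reference Reference treatment name (default: first treatment).
#' @return Data frame with one row per arm: totals, increments versus the
#'   reference, and ICER or dominance label.
#' @export
base_case_table <- function(config, reference = names(config$treatments)[1]) {
  arms <- run_all_arms(config)
  if (!reference %in% names(arms))
    stop("parameter error: unknown reference treatment '", reference, "'",
         call. = FALSE)
  ref <- arms[[reference]]
  rows <- lapply(names(arms), function(nm) {
    a <- arms[[nm]]
    if (nm == reference) {
      data.frame(treatment = nm, total_cost = a$total_cost,
                 total_qalys = a$total_qalys, delta_cost = NA_real_,
                 delta_qalys = NA_real_, icer = NA_real_,
                 label = "reference", stringsAsFactors = FALSE)
    } else {
      ce <- incremental_analysis(ref, a, config$econ$wtp_thresholds)
      data.frame(treatment = nm, total_cost = a$total_cost,
                 total_qalys = a$total_qalys, delta_cost = ce$delta_cost,
                 delta_qalys = ce$delta_qalys, icer = ce$icer,
                 label = ce$label, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
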