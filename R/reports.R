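# Report generation: base-case, PSA, DSA and break-even outputs as CSV +
# JSON beside a run manifest. Human-readable tables round euro amounts to
# whole units and QALYs to 3 decimals; the JSON keeps full precision.

run_manifest <- function(config_path, subcommand, seed, perspective,
                         horizon) {
  list(
    config_path = config_path %||% "<in-memory>",
    config_hash = if (!is.null(config_path) && file.exists(config_path))
      unname(tools::md5sum(config_path)) else NA_character_,
    subcommand = subcommand,
    seed = seed,
    perspective = perspective,
    horizon_cycles = horizon,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("adcea"))
  )
}

write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

# Remove any files this report created before failing; reports are atomic.
with_atomic_outputs <- function(out_dir, files, expr) {
  paths <- file.path(out_dir, files)
  tryCatch(expr, error = function(e) {
    unlink(paths)
    stop(e)
  })
}

round_table <- function(d) {
  for (nm in names(d)) {
    if (grepl("cost|nmb|icer|span", nm) && is.numeric(d[[nm]]))
      d[[nm]] <- round(d[[nm]])
    if (grepl("qaly", nm) && is.numeric(d[[nm]]))
      d[[nm]] <- round(d[[nm]], 3)
  }
  d
}

#' Base-case report
#'
#' Runs every arm, writes the per-arm totals and pairwise incremental
#' table (`base_case.csv`, rounded for reading; `base_case.json` at full
#' precision), a cost-component decomposition per arm
#' (`cost_components.csv`), and a run manifest. On any error, partial
#' outputs are removed.
#'
#' @param config A [model_config()] or a path to a YAML configuration.
#' @param out_dir Output directory (created if missing).
#' @param perspective Optional override: `"societal"` or `"payer"`.
#' @param reference Reference treatment name (default: first treatment).
#' @return Invisibly, the full-precision incremental table.
#' @export
report_base_case <- function(config, out_dir, perspective = NULL,
                             reference = NULL) {
  config_path <- if (is.character(config)) config else NULL
  if (is.character(config)) config <- load_config(config)
  if (!is.null(perspective)) config$econ$perspective <- match.arg(
    perspective, c("societal", "payer"))
  validate_config(config)
  reference <- reference %||% names(config$treatments)[1]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c("base_case.csv", "base_case.json", "cost_components.csv",
             "manifest.json")
  with_atomic_outputs(out_dir, files, {
    tab <- base_case_table(config, reference)
    arms <- run_all_arms(config)
    comp <- do.call(rbind, lapply(arms, function(a)
      data.frame(treatment = a$treatment, t(a$components),
                 stringsAsFactors = FALSE)))
    rownames(comp) <- NULL
    if (config$econ$perspective == "payer") comp$indirect <- NULL
    write.csv(round_table(tab), file.path(out_dir, "base_case.csv"),
              row.names = FALSE)
    write.csv(round_table(comp), file.path(out_dir, "cost_components.csv"),
              row.names = FALSE)
    jsonlite::write_json(list(results = tab, cost_components = comp),
                         file.path(out_dir, "base_case.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    write_manifest(run_manifest(config_path, "base-case", NA,
                                config$econ$perspective,
                                config$econ$horizon_cycles), out_dir)
    invisible(tab)
  })
}

#' PSA report
#'
#' Runs [run_psa()], writes the raw draws (`psa_draws.csv`), one
#' acceptability curve per comparator (`ceac_<comparator>.csv`), a
#' dominance-fraction summary (`psa_summary.csv`) and a manifest carrying
#' the seed.
#'
#' @param config A [model_config()] or a path to a YAML configuration.
#' @param out_dir Output directory.
#' @param n Iterations (>= 1).
#' @param seed Integer seed; all randomness flows from it.
#' @param wtp_grid Willingness-to-pay grid for the curves.
#' @param perspective Optional perspective override.
#' @return Invisibly, the [run_psa()] result.
#' @export
report_psa <- function(config, out_dir, n = 1000L, seed = 1L,
                       wtp_grid = seq(0, 100000, by = 2500),
                       perspective = NULL) {
  if (n < 1) stop("usage error: n must be >= 1", call. = FALSE)
  config_path <- if (is.character(config)) config else NULL
  if (is.character(config)) config <- load_config(config)
  if (!is.null(perspective)) config$econ$perspective <- match.arg(
    perspective, c("societal", "payer"))
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- run_psa(config, n = n, seed = seed)
  comparators <- unique(res$draws$comparator)
  slug <- function(x) gsub("[^A-Za-z0-9]+", "_", tolower(x))
  files <- c("psa_draws.csv", "psa_summary.csv",
             sprintf("ceac_%s.csv", slug(comparators)), "manifest.json")
  with_atomic_outputs(out_dir, files, {
    write.csv(res$draws, file.path(out_dir, "psa_draws.csv"),
              row.names = FALSE)
    for (cm in comparators) {
      cv <- ceac(res, cm, wtp_grid)
      write.csv(as.data.frame(cv),
                file.path(out_dir, sprintf("ceac_%s.csv", slug(cm))),
                row.names = FALSE)
    }
    write.csv(dominance_summary(res),
              file.path(out_dir, "psa_summary.csv"), row.names = FALSE)
    write_manifest(run_manifest(config_path, "psa", seed,
                                config$econ$perspective,
                                config$econ$horizon_cycles), out_dir)
  })
  invisible(res)
}

#' DSA (tornado) report
#'
#' Runs [run_dsa()] for an arm pair and writes `tornado.csv` (sorted by
#' NMB span, descending) plus a manifest.
#'
#' @inheritParams report_psa
#' @param arm_pair Character vector `c(treatment, comparator)`.
#' @param param_grid Optional grid; defaults to [default_dsa_grid()].
#' @return Invisibly, the tornado data frame.
#' @export
report_dsa <- function(config, out_dir, arm_pair, param_grid = NULL,
                       perspective = NULL) {
  config_path <- if (is.character(config)) config else NULL
  if (is.character(config)) config <- load_config(config)
  if (!is.null(perspective)) config$econ$perspective <- match.arg(
    perspective, c("societal", "payer"))
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  with_atomic_outputs(out_dir, c("tornado.csv", "manifest.json"), {
    grid <- param_grid %||% default_dsa_grid(config, arm_pair)
    torn <- suppressWarnings(run_dsa(config, arm_pair, grid))
    write.csv(round_table(torn), file.path(out_dir, "tornado.csv"),
              row.names = FALSE)
    write_manifest(run_manifest(config_path, "dsa", NA,
                                config$econ$perspective,
                                config$econ$horizon_cycles), out_dir)
    invisible(torn)
  })
}

#' Break-even report
#'
#' Runs [breakeven_remission()] for each requested comparator, re-verifies
#' the bracket by re-running both endpoints, and writes `breakeven.csv`
#' plus a manifest.
#'
#' @inheritParams report_psa
#' @param comparators Character vector of comparator names.
#' @param tolerance Bisection tolerance.
#' @return Invisibly, the break-even data frame.
#' @export
report_breakeven <- function(config, out_dir, comparators,
                             tolerance = 1e-4, perspective = NULL) {
  config_path <- if (is.character(config)) config else NULL
  if (is.character(config)) config <- load_config(config)
  if (!is.null(perspective)) config$econ$perspective <- match.arg(
    perspective, c("societal", "payer"))
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  with_atomic_outputs(out_dir, c("breakeven.csv", "manifest.json"), {
    rows <- lapply(comparators, function(cm) {
      be <- breakeven_remission(config, cm, tolerance = tolerance)
      br <- attr(be, "bracket")
      data.frame(comparator = cm, breakeven_remission_prob = as.numeric(be),
                 bracket_low = br[1], bracket_high = br[2],
                 crossed = attr(be, "crossed"), stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    write.csv(out, file.path(out_dir, "breakeven.csv"), row.names = FALSE)
    write_manifest(run_manifest(config_path, "breakeven", NA,
                                config$econ$perspective,
                                config$econ$horizon_cycles), out_dir)
    invisible(out)
  })
}
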