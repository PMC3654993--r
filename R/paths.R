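# Slash-separated paths into a model_config, e.g.
# "state_values/utility_episode" or
# "treatments/Agomelatine/adr_monthly_freq/nausea". Used by the
# deterministic and probabilistic sensitivity analyses to address
# individual numeric fields.

split_path <- function(path) strsplit(path, "/", fixed = TRUE)[[1]]

#' Get or set a configuration field by path
#'
#' Paths are slash-separated component names descending into the
#' configuration list, with named-vector elements (ADR frequencies, life
#' table entries) addressable as the final component.
#'
#' @param config A [model_config()].
#' @param path Character path, e.g. `"treatments/Agomelatine/monthly_remission_prob"`.
#' @param value Replacement value for `config_set()`.
#' @return `config_get()` returns the addressed value; `config_set()` the
#'   modified (revalidated) configuration.
#' @export
#' @examples
#' cfg <- base_case_config()
#' config_get(cfg, "state_values/utility_episode")
config_get <- function(config, path) {
  x <- config
  for (p in split_path(path)) {
    if (is.null(x) || !(is.list(x) || !is.null(names(x))) ||
        !(p %in% names(x)))
      stop("path error: cannot resolve '", path, "' at component '", p, "'",
           call. = FALSE)
    x <- x[[p]]
  }
  if (!is.numeric(x) && !is.logical(x))
    stop("path error: '", path, "' does not address a numeric field",
         call. = FALSE)
  x
}

set_by_path <- function(config, path, value) {
  assign_rec <- function(x, parts) {
    p <- parts[1]
    if (!(p %in% names(x)))
      stop("path error: cannot resolve component '", p, "'", call. = FALSE)
    if (length(parts) == 1L) {
      x[[p]] <- value
    } else {
      x[[p]] <- assign_rec(x[[p]], parts[-1])
    }
    x
  }
  assign_rec(config, split_path(path))
}

#' @rdname config_get
#' @export
config_set <- function(config, path, value) {
  out <- set_by_path(config, path, value)
  validate_config(out)
  out
}
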