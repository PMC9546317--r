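#' Write a concentration dataset to delimited text
#'
#' The dataset layout is an event/observation table: one row per dose
#' (`event = "dose"`, with `amount_mg_per_kg`) or observation
#' (`event = "obs"`, with `matrix`, `conc_ng_per_ml` and `blq`). Times are
#' hours since the first administration. The optional noise-free side
#' channel `conc_true_ng_per_ml` is written when present.
#'
#' @param data Dataset tibble (see [generate_dataset()]).
#' @param path Output CSV path (UTF-8, period decimal separator).
#' @param keep_true Write the `conc_true_ng_per_ml` side channel if
#'   present (default TRUE).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path, keep_true = TRUE) {
  cols <- c("subject", "arm", "time_h", "event", "matrix",
            "amount_mg_per_kg", "conc_ng_per_ml", "blq")
  if (keep_true && "conc_true_ng_per_ml" %in% names(data)) {
    cols <- c(cols, "conc_true_ng_per_ml")
  }
  cols <- intersect(cols, names(data))
  out <- dplyr::mutate(data[, cols], blq = as.integer(.data$blq))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read and validate a concentration dataset
#'
#' Validates the event/observation schema row by row: dose rows must carry
#' an amount and no concentration, observation rows the converse with a
#' known matrix label; times must be nonnegative; every observed subject
#' needs at least one dose row; there must be at least one observation.
#' Violations are reported with the offending row number.
#'
#' @param path CSV path as written by [write_dataset()].
#' @return Validated dataset tibble.
#' @export
read_dataset <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("subject", "time_h", "event", "matrix", "amount_mg_per_kg",
            "conc_ng_per_ml", "blq")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    abort(paste0("dataset missing column(s): ", paste(miss, collapse = ", ")),
          class = "flx_error_schema")
  }
  row_fail <- function(rows, what) {
    if (length(rows)) {
      abort(sprintf("dataset row %s: %s", paste(head(rows, 5), collapse = ", "),
                    what),
            class = "flx_error_schema")
    }
  }
  rows <- seq_len(nrow(d))
  row_fail(rows[!d$event %in% c("dose", "obs")],
           "column 'event' must be 'dose' or 'obs'")
  row_fail(rows[!is.finite(d$time_h) | d$time_h < 0],
           "column 'time_h' must be a nonnegative number")
  is_dose <- d$event == "dose"
  row_fail(rows[is_dose & !is.na(d$conc_ng_per_ml)],
           "dose rows must not carry a concentration (column 'conc_ng_per_ml')")
  row_fail(rows[is_dose & (is.na(d$amount_mg_per_kg) | d$amount_mg_per_kg <= 0)],
           "dose rows need a positive 'amount_mg_per_kg'")
  row_fail(rows[!is_dose & !is.na(d$amount_mg_per_kg)],
           "observation rows must not carry an amount (column 'amount_mg_per_kg')")
  row_fail(rows[!is_dose & !d$matrix %in% c("plasma", "urine")],
           "observation rows need matrix 'plasma' or 'urine'")
  row_fail(rows[!is_dose & (is.na(d$conc_ng_per_ml) | d$conc_ng_per_ml < 0)],
           "observation rows need a nonnegative 'conc_ng_per_ml'")
  if (!any(!is_dose)) {
    abort("dataset has no observation rows", class = "flx_error_schema")
  }
  no_dose <- setdiff(unique(d$subject[!is_dose]), unique(d$subject[is_dose]))
  if (length(no_dose)) {
    abort(paste0("subjects without dosing records: ",
                 paste(no_dose, collapse = ", ")),
          class = "flx_error_schema")
  }
  d$blq <- as.logical(d$blq)
  d$blq[is.na(d$blq)] <- FALSE
  if (!"arm" %in% names(d)) d$arm <- "all"
  tibble::as_tibble(d)
}

#' Read a run configuration
#'
#' Structured YAML configuration with blocks `model` (typical values,
#' exactly one of `cv` / `omega2` per parameter, residual components,
#' units as declared), `regimens`, `screening_limits`, `simulation`
#' (n, seed, quantile levels) and `estimation` (tolerances, bootstrap
#' replicates). Only `model` is mandatory.
#'
#' @param path YAML file path.
#' @return Validated configuration list of class `flx_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$model)) {
    abort("config needs a 'model' block", class = "flx_error_schema")
  }
  m <- cfg$model
  if (is.null(m$theta) ||
      !all(pk_param_names %in% names(m$theta))) {
    abort("config model block needs theta values for V1, V2, V3, CL, CL2, CL3, Rss",
          class = "flx_error_schema")
  }
  if (is.null(m$cv) == is.null(m$omega2)) {
    abort("config model block needs exactly one of 'cv' or 'omega2'",
          class = "flx_error_schema")
  }
  if (!is.null(cfg$simulation$seed) &&
      cfg$simulation$seed != round(cfg$simulation$seed)) {
    abort("simulation seed must be an integer", class = "flx_error_schema")
  }
  structure(cfg, class = "flx_config")
}

#' Parse the regimens block of a configuration
#'
#' @param cfg An `flx_config`.
#' @return Named list of [regimen()] objects ([standard_regimens()] when
#'   the block is absent).
#' @export
config_regimens <- function(cfg) {
  if (is.null(cfg$regimens)) return(standard_regimens())
  out <- lapply(cfg$regimens, function(r) {
    regimen(dose = r$dose %||% 1.1, interval = r$interval %||% 24,
            n_doses = r$n_doses %||% 1)
  })
  out
}
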