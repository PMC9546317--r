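#' Effective plasma concentration (EPC)
#'
#' The average plasma concentration sustained by a dosing rate, computed as
#' daily dose divided by daily clearance:
#' `EPC = (dose per 24 h) / (CL * 24)`, reported in ng/mL.
#'
#' @param dose Dose per administration (mg/kg bodyweight).
#' @param interval Inter-dose interval (h); the dose is rescaled to a
#'   24-hour dosing rate, so `dose = 1.1, interval = 24` means
#'   1.1 mg/kg/day.
#' @param CL Plasma clearance (L/kg/h).
#' @return EPC in ng/mL.
#' @examples
#' epc(1.1, 24, 0.046) # ~996 ng/mL
#' @export
epc <- function(dose, interval = 24, CL) {
  if (!is.finite(dose) || dose < 0 || !is.finite(interval) || interval <= 0) {
    abort("dose must be nonnegative and interval positive",
          class = "flx_error_invalid_parameter")
  }
  if (!is.finite(CL) || CL <= 0) {
    abort("clearance must be positive", class = "flx_error_invalid_parameter")
  }
  daily_dose_ng <- dose * (24 / interval) * 1e6   # ng/kg/day
  daily_cl_l <- CL * 24                           # L/kg/day
  daily_dose_ng / daily_cl_l / 1000               # ng/L -> ng/mL
}

#' Irrelevant plasma and urine concentrations (IPC, IUC)
#'
#' Scales the EPC down by an uncertainty factor (default 500, the product
#' of 50 for the effect scale and 10 for between-horse PK/PD variability)
#' to the irrelevant plasma concentration, and multiplies by the
#' urine-to-plasma ratio for the irrelevant urine concentration:
#' `IPC = EPC / safety_factor`, `IUC = IPC * Rss`.
#'
#' @param epc Effective plasma concentration (ng/mL), see [epc()].
#' @param Rss Urine-to-plasma concentration ratio (> 0).
#' @param safety_factor Uncertainty factor (> 0), default 500.
#' @return One-row tibble with columns `EPC`, `IPC`, `IUC` (ng/mL) and
#'   `safety_factor`.
#' @examples
#' ipc_iuc(epc(1.1, 24, 0.046), Rss = 36.8)
#' @export
ipc_iuc <- function(epc, Rss, safety_factor = 500) {
  if (!is.finite(epc) || epc <= 0) {
    abort("EPC must be positive", class = "flx_error_invalid_parameter")
  }
  if (!is.finite(Rss) || Rss <= 0) {
    abort("Rss must be positive", class = "flx_error_invalid_parameter")
  }
  if (!is.finite(safety_factor) || safety_factor <= 0) {
    abort("safety factor must be positive",
          class = "flx_error_invalid_parameter")
  }
  ipc <- epc / safety_factor
  tibble::tibble(EPC = epc, IPC = ipc, IUC = ipc * Rss,
                 safety_factor = safety_factor)
}

#' Screening limits used in routine medication control
#'
#' @return Tibble of the reference screening limits: the international
#'   screening limits (plasma 1 ng/mL, urine 100 ng/mL) and the US RMTC
#'   plasma limit (5 ng/mL).
#' @export
screening_limits <- function() {
  tibble::tibble(label  = c("IFHA-ISL", "IFHA-ISL", "RMTC"),
                 matrix = c("plasma", "urine", "plasma"),
                 limit_ng_per_ml = c(1, 100, 5))
}

# detection time for one individual, measured from the last administration.
# Post-last-dose concentration is a positive tri-exponential, hence strictly
# decreasing: bracket the final downward crossing by geometric horizon
# expansion, then root-find to `tol` hours.
dt_single <- function(p, reg, limit, matrix = "plasma", horizon = 2000,
                      tol = 1e-3) {
  td <- dose_times(reg)
  tlast <- max(td)
  V1 <- p[["V1"]]
  te <- tri_exp_terms(p[["CL"]] / V1, p[["CL2"]] / V1, p[["CL2"]] / p[["V2"]],
                      p[["CL3"]] / V1, p[["CL3"]] / p[["V3"]])
  lam <- te$lambda
  A <- reg$dose * 1000 / V1 * te$frac
  if (matrix == "urine") A <- A * p[["Rss"]]
  # accumulate the bolus history into the post-last-dose coefficients
  B <- vapply(lam, function(l) sum(exp(-l * (tlast - td))), numeric(1))
  AB <- A * B
  cf <- function(s) AB[1] * exp(-lam[1] * s) + AB[2] * exp(-lam[2] * s) +
    AB[3] * exp(-lam[3] * s)
  if (cf(0) <= limit) return(0)
  hi <- 8
  while (cf(hi) >= limit) {
    hi <- hi * 2
    if (hi > horizon) {
      abort(sprintf("no crossing below %g ng/mL within %g h", limit, horizon),
            class = "flx_error_horizon")
    }
  }
  uniroot(function(s) cf(s) - limit, c(0, hi), tol = tol)$root
}

#' Detection times for a table of individuals
#'
#' For each individual, the time after the last administration at which the
#' (noise-free, IPRED) concentration in the chosen matrix falls below the
#' screening limit for good — i.e. the final downward crossing of the
#' limit. Individuals whose post-dose concentration never reaches the limit
#' get 0. Urine concentrations are `Rss * plasma`.
#'
#' @param horses Data frame with one row per individual and the seven
#'   structural parameter columns (see [sample_individuals()]); a single
#'   named parameter vector is also accepted.
#' @param reg A [regimen()].
#' @param limit Screening limit (ng/mL, > 0).
#' @param matrix `"plasma"` or `"urine"`.
#' @param horizon Error if no crossing is found within this many hours
#'   after the last dose (default 2000).
#' @return The input tibble with an added `dt_h` column (hours after last
#'   administration); for a single parameter vector, a bare number.
#' @examples
#' detection_times(pk_params(0.149, 0.012, 0.029, 0.047, 0.00015,
#'                           0.00443, 36.8),
#'                 regimen(1.1), limit = 1)
#' @export
detection_times <- function(horses, reg, limit, matrix = c("plasma", "urine"),
                            horizon = 2000) {
  matrix <- match.arg(matrix)
  if (!is.finite(limit) || limit <= 0) {
    abort("screening limit must be positive",
          class = "flx_error_invalid_parameter")
  }
  if (is.numeric(horses) && !is.null(names(horses))) {
    validate_pk_params(horses)
    return(dt_single(horses, reg, limit, matrix, horizon))
  }
  horses <- tibble::as_tibble(horses)
  dts <- vapply(seq_len(nrow(horses)), function(i) {
    p <- as.numeric(horses[i, pk_param_names])
    names(p) <- pk_param_names
    dt_single(p, reg, limit, matrix, horizon)
  }, numeric(1))
  dplyr::mutate(horses, dt_h = dts)
}

#' Monte Carlo detection-time quantiles for a virtual horse population
#'
#' Draws a single virtual meta-population from the population model
#' (independent lognormal etas, no residual error), computes each horse's
#' detection time under every requested regimen x screening-limit
#' combination, and summarises them as empirical (type-7) quantiles. The
#' same meta-population is reused across all combinations so regimens are
#' compared on identical horses.
#'
#' @param pop An [population_model()].
#' @param regimens A [regimen()] or named list of regimens (default
#'   [standard_regimens()]).
#' @param limits Tibble with columns `matrix` and `limit_ng_per_ml`
#'   (default the IFHA international screening limits row of
#'   [screening_limits()]).
#' @param n Number of virtual horses (>= 100), default 5000.
#' @param levels Quantile levels in percent, default
#'   `c(5, 10, 25, 50, 75, 90, 95)`.
#' @param seed Optional integer seed (fixes the meta-population).
#' @return Tibble of class `flx_dtq` with columns `regimen`, `matrix`,
#'   `limit_ng_per_ml`, `level`, `dt_h` (raw quantile) and `dt_h_reported`
#'   (rounded to whole hours, the reporting convention). The raw per-horse
#'   detection times are attached as attribute `"detection_times"` (a
#'   tibble with `regimen`, `matrix`, `limit_ng_per_ml`, `subject`,
#'   `dt_h`).
#' @export
detection_quantiles <- function(pop, regimens = standard_regimens(),
                                limits = NULL, n = 5000,
                                levels = c(5, 10, 25, 50, 75, 90, 95),
                                seed = NULL) {
  if (n < 100) {
    abort("n must be at least 100", class = "flx_error_invalid_input")
  }
  if (inherits(regimens, "flx_regimen")) regimens <- list(regimen = regimens)
  if (is.null(names(regimens))) names(regimens) <- paste0("regimen", seq_along(regimens))
  if (is.null(limits)) {
    limits <- dplyr::filter(screening_limits(), .data$label == "IFHA-ISL")
  }
  horses <- sample_individuals(pop, n, seed = seed)

  raw <- purrr::map_dfr(names(regimens), function(rn) {
    purrr::map_dfr(seq_len(nrow(limits)), function(li) {
      d <- detection_times(horses, regimens[[rn]],
                           limit = limits$limit_ng_per_ml[li],
                           matrix = limits$matrix[li])
      tibble::tibble(regimen = rn, matrix = limits$matrix[li],
                     limit_ng_per_ml = limits$limit_ng_per_ml[li],
                     subject = d$subject, dt_h = d$dt_h)
    })
  })

  out <- dplyr::reframe(
    dplyr::group_by(raw, .data$regimen, .data$matrix, .data$limit_ng_per_ml),
    level = levels,
    dt_h = quantile(.data$dt_h, levels / 100, type = 7, names = FALSE))
  out <- dplyr::mutate(out, dt_h_reported = round(.data$dt_h))
  attr(out, "detection_times") <- raw
  attr(out, "n") <- n
  class(out) <- c("flx_dtq", class(out))
  out
}

#' Tolerance-limit withdrawal time (95/95 style, nonparametric bootstrap)
#'
#' The upper one-sided confidence bound on a high percentile of the
#' detection-time distribution, as used for withdrawal-time setting: the
#' `p`-th percentile is bootstrapped (resampling detection times with
#' replacement) and the `confidence` quantile of the bootstrap
#' distribution is returned.
#'
#' @param dts Vector of detection times (h), at least 100 values (fewer
#'   only if all are equal).
#' @param p Percentile of protection, default 0.95.
#' @param confidence One-sided confidence level, default 0.95.
#' @param n_boot Bootstrap replicates, default 1000.
#' @param seed Optional integer seed.
#' @return One-row tibble with `percentile` (the point estimate),
#'   `withdrawal_h` (the upper bound), `p`, `confidence`, `n`, `n_boot`.
#' @export
rmtc_withdrawal <- function(dts, p = 0.95, confidence = 0.95, n_boot = 1000,
                            seed = NULL) {
  if (p <= 0 || p >= 1) {
    abort("p must be in (0, 1)", class = "flx_error_invalid_input")
  }
  degenerate <- length(unique(dts)) == 1L
  if (length(dts) < 100 && !degenerate) {
    abort("need at least 100 detection times",
          class = "flx_error_invalid_input")
  }
  point <- quantile(dts, p, type = 7, names = FALSE)
  if (degenerate) {
    upper <- point
  } else {
    if (!is.null(seed)) set.seed(seed)
    boot <- vapply(seq_len(n_boot), function(i) {
      quantile(sample(dts, replace = TRUE), p, type = 7, names = FALSE)
    }, numeric(1))
    upper <- quantile(boot, confidence, type = 7, names = FALSE)
  }
  tibble::tibble(percentile = point, withdrawal_h = upper, p = p,
                 confidence = confidence, n = length(dts), n_boot = n_boot)
}
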