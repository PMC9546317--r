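#' Population pharmacokinetic model
#'
#' Bundles the typical structural parameter values, the between-horse
#' variability (lognormal, one independent log-scale random effect per
#' parameter) and the residual-error model (combined additive +
#' proportional, separate per matrix) into a single object.
#'
#' Between-horse variability follows the exponential model
#' `P_i = theta_P * exp(eta_i)` with `eta_i ~ N(0, omega2_P)`; it can be
#' declared either as the variance `omega2` or as a lognormal CV percent
#' (converted with [omega2_from_cv()]). Exactly one of `cv` / `omega2`
#' must be given.
#'
#' @param theta Named vector of typical values (`V1, V2, V3, CL, CL2,
#'   CL3, Rss`), units as in [pk_params()].
#' @param cv Named vector of between-horse CV percent per parameter
#'   (parameters omitted get 0).
#' @param omega2 Named vector of log-scale variances per parameter
#'   (alternative to `cv`).
#' @param residual_plasma,residual_urine Lists with elements `add`
#'   (additive SD, ng/mL) and `prop` (proportional SD, fraction).
#' @return An object of class `flx_population`.
#' @examples
#' population_model(
#'   theta = c(V1 = 0.149, V2 = 0.012, V3 = 0.029, CL = 0.047,
#'             CL2 = 0.00015, CL3 = 0.00443, Rss = 36.8),
#'   cv = c(V1 = 2, V2 = 4.2, V3 = 19.1, CL = 30, CL2 = 14.8,
#'          CL3 = 10.3, Rss = 55.5))
#' @export
population_model <- function(theta, cv = NULL, omega2 = NULL,
                             residual_plasma = list(add = 0, prop = 0),
                             residual_urine = list(add = 0, prop = 0)) {
  theta <- theta[pk_param_names]
  names(theta) <- pk_param_names
  validate_pk_params(theta)
  if (is.null(cv) == is.null(omega2)) {
    abort("give exactly one of `cv` or `omega2`",
          class = "flx_error_invalid_input")
  }
  expand <- function(x) {
    out <- setNames(numeric(length(pk_param_names)), pk_param_names)
    if (!is.null(names(x))) out[names(x)] <- x else out[] <- x
    out
  }
  if (!is.null(cv)) omega2 <- omega2_from_cv(expand(cv)) else omega2 <- expand(omega2)
  if (any(omega2 < 0)) {
    abort("omega2 must be nonnegative", class = "flx_error_invalid_input")
  }
  chk_res <- function(r) {
    stopifnot(is.list(r), all(c("add", "prop") %in% names(r)))
    if (r$add < 0 || r$prop < 0) {
      abort("residual error SDs must be nonnegative",
            class = "flx_error_invalid_input")
    }
    list(add = as.numeric(r$add), prop = as.numeric(r$prop))
  }
  structure(list(theta = theta, omega2 = omega2,
                 residual = list(plasma = chk_res(residual_plasma),
                                 urine = chk_res(residual_urine))),
            class = "flx_population")
}

#' @export
print.flx_population <- function(x, ...) {
  cat("Population PK model (3-compartment IV bolus + proportional urine)\n")
  tab <- tibble::tibble(parameter = pk_param_names,
                        theta = unname(x$theta),
                        omega2 = unname(x$omega2),
                        cv_pct = cv_from_omega2(unname(x$omega2)))
  print(tab, n = Inf)
  cat(sprintf("Residual: plasma add %.4g ng/mL, prop %.4g; urine add %.4g ng/mL, prop %.4g\n",
              x$residual$plasma$add, x$residual$plasma$prop,
              x$residual$urine$add, x$residual$urine$prop))
  invisible(x)
}

#' Fitted flunixin population model shipped with the package
#'
#' The population estimates for intravenous flunixin in Thoroughbred horses
#' (typical values, between-horse CV percent per parameter, and the combined
#' residual-error components) read from the packaged configuration file.
#' These are the default generating values for the synthetic-data module
#' and the default inputs for detection-time simulation.
#'
#' @return An `flx_population`.
#' @export
default_population <- function() {
  path <- system.file("extdata", "flunixin_population.yaml",
                      package = "flunixinpk")
  cfg <- read_run_config(path)
  population_from_config(cfg$model)
}

population_from_config <- function(model) {
  population_model(
    theta = unlist(model$theta),
    cv = if (!is.null(model$cv)) unlist(model$cv) else NULL,
    omega2 = if (!is.null(model$omega2)) unlist(model$omega2) else NULL,
    residual_plasma = model$residual$plasma,
    residual_urine = model$residual$urine)
}

#' Convert a log-scale variance to a lognormal CV percent
#'
#' The standard lognormal relation `CV% = 100 * sqrt(exp(omega2) - 1)`.
#' `form = "literal"` instead applies `100 * (exp(omega2) - 1)`, a variant
#' occasionally seen in software reports; it is provided for comparison
#' only.
#'
#' @param omega2 Nonnegative log-scale variance(s).
#' @param form `"lognormal"` (default) or `"literal"`.
#' @return CV in percent.
#' @export
cv_from_omega2 <- function(omega2, form = c("lognormal", "literal")) {
  form <- match.arg(form)
  if (any(!is.finite(omega2)) || any(omega2 < 0)) {
    abort("omega2 must be nonnegative", class = "flx_error_invalid_input")
  }
  if (form == "lognormal") 100 * sqrt(exp(omega2) - 1) else 100 * (exp(omega2) - 1)
}

#' Convert a lognormal CV percent to a log-scale variance
#'
#' Exact inverse of [cv_from_omega2()]: `omega2 = log(1 + (cv/100)^2)` for
#' the lognormal form.
#'
#' @param cv CV in percent (nonnegative).
#' @param form `"lognormal"` (default) or `"literal"`.
#' @return Log-scale variance(s).
#' @export
omega2_from_cv <- function(cv, form = c("lognormal", "literal")) {
  form <- match.arg(form)
  if (any(!is.finite(cv)) || any(cv < 0)) {
    abort("cv must be nonnegative", class = "flx_error_invalid_input")
  }
  if (form == "lognormal") log(1 + (cv / 100)^2) else log(1 + cv / 100)
}

#' Draw a virtual population of horses
#'
#' Samples individual parameter sets `P_i = theta * exp(eta_i)` with
#' independent `eta_i ~ N(0, omega2)` per parameter (diagonal covariance:
#' no between-parameter correlations, which is the only reproducible
#' reading of a model reported without an off-diagonal omega block).
#'
#' @param pop An [population_model()].
#' @param n Number of individuals.
#' @param seed Optional integer seed for reproducible sampling.
#' @return Tibble with columns `subject` and the seven structural
#'   parameters; the sampled eta matrix is attached as attribute `"eta"`.
#' @export
sample_individuals <- function(pop, n, seed = NULL) {
  stopifnot(inherits(pop, "flx_population"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  eta <- vapply(pk_param_names,
                function(nm) rnorm(n, 0, sqrt(pop$omega2[[nm]])),
                numeric(n))
  eta <- matrix(eta, nrow = n,
                dimnames = list(NULL, pk_param_names))
  pars <- sweep(exp(eta), 2, pop$theta[pk_param_names], "*")
  out <- tibble::as_tibble(as.data.frame(pars))
  out <- dplyr::bind_cols(tibble::tibble(subject = seq_len(n)), out)
  attr(out, "eta") <- eta
  out
}

#' Eta shrinkage
#'
#' `shrinkage = 1 - var(eta_posthoc) / omega2`, computed per parameter from
#' the post-hoc (empirical Bayes) eta estimates. Values above 0.3 indicate
#' that the data do not support robust estimation of that random component
#' and are flagged.
#'
#' @param etas Matrix or data frame of post-hoc etas, one column per
#'   parameter, one row per subject (at least two subjects).
#' @param omega2 Named vector of log-scale variances (matching columns of
#'   `etas`). Parameters with `omega2 = 0` are reported as `NA`.
#' @param flag_above Flag threshold, default 0.3.
#' @return Tibble with columns `parameter`, `shrinkage`, `flagged`.
#' @export
shrinkage <- function(etas, omega2, flag_above = 0.3) {
  etas <- as.matrix(etas)
  if (nrow(etas) < 2) {
    abort("shrinkage needs at least two individuals",
          class = "flx_error_invalid_input")
  }
  pars <- colnames(etas) %||% names(omega2)
  om <- omega2[pars]
  sh <- ifelse(om > 0, 1 - apply(etas, 2, var) / om, NA_real_)
  tibble::tibble(parameter = pars,
                 shrinkage = unname(sh),
                 flagged = !is.na(sh) & sh > flag_above)
}

#' Apply the residual-error model to noise-free concentrations
#'
#' Observed concentrations follow `y = f * (1 + e1) + e2` with proportional
#' `e1 ~ N(0, prop^2)` and additive `e2 ~ N(0, add^2)` taken from the
#' matrix-specific residual model. Negative draws are floored at zero and
#' flagged rather than resampled, so the error distribution is preserved
#' everywhere except at the boundary.
#'
#' @param true_conc Nonnegative noise-free concentrations (ng/mL).
#' @param matrix `"plasma"` or `"urine"`.
#' @param pop An [population_model()] carrying the residual components.
#' @param seed Optional integer seed.
#' @return Tibble with columns `observed` (ng/mL) and `floored` (logical).
#' @export
apply_residual <- function(true_conc, matrix = c("plasma", "urine"), pop,
                           seed = NULL) {
  matrix <- match.arg(matrix)
  if (any(!is.finite(true_conc)) || any(true_conc < 0)) {
    abort("true concentrations must be nonnegative",
          class = "flx_error_invalid_input")
  }
  if (!is.null(seed)) set.seed(seed)
  r <- pop$residual[[matrix]]
  n <- length(true_conc)
  y <- true_conc * (1 + rnorm(n, 0, r$prop)) + rnorm(n, 0, r$add)
  floored <- y < 0
  y[floored] <- 0
  tibble::tibble(observed = y, floored = floored)
}

#' Visual-predictive-check percentiles
#'
#' Compares percentile bands of the observations with the envelope of the
#' same percentiles across simulated replicate studies of the identical
#' design (between-horse variability plus residual error), per time bin and
#' matrix.
#'
#' @param data Observation tibble in the package's dataset layout (see
#'   [generate_dataset()]); only `event == "obs"` rows are used, records
#'   flagged below the quantification limit are dropped.
#' @param pop Population model used to simulate the replicates.
#' @param design Study design (see [default_design()]) describing the
#'   replicate studies; defaults to the design reconstructed from `data`'s
#'   dose rows and observation schedule.
#' @param n_sim Number of replicate studies (>= 100).
#' @param probs Percentile levels of the bands.
#' @param envelope Coverage of the simulation envelope around each
#'   percentile, default 0.95.
#' @param seed Optional integer seed.
#' @return Tibble with one row per (matrix, time bin, level):
#'   `matrix`, `time_h`, `level`, `observed`, `sim_lo`, `sim_med`,
#'   `sim_hi`, `n_obs`. Empty bins are dropped with a warning.
#' @export
vpc_percentiles <- function(data, pop, design = NULL, n_sim = 200,
                            probs = c(0.1, 0.5, 0.9), envelope = 0.95,
                            seed = NULL) {
  if (n_sim < 100) {
    abort("n_sim must be at least 100", class = "flx_error_invalid_input")
  }
  if (!is.null(seed)) set.seed(seed)
  obs <- dplyr::filter(data, .data$event == "obs", !.data$blq)
  if (nrow(obs) == 0) {
    abort("no quantifiable observations", class = "flx_error_invalid_input")
  }
  if (is.null(design)) design <- design_from_dataset(data)

  band <- function(d) {
    dplyr::reframe(dplyr::group_by(d, .data$matrix, .data$time_h),
                   level = probs,
                   value = quantile(.data$conc_ng_per_ml, probs, type = 7),
                   n_obs = dplyr::n())
  }
  obs_band <- band(obs)

  sims <- purrr::map(seq_len(n_sim), function(i) {
    d <- generate_dataset(pop, design)
    band(dplyr::filter(d, .data$event == "obs", !.data$blq))
  })
  sim_all <- dplyr::bind_rows(sims, .id = "replicate")
  a <- (1 - envelope) / 2
  sim_env <- dplyr::summarise(
    dplyr::group_by(sim_all, .data$matrix, .data$time_h, .data$level),
    sim_lo = quantile(.data$value, a),
    sim_med = quantile(.data$value, 0.5),
    sim_hi = quantile(.data$value, 1 - a),
    .groups = "drop")

  out <- dplyr::inner_join(obs_band, sim_env,
                           by = c("matrix", "time_h", "level"))
  lost <- nrow(obs_band) - nrow(out)
  if (lost > 0) {
    warn(sprintf("%d observed bin/level combinations had no simulated counterpart and were dropped", lost))
  }
  dplyr::rename(out, observed = "value")
}
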