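#' Structural parameters of the three-compartment disposition model
#'
#' Builds a validated named parameter vector for the mammillary
#' three-compartment intravenous-bolus model with a plasma-proportional
#' urine model. All quantities are bodyweight-normalised: volumes in L/kg,
#' clearances in L/kg/h. `Rss` is the dimensionless steady-state
#' urine-to-plasma concentration ratio.
#'
#' @param V1 Central volume of distribution (L/kg).
#' @param V2,V3 Peripheral volumes of distribution (L/kg).
#' @param CL Plasma (elimination) clearance (L/kg/h).
#' @param CL2,CL3 Inter-compartmental distribution clearances (L/kg/h).
#' @param Rss Steady-state urine-to-plasma concentration ratio (unitless).
#'
#' @return A named numeric vector with elements
#'   `V1, V2, V3, CL, CL2, CL3, Rss`.
#' @examples
#' pk_params(V1 = 0.149, V2 = 0.012, V3 = 0.029,
#'           CL = 0.047, CL2 = 0.00015, CL3 = 0.00443, Rss = 36.8)
#' @export
pk_params <- function(V1, V2, V3, CL, CL2, CL3, Rss) {
  p <- c(V1 = V1, V2 = V2, V3 = V3, CL = CL,
         CL2 = CL2, CL3 = CL3, Rss = Rss)
  validate_pk_params(p)
  p
}

pk_param_names <- c("V1", "V2", "V3", "CL", "CL2", "CL3", "Rss")

validate_pk_params <- function(p, require_rss = TRUE) {
  need <- if (require_rss) pk_param_names else setdiff(pk_param_names, "Rss")
  if (!all(need %in% names(p))) {
    abort(paste0("missing parameter(s): ",
                 paste(setdiff(need, names(p)), collapse = ", ")),
          class = "flx_error_invalid_parameter")
  }
  bad <- names(p)[!is.finite(p) | p <= 0]
  # distribution clearances may be zero (degenerate exchange), volumes and CL
  # must be strictly positive
  bad <- setdiff(bad, intersect(c("CL2", "CL3"), names(p)[p == 0]))
  if (length(bad)) {
    abort(paste0("non-positive or non-finite parameter(s): ",
                 paste(bad, collapse = ", ")),
          class = "flx_error_invalid_parameter")
  }
  invisible(p)
}

#' Micro rate constants of the mammillary model
#'
#' Converts volumes and clearances to first-order rate constants:
#' `k10 = CL/V1`, `k12 = CL2/V1`, `k21 = CL2/V2`, `k13 = CL3/V1`,
#' `k31 = CL3/V3`.
#'
#' @param p Named parameter vector as returned by [pk_params()].
#' @return Named numeric vector `k10, k12, k21, k13, k31` (1/h).
#' @export
micro_rates <- function(p) {
  validate_pk_params(p, require_rss = FALSE)
  c(k10 = unname(p["CL"] / p["V1"]),
    k12 = unname(p["CL2"] / p["V1"]),
    k21 = unname(p["CL2"] / p["V2"]),
    k13 = unname(p["CL3"] / p["V1"]),
    k31 = unname(p["CL3"] / p["V3"]))
}

# 3x3 first-order rate matrix for amounts (per kg), columns act on
# c(central, peripheral2, peripheral3)
rate_matrix <- function(m) {
  matrix(c(-(m[["k10"]] + m[["k12"]] + m[["k13"]]), m[["k21"]], m[["k31"]],
           m[["k12"]], -m[["k21"]], 0,
           m[["k13"]], 0, -m[["k31"]]),
         nrow = 3, byrow = TRUE)
}

# Disposition eigenvalues (positive, descending). Uses a diagonal similarity
# transform to a symmetric matrix when the exchange rates permit it, which is
# far better conditioned near the interlacing bounds than the cubic formula.
disposition_eigenvalues <- function(m, tol = 1e-9) {
  if (all(m[c("k12", "k21", "k13", "k31")] > 0)) {
    d <- c(1, sqrt(m[["k21"]] / m[["k12"]]), sqrt(m[["k31"]] / m[["k13"]]))
    K <- rate_matrix(m)
    S <- diag(d) %*% K %*% diag(1 / d) # S[i,j] = d_i K_ij / d_j, symmetric
    S <- (S + t(S)) / 2
    lam <- -eigen(S, symmetric = TRUE, only.values = TRUE)$values
  } else {
    ev <- eigen(rate_matrix(m), only.values = TRUE)$values
    if (any(abs(Im(ev)) > tol * max(abs(ev)))) {
      abort("complex disposition eigenvalues: invalid rate constants",
            class = "flx_error_degenerate_model")
    }
    lam <- -Re(ev)
  }
  lam <- sort(lam, decreasing = TRUE)
  if (any(lam <= 0)) {
    abort("non-positive disposition eigenvalue: model has no tri-exponential solution (zero exchange or elimination rate)",
          class = "flx_error_degenerate_model")
  }
  if (min(diff(-lam)) < tol * max(lam)) {
    abort("repeated disposition eigenvalues within tolerance: degenerate tri-exponential",
          class = "flx_error_degenerate_model")
  }
  lam
}

#' Macro (exponential) constants of the intravenous-bolus solution
#'
#' Solves the characteristic system of the three-compartment model for the
#' exponential rates and intercepts of the tri-exponential plasma
#' concentration `C(t) = A1 exp(-lambda1 t) + A2 exp(-lambda2 t) +
#' A3 exp(-lambda3 t)` after a single IV bolus. Rates are strictly ordered
#' `lambda1 > lambda2 > lambda3 > 0` and interlace the exchange rates
#' (`lambda3 < min(k21, k31)`); the intercepts satisfy
#' `A1 + A2 + A3 = C(0) = dose/V1`.
#'
#' @param m Micro rate constants from [micro_rates()].
#' @param dose Dose per administration (mg/kg bodyweight).
#' @param V1 Central volume (L/kg).
#' @return A list of class `flx_macro` with elements `lambda` (1/h,
#'   descending) and `A` (ng/mL, same order).
#' @export
macro_constants <- function(m, dose, V1) {
  if (!is.finite(dose) || dose < 0) {
    abort("dose must be a nonnegative number", class = "flx_error_invalid_parameter")
  }
  lam <- disposition_eigenvalues(m)
  C0 <- dose_to_c0(dose, V1)
  A <- vapply(1:3, function(i) {
    j <- setdiff(1:3, i)
    C0 * (m[["k21"]] - lam[i]) * (m[["k31"]] - lam[i]) /
      ((lam[j[1]] - lam[i]) * (lam[j[2]] - lam[i]))
  }, numeric(1))
  structure(list(lambda = lam, A = A), class = "flx_macro")
}

# 1 mg/kg in a volume V1 L/kg gives 1/V1 mg/L = 1000/V1 ng/mL
dose_to_c0 <- function(dose, V1) dose * 1000 / V1

#' @export
print.flx_macro <- function(x, ...) {
  cat("Tri-exponential IV-bolus solution\n")
  cat("  lambda (1/h):   ", format(x$lambda, digits = 4), "\n")
  cat("  half-lives (h): ", format(log(2) / x$lambda, digits = 4), "\n")
  cat("  A (ng/mL):      ", format(x$A, digits = 4), "\n")
  invisible(x)
}

#' Dosing regimen for repeated IV bolus administration
#'
#' @param dose Dose per administration (mg/kg bodyweight).
#' @param interval Inter-dose interval (h); ignored when `n_doses = 1`.
#' @param n_doses Number of administrations (doses are given at
#'   `0, interval, ..., (n_doses - 1) * interval` hours).
#' @return An object of class `flx_regimen`.
#' @examples
#' regimen(1.1, 24, 5) # 1.1 mg/kg q24h for 5 days
#' @export
regimen <- function(dose = 1.1, interval = 24, n_doses = 1) {
  if (!is.finite(dose) || dose <= 0) {
    abort("dose must be positive", class = "flx_error_invalid_parameter")
  }
  if (n_doses < 1 || n_doses != round(n_doses)) {
    abort("n_doses must be a positive integer", class = "flx_error_invalid_parameter")
  }
  if (n_doses > 1 && (!is.finite(interval) || interval <= 0)) {
    abort("interval must be positive for multiple dosing",
          class = "flx_error_invalid_parameter")
  }
  structure(list(dose = dose, interval = interval, n_doses = as.integer(n_doses),
                 route = "iv_bolus"),
            class = "flx_regimen")
}

#' @export
print.flx_regimen <- function(x, ...) {
  if (x$n_doses == 1L) {
    cat(sprintf("IV bolus %g mg/kg, single dose\n", x$dose))
  } else {
    cat(sprintf("IV bolus %g mg/kg q%gh x %d doses (last at %g h)\n",
                x$dose, x$interval, x$n_doses, max(dose_times(x))))
  }
  invisible(x)
}

#' Administration times of a regimen
#'
#' @param reg A [regimen()].
#' @return Numeric vector of dose times in hours since the first dose.
#' @export
dose_times <- function(reg) {
  (seq_len(reg$n_doses) - 1) * ifelse(reg$n_doses > 1, reg$interval, 0)
}

#' The four regimens used for detection-time reporting
#'
#' Single dose; two doses 12 h apart ("q12h for one day"); five daily doses;
#' and ten doses at 12-h intervals over five days.
#'
#' @param dose Dose per administration (mg/kg), default 1.1.
#' @return Named list of [regimen()] objects.
#' @export
standard_regimens <- function(dose = 1.1) {
  list(single   = regimen(dose, 24, 1),
       q12h_1d  = regimen(dose, 12, 2),
       q24h_5d  = regimen(dose, 24, 5),
       q12h_5d  = regimen(dose, 12, 10))
}

#' Plasma concentration under multiple-dose superposition
#'
#' Evaluates the tri-exponential solution at arbitrary times, summing the
#' time-shifted single-dose solutions over every administration at or before
#' `t` (the model is linear, so superposition is exact). The value reported
#' at a dose instant is the post-bolus (right-continuous) value; times before
#' the first dose give 0.
#'
#' @param mc Macro constants from [macro_constants()] for one administration.
#' @param reg A [regimen()]; the dose must match the one used for `mc`.
#' @param t Times in hours since the first administration (any numeric
#'   vector).
#' @return Numeric vector of plasma concentrations (ng/mL).
#' @export
plasma_concentration <- function(mc, reg, t) {
  td <- dose_times(reg)
  out <- numeric(length(t))
  for (d in td) {
    on <- t >= d
    if (!any(on)) next
    dt <- t[on] - d
    out[on] <- out[on] +
      mc$A[1] * exp(-mc$lambda[1] * dt) +
      mc$A[2] * exp(-mc$lambda[2] * dt) +
      mc$A[3] * exp(-mc$lambda[3] * dt)
  }
  out
}

#' Urine concentration from the plasma-proportional model
#'
#' The urine model asserts `C_urine = Rss * C_plasma`. The proportionality
#' is a pseudo-distribution-equilibrium result: it is physiologically
#' meaningful from about 24 h after an administration onwards, and callers
#' interpreting earlier times should treat the value as an extrapolation.
#'
#' @param plasma_conc Nonnegative plasma concentrations (ng/mL).
#' @param Rss Urine-to-plasma concentration ratio (> 0).
#' @return Urine concentrations (ng/mL).
#' @export
urine_concentration <- function(plasma_conc, Rss) {
  if (any(!is.finite(plasma_conc)) || any(plasma_conc < 0)) {
    abort("plasma concentrations must be nonnegative",
          class = "flx_error_invalid_input")
  }
  if (!is.finite(Rss) || Rss <= 0) {
    abort("Rss must be positive", class = "flx_error_invalid_parameter")
  }
  Rss * plasma_conc
}

#' Secondary disposition parameters
#'
#' Half-lives of the three exponential phases (`ln 2 / lambda`), steady-state
#' volume of distribution `Vss = V1 + V2 + V3` and mean residence time
#' `MRT = Vss / CL`.
#'
#' @param p Named parameter vector as returned by [pk_params()].
#' @return One-row tibble with columns `half_life_alpha`, `half_life_beta`,
#'   `half_life_gamma` (h), `Vss` (L/kg) and `MRT` (h).
#' @examples
#' secondary_parameters(pk_params(0.151, 0.013, 0.03, 0.046,
#'                                0.00015, 0.00429, 37.1))
#' @export
secondary_parameters <- function(p) {
  validate_pk_params(p, require_rss = FALSE)
  lam <- disposition_eigenvalues(micro_rates(p))
  hl <- log(2) / lam # descending lambda -> ascending half-life
  Vss <- unname(p[["V1"]] + p[["V2"]] + p[["V3"]])
  tibble::tibble(half_life_alpha = hl[1],
                 half_life_beta  = hl[2],
                 half_life_gamma = hl[3],
                 Vss = Vss,
                 MRT = Vss / unname(p[["CL"]]))
}

# Exponential rates and intercept fractions of the tri-exponential solution,
# on the fast path: the symmetric similarity transform solved with the
# closed-form (trigonometric) eigenvalue formulas for symmetric 3x3
# matrices, which are stable because the roots are real by construction.
# Falls back to the LAPACK route for degenerate exchange rates.
tri_exp_terms <- function(k10, k12, k21, k13, k31) {
  if (k12 <= 0 || k21 <= 0 || k13 <= 0 || k31 <= 0) {
    lam <- disposition_eigenvalues(c(k10 = k10, k12 = k12, k21 = k21,
                                     k13 = k13, k31 = k31))
  } else {
    a11 <- -(k10 + k12 + k13)
    a12 <- sqrt(k12 * k21)
    a13 <- sqrt(k13 * k31)
    p1 <- a12 * a12 + a13 * a13
    q <- (a11 - k21 - k31) / 3
    b11 <- a11 - q; b22 <- -k21 - q; b33 <- -k31 - q
    p2 <- b11 * b11 + b22 * b22 + b33 * b33 + 2 * p1
    pp <- sqrt(p2 / 6)
    if (!is.finite(pp) || pp <= 0) {
      lam <- disposition_eigenvalues(c(k10 = k10, k12 = k12, k21 = k21,
                                       k13 = k13, k31 = k31))
    } else {
      detB <- (b11 * b22 * b33 - a13 * a13 * b22 - a12 * a12 * b33) / pp^3
      r <- min(max(detB / 2, -1), 1)
      phi <- acos(r) / 3
      e1 <- q + 2 * pp * cos(phi)
      e3 <- q + 2 * pp * cos(phi + 2 * pi / 3)
      e2 <- 3 * q - e1 - e3
      lam <- c(-e3, -e2, -e1) # descending, positive for a valid model
      # polish to machine precision on the characteristic cubic
      # (roots are simple, so two Newton steps suffice)
      s1 <- k10 + k12 + k13 + k21 + k31
      s2 <- k10 * (k21 + k31) + k21 * k31 + k12 * k31 + k13 * k21
      s3 <- k10 * k21 * k31
      for (it in 1:2) {
        cval <- ((lam - s1) * lam + s2) * lam - s3
        cder <- (3 * lam - 2 * s1) * lam + s2
        lam <- lam - cval / cder
      }
      if (!all(is.finite(lam)) || lam[3] <= 0 ||
          lam[1] - lam[2] < 1e-9 * lam[1] || lam[2] - lam[3] < 1e-9 * lam[1]) {
        lam <- disposition_eigenvalues(c(k10 = k10, k12 = k12, k21 = k21,
                                         k13 = k13, k31 = k31))
      }
    }
  }
  d21 <- lam[2] - lam[1]; d31 <- lam[3] - lam[1]; d32 <- lam[3] - lam[2]
  frac <- c((k21 - lam[1]) * (k31 - lam[1]) / (d21 * d31),
            (k21 - lam[2]) * (k31 - lam[2]) / (-d21 * d32),
            (k21 - lam[3]) * (k31 - lam[3]) / (d31 * d32))
  list(lambda = lam, frac = frac)
}

# Fast internal evaluator used by simulation and estimation: concentrations
# for one individual at arbitrary (time, matrix) rows under arbitrary dose
# times/amounts. Returns ng/mL. `predose = TRUE` excludes a bolus given at
# exactly the sampling time (trough-sampling convention).
conc_eval <- function(p, dose_t, dose_amt, time, matrix, predose = FALSE) {
  V1 <- p[["V1"]]
  te <- tri_exp_terms(p[["CL"]] / V1, p[["CL2"]] / V1, p[["CL2"]] / p[["V2"]],
                      p[["CL3"]] / V1, p[["CL3"]] / p[["V3"]])
  lam <- te$lambda
  A1 <- 1000 / V1 * te$frac # per mg/kg
  out <- numeric(length(time))
  for (k in seq_along(dose_t)) {
    on <- if (predose) time > dose_t[k] else time >= dose_t[k]
    if (!any(on)) next
    dt <- time[on] - dose_t[k]
    out[on] <- out[on] + dose_amt[k] *
      (A1[1] * exp(-lam[1] * dt) + A1[2] * exp(-lam[2] * dt) +
         A1[3] * exp(-lam[3] * dt))
  }
  if (!is.null(matrix)) {
    u <- matrix == "urine"
    if (any(u)) out[u] <- out[u] * p[["Rss"]]
  }
  out
}

# Concentration and its analytic Jacobian with respect to the log
# parameters (equivalently the etas, since d/d log p = d/d eta for
# lognormal parameters). Uses first-order eigenvalue perturbation on the
# symmetric similarity transform: dlambda_i = -v_i' dS v_i with orthonormal
# eigenvectors v_i. Returns list(f, J) with J of dimension
# length(time) x 7 (column order V1, V2, V3, CL, CL2, CL3, Rss), or NULL
# when the model is too close to degenerate for the perturbation formulas
# (callers then fall back to finite differences).
conc_eval_grad <- function(p, dose_t, dose_amt, time, matrix,
                           predose = FALSE) {
  V1 <- p[["V1"]]
  k10 <- p[["CL"]] / V1; k12 <- p[["CL2"]] / V1; k21 <- p[["CL2"]] / p[["V2"]]
  k13 <- p[["CL3"]] / V1; k31 <- p[["CL3"]] / p[["V3"]]
  if (k12 <= 0 || k21 <= 0 || k13 <= 0 || k31 <= 0) return(NULL)
  te <- tri_exp_terms(k10, k12, k21, k13, k31)
  lam <- te$lambda
  frac <- te$frac

  # Eigenvectors of the symmetric similarity matrix for eigenvalue
  # e = -lambda, with S22 = -k21, S33 = -k31, S23 = 0: up to normalisation
  # v = (1, -S12/(lambda - k21), -S13/(lambda - k31)). Vectorised over the
  # three phases.
  S12 <- sqrt(k12 * k21); S13 <- sqrt(k13 * k31)
  d2 <- lam - k21; d3 <- lam - k31
  if (any(abs(d2) < 1e-10 * lam[1]) || any(abs(d3) < 1e-10 * lam[1])) {
    return(NULL) # eigenvalue at an interlacing bound: perturbation unsafe
  }
  v2 <- -S12 / d2; v3 <- -S13 / d3
  nrm <- 1 + v2 * v2 + v3 * v3
  w1 <- 1 / nrm; w2 <- v2 * v2 / nrm; w3 <- v3 * v3 / nrm
  c12 <- 2 * v2 / nrm; c13 <- 2 * v3 / nrm

  # dlambda_i/deta_j = -v_i' (dS/deta_j) v_i, expanded per eta column
  # (column order V1, V2, V3, CL, CL2, CL3, Rss); each k entering S is a
  # ratio of lognormal parameters, so d k / d eta = +/- k
  ksum <- k10 + k12 + k13
  dlam <- cbind(-w1 * ksum + (c12 * S12 + c13 * S13) / 2, # V1
                -w2 * k21 + c12 * S12 / 2,                # V2
                -w3 * k31 + c13 * S13 / 2,                # V3
                w1 * k10,                                 # CL
                w1 * k12 + w2 * k21 - c12 * S12,          # CL2
                w1 * k13 + w3 * k31 - c13 * S13,          # CL3
                0)                                        # Rss

  # d k21 / d eta and d k31 / d eta as 7-vectors
  dk21 <- c(0, -k21, 0, 0, k21, 0, 0)
  dk31 <- c(0, 0, -k31, 0, 0, k31, 0)

  # d frac_i / d eta by the quotient rule on
  # frac_i = (k21 - lam_i)(k31 - lam_i) / prod_{j != i}(lam_j - lam_i)
  dfrac <- matrix(0, 3, 7)
  for (i in 1:3) {
    j <- if (i == 1) c(2L, 3L) else if (i == 2) c(1L, 3L) else c(1L, 2L)
    Di <- (lam[j[1]] - lam[i]) * (lam[j[2]] - lam[i])
    dNi <- (dk21 - dlam[i, ]) * (-d3[i]) + (-d2[i]) * (dk31 - dlam[i, ])
    dDi <- (dlam[j[1], ] - dlam[i, ]) * (lam[j[2]] - lam[i]) +
      (lam[j[1]] - lam[i]) * (dlam[j[2], ] - dlam[i, ])
    dfrac[i, ] <- (dNi - frac[i] * dDi) / Di
  }

  # per-unit-dose intercepts a_i = 1000 frac_i / V1 and their derivatives
  a <- 1000 * frac / V1
  da <- 1000 * dfrac / V1
  da[, 1] <- da[, 1] - a # V1 column: d(1/V1)/d eta_V1 = -1/V1

  # accumulate the bolus history once per phase:
  # f = sum_i a_i P_i,  J = P %*% da - (Q a_i-scaled) %*% dlam
  # with P_i(t) = sum_d amt_d exp(-lam_i (t - t_d)) and
  # Q_i(t) = sum_d amt_d (t - t_d) exp(-lam_i (t - t_d))
  n <- length(time)
  P <- matrix(0, n, 3)
  Q <- matrix(0, n, 3)
  for (k in seq_along(dose_t)) {
    on <- if (predose) time > dose_t[k] else time >= dose_t[k]
    if (!any(on)) next
    dt <- time[on] - dose_t[k]
    for (i in 1:3) {
      E <- dose_amt[k] * exp(-lam[i] * dt)
      P[on, i] <- P[on, i] + E
      Q[on, i] <- Q[on, i] + E * dt
    }
  }
  f <- as.numeric(P %*% a)
  J <- P %*% da - (Q * rep(a, each = n)) %*% dlam
  colnames(J) <- pk_param_names
  if (!is.null(matrix)) {
    u <- matrix == "urine"
    if (any(u)) {
      Rss <- p[["Rss"]]
      J[u, ] <- J[u, ] * Rss
      J[u, "Rss"] <- J[u, "Rss"] + Rss * f[u] # d(Rss f)/d eta_Rss = Rss f
      f[u] <- f[u] * Rss
    }
  }
  list(f = f, J = J)
}

#' Simulate concentration-time profiles for a set of individuals
#'
#' Evaluates noise-free (IPRED-style) profiles for every individual in a
#' parameter table, in plasma and/or urine (urine via the `Rss`
#' proportionality).
#'
#' @param horses Data frame with one row per individual and columns
#'   `V1, V2, V3, CL, CL2, CL3, Rss` (e.g. from [sample_individuals()]);
#'   a `subject` column is carried through if present.
#' @param reg A [regimen()].
#' @param times Sampling times (h since the first dose).
#' @param matrix `"plasma"`, `"urine"`, or both.
#' @return Long tibble with columns `subject`, `time_h`, `matrix`,
#'   `conc_ng_per_ml`.
#' @export
simulate_profiles <- function(horses, reg, times,
                              matrix = c("plasma", "urine")) {
  matrix <- match.arg(matrix, several.ok = TRUE)
  horses <- tibble::as_tibble(horses)
  if (!"subject" %in% names(horses)) horses$subject <- seq_len(nrow(horses))
  td <- dose_times(reg)
  amt <- rep(reg$dose, length(td))
  grid <- tidyr::expand_grid(time_h = times, matrix = matrix)
  purrr::map_dfr(seq_len(nrow(horses)), function(i) {
    p <- as.numeric(horses[i, pk_param_names])
    names(p) <- pk_param_names
    tibble::tibble(subject = horses$subject[i],
                   time_h = grid$time_h,
                   matrix = grid$matrix,
                   conc_ng_per_ml = conc_eval(p, td, amt, grid$time_h,
                                              grid$matrix))
  })
}
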