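#' Settings for the population fit
#'
#' @param urine_rule Urine records enter the joint fit only after
#'   pseudo-distribution equilibrium: `"per_dose"` (default) requires
#'   `time - time of most recent administration >= urine_lag`;
#'   `"first_dose"` requires `time >= urine_lag` counted from the first
#'   administration only.
#' @param urine_lag Equilibration lag in hours, default 24.
#' @param estimate_omega2 Estimate the between-horse variances (default
#'   TRUE). When FALSE the variances are fixed at their initial values;
#'   fixing them all at zero reduces the model to a naive pooled fit.
#' @param estimate_sigma Estimate the residual-error components (default
#'   TRUE).
#' @param max_iter Maximum outer iterations, default 500.
#' @param rel_tol Relative objective-change convergence tolerance of the
#'   outer problem, default 1e-6 (parameters are additionally required to
#'   move by less than about 1e-4 relative at convergence).
#' @param inner_max_iter,inner_tol Inner (eta posterior mode) Gauss-Newton
#'   iteration cap and relative tolerance.
#' @param max_restarts The outer optimiser is restarted from its stopping
#'   point after a false-convergence report, at most this many times.
#' @return A settings list.
#' @export
fit_settings <- function(urine_rule = c("per_dose", "first_dose"),
                         urine_lag = 24, estimate_omega2 = TRUE,
                         estimate_sigma = TRUE, max_iter = 500,
                         rel_tol = 1e-6, inner_max_iter = 40,
                         inner_tol = 1e-9, max_restarts = 4) {
  list(urine_rule = match.arg(urine_rule), urine_lag = urine_lag,
       estimate_omega2 = estimate_omega2, estimate_sigma = estimate_sigma,
       max_iter = max_iter, rel_tol = rel_tol,
       inner_max_iter = inner_max_iter, inner_tol = inner_tol,
       max_restarts = max_restarts)
}

# ---- data preparation -------------------------------------------------------

# Split a dataset into per-subject fitting units. Below-quantification
# records are excluded from all objectives (M1 handling); urine records are
# restricted by the equilibration rule.
prepare_fit_data <- function(data, settings) {
  obs <- dplyr::filter(data, .data$event == "obs")
  doses <- dplyr::filter(data, .data$event == "dose")
  if (nrow(obs) == 0) {
    abort("dataset has no observations", class = "flx_error_invalid_input")
  }
  missing_dose <- setdiff(unique(obs$subject), unique(doses$subject))
  if (length(missing_dose)) {
    abort(paste0("subjects without dosing records: ",
                 paste(missing_dose, collapse = ", ")),
          class = "flx_error_invalid_input")
  }
  n_blq <- sum(obs$blq)
  obs <- dplyr::filter(obs, !.data$blq)

  units <- lapply(split(obs, obs$subject), function(o) {
    d <- doses[doses$subject == o$subject[1], ]
    d <- d[order(d$time_h), ]
    last_admin <- vapply(o$time_h, function(t) {
      prev <- d$time_h[d$time_h < t | (d$time_h == t & t == 0)]
      if (length(prev)) max(prev) else d$time_h[1]
    }, numeric(1))
    keep <- o$matrix == "plasma" |
      (if (settings$urine_rule == "per_dose") {
        o$time_h - last_admin >= settings$urine_lag
      } else {
        o$time_h >= settings$urine_lag
      })
    o <- o[keep, ]
    list(subject = o$subject[1], time = o$time_h, matrix = o$matrix,
         y = o$conc_ng_per_ml, dose_t = d$time_h,
         dose_amt = d$amount_mg_per_kg,
         arm = if ("arm" %in% names(o)) o$arm[1] else "all")
  })
  units <- units[vapply(units, function(u) length(u$y) > 0, logical(1))]
  list(units = units, n_blq = n_blq)
}

# residual variance under the combined error model
res_var <- function(f, matrix, sigma) {
  add <- ifelse(matrix == "urine", sigma[["add_urine"]], sigma[["add_plasma"]])
  add^2 + (sigma[["prop"]] * f)^2
}

# ---- initial estimates ------------------------------------------------------

# Peel exponential phases from a decaying curve, slowest first. Returns
# list(lambda, A) in descending lambda order, or NULL when peeling fails.
peel_exponentials <- function(s, y, n_phases = 3) {
  ok <- y > 0
  s <- s[ok]; y <- y[ok]
  lam <- numeric(0); A <- numeric(0)
  res <- y
  for (ph in seq_len(n_phases)) {
    use <- which(res > 0)
    if (length(use) < 2) return(NULL)
    # latest third of the surviving points, at least 3 (2 for the last phase)
    need <- if (ph < n_phases) max(3, ceiling(length(use) / 3)) else length(use)
    pts <- use[order(s[use])]
    pts <- tail(pts, need)
    fit <- lm(log(res[pts]) ~ s[pts])
    l <- -coef(fit)[[2]]; a <- exp(coef(fit)[[1]])
    if (!is.finite(l) || l <= 0 || !is.finite(a)) return(NULL)
    lam <- c(lam, l); A <- c(A, a)
    res <- res - a * exp(-l * s)
    res[s >= min(s[pts])] <- -1 # consumed by this phase
    if (all(res <= 0) && ph < n_phases) return(NULL)
  }
  o <- order(lam, decreasing = TRUE)
  list(lambda = lam[o], A = A[o])
}

# Invert a tri-exponential (lambda descending, A for a single dose) to the
# mammillary micro constants and volumes/clearances.
macro_to_params <- function(lambda, A, dose) {
  C0 <- sum(A)
  if (C0 <= 0) return(NULL)
  f <- A / C0
  V1 <- dose * 1000 / C0
  # quadratic whose roots are -k21, -k31:
  #   sum_i f_i (s + lambda_j)(s + lambda_k) = s^2 + b s + c
  b <- sum(f * (sum(lambda) - lambda))
  c2 <- f[1] * lambda[2] * lambda[3] + f[2] * lambda[1] * lambda[3] +
    f[3] * lambda[1] * lambda[2]
  disc <- b^2 - 4 * c2
  if (disc < 0) return(NULL)
  k21 <- (b - sqrt(disc)) / 2
  k31 <- (b + sqrt(disc)) / 2
  if (k21 <= 0 || k31 <= 0) return(NULL)
  k10 <- prod(lambda) / (k21 * k31)
  s1 <- sum(lambda) - k10 - k21 - k31
  pairsum <- lambda[1] * lambda[2] + lambda[1] * lambda[3] +
    lambda[2] * lambda[3]
  s2 <- pairsum - k21 * k31 - k10 * (k21 + k31)
  if (abs(k31 - k21) < 1e-12) return(NULL)
  k12 <- (s2 - k21 * s1) / (k31 - k21)
  k13 <- s1 - k12
  eps <- 1e-6
  k12 <- max(k12, eps * k10); k13 <- max(k13, eps * k10)
  p <- c(V1 = V1, V2 = k12 * V1 / k21, V3 = k13 * V1 / k31,
         CL = k10 * V1, CL2 = k12 * V1, CL3 = k13 * V1, Rss = 1)
  if (any(!is.finite(p)) || any(p <= 0)) return(NULL)
  p
}

# Curve-stripping initial estimate for one subject. Works on data at or
# after the last administration, where the profile is a (superposed)
# tri-exponential, then deflates the intercepts by the accumulation factors.
init_from_subject <- function(u) {
  pl <- u$matrix == "plasma"
  t_last <- max(u$dose_t)
  use <- pl & u$time >= t_last
  s <- u$time[use] - t_last
  y <- u$y[use]
  pe <- peel_exponentials(s, y)
  p <- NULL
  if (!is.null(pe)) {
    B <- vapply(pe$lambda, function(l) sum(exp(-l * (t_last - u$dose_t))),
                numeric(1))
    p <- macro_to_params(pe$lambda, pe$A / B, u$dose_amt[1])
  }
  if (is.null(p)) return(NULL)
  # Rss from the ratio of urine observations to the plasma model
  ur <- which(u$matrix == "urine")
  if (length(ur)) {
    fpl <- conc_eval(p, u$dose_t, u$dose_amt, u$time[ur],
                     NULL, predose = TRUE)
    ratio <- u$y[ur][fpl > 0] / fpl[fpl > 0]
    if (length(ratio)) p["Rss"] <- median(ratio)
  }
  validate_pk_params(p)
  p
}

# ---- individual (single-subject) fit ---------------------------------------

# Damped Gauss-Newton on a weighted least-squares objective in log-parameter
# space; `fun(logp)` returns predictions, weights are refreshed from the
# residual model each iteration (IRLS). `include_logv` adds the sum of log
# residual variances (the likelihood form used by the inner eta problem);
# the plain weighted-least-squares form omits it. `jac(logp)`, when given,
# returns the analytic Jacobian of the predictions; otherwise forward
# differences are used.
gauss_newton <- function(start, fun, y, var_fun, penalty = NULL,
                         include_logv = FALSE, max_iter = 50, tol = 1e-10,
                         fd_step = 1e-4, jac = NULL) {
  x <- start
  f <- fun(x)
  obj_of <- function(f, x) {
    v <- var_fun(f)
    o <- sum((y - f)^2 / v)
    if (include_logv) o <- o + sum(log(v))
    if (!is.null(penalty)) o <- o + sum(x[penalty]^2)
    o
  }
  obj <- obj_of(f, x)
  damp <- 1e-6
  converged <- FALSE
  J <- NULL
  for (it in seq_len(max_iter)) {
    v <- var_fun(f)
    w <- 1 / v
    J <- if (!is.null(jac)) jac(x) else NULL
    if (is.null(J)) {
      J <- vapply(seq_along(x), function(k) {
        xk <- x; xk[k] <- xk[k] + fd_step
        (fun(xk) - f) / fd_step
      }, numeric(length(y)))
    }
    J <- matrix(J, nrow = length(y))
    r <- y - f
    Hw <- crossprod(J, J * w)
    g <- crossprod(J, r * w)
    if (!is.null(penalty)) {
      diag(Hw)[penalty] <- diag(Hw)[penalty] + 1
      g[penalty] <- g[penalty] - x[penalty]
    }
    ok <- FALSE
    for (try in 1:10) {
      H <- Hw; diag(H) <- diag(H) * (1 + damp) + 1e-12
      delta <- tryCatch(solve(H, g), error = function(e) NULL)
      if (!is.null(delta)) {
        xn <- x + as.numeric(delta)
        fn <- tryCatch(fun(xn), error = function(e) NULL)
        if (!is.null(fn) && all(is.finite(fn))) {
          objn <- obj_of(fn, xn)
          if (is.finite(objn) && objn <= obj + 1e-12) {
            ok <- TRUE
            break
          }
        }
      }
      damp <- damp * 10
    }
    if (!ok) break
    moved <- max(abs(xn - x))
    conv <- abs(obj - objn) < tol * (abs(obj) + 1)
    x <- xn; f <- fn; obj <- objn
    damp <- max(damp / 3, 1e-8)
    if (conv || moved < 1e-10) {
      converged <- TRUE
      break
    }
  }
  list(x = x, f = f, objective = obj, converged = converged, J = J,
       iterations = it)
}

#' Fit the structural model to a single subject
#'
#' Minimises the residual-model-weighted least-squares objective over the
#' log structural parameters for one subject's quantifiable records, by
#' damped Gauss-Newton. Used to initialise the population fit and as the
#' degenerate (no between-horse variability) reference.
#'
#' @param data Dataset tibble (see [generate_dataset()]); must contain
#'   exactly one subject, or use `subject` to pick one.
#' @param init Named starting parameter vector; `NULL` uses a
#'   curve-stripping estimate from the subject's own data.
#' @param residual List with `plasma`/`urine` components each holding
#'   `add` and `prop` (the weighting model; not estimated here).
#' @param subject Optional subject id to extract from `data`.
#' @param settings See [fit_settings()] (urine eligibility applies).
#' @return List with `params` (named vector), `objective` (weighted SSQ
#'   plus log-variance terms), `converged`, `iterations`, `n_obs`.
#' @export
individual_fit <- function(data, init = NULL,
                           residual = list(plasma = list(add = 0.063, prop = 0.3),
                                           urine = list(add = 0.080, prop = 0.3)),
                           subject = NULL, settings = fit_settings()) {
  if (!is.null(subject)) {
    data <- dplyr::filter(data, .data$subject == !!subject)
  }
  prep <- prepare_fit_data(data, settings)
  if (length(prep$units) == 0) {
    abort("insufficient data: no quantifiable observations for this subject",
          class = "flx_error_insufficient_data")
  }
  if (length(prep$units) > 1) {
    abort("individual_fit expects exactly one subject",
          class = "flx_error_invalid_input")
  }
  out <- fit_unit(prep$units[[1]], init = init, residual = residual,
                  settings = settings)
  if (!out$converged) {
    warn("individual fit did not meet the convergence tolerance; returning best iterate")
  }
  out
}

# core single-subject weighted least-squares fit on one prepared unit
fit_unit <- function(u, init = NULL,
                     residual = list(plasma = list(add = 0.063, prop = 0.3),
                                     urine = list(add = 0.080, prop = 0.3)),
                     settings = fit_settings()) {
  if (sum(u$matrix == "plasma") < 7) {
    abort("insufficient data: need at least 7 quantifiable plasma observations",
          class = "flx_error_insufficient_data")
  }
  if (is.null(init)) init <- init_from_subject(u)
  if (is.null(init)) {
    abort("could not construct initial estimates by curve stripping; supply `init`",
          class = "flx_error_insufficient_data")
  }
  validate_pk_params(init)
  est_rss <- any(u$matrix == "urine")
  free <- if (est_rss) pk_param_names else setdiff(pk_param_names, "Rss")
  sigma <- c(add_plasma = residual$plasma$add, add_urine = residual$urine$add,
             prop = residual$plasma$prop)
  fun <- function(lp) {
    p <- init
    p[free] <- exp(lp)
    conc_eval(p, u$dose_t, u$dose_amt, u$time, u$matrix, predose = TRUE)
  }
  jac <- function(lp) {
    p <- init
    p[free] <- exp(lp)
    g <- conc_eval_grad(p, u$dose_t, u$dose_amt, u$time, u$matrix,
                        predose = TRUE)
    if (is.null(g)) NULL else g$J[, free, drop = FALSE]
  }
  gn <- gauss_newton(log(init[free]), fun, u$y,
                     var_fun = function(f) res_var(f, u$matrix, sigma),
                     jac = jac)
  params <- init
  params[free] <- exp(gn$x)
  list(params = params, objective = gn$objective, converged = gn$converged,
       iterations = gn$iterations, n_obs = length(u$y))
}

# ---- Laplace population likelihood -----------------------------------------

# Per-subject -2 log marginal likelihood by Laplace approximation.
# Parameterised in u = eta / omega (so the prior is standard normal and the
# log-determinant term is log det(I + J'WJ) with J = df/du), which stays
# well-conditioned as omega2 -> 0. The inner problem is solved by damped
# Gauss-Newton from `u_start` (the prior mode when NULL); callers must pass
# starts that are deterministic functions of the outer parameters so the
# objective stays reproducible. The Gauss-Newton Hessian approximation is
# used in the Laplace determinant.
subject_m2ll <- function(u, theta, d_om, sigma, u_start = NULL, settings) {
  est <- which(d_om > 0)
  n <- length(u$y)
  p_of <- function(uu) {
    eta <- numeric(length(d_om))
    eta[est] <- d_om[est] * uu
    theta * exp(eta)
  }
  fun_eta <- function(uu) {
    conc_eval(p_of(uu), u$dose_t, u$dose_amt, u$time, u$matrix,
              predose = TRUE)
  }
  jac_eta <- function(uu) {
    g <- conc_eval_grad(p_of(uu), u$dose_t, u$dose_amt, u$time, u$matrix,
                        predose = TRUE)
    if (is.null(g)) return(NULL)
    # chain rule u -> eta: scale the eta columns by omega
    g$J[, est, drop = FALSE] *
      rep(d_om[est], each = length(u$y))
  }
  add2 <- ifelse(u$matrix == "urine", sigma[["add_urine"]],
                 sigma[["add_plasma"]])^2
  sp <- sigma[["prop"]]
  var_fun <- function(f) add2 + (sp * f)^2

  if (length(est) == 0) { # no random effects: naive pooled contribution
    f <- fun_eta(numeric(0))
    v <- var_fun(f)
    return(list(m2ll = n * log(2 * pi) + sum(log(v) + (u$y - f)^2 / v),
                u_hat = numeric(0), ok = TRUE))
  }

  uu0 <- u_start %||% numeric(length(est))
  if (length(uu0) != length(est)) uu0 <- numeric(length(est))
  use_jac <- if (is.null(jac_eta(uu0))) NULL else jac_eta
  gn <- gauss_newton(uu0, fun_eta, u$y, var_fun,
                     penalty = seq_along(est), include_logv = TRUE,
                     max_iter = settings$inner_max_iter,
                     tol = settings$inner_tol, jac = use_jac)
  f <- gn$f
  v <- var_fun(f)
  JW <- crossprod(gn$J, gn$J / v)
  ld <- determinant(diag(length(est)) + JW, logarithm = TRUE)$modulus[1]
  m2ll <- n * log(2 * pi) + sum(log(v) + (u$y - f)^2 / v) +
    sum(gn$x^2) + ld
  list(m2ll = m2ll, u_hat = gn$x, ok = gn$converged)
}

#' Fit the population model by Laplace-approximated marginal likelihood
#'
#' Maximises the Laplace approximation to the marginal likelihood of a
#' nonlinear mixed-effects model over the typical values (log scale), the
#' diagonal between-horse variances and the residual-error components.
#' For each subject the inner problem locates the posterior mode of the
#' random effects (empirical Bayes estimates) by damped Gauss-Newton with
#' warm starts across outer iterations; the outer objective sums the
#' subject-level Laplace terms and is minimised with [stats::nlminb()].
#' `Rss` is estimated jointly as a structural parameter from the urine
#' records that satisfy the equilibration rule (see [fit_settings()]).
#'
#' @param data Dataset tibble in the event/observation layout (see
#'   [generate_dataset()] / [read_dataset()]).
#' @param init Initial [population_model()]; `NULL` builds data-driven
#'   initials: per-subject curve-stripping + individual fits, with the
#'   typical values at the medians of the per-subject estimates, the
#'   variances at the empirical variance of the per-subject log estimates,
#'   and the residual components from pooled residuals.
#' @param settings See [fit_settings()].
#' @return An object of class `flx_fit`; see [tidy.flx_fit()],
#'   [glance.flx_fit()], [pred_ipred()] and [autoplot.flx_fit()].
#' @export
population_fit <- function(data, init = NULL, settings = fit_settings()) {
  prep <- prepare_fit_data(data, settings)
  units <- prep$units
  n_subj <- length(units)
  if (n_subj < 2 && settings$estimate_omega2) {
    abort("between-horse variances are not identifiable from a single subject; fix omega2 (estimate_omega2 = FALSE)",
          class = "flx_error_invalid_input")
  }
  # bootstrap replicates resample subjects with replacement, so identical
  # units recur; compute each distinct unit once and weight by multiplicity
  unit_key <- vapply(units, function(u) {
    paste(c(u$time, u$matrix, signif(u$y, 12), u$dose_t, u$dose_amt),
          collapse = "|")
  }, character(1))
  uniq_idx <- which(!duplicated(unit_key))
  match_uniq <- match(unit_key, unit_key[uniq_idx])
  uniq_count <- tabulate(match_uniq, nbins = length(uniq_idx))

  # per-subject individual estimates: they seed the data-driven initial
  # population model and provide the deterministic data-informed starting
  # points for the inner eta problems
  ind_residual <- if (!is.null(init)) {
    init$residual
  } else {
    list(plasma = list(add = 0.063, prop = 0.3),
         urine = list(add = 0.080, prop = 0.3))
  }
  p_ind <- lapply(uniq_idx, function(i) {
    tryCatch(fit_unit(units[[i]], residual = ind_residual,
                      settings = settings)$params,
             error = function(e) NULL)
  })

  if (is.null(init)) {
    init <- initial_population(units[uniq_idx], p_ind)
  }
  stopifnot(inherits(init, "flx_population"))

  theta0 <- init$theta
  om0 <- init$omega2
  if (settings$estimate_omega2) om0 <- pmax(om0, 1e-4)
  sig0 <- c(add_plasma = max(init$residual$plasma$add, 1e-3),
            add_urine = max(init$residual$urine$add, 1e-3),
            prop = max(init$residual$plasma$prop, 1e-3))

  i_theta <- seq_len(7)
  i_om <- if (settings$estimate_omega2) 7 + seq_len(7) else integer(0)
  i_sig <- if (settings$estimate_sigma) max(c(i_theta, i_om)) + seq_len(3) else integer(0)
  x0 <- c(log(theta0),
          if (settings$estimate_omega2) log(om0),
          if (settings$estimate_sigma) log(sig0))

  env <- new.env()
  env$trace <- numeric(0)
  env$flagged <- 0L

  unpack <- function(x) {
    theta <- setNames(exp(x[i_theta]), pk_param_names)
    om <- if (settings$estimate_omega2) {
      setNames(exp(x[i_om]), pk_param_names)
    } else om0
    sig <- if (settings$estimate_sigma) {
      setNames(exp(x[i_sig]), c("add_plasma", "add_urine", "prop"))
    } else sig0
    list(theta = theta, om = om, sig = sig)
  }

  # deterministic data-informed start for the inner problem of unit k:
  # the eta implied by the subject's own individual estimate, clipped to
  # +/- 2.5 prior standard deviations
  u_start_of <- function(k, theta, d_om) {
    p <- p_ind[[k]]
    if (is.null(p)) return(NULL)
    est <- which(d_om > 0)
    pmin(pmax(log(p[est] / theta[est]) / d_om[est], -2.5), 2.5)
  }

  eval_all <- function(x) {
    pp <- unpack(x)
    d_om <- sqrt(pp$om)
    tot <- 0
    flagged <- 0L
    u_hat <- vector("list", length(uniq_idx))
    for (k in seq_along(uniq_idx)) {
      i <- uniq_idx[k]
      res <- tryCatch(
        subject_m2ll(units[[i]], pp$theta, d_om, pp$sig,
                     u_start = u_start_of(k, pp$theta, d_om),
                     settings = settings),
        error = function(e) NULL)
      if (is.null(res) || !is.finite(res$m2ll)) {
        # fall back to the prior mode for this subject
        res <- tryCatch(
          subject_m2ll(units[[i]], pp$theta, d_om * 0, pp$sig,
                       settings = settings),
          error = function(e) NULL)
        flagged <- flagged + uniq_count[k]
        if (is.null(res) || !is.finite(res$m2ll)) {
          return(list(m2ll = 1e10, flagged = flagged, u_hat = u_hat))
        }
      }
      u_hat[[k]] <- res$u_hat
      tot <- tot + uniq_count[k] * res$m2ll
    }
    list(m2ll = if (flagged > 0.2 * n_subj) 1e10 else tot,
         flagged = flagged, u_hat = u_hat)
  }

  objective <- function(x) {
    res <- eval_all(x)
    env$flagged <- res$flagged
    env$trace <- c(env$trace, res$m2ll)
    res$m2ll
  }

  # finite-difference gradient with a step wide enough to sit far above the
  # inner-optimisation noise floor (the objective is only evaluated to
  # about the inner tolerance)
  gradient <- function(x, h = 1e-4) {
    # central differences: the forward-difference bias is enough to stall
    # the PORT line search near the optimum. Perturbed evaluations use the
    # same cold-started inner solves as the objective so the two stay
    # mutually consistent even where the inner problem is multimodal.
    vapply(seq_along(x), function(k) {
      xp <- x; xp[k] <- xp[k] + h
      xm <- x; xm[k] <- xm[k] - h
      (eval_all(xp)$m2ll - eval_all(xm)$m2ll) / (2 * h)
    }, numeric(1))
  }
  # The Laplace objective has occasional kinks where a subject's inner
  # problem switches posterior modes; PORT then reports false convergence.
  # Restarting from the stopping point (fresh trust region) recovers, so
  # iterate until genuine convergence or no further improvement.
  opt <- nlminb(x0, objective, gradient = gradient,
                control = list(iter.max = settings$max_iter,
                               eval.max = settings$max_iter * 4,
                               rel.tol = settings$rel_tol))
  iters <- opt$iterations
  for (rs in seq_len(settings$max_restarts)) {
    if (opt$convergence == 0 || iters >= settings$max_iter) break
    opt2 <- nlminb(opt$par, objective, gradient = gradient,
                   control = list(iter.max = settings$max_iter - iters,
                                  eval.max = (settings$max_iter - iters) * 4,
                                  rel.tol = settings$rel_tol))
    iters <- iters + opt2$iterations
    improved <- opt$objective - opt2$objective >
      settings$rel_tol * (abs(opt$objective) + 1)
    if (opt2$objective <= opt$objective) opt <- opt2
    if (!improved) break
  }
  opt$iterations <- iters
  if (env$flagged > 0.2 * n_subj) {
    abort("more than 20% of subjects failed the inner eta optimisation",
          class = "flx_error_nonconvergence")
  }

  pp <- unpack(opt$par)
  d_om <- sqrt(pp$om)
  # final empirical Bayes etas at the optimum
  eta <- t(vapply(seq_along(units), function(i) {
    res <- subject_m2ll(units[[i]], pp$theta, d_om, pp$sig,
                        u_start = u_start_of(match_uniq[i], pp$theta, d_om),
                        settings = settings)
    eta <- setNames(numeric(7), pk_param_names)
    eta[d_om > 0] <- d_om[d_om > 0] * res$u_hat
    eta
  }, setNames(numeric(7), pk_param_names)))
  eta_tb <- dplyr::bind_cols(
    tibble::tibble(subject = vapply(units, function(u) u$subject[1],
                                    vector(mode = mode(units[[1]]$subject), 1))),
    tibble::as_tibble(as.data.frame(eta)))

  pop <- population_model(
    theta = pp$theta, omega2 = pp$om,
    residual_plasma = list(add = pp$sig[["add_plasma"]], prop = pp$sig[["prop"]]),
    residual_urine = list(add = pp$sig[["add_urine"]], prop = pp$sig[["prop"]]))

  fit <- structure(list(
    pop = pop, theta = pp$theta, omega2 = pp$om, sigma = pp$sig,
    eta = eta_tb, objective = opt$objective, trace = env$trace,
    convergence = list(code = opt$convergence, message = opt$message,
                       iterations = opt$iterations,
                       flagged_subjects = env$flagged),
    n_subjects = n_subj,
    n_obs = sum(vapply(units, function(u) length(u$y), integer(1))),
    n_blq_excluded = prep$n_blq,
    init = init, settings = settings, data = data), class = "flx_fit")
  fit
}

# Data-driven initial population model from per-subject estimates (curve
# stripping + individual fits): medians / log-variances across subjects,
# sigmas from pooled residuals.
initial_population <- function(units, p_ind) {
  ok <- !vapply(p_ind, is.null, logical(1))
  if (sum(ok) < max(2, 0.5 * length(units))) {
    abort("too few subjects with usable individual fits to initialise the population model",
          class = "flx_error_insufficient_data")
  }
  P <- do.call(rbind, p_ind[ok])
  colnames(P) <- pk_param_names
  theta <- exp(apply(log(P), 2, median))
  om <- apply(log(P), 2, var)
  om <- pmin(pmax(om, 1e-4), 0.3) # keep the start away from degenerate corners

  # pooled residuals against the individual fits; robust scale, since poorly
  # identified subjects leave large stray residuals
  rel <- unlist(lapply(which(ok), function(i) {
    u <- units[[i]]
    f <- conc_eval(p_ind[[i]], u$dose_t, u$dose_amt, u$time, u$matrix,
                   predose = TRUE)
    (u$y - f)[f > 0] / f[f > 0]
  }))
  prop0 <- min(max(1.4826 * median(abs(rel)), 0.05), 0.5)
  population_model(theta = theta, omega2 = om,
                   residual_plasma = list(add = 0.05, prop = prop0),
                   residual_urine = list(add = 0.05, prop = prop0))
}

#' @export
print.flx_fit <- function(x, ...) {
  cat(sprintf("Population fit: %d subjects, %d observations (%d BLQ excluded)\n",
              x$n_subjects, x$n_obs, x$n_blq_excluded))
  cat(sprintf("-2LL (Laplace): %.3f after %d outer iterations (nlminb code %d)\n",
              x$objective, x$convergence$iterations, x$convergence$code))
  print(x$pop)
  invisible(x)
}

#' Population and individual predictions for every record
#'
#' PRED evaluates the fitted typical values (all etas zero); IPRED uses
#' each subject's empirical Bayes etas. Both use the pre-dose convention
#' for samples scheduled exactly at an administration time, matching the
#' fitting rules.
#'
#' @param fit An `flx_fit`.
#' @param data Dataset to predict for; default the fitted data. Subjects
#'   must have dosing records; subjects unseen at fit time get IPRED =
#'   PRED.
#' @return Observation rows of `data` with `pred` and `ipred` columns
#'   (ng/mL).
#' @export
pred_ipred <- function(fit, data = NULL) {
  stopifnot(inherits(fit, "flx_fit"))
  data <- data %||% fit$data
  obs <- dplyr::filter(data, .data$event == "obs")
  doses <- dplyr::filter(data, .data$event == "dose")
  eta <- fit$eta
  out <- purrr::map_dfr(split(obs, obs$subject), function(o) {
    sid <- o$subject[1]
    d <- doses[doses$subject == sid, ]
    d <- d[order(d$time_h), ]
    pred <- conc_eval(fit$theta, d$time_h, d$amount_mg_per_kg,
                      o$time_h, o$matrix, predose = TRUE)
    ei <- eta[eta$subject == sid, pk_param_names]
    p_i <- if (nrow(ei) == 1) fit$theta * exp(as.numeric(ei)) else fit$theta
    ipred <- conc_eval(p_i, d$time_h, d$amount_mg_per_kg,
                       o$time_h, o$matrix, predose = TRUE)
    dplyr::mutate(o, pred = pred, ipred = ipred)
  })
  dplyr::arrange(out, .data$subject, .data$time_h)
}

#' Nonparametric bootstrap precision of the population estimates
#'
#' Resamples subjects with replacement (stratified by study arm so every
#' replicate keeps both designs), refits the population model on each
#' replicate starting from the point estimates, and summarises the primary
#' and secondary parameters across replicates as median, CV%, and 2.5th /
#' 97.5th percentiles.
#'
#' @param data Dataset tibble.
#' @param init An `flx_fit` (its estimates seed each replicate) or an
#'   [population_model()].
#' @param n_replicates Number of bootstrap replicates (>= 2); 50 is the
#'   conventional choice, smaller values give a faster, coarser precision
#'   estimate.
#' @param seed Optional integer seed for the resampling.
#' @param settings See [fit_settings()]; replicate fits cap the outer
#'   iterations at `max_iter`.
#' @return Object of class `flx_boot`: a tibble with columns `parameter`,
#'   `type` (primary/secondary), `median`, `cv_pct`, `q02.5`, `q97.5`,
#'   with attributes `n_ok` and `n_dropped`. Replicates whose fit fails
#'   are dropped; more than 20% dropped is an error.
#' @export
bootstrap_precision <- function(data, init, n_replicates = 50, seed = NULL,
                                settings = fit_settings()) {
  if (n_replicates < 2) {
    abort("need at least 2 bootstrap replicates",
          class = "flx_error_invalid_input")
  }
  if (inherits(init, "flx_fit")) init <- init$pop
  stopifnot(inherits(init, "flx_population"))
  if (!is.null(seed)) set.seed(seed)

  obs <- dplyr::filter(data, .data$event == "obs")
  arm_of <- dplyr::distinct(
    dplyr::mutate(obs, arm = if ("arm" %in% names(obs)) .data$arm else "all"),
    .data$subject, .data$arm)
  strata <- split(arm_of$subject, arm_of$arm)

  # replicate fits start at the point estimates and use a looser outer
  # tolerance and a tighter effort cap: bootstrap summaries are
  # percentile-level statistics, so replicate objectives converged to 1e-4
  # relative are ample
  rep_settings <- settings
  rep_settings$rel_tol <- max(settings$rel_tol, 1e-4)
  rep_settings$max_iter <- min(settings$max_iter, 120)
  rep_settings$max_restarts <- 1

  reps <- list()
  dropped <- 0L
  for (b in seq_len(n_replicates)) {
    picked <- unlist(lapply(strata, function(s) sample(s, replace = TRUE)))
    rep_data <- purrr::map_dfr(seq_along(picked), function(k) {
      d <- dplyr::filter(data, .data$subject == picked[k])
      d$subject <- k # relabel so duplicates are distinct subjects
      d
    })
    fit <- tryCatch(population_fit(rep_data, init = init,
                                   settings = rep_settings),
                    error = function(e) NULL)
    if (is.null(fit)) {
      dropped <- dropped + 1L
      next
    }
    sec <- secondary_parameters(fit$theta)
    reps[[length(reps) + 1]] <-
      c(fit$theta, half_life_alpha = sec$half_life_alpha,
        half_life_beta = sec$half_life_beta,
        half_life_gamma = sec$half_life_gamma, Vss = sec$Vss, MRT = sec$MRT)
  }
  if (dropped > 0.2 * n_replicates) {
    abort(sprintf("%d of %d bootstrap replicates failed to converge", dropped,
                  n_replicates),
          class = "flx_error_nonconvergence")
  }
  M <- do.call(rbind, reps)
  out <- tibble::tibble(
    parameter = colnames(M),
    type = ifelse(colnames(M) %in% pk_param_names, "primary", "secondary"),
    median = apply(M, 2, median),
    cv_pct = 100 * apply(M, 2, sd) / apply(M, 2, mean),
    q02.5 = apply(M, 2, quantile, 0.025),
    q97.5 = apply(M, 2, quantile, 0.975))
  attr(out, "n_ok") <- length(reps)
  attr(out, "n_dropped") <- dropped
  class(out) <- c("flx_boot", class(out))
  out
}
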