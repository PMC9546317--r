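#' Tidy a population fit
#'
#' One row per estimated quantity: typical values, between-horse
#' variances (with their lognormal CV%), and residual components.
#'
#' @param x An `flx_fit`.
#' @param ... Unused.
#' @return Tibble with columns `term`, `type`, `estimate`, `cv_pct`.
#' @method tidy flx_fit
#' @export
tidy.flx_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(term = pk_param_names, type = "theta",
                   estimate = unname(x$theta), cv_pct = NA_real_),
    tibble::tibble(term = pk_param_names, type = "omega2",
                   estimate = unname(x$omega2),
                   cv_pct = cv_from_omega2(unname(x$omega2))),
    tibble::tibble(term = names(x$sigma), type = "sigma",
                   estimate = unname(x$sigma), cv_pct = NA_real_))
}

#' One-row summary of a population fit
#'
#' @param x An `flx_fit`.
#' @param ... Unused.
#' @return Tibble with the Laplace -2 log-likelihood, counts, convergence
#'   code and iteration count.
#' @method glance flx_fit
#' @export
glance.flx_fit <- function(x, ...) {
  tibble::tibble(objective = x$objective,
                 n_subjects = x$n_subjects,
                 n_obs = x$n_obs,
                 n_blq_excluded = x$n_blq_excluded,
                 convergence = x$convergence$code,
                 iterations = x$convergence$iterations,
                 flagged_subjects = x$convergence$flagged_subjects)
}

#' Per-record predictions from a population fit
#'
#' @param x An `flx_fit`.
#' @param data Dataset to predict for (default the fitted data).
#' @param ... Unused.
#' @return Observation rows with `pred` and `ipred` columns; see
#'   [pred_ipred()].
#' @method augment flx_fit
#' @export
augment.flx_fit <- function(x, data = NULL, ...) {
  pred_ipred(x, data)
}

#' Tidy a bootstrap precision summary
#'
#' @param x An `flx_boot`.
#' @param ... Unused.
#' @return The underlying tibble (parameter, type, median, cv_pct,
#'   percentiles).
#' @method tidy flx_boot
#' @export
tidy.flx_boot <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' One-row summary of a bootstrap run
#'
#' @param x An `flx_boot`.
#' @param ... Unused.
#' @return Tibble with replicate counts.
#' @method glance flx_boot
#' @export
glance.flx_boot <- function(x, ...) {
  tibble::tibble(n_ok = attr(x, "n_ok"), n_dropped = attr(x, "n_dropped"))
}

#' Tidy a detection-time quantile table
#'
#' @param x An `flx_dtq` from [detection_quantiles()].
#' @param ... Unused.
#' @return The quantile tibble without the class decoration.
#' @method tidy flx_dtq
#' @export
tidy.flx_dtq <- function(x, ...) {
  out <- x
  attr(out, "detection_times") <- NULL
  class(out) <- setdiff(class(out), "flx_dtq")
  out
}
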