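#' Study design descriptions
#'
#' A study design is a set of arms, each with a number of subjects, a
#' dosing [regimen()], and nominal plasma and urine sampling schedules,
#' plus per-matrix lower limits of quantification (LLOQ).
#'
#' @param arms List of arms; each arm is a list with elements
#'   `n_subjects`, `regimen`, `plasma_times`, `urine_times`.
#' @param lloq Named vector of quantification limits (ng/mL) for
#'   `plasma` and `urine`.
#' @return An object of class `flx_design`.
#' @export
study_design <- function(arms, lloq = c(plasma = 0.1, urine = 3)) {
  if (is.null(names(arms))) names(arms) <- paste0("arm", seq_along(arms))
  for (nm in names(arms)) {
    a <- arms[[nm]]
    stopifnot(a$n_subjects >= 1, inherits(a$regimen, "flx_regimen"))
    if (is.unsorted(a$plasma_times) || is.unsorted(a$urine_times) ||
        any(c(a$plasma_times, a$urine_times) < 0)) {
      abort(sprintf("arm '%s': sampling times must be sorted and nonnegative", nm),
            class = "flx_error_invalid_input")
    }
  }
  if (any(lloq[c("plasma", "urine")] <= 0)) {
    abort("quantification limits must be positive",
          class = "flx_error_invalid_input")
  }
  structure(list(arms = arms, lloq = lloq), class = "flx_design")
}

#' The two-arm flunixin study design
#'
#' Ten horses with a single 1.1 mg/kg IV bolus and rich plasma sampling
#' over 240 h plus urine sampling to 120 h; ten horses with five daily
#' 1.1 mg/kg doses (administrations at 0, 24, 48, 72 and 96 h), plasma
#' sampling to 336 h including pre-dose troughs, and urine sampling from
#' 99 h onwards. Samples scheduled exactly at an administration time are
#' taken immediately before the bolus (the pre-dose convention of trough
#' sampling). Quantification limits are 0.1 ng/mL in plasma and 3 ng/mL
#' in urine.
#'
#' @param dose Dose per administration (mg/kg), default 1.1.
#' @return An `flx_design` with arms `single` and `q24h_5d`.
#' @export
default_design <- function(dose = 1.1) {
  study_design(list(
    single = list(
      n_subjects = 10,
      regimen = regimen(dose, 24, 1),
      plasma_times = c(0, 0.5, 1, 3, 6, 9, 24, 30, 48, 72, 120, 144, 168,
                       192, 216, 240),
      urine_times = c(3, 6, 9, 24, 30, 48, 72, 96, 120)),
    q24h_5d = list(
      n_subjects = 10,
      regimen = regimen(dose, 24, 5),
      plasma_times = c(24, 48, 72, 96, 96.5, 97, 99, 102, 105, 120, 126,
                       144, 168, 192, 216, 240, 264, 288, 312, 336),
      urine_times = c(99, 102, 105, 120, 126, 144, 168, 192, 216, 240,
                      264, 288, 312, 336))),
    lloq = c(plasma = 0.1, urine = 3))
}

#' Flag records below the quantification limit
#'
#' Sets `blq = TRUE` for observation rows whose concentration is strictly
#' below the matrix quantification limit; the numeric value is preserved.
#' A value exactly at the limit is quantifiable.
#'
#' @param records Observation tibble with columns `event`, `matrix`,
#'   `conc_ng_per_ml`.
#' @param limits Named vector of limits (ng/mL) per matrix.
#' @return `records` with the `blq` column set.
#' @export
blq_censor <- function(records, limits = c(plasma = 0.1, urine = 3)) {
  if (any(limits <= 0)) {
    abort("quantification limits must be positive",
          class = "flx_error_invalid_input")
  }
  dplyr::mutate(records, blq = dplyr::case_when(
    .data$event != "obs" ~ FALSE,
    TRUE ~ .data$conc_ng_per_ml < unname(limits[.data$matrix])))
}

#' Generate a synthetic concentration dataset
#'
#' Simulates a study: samples individual parameter sets per arm
#' (independent lognormal etas), evaluates noise-free plasma profiles and
#' proportional urine profiles at the scheduled times, applies the combined
#' residual-error model per matrix, and flags records below the
#' quantification limit. Samples scheduled exactly at an administration
#' time are drawn pre-dose. The noise-free value is retained in
#' `conc_true_ng_per_ml` as a test-only side channel — the estimation
#' functions never read it.
#'
#' @param pop Generating [population_model()].
#' @param design An `flx_design`, default [default_design()].
#' @param seed Optional integer seed; a fixed seed gives a byte-identical
#'   dataset.
#' @return Tibble in the package's event/observation layout: columns
#'   `subject`, `arm`, `time_h`, `event` (`"dose"`/`"obs"`), `matrix`,
#'   `amount_mg_per_kg`, `conc_ng_per_ml`, `blq`, `conc_true_ng_per_ml`.
#'   The generating parameter table is attached as attribute
#'   `"individuals"`.
#' @export
generate_dataset <- function(pop, design = default_design(), seed = NULL) {
  stopifnot(inherits(pop, "flx_population"), inherits(design, "flx_design"))
  if (!is.null(seed)) set.seed(seed)
  subj0 <- 0L
  all_ind <- list()
  rows <- purrr::map_dfr(names(design$arms), function(an) {
    arm <- design$arms[[an]]
    reg <- arm$regimen
    td <- dose_times(reg)
    ind <- sample_individuals(pop, arm$n_subjects)
    ind$subject <- ind$subject + subj0
    subj0 <<- subj0 + arm$n_subjects
    all_ind[[an]] <<- ind

    sched <- dplyr::bind_rows(
      tibble::tibble(time_h = arm$plasma_times, matrix = "plasma"),
      tibble::tibble(time_h = arm$urine_times, matrix = "urine"))

    purrr::map_dfr(seq_len(nrow(ind)), function(i) {
      p <- as.numeric(ind[i, pk_param_names])
      names(p) <- pk_param_names
      true <- conc_eval(p, td, rep(reg$dose, length(td)),
                        sched$time_h, sched$matrix, predose = TRUE)
      obs_p <- apply_residual(true[sched$matrix == "plasma"], "plasma", pop)
      obs_u <- apply_residual(true[sched$matrix == "urine"], "urine", pop)
      obs <- dplyr::bind_rows(obs_p, obs_u)
      dose_rows <- tibble::tibble(
        subject = ind$subject[i], arm = an, time_h = td, event = "dose",
        matrix = NA_character_, amount_mg_per_kg = reg$dose,
        conc_ng_per_ml = NA_real_, blq = FALSE,
        conc_true_ng_per_ml = NA_real_)
      obs_rows <- tibble::tibble(
        subject = ind$subject[i], arm = an, time_h = sched$time_h,
        event = "obs", matrix = sched$matrix,
        amount_mg_per_kg = NA_real_, conc_ng_per_ml = obs$observed,
        blq = FALSE, conc_true_ng_per_ml = true)
      dplyr::bind_rows(dose_rows, obs_rows)
    })
  })
  rows <- blq_censor(rows, design$lloq)
  rows <- dplyr::arrange(rows, .data$subject, .data$time_h,
                         dplyr::desc(.data$event))
  attr(rows, "individuals") <- dplyr::bind_rows(all_ind)
  attr(rows, "lloq") <- design$lloq
  rows
}

# Reconstruct a study design from a dataset's dose rows and observation
# schedule (used by the VPC to simulate replicate studies of the same
# design). Subjects sharing a dose-time signature form an arm.
design_from_dataset <- function(data) {
  doses <- dplyr::filter(data, .data$event == "dose")
  if (nrow(doses) == 0) {
    abort("dataset has no dose rows", class = "flx_error_invalid_input")
  }
  sig <- dplyr::summarise(
    dplyr::group_by(doses, .data$subject),
    signature = paste(.data$time_h, .data$amount_mg_per_kg, collapse = ";"),
    .groups = "drop")
  arms <- lapply(split(sig$subject, sig$signature), function(subjects) {
    sd <- dplyr::filter(doses, .data$subject == subjects[1])
    obs <- dplyr::filter(data, .data$event == "obs",
                         .data$subject %in% subjects)
    n_d <- nrow(sd)
    list(n_subjects = length(subjects),
         regimen = regimen(sd$amount_mg_per_kg[1],
                           interval = if (n_d > 1) diff(sd$time_h)[1] else 24,
                           n_doses = n_d),
         plasma_times = sort(unique(obs$time_h[obs$matrix == "plasma"])),
         urine_times = sort(unique(obs$time_h[obs$matrix == "urine"])))
  })
  names(arms) <- paste0("arm", seq_along(arms))
  lloq <- attr(data, "lloq") %||% c(plasma = 0.1, urine = 3)
  study_design(arms, lloq = lloq)
}
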