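test_that("a noise-free subject is recovered exactly by the individual fit", {
  truth <- typical_params()
  d0 <- generate_dataset(noise_free_pop(truth), default_design(), seed = 424)
  # curve-stripping start, no hints
  f <- individual_fit(d0, subject = 1)
  expect_true(f$converged)
  expect_lt(max(abs(f$params / truth - 1)), 1e-4)
  # multi-dose arm subjects are recovered through the superposed profile
  f11 <- individual_fit(d0, subject = 11)
  expect_lt(max(abs(f11$params / truth - 1)), 1e-4)

  # starting at the truth, the weighted least-squares objective is already 0
  ft <- individual_fit(d0, subject = 1, init = truth)
  expect_lt(ft$objective, 1e-8)
  expect_lte(ft$iterations, 2)
})

test_that("subjects without quantifiable data are rejected", {
  d <- generate_dataset(fitted_pop(), tiny_design(), seed = 425)
  d$blq[d$subject == 1 & d$event == "obs"] <- TRUE
  expect_error(individual_fit(d, subject = 1),
               class = "flx_error_insufficient_data")
})

test_that("with no random effects the population fit collapses to the individual fit", {
  truth <- typical_params()
  d0 <- generate_dataset(noise_free_pop(truth), default_design(), seed = 426)
  one <- dplyr::filter(d0, subject == 3)
  pooled_init <- population_model(
    theta = truth * exp(0.2), # start away from the answer
    omega2 = setNames(rep(0, 7), names(truth)),
    residual_plasma = list(add = 1e-3, prop = 1e-3),
    residual_urine = list(add = 1e-3, prop = 1e-3))
  fit <- population_fit(one, init = pooled_init,
                        settings = fit_settings(estimate_omega2 = FALSE,
                                                estimate_sigma = FALSE))
  ind <- individual_fit(one, init = truth * exp(0.2),
                        residual = list(plasma = list(add = 1e-3, prop = 1e-3),
                                        urine = list(add = 1e-3, prop = 1e-3)))
  expect_lt(max(abs(fit$theta / ind$params - 1)), 1e-3)
  # both sit at the generating values on noise-free data
  expect_lt(max(abs(fit$theta / truth - 1)), 1e-3)
  expect_true(all(fit$eta[, -1] == 0))
})

test_that("the Laplace objective tends to the naive pooled likelihood as omega2 -> 0", {
  d <- generate_dataset(fitted_pop(), tiny_design(3, 0), seed = 427)
  settings <- fit_settings()
  units <- flunixinpk:::prepare_fit_data(d, settings)$units
  theta <- typical_params()
  sig <- c(add_plasma = 0.063, add_urine = 0.080, prop = 0.3)
  pooled <- sum(vapply(units, function(u) {
    flunixinpk:::subject_m2ll(u, theta, rep(0, 7), sig,
                              settings = settings)$m2ll
  }, numeric(1)))
  tiny <- sum(vapply(units, function(u) {
    flunixinpk:::subject_m2ll(u, theta, rep(1e-6, 7), sig,
                              settings = settings)$m2ll
  }, numeric(1)))
  expect_equal(tiny, pooled, tolerance = 1e-6)
})

test_that("the marginal likelihood ignores subject labels and record order", {
  d <- generate_dataset(fitted_pop(), tiny_design(), seed = 428)
  settings <- fit_settings()
  m2ll_of <- function(data) {
    units <- flunixinpk:::prepare_fit_data(data, settings)$units
    sum(vapply(units, function(u) {
      flunixinpk:::subject_m2ll(u, typical_params(),
                                sqrt(fitted_pop()$omega2),
                                c(add_plasma = 0.063, add_urine = 0.080,
                                  prop = 0.3),
                                settings = settings)$m2ll
    }, numeric(1)))
  }
  base <- m2ll_of(d)
  shuffled <- d[sample(nrow(d)), ]
  expect_equal(m2ll_of(shuffled), base, tolerance = 1e-9)
  relabeled <- dplyr::mutate(d, subject = 100 - subject)
  expect_equal(m2ll_of(relabeled), base, tolerance = 1e-9)
})

test_that("urine records only enter the fit once pseudo-equilibrium holds", {
  d <- generate_dataset(fitted_pop(), default_design(), seed = 429)
  settings <- fit_settings()
  units <- flunixinpk:::prepare_fit_data(d, settings)$units
  multi <- units[[which(vapply(units, function(u) u$subject, 0) == 11)]]
  ur <- multi$time[multi$matrix == "urine"]
  # administrations at 0..96 h: urine before 120 h is within 24 h of a dose
  expect_true(all(ur >= 120))
  # the first-dose reading instead admits everything from 24 h onwards
  alt <- fit_settings(urine_rule = "first_dose")
  units2 <- flunixinpk:::prepare_fit_data(d, alt)$units
  multi2 <- units2[[which(vapply(units2, function(u) u$subject, 0) == 11)]]
  expect_gt(sum(multi2$matrix == "urine"), sum(multi$matrix == "urine"))
})

test_that("a small population fit behaves sensibly end to end", {
  pop <- fitted_pop()
  d <- generate_dataset(pop, tiny_design(4, 4), seed = 430)
  fit <- suppressWarnings(
    population_fit(d, init = pop,
                   settings = fit_settings(max_iter = 60)))
  expect_s3_class(fit, "flx_fit")
  # the optimiser only ever improves on its starting point
  expect_lte(min(fit$trace), fit$trace[1])
  expect_equal(nrow(fit$eta), 8)
  sh <- shrinkage(as.matrix(fit$eta[, -1]), fit$omega2)
  expect_true(all(sh$shrinkage[!is.na(sh$shrinkage)] <= 1))

  # predictions: IPRED tracks the data more closely than PRED
  pr <- pred_ipred(fit)
  expect_named(pr, c(names(d), "pred", "ipred"), ignore.order = TRUE)
  ok <- !pr$blq & pr$conc_ng_per_ml > 0
  r_pred <- log(pr$conc_ng_per_ml[ok] / pr$pred[ok])
  r_ipred <- log(pr$conc_ng_per_ml[ok] / pr$ipred[ok])
  expect_lt(var(r_ipred), var(r_pred))

  td <- tidy(fit)
  expect_setequal(unique(td$type), c("theta", "omega2", "sigma"))
  expect_equal(glance(fit)$n_subjects, 8)
})

test_that("single-subject data cannot identify between-horse variances", {
  d <- generate_dataset(fitted_pop(), tiny_design(1, 0), seed = 431)
  expect_error(population_fit(d), class = "flx_error_invalid_input")
})
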