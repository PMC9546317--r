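test_that("omega2 and CV percent convert both ways", {
  expect_equal(cv_from_omega2(0), 0)
  # the reported between-horse CVs invert to these variances
  expect_equal(cv_from_omega2(0.26864), 55.5, tolerance = 1e-3)
  expect_equal(cv_from_omega2(0.08618), 30.0, tolerance = 1e-3)
  expect_equal(omega2_from_cv(55.5), log(1 + 0.555^2), tolerance = 1e-12)

  set.seed(405)
  cvs <- runif(100, 0, 120)
  expect_equal(cv_from_omega2(omega2_from_cv(cvs)), cvs, tolerance = 1e-12)

  # the literal (no-radical) variant is available but distinct
  expect_equal(cv_from_omega2(0.26864, form = "literal"),
               100 * (exp(0.26864) - 1))
  expect_equal(cv_from_omega2(omega2_from_cv(42, form = "literal"),
                              form = "literal"), 42, tolerance = 1e-12)
  expect_error(omega2_from_cv(-1), class = "flx_error_invalid_input")
  expect_error(cv_from_omega2(-0.1), class = "flx_error_invalid_input")
})

test_that("virtual horses are lognormal with the declared spread", {
  pop <- fitted_pop()
  h <- sample_individuals(pop, 50000, seed = 406)
  # empirical CV of clearance close to the declared 30%
  cv_cl <- 100 * sd(h$CL) / mean(h$CL)
  expect_gt(cv_cl, 29)
  expect_lt(cv_cl, 31)
  # lognormal location: median at theta, mean at theta exp(omega2/2)
  expect_equal(median(h$CL), pop$theta[["CL"]], tolerance = 0.01)
  expect_equal(mean(h$Rss),
               pop$theta[["Rss"]] * exp(pop$omega2[["Rss"]] / 2),
               tolerance = 0.01)
  # parameter-wise independence
  eta <- attr(h, "eta")
  cors <- cor(eta[, c("V3", "CL", "CL3", "Rss")])
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.02)

  # degenerate and reproducible cases
  h0 <- sample_individuals(noise_free_pop(), 5, seed = 1)
  expect_true(all(h0$CL == 0.047))
  expect_identical(sample_individuals(pop, 100, seed = 7),
                   sample_individuals(pop, 100, seed = 7))
})

test_that("shrinkage follows 1 - var(eta)/omega2", {
  om <- c(CL = 0.08, Rss = 0.2)
  etas <- cbind(CL = c(0.1, -0.1, 0.3, -0.3), Rss = rep(0.5, 4))
  sh <- shrinkage(etas, om)
  expect_equal(sh$shrinkage[sh$parameter == "CL"],
               1 - var(etas[, "CL"]) / 0.08)
  # identical etas shrink completely
  expect_equal(sh$shrinkage[sh$parameter == "Rss"], 1)
  expect_true(sh$flagged[sh$parameter == "Rss"])
  # worked example: var 0.02 against omega2 0.08
  etas2 <- cbind(CL = sqrt(0.02) * scale(rnorm(50))[, 1])
  expect_equal(shrinkage(etas2, c(CL = 0.08))$shrinkage, 0.75,
               tolerance = 1e-10)
  expect_true(is.na(shrinkage(etas, c(CL = 0, Rss = 0))$shrinkage[1]))
})

test_that("the combined residual-error model has the declared moments", {
  pop <- population_model(theta = typical_params(),
                          omega2 = setNames(rep(0, 7), pk_param_names),
                          residual_plasma = list(add = 0.063, prop = 0.30),
                          residual_urine = list(add = 0.080, prop = 0.30))
  # no noise components: observation equals truth
  none <- apply_residual(c(0, 5, 100), "plasma", noise_free_pop())
  expect_equal(none$observed, c(0, 5, 100))

  obs <- apply_residual(rep(100, 1e5), "plasma", pop, seed = 407)
  expect_equal(sd(obs$observed), 30, tolerance = 0.02)
  expect_equal(mean(obs$observed), 100, tolerance = 0.01)

  # at zero truth only the additive component remains (before flooring)
  z <- apply_residual(rep(0, 1e5), "urine", pop, seed = 408)
  expect_equal(sd(z$observed[!z$floored] - 0),
               sd(abs(rnorm(1e5, 0, 0.080))), tolerance = 0.1)
  expect_true(all(z$observed >= 0))
  expect_gt(mean(z$floored), 0.45) # about half the draws get floored
})

test_that("VPC bands collapse without variability and stay ordered", {
  des <- tiny_design()
  pop0 <- noise_free_pop()
  d0 <- generate_dataset(pop0, des, seed = 409)
  v0 <- vpc_percentiles(d0, pop0, des, n_sim = 100, seed = 410)
  expect_true(all(abs(v0$sim_hi - v0$sim_lo) < 1e-9))
  expect_true(all(abs(v0$observed - v0$sim_med) < 1e-9))

  pop <- fitted_pop()
  d <- generate_dataset(pop, des, seed = 411)
  v <- vpc_percentiles(d, pop, des, n_sim = 100, seed = 412)
  wide <- tidyr::pivot_wider(v, id_cols = c("matrix", "time_h"),
                             names_from = "level", values_from = "observed")
  expect_true(all(wide$`0.1` <= wide$`0.5` & wide$`0.5` <= wide$`0.9`))

  # self-consistency: data simulated from the model itself should fall
  # inside the simulation envelope almost everywhere
  inside <- v$observed >= v$sim_lo & v$observed <= v$sim_hi
  expect_gt(mean(inside), 0.9)
})
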