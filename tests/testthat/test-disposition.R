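test_that("micro rate constants follow the clearance/volume ratios", {
  p <- typical_params()
  m <- micro_rates(p)
  expect_equal(m[["k10"]], 0.047 / 0.149, tolerance = 1e-12)
  expect_equal(m[["k21"]], 0.00015 / 0.012, tolerance = 1e-12)
  expect_equal(m[["k31"]], 0.00443 / 0.029, tolerance = 1e-12)

  unitary <- pk_params(1, 1, 1, 1, 1, 1, 1)
  expect_equal(micro_rates(unitary)[["k10"]], 1)

  # zero distribution clearance degenerates to no exchange
  p2 <- pk_params(0.1, 0.05, 0.05, 0.05, 0, 0.004, 10)
  m2 <- micro_rates(p2)
  expect_identical(unname(m2[c("k12", "k21")]), c(0, 0))

  expect_error(micro_rates(c(V1 = -1, V2 = 1, V3 = 1, CL = 1,
                             CL2 = 0, CL3 = 0, Rss = 1)),
               class = "flx_error_invalid_parameter")
})

test_that("macro constants conserve the initial condition and interlace", {
  p <- typical_params()
  mc <- macro_constants(micro_rates(p), dose = 1.1, V1 = p[["V1"]])
  expect_equal(sum(mc$A), 1.1 * 1000 / p[["V1"]], tolerance = 1e-10)
  expect_true(all(diff(mc$lambda) < 0))
  expect_true(all(mc$lambda > 0))

  set.seed(401)
  for (i in 1:200) {
    pr <- random_params()
    m <- micro_rates(pr)
    mc <- macro_constants(m, 1, pr[["V1"]])
    expect_true(all(mc$lambda > 0))
    expect_lt(mc$lambda[3], min(m[["k21"]], m[["k31"]]))
    expect_gt(mc$lambda[1], max(m[["k21"]], m[["k31"]]))
    expect_true(all(mc$A > 0)) # mammillary bolus solution is positive
    expect_equal(sum(mc$A), 1000 / pr[["V1"]], tolerance = 1e-9)
  }
})

test_that("half-lives from the fitted typical values match the reported secondary parameters", {
  hl <- secondary_parameters(typical_params())
  # reported: 2.0, 5.1 and 58.8 h; printed inputs carry 2-significant-figure
  # rounding, so a 10% slack is used (documented for the terminal phase)
  expect_equal(hl$half_life_alpha, 2.0, tolerance = 0.10)
  expect_equal(hl$half_life_beta, 5.1, tolerance = 0.10)
  expect_equal(hl$half_life_gamma, 58.8, tolerance = 0.10)
  expect_true(hl$half_life_alpha < hl$half_life_beta &&
                hl$half_life_beta < hl$half_life_gamma)
})

test_that("Vss and MRT follow from the primary parameters", {
  # bootstrap-median primaries with the reported clearance 0.046
  sec <- secondary_parameters(pk_params(0.151, 0.013, 0.03, 0.046,
                                        0.00015, 0.00429, 37.1))
  expect_equal(round(sec$MRT, 1), 4.2)
  expect_equal(secondary_parameters(typical_params())$Vss, 0.190,
               tolerance = 1e-12)

  # rate constants are scale invariant: doubling all volumes and clearances
  # leaves every half-life unchanged
  p <- typical_params()
  p2 <- p; p2[1:6] <- 2 * p2[1:6]
  s1 <- secondary_parameters(p)
  s2 <- secondary_parameters(p2)
  expect_equal(s1$half_life_gamma, s2$half_life_gamma, tolerance = 1e-10)
  expect_equal(s1$half_life_alpha, s2$half_life_alpha, tolerance = 1e-10)
})

test_that("bolus concentration starts at dose/V1 and vanishes for zero dose", {
  p <- typical_params()
  mc <- macro_constants(micro_rates(p), 1.1, p[["V1"]])
  c0 <- plasma_concentration(mc, regimen(1.1), 0)
  expect_equal(c0, 1.1 * 1000 / 0.149, tolerance = 1e-9)
  # inside the observed initial-concentration range 6.54-9.91 ug/mL
  expect_gt(c0 / 1000, 6.54)
  expect_lt(c0 / 1000, 9.91)

  mc0 <- macro_constants(micro_rates(p), 0, p[["V1"]])
  expect_equal(plasma_concentration(mc0, regimen(1.1), c(0, 1, 10)),
               c(0, 0, 0))
  # before the first dose the concentration is zero
  expect_equal(plasma_concentration(mc, regimen(1.1), -1), 0)
})

test_that("multiple dosing is exact superposition of shifted single doses", {
  set.seed(402)
  for (i in 1:20) {
    p <- random_params()
    mc <- macro_constants(micro_rates(p), 1.1, p[["V1"]])
    reg <- regimen(1.1, 12, 10)
    t <- sort(runif(50, 0, 300))
    multi <- plasma_concentration(mc, reg, t)
    by_hand <- Reduce(`+`, lapply(dose_times(reg), function(td) {
      plasma_concentration(mc, regimen(1.1), t - td)
    }))
    expect_equal(multi, by_hand, tolerance = 1e-12)
  }
})

test_that("analytic solution matches stiff ODE integration to 1e-8", {
  skip_if_not_installed("deSolve")
  set.seed(403)
  ode_conc <- function(p, reg, times) {
    m <- micro_rates(p)
    rhs <- function(t, y, parms) {
      list(c(-(m[["k10"]] + m[["k12"]] + m[["k13"]]) * y[1] +
               m[["k21"]] * y[2] + m[["k31"]] * y[3],
             m[["k12"]] * y[1] - m[["k21"]] * y[2],
             m[["k13"]] * y[1] - m[["k31"]] * y[3]))
    }
    ev <- data.frame(var = "A1", time = dose_times(reg),
                     value = reg$dose * 1e6, method = "add")
    grid <- sort(unique(c(0, dose_times(reg), times)))
    out <- deSolve::lsoda(c(A1 = 0, A2 = 0, A3 = 0), grid, rhs, NULL,
                          events = list(data = ev),
                          rtol = 1e-12, atol = 1e-10)
    # ng/kg -> ng/mL through the central volume
    out[match(times, out[, "time"]), "A1"] / p[["V1"]] / 1000
  }
  for (reg in list(regimen(1.1), regimen(1.1, 24, 5))) {
    p <- random_params()
    mc <- macro_constants(micro_rates(p), reg$dose, p[["V1"]])
    tmax <- max(dose_times(reg)) + 72
    times <- sort(runif(200, 0.01, tmax))
    times <- times[!times %in% dose_times(reg)]
    ana <- plasma_concentration(mc, reg, times)
    ode <- ode_conc(p, reg, times)
    keep <- ana > 1e-6 * max(ana) # avoid digits lost to absolute tolerance
    expect_true(all(abs(ana[keep] - ode[keep]) / ana[keep] < 1e-8))
  }
})

test_that("the profile decays strictly after the distribution phases wash out", {
  set.seed(404)
  for (i in 1:10) {
    p <- random_params()
    reg <- regimen(1.1, 24, 3)
    mc <- macro_constants(micro_rates(p), reg$dose, p[["V1"]])
    start <- max(dose_times(reg)) + 10 / mc$lambda[2]
    t <- seq(start, start + 500, length.out = 200)
    expect_true(all(diff(plasma_concentration(mc, reg, t)) < 0))
  }
})

test_that("urine concentrations are plasma times Rss", {
  expect_equal(urine_concentration(2.0, 36.8), 73.6)
  expect_equal(urine_concentration(0, 36.8), 0)
  expect_error(urine_concentration(-1, 36.8),
               class = "flx_error_invalid_input")
  expect_error(urine_concentration(1, 0),
               class = "flx_error_invalid_parameter")
})

test_that("degenerate models are rejected with a clear error", {
  # zero exchange into compartment 2 leaves a zero eigenvalue
  p <- pk_params(0.1, 0.05, 0.05, 0.05, 0, 0.004, 10)
  expect_error(macro_constants(micro_rates(p), 1.1, p[["V1"]]),
               class = "flx_error_degenerate_model")
})
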