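test_that("EPC is daily dose over daily clearance", {
  expect_equal(round(epc(1.1, 24, 0.046)), 996)
  expect_equal(epc(0, 24, 0.046), 0)
  expect_equal(epc(2.2, 24, 0.046), 2 * epc(1.1, 24, 0.046))
  # a 12-hourly dose doubles the daily dose rate
  expect_equal(epc(1.1, 12, 0.046), 2 * epc(1.1, 24, 0.046))
  expect_error(epc(1.1, 24, 0), class = "flx_error_invalid_parameter")
})

test_that("IPC and IUC scale the EPC by the uncertainty factor and Rss", {
  tab <- ipc_iuc(epc(1.1, 24, 0.046), Rss = 36.8)
  expect_equal(round(tab$IPC, 1), 2.0)
  expect_equal(tab$IUC, tab$IPC * 36.8)
  expect_equal(tab$IUC, 73.0, tolerance = 0.01)
  expect_equal(ipc_iuc(500, Rss = 10, safety_factor = 1)$IPC, 500)
  expect_error(ipc_iuc(996, Rss = 0), class = "flx_error_invalid_parameter")
})

test_that("detection time is the final crossing below the screening limit", {
  p <- typical_params()
  # limit above the whole profile: never detectable
  expect_equal(detection_times(p, regimen(1.1), limit = 1e6), 0)
  # typical horse, single dose, plasma 1 ng/mL: inside the observed
  # 30-96 h range
  dt <- detection_times(p, regimen(1.1), limit = 1)
  expect_gt(dt, 30)
  expect_lt(dt, 96)

  # against a dense grid scan at 0.01 h resolution
  set.seed(413)
  horses <- sample_individuals(fitted_pop(), 40, seed = 413)
  d <- detection_times(horses, regimen(1.1, 24, 2), limit = 1)
  for (i in seq_len(nrow(horses))) {
    pi <- as.numeric(horses[i, c("V1", "V2", "V3", "CL", "CL2", "CL3", "Rss")])
    names(pi) <- c("V1", "V2", "V3", "CL", "CL2", "CL3", "Rss")
    mc <- macro_constants(micro_rates(pi), 1.1, pi[["V1"]])
    grid <- seq(24, 24 + 600, by = 0.01)
    above <- plasma_concentration(mc, regimen(1.1, 24, 2), grid) >= 1
    dt_grid <- if (any(above)) grid[max(which(above))] - 24 else 0
    expect_lt(abs(d$dt_h[i] - dt_grid), 0.02)
  }
})

test_that("detection time is monotone in limit, dose and number of doses", {
  p <- typical_params()
  expect_gte(detection_times(p, regimen(1.1), 0.5),
             detection_times(p, regimen(1.1), 1))
  expect_gte(detection_times(p, regimen(1.1), 1),
             detection_times(p, regimen(1.1), 5))
  expect_gte(detection_times(p, regimen(2.2), 1),
             detection_times(p, regimen(1.1), 1))
  expect_gte(detection_times(p, regimen(1.1, 24, 5), 1),
             detection_times(p, regimen(1.1, 24, 1), 1))
})

test_that("quantile tables are ordered, regimen-monotone and reproducible", {
  pop <- fitted_pop()
  dtq <- detection_quantiles(pop, n = 500, seed = 414)
  tab <- tidy(dtq)
  by_cell <- split(tab, interaction(tab$regimen, tab$matrix))
  for (cell in by_cell) {
    expect_true(all(diff(cell$dt_h[order(cell$level)]) >= 0))
  }
  # the same horses take longer to clear heavier regimens
  pl <- tab[tab$matrix == "plasma", ]
  for (lv in unique(pl$level)) {
    x <- pl[pl$level == lv, ]
    expect_gte(x$dt_h[x$regimen == "q12h_5d"], x$dt_h[x$regimen == "q24h_5d"])
    expect_gte(x$dt_h[x$regimen == "q24h_5d"], x$dt_h[x$regimen == "single"])
    expect_gte(x$dt_h[x$regimen == "q12h_1d"], x$dt_h[x$regimen == "single"])
  }
  expect_identical(tidy(detection_quantiles(pop, n = 500, seed = 414)), tab)

  # no variability: every quantile is the typical horse's detection time
  dtq0 <- detection_quantiles(noise_free_pop(),
                              regimens = list(single = regimen(1.1)),
                              n = 100, seed = 1)
  t0 <- detection_times(typical_params(), regimen(1.1), 1)
  pl0 <- tidy(dtq0)
  expect_true(all(abs(pl0$dt_h[pl0$matrix == "plasma"] - t0) < 1e-6))
})

test_that("plasma detection outlasts urine detection whenever Rss < 100", {
  # under limits 1 (plasma) and 100 (urine), urine = Rss * plasma crosses
  # its limit earlier iff Rss < 100
  horses <- sample_individuals(fitted_pop(), 200, seed = 415)
  dp <- detection_times(horses, regimen(1.1), 1, matrix = "plasma")
  du <- detection_times(horses, regimen(1.1), 100, matrix = "urine")
  sub <- horses$Rss < 100
  expect_true(all(dp$dt_h[sub] >= du$dt_h[sub]))
})

test_that("the bootstrap tolerance bound sits above the point percentile", {
  expect_equal(rmtc_withdrawal(rep(10, 200))$withdrawal_h, 10)
  set.seed(416)
  dts <- rexp(500, 1 / 50)
  wd <- rmtc_withdrawal(dts, seed = 417)
  expect_gte(wd$withdrawal_h, wd$percentile)
  expect_error(rmtc_withdrawal(dts, p = 1.2),
               class = "flx_error_invalid_input")
  expect_error(rmtc_withdrawal(c(1, 2, 3)),
               class = "flx_error_invalid_input")
})
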