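# Shared fixtures: the fitted flunixin population values and small designs
# used across the suite. Everything is built in code at test time.

typical_params <- function() {
  pk_params(V1 = 0.149, V2 = 0.012, V3 = 0.029,
            CL = 0.047, CL2 = 0.00015, CL3 = 0.00443, Rss = 36.8)
}

typical_cv <- function() {
  c(V1 = 2.0, V2 = 4.2, V3 = 19.1, CL = 30.0,
    CL2 = 14.8, CL3 = 10.3, Rss = 55.5)
}

fitted_pop <- function() default_population()

# population with no between-horse variability and optionally no noise
noise_free_pop <- function(theta = typical_params()) {
  population_model(theta = theta,
                   omega2 = setNames(rep(0, 7), names(theta)))
}

# a small (optionally one-arm) two-arm design for fast simulation tests
tiny_design <- function(n1 = 3, n2 = 3) {
  arms <- list(
    single = list(
      n_subjects = n1,
      regimen = regimen(1.1, 24, 1),
      plasma_times = c(0.5, 1, 3, 6, 9, 24, 48, 72, 120, 168),
      urine_times = c(24, 48, 96)),
    multi = list(
      n_subjects = n2,
      regimen = regimen(1.1, 24, 3),
      plasma_times = c(0.5, 3, 9, 24, 48, 48.5, 51, 72, 96, 144, 192),
      urine_times = c(72, 96, 144)))
  arms <- arms[vapply(arms, function(a) a$n_subjects > 0, logical(1))]
  study_design(arms, lloq = c(plasma = 0.1, urine = 3))
}

# random but physiologic parameter draws for property-style tests
random_params <- function() {
  pk_params(V1 = runif(1, 0.05, 0.5),
            V2 = runif(1, 0.005, 0.1),
            V3 = runif(1, 0.005, 0.1),
            CL = runif(1, 0.01, 0.2),
            CL2 = 10^runif(1, -5, -1.5),
            CL3 = 10^runif(1, -4, -1.5),
            Rss = runif(1, 5, 100))
}
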