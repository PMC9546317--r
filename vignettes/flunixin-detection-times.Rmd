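---
title: "Population pharmacokinetics and detection-time simulation for flunixin in horses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population pharmacokinetics and detection-time simulation for flunixin in horses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flunixinpk)
```

## The problem

Flunixin meglumine is a routinely used NSAID in horses and a controlled
medication in racing. Regulators publish *screening limits* (SL) — plasma
and urine concentrations above which a sample tests positive — and
veterinarians need *detection times*: how long after the last
administration a horse's concentrations stay above those limits. A
detection time measured in six or eight experimental horses carries no
statistical guarantee for the population of racehorses. This package
implements the model-based alternative: fit a population pharmacokinetic
model to experimental horses, then simulate thousands of virtual horses
and report the quantiles of their detection times, together with the
regulatory concentrations (EPC/IPC/IUC) that motivate the screening
limits in the first place.

## The model

**Disposition.** Plasma kinetics after an intravenous bolus follow a
three-compartment mammillary model, parameterised by the central and two
peripheral volumes (`V1`, `V2`, `V3`, L/kg), plasma clearance (`CL`,
L/kg/h) and two distribution clearances (`CL2`, `CL3`, L/kg/h). All
quantities are per kilogram of bodyweight, so bodyweight itself never
enters. The analytic solution is a tri-exponential,
$C(t) = A_1 e^{-\lambda_1 t} + A_2 e^{-\lambda_2 t} + A_3 e^{-\lambda_3 t}$,
whose rates are the eigenvalues of the compartmental rate matrix. They are
computed from the symmetric similarity transform of that matrix (closed
form plus Newton polishing on the characteristic cubic), which is well
conditioned near the interlacing bounds where a naive cubic formula loses
digits; the degenerate case of repeated roots raises an explicit error.
Multiple dosing is handled by superposition, which is exact for a linear
model. A sample drawn exactly at an administration time is a pre-dose
trough in the study convention used throughout the data layer;
`plasma_concentration()` itself reports the right-continuous (post-bolus)
value, which is what detection-time logic needs.

**Urine.** Urinary concentration is modelled as proportional to plasma:
$C_u(t) = R_{ss}\,C_p(t)$, with `Rss` the steady-state urine-to-plasma
ratio estimated jointly with the disposition parameters. The
proportionality presumes pseudo-distribution equilibrium, so urine records
enter the fit only when taken at least 24 h after an administration. The
default reads "after an administration" per dose (a record is eligible
when the most recent dose is at least 24 h old); the alternative reading —
24 h after the *first* dose only — is available as
`fit_settings(urine_rule = "first_dose")`. The per-dose rule is the
conservative one: it keeps the multi-dose troughs and the late washout
but excludes samples drawn shortly after any bolus, where proportionality
cannot hold.

**Between-horse variability.** Each parameter is lognormal across horses:
$P_i = \theta_P\,e^{\eta_i}$, $\eta_i \sim N(0, \omega^2_P)$,
independently per parameter (a diagonal omega matrix — no correlation
structure is estimated or assumed, which matters for what the simulations
can and cannot reproduce; see *Limitations*). Variances are reported as
lognormal CV%, $100\sqrt{e^{\omega^2}-1}$; the no-radical variant
sometimes seen in software output is available via `form = "literal"` in
`cv_from_omega2()` for comparison, but the radical form is the standard
lognormal relation and is used everywhere.

**Residual error.** Observations follow a combined model,
$y = f\,(1+\varepsilon_1) + \varepsilon_2$, with a proportional SD shared
between matrices (default 0.30) and separate additive SDs for plasma
(0.063) and urine (0.080), in the concentration unit of the data
(ng/mL as declared in the packaged configuration; the two additive terms
are mapped plasma-first, an assumption recorded here because the source
estimates do not label them by matrix). Negative simulated observations
are floored at zero and flagged rather than resampled, preserving the
error distribution except on a boundary of measure zero.

## Estimation

`population_fit()` maximises the Laplace approximation to the marginal
likelihood. For each subject the inner problem finds the posterior mode of
the random effects — the empirical Bayes estimates — by damped
Gauss-Newton with an analytic Jacobian of the tri-exponential with
respect to the log parameters (first-order eigenvalue perturbation on the
symmetric form). The inner problem is parameterised as $u = \eta/\omega$
so the prior is standard normal and the Laplace log-determinant,
$\log\det(I + J^\top W J)$, stays well conditioned as $\omega^2 \to 0$.
The inner solve always starts from the prior mode, making the outer
objective a deterministic function of its parameters; this matters
because the inner problem can be multimodal, and a history-dependent
objective derails quasi-Newton outer optimisation. The outer problem —
log typical values, log variances, log residual SDs — is minimised with
`nlminb` (PORT), using central finite differences with a step of `1e-4`
on the log scale, far above the inner-solve noise floor; forward
differences bias the gradient enough to stall the line search. PORT's
occasional "false convergence" at a kink is handled by restarting from
the stopping point until the objective stops improving. Convergence uses
a relative objective tolerance of `1e-6` with at most 500 outer
iterations.

Below-quantification records are excluded from every objective (the
simple "M1" convention) and counted in the fit summary; the source
analysis does not describe censored-likelihood handling, so none is
invented here.

**Initial estimates** are data driven: for each subject, exponential
curve stripping on the post-last-dose profile (slowest phase first),
inversion of the stripped tri-exponential to micro constants, `Rss` from
the urine/plasma ratio, then a weighted least-squares individual fit.
Typical values start at the medians of the per-subject estimates,
variances at the empirical variance of the per-subject log estimates
(kept inside [1e-4, 0.3] so the start is never degenerate), and the
proportional residual SD at a robust MAD of the pooled relative
residuals.

**Precision** is estimated by a nonparametric bootstrap
(`bootstrap_precision()`): subjects are resampled with replacement,
stratified by study arm so each replicate retains both designs, each
replicate is refitted starting from the point estimates, and parameters
are summarised as median, CV% and 2.5/97.5 percentiles. Replicate fits
use a looser outer tolerance (1e-4 relative) and a tighter iteration cap
than the primary fit — bootstrap outputs are percentile-level statistics,
for which that precision is ample. Fifty replicates is the conventional
choice; the examples and tests use ten, which is enough for percentile
intervals at test precision.

## Regulatory quantities

- `epc()`: effective plasma concentration, daily dose over daily
  clearance; 1.1 mg/kg/day at CL = 0.046 L/kg/h gives ≈ 996 ng/mL.
- `ipc_iuc()`: the irrelevant plasma concentration divides the EPC by an
  uncertainty factor (default 500 = 50 for the effect scale × 10 for
  PK/PD variability); the irrelevant urine concentration multiplies the
  IPC by `Rss`.
- `detection_times()`: the final downward crossing of the screening limit
  after the last administration, on noise-free individual predictions
  (IPRED) — measurement error belongs to assays, not horses. After the
  last bolus the profile is a positive tri-exponential and hence strictly
  decreasing, so the final crossing is unique; it is bracketed by
  geometric horizon expansion and solved to 1e-3 h.
- `detection_quantiles()`: one meta-population (default 5000 horses) is
  sampled and reused across all regimens and matrices, so regimens are
  compared on identical horses; type-7 empirical quantiles are reported,
  rounded to whole hours for tables while raw values are retained.
- `rmtc_withdrawal()`: the US-style 95/95 tolerance limit — the upper
  95% percentile-bootstrap confidence bound (default 1000 resamples) of
  the 95th detection-time percentile.

The four reporting regimens are a single 1.1 mg/kg dose, two doses 12 h
apart (the "q12h one day" reading of a twice-daily course), five daily
doses, and ten doses at 12-h intervals.

## The synthetic-data generator

`generate_dataset()` emulates the source study design
(`default_design()`): ten horses with a single dose, rich plasma sampling
from 0 to 240 h and urine from 3 to 120 h; ten horses dosed daily for five
days with plasma sampling to 336 h (including pre-dose troughs) and urine
from 99 h. Quantification limits are 0.1 ng/mL (plasma) and 3 ng/mL
(urine), applied with values preserved and a flag set strictly below the
limit. Urine is generated at *all* scheduled times, including those less
than 24 h post dose, precisely so the estimation module's eligibility
filter is exercised rather than bypassed. The noise-free truth rides
along in a `conc_true_ng_per_ml` side channel that the estimation code
never reads. The generator's defaults are the fitted population values in
`inst/extdata/flunixin_population.yaml`; they are the study conditions,
not tuning knobs.

What the generator does *not* emulate: assay drift, dilution artifacts,
urine-flow physiology, correlated etas, or any covariate structure (age,
sex, bodyweight). Tests passing on these data therefore demonstrate
internal consistency of the pipeline — simulate, fit, simulate forward —
not robustness to the full messiness of field data.

## Numerical choices

- Units: hours, L/kg, mg/kg doses, ng/mL concentrations; the dose is
  converted once at the boundary (1 mg/kg in `V1` L/kg is
  `1000/V1` ng/mL).
- Eigenvalues: symmetric-similarity closed form with two Newton polish
  steps (≈ 1e-11 relative agreement with LAPACK); repeated roots within
  1e-9 relative raise a degenerate-model error.
- Quantiles: type 7 everywhere, matching the default of `quantile()`.
- Detection-time root finding: bisection-based `uniroot` to 1e-3 h inside
  a geometrically expanded bracket; a 2000 h horizon guards against
  parameter sets that never clear the limit.
- Problem sizes in the test-suite: Monte Carlo checks run at n = 5000
  (the published population size); recovery uses one 20-subject study
  and a 10-replicate bootstrap; the VPC self-consistency check uses 100
  replicate studies of a reduced two-arm design. These sizes give
  Monte Carlo standard errors comfortably inside the tolerances asserted.

## Limitations

- Independence of the etas is an assumption, not an estimate. The
  published meta-population ("eta was as estimated") appears narrower
  than independent lognormal sampling from the reported CVs — its
  observed urine detection ranges match its simulated quantiles almost
  exactly, which shrunken, correlated post-hoc etas would produce and
  independent parametric sampling cannot. Consequently the package's
  urine detection-time upper quantiles are systematically wider
  (longer) than the published ones, while plasma quantiles agree within
  Monte Carlo tolerance. `detection_quantiles()` documents this; anyone
  with access to the original post-hoc eta vectors can resample them
  instead via `sample_individuals()`'s output contract.
- Laplace with a Gauss-Newton Hessian is not the (unnamed) estimation
  engine of the original commercial software; second-decimal differences
  in estimates are expected.
- Half-life and detection-time cross-checks against printed tables
  inherit the tables' 2-significant-figure rounding; the terminal
  half-life check carries a documented ±10% slack for that reason.
- Single IV bolus only: no absorption models, no metabolites, no
  saturable clearance, no urine-volume physiology.

## A worked pass through the pipeline

```{r example, eval = FALSE}
pop <- default_population()

# regulatory concentrations
ipc_iuc(epc(1.1, 24, CL = 0.046), Rss = 36.8)

# detection-time quantiles for the four regimens, 5000 horses
dtq <- detection_quantiles(pop, standard_regimens(), n = 5000, seed = 1)
tidy(dtq)
autoplot(dtq)

# synthetic study, fit, diagnostics, precision
d <- generate_dataset(pop, default_design(), seed = 1)
fit <- population_fit(d)
tidy(fit); glance(fit)
autoplot(fit)
vpc <- vpc_percentiles(d, fit$pop, n_sim = 200, seed = 2)
plot_vpc(vpc)
bootstrap_precision(d, fit, n_replicates = 10, seed = 3)
```
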