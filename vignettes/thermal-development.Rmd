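---
title: "Modelling temperature-dependent stemborer development with tpcdev"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling temperature-dependent stemborer development with tpcdev}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpcdev)
```

This vignette is the package's account of its models and of the numerical
and design choices behind them.

## The development-rate model

An immature insect stage held at constant temperature $T$ completes a
fraction $r(T)$ of its development per day; the mean development time is
$1/r(T)$. Across temperature, $r(T)$ traces a thermal performance curve:
zero at and below a critical minimum $CT_{min}$, rising to a maximum at
$T_{opt}$, collapsing to zero at a critical maximum $CT_{max}$. The
package's catalogue (`tpc_model_specs()`) holds eleven nonlinear forms
that parameterise both thresholds explicitly, so the three thermal traits
are always identifiable from a fit. Linear (degree-day) models are
excluded on principle: they have no thresholds and extrapolate falsely
outside the quasi-linear range.

Two catalogue equations deserve a note. The Ratkowsky form is the
square-root regression squared,
$r(T) = [c\,(T-CT_{min})(1-e^{k(T-CT_{max})})]^2$, and the Régnière form
is implemented from its original formulation with a single boundary-layer
width $\Delta_b$ applied at both thresholds and the upper threshold
identified with $CT_{max}$; the exact expressions are recorded in the
catalogue documentation and every catalogue member is tested for
unimodality on its thermal domain.

**Non-negativity contract.** Several raw formulas go negative or become
undefined outside $(CT_{min}, CT_{max})$ (the Brière square root, the
performance-2 exponential). `tpc_rate()` therefore clamps raw values at
zero and returns exactly 0 at and outside the thresholds. This makes
"development is null beyond the critical limits" a property of the code,
not of each formula.

**$T_{opt}$.** `tpc_traits()` locates the maximum by a 0.001 °C grid scan
followed by golden-section refinement (`optimize`, tolerance 1e-5 °C) in
the bracketing cells; ties on a non-unimodal pathology resolve to the
lowest temperature. For the two models with closed-form stationary points
the numeric optimum agrees with
$T_{opt} = (2\,CT_{max}+CT_{min})/3$ (Kontodimas) and
$T_{opt} = \bigl(4CT_{max}+3CT_{min}+\sqrt{16CT_{max}^2+9CT_{min}^2-16CT_{min}CT_{max}}\bigr)/10$
(Brière-1) to within 1e-3 °C; the test suite uses those closed forms as
independent oracles.

## Fitting and the selection ledger

`fit_stage()` minimises the residual sum of squares of observed rates
(inverse mean development times, pooled across studies, unweighted)
against the curve, using Levenberg–Marquardt (`minpack.lm::nls.lm`).
Starting values are data-driven — $CT_{min}^0 = \min T - 2$ °C,
$CT_{max}^0 = \max T + 2$ °C, shape parameters at mild defaults, and the
single multiplicative scale parameter solved so the start curve passes
through the largest observed rate — with 20 jittered restarts under a
fixed seed, keeping the best RSS. LM is a local optimiser and no
published starting values exist for these data, so multi-start under a
seed is the reproducible compromise. Standard errors are the usual NLS
curvature estimates $(J^\top J)^{-1}\,RSS/(n-k)$; they match `nls()`
exactly on shared problems.

The AIC convention is $n\ln(RSS/n) + 2(k+1)$ — the Gaussian
least-squares likelihood up to a constant, counting the error variance as
a parameter. Only $\Delta AIC$ matters downstream and that is invariant
to the constant (tested). `select_model()` applies the ledger in order:
discard $\Delta AIC \ge 10$; mark $\Delta AIC \le 2$ equivalent; discard
biologically implausible thresholds ($CT_{min} < 0$ °C or
$CT_{max} > 50$ °C, including fits that converge exactly onto a bound —
they are discarded, not clipped); select the lowest-AIC survivor. A
zero-RSS fit is flagged as perfect and treated as tied at the top rather
than producing NaN differences. When nothing survives, the error lists
every fit and the reason it fell.

Pooling across rearing studies assumes no study effect, which NLS cannot
absorb as a random factor. `study_effect_check()` therefore runs a
one-way ANOVA of the fit residuals grouped by study — residuals rather
than raw rates, so the shared temperature dependence is removed first.
This operationalisation is a package choice (the grouping variable and
response are otherwise under-determined) and is labelled in the output.
`residual_diagnostics()` exports residuals, a Shapiro–Wilk statistic and
a scale-location slope for the usual graphical checks; nothing is
rejected automatically.

## The individual-based simulator

For a species model (three selected stage curves plus a coefficient of
variation), individual $i$'s rate in stage $j$ at temperature $T$ is

$$r_{ij}(T) \sim \mathcal{N}\!\left(\mu = \tau_j(T),\ \sigma = cv \cdot \tau_j(T)\right)
\quad \text{truncated to } [0, \infty),$$

independent across stages, with $cv = 0.15$ by default — a value
supported by the few insect taxa where inter-individual rate variation
has been measured, held constant across stages, species and temperatures
for lack of anything better. Total time is $d_i = \sum_j 1/r_{ij}$; a
zero stage rate makes $d_i$ infinite. All eggs are laid at $t = 0$;
diapause and temperature-dependent mortality are deliberately outside the
model.

Sampling uses the inverse-CDF construction (`qnorm` of a uniform
restricted above the normal mass below zero): exact, vectorised, and
deterministic under seed. At $cv = 0.15$ the truncation mass is
$\approx 10^{-11}$, so the method choice is numerically immaterial but
the determinism matters. Each temperature gets its own sub-stream derived
from the master seed, so refining a temperature grid never reshuffles
draws at existing temperatures.

An individual **fails** when $d_i$ strictly exceeds the 182-day deadline
(six months: the gap between dry seasons in the tropics, spring to autumn
at temperate latitudes); equality counts as success. The thermal window
(`thermal_window()`) is the pair of temperatures bounding the region
where the failure fraction of a 5000-individual cohort is at most 0.5,
found by a 0.5 °C scan of [0, 50] °C plus bisection to 0.05 °C. The suite
cross-checks the simulated failure fractions against an independent
numeric-integration oracle (2-D quadrature over two truncated-normal
stage rates with the analytic CDF of the third) to within 0.02, and the
cv = 0 limit against deterministic deadline crossings.

The deterministic total-rate curve $r(T) = 1/\sum_j 1/\tau_j(T)$ and its
maximum `rmax` (0.01 °C grid over [0, 50] °C) underpin the impact metric.
The simulated median total time tracks $1/r(T)$ within 2 % at cv = 0.15,
which justifies computing $r/r_{max}$ on the deterministic curve rather
than by simulation.

With the packaged parameter sets, the simulated windows are
(16.6, 37.0) °C for *C. partellus* and (15.2, 33.0) °C for *B. fusca*.
For *O. nubilalis* and *S. nonagrioides* the parameter table itself caps
what any simulation can produce — e.g. the *O. nubilalis* pupal
$CT_{max}$ of 36.3 °C bounds $T_{50max}$ below previously reported
window values near 38.9 °C — so only the first two species serve as
quantitative anchors; the other two are exercised through the bound and
oracle properties instead. No parameter was adjusted to close that gap.

## Climate impact

`period_monthly_means()` averages each calendar month across the years of
a period (current 1990–2014, future 2081–2100 by default) for one GCM's
regional aggregate, with equal weight per year-month (day-weighting is
not recoverable from monthly aggregates) and a hard error on any missing
year-month. `r_over_rmax()` maps a temperature to the fraction of maximal
development, 0 when any stage is outside its domain, and
`impact_difference()` is the per-month future-minus-current difference,
bounded in $[-1, 1]$ by construction. `impact_assessment()` runs every
GCM present in both periods and `ensemble_summary()` reduces to per-month
mean/min/quartiles/max (type-7 interpolated quantiles, matching how
ensemble boxplots are usually drawn). Regions arrive pre-aggregated; the
reader normalises scenario spellings (`SSP1-2.6` → `ssp126`) and counts
GCMs rather than asserting ensemble sizes.

## What the synthetic generators do and do not emulate

`generate_observations()` produces literature-style observation tables by
simulating `n_reps` individuals per study × temperature × stage under the
same truncated-normal rate model the simulator assumes and recording mean
times — so fitting, selection and the study-effect check are exercised
against data whose generating process is known. Multiplicative per-study
offsets inject a detectable study effect. Non-developing temperature ×
stage combinations are dropped, as real studies report no time there.
Larval observations are stage totals; instar-level bookkeeping is not
modelled. What the generator does **not** emulate: digitisation error in
extracted means, unequal replicate counts, between-population TPC
differences, or temperature-dependent mortality censoring slow
individuals. Passing the recovery tests therefore shows the estimator is
correct under its own assumptions, not that literature data satisfy them.

`generate_ensemble()` is a shift-plus-noise fixture (baseline
climatology, scenario offset, one GCM-level shift per GCM, interannual
noise), adequate for schema and invariant testing; it is not a climate
emulator and has no trends within periods or autocorrelation.

## Problem sizes and tolerances

Default simulations use 5000 individuals (doubling changes the window
bounds by under 0.05 °C); the parameter-recovery study uses 100 synthetic
datasets of 50 replicates at six temperatures, recovering the larval
$CT_{max}$ with a median absolute error well under 1.5 °C. Window
bisection stops at 0.05 °C (0.01 °C where tests compare against
deterministic crossings); $T_{opt}$ is reported to 1e-3 °C. The whole
test suite runs in well under a minute on one core.

## Known limitations

Constant-temperature development only: no daily rate summation under
fluctuating regimes, hence no heat-wave effects. No diapause induction or
termination, no mortality, no cohort staggering. The cv is assumed
temperature-independent; if variance actually shrinks near the thermal
limits, the simulated windows are slightly conservative. Monthly regional
mean temperatures hide microclimate — canopy shade, within-stem
buffering — so impact differences describe regional potential, not
realised phenology.
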