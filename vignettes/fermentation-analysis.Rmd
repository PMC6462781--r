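---
title: "Fermentation time-course analysis with fermentr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fermentation time-course analysis with fermentr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(fermentr)
```

## The problem

A typical strain-characterization campaign produces analyte measurements
scattered across instruments: optical density from a plate reader, sugar and
product concentrations from HPLC injections, each export in its own tabular
dialect, each sample labeled by hand. fermentr organizes this into a single
hierarchy — time point, analyte time course, single trial (one independent
fermentation volume), replicate trial, experiment — and computes the derived
quantities a metabolic engineer actually compares: growth rates, titers,
yields, specific productivities, and a carbon balance closed by a
stoichiometric model.

The only metadata convention required is the flat trial identifier, a string
of `key:value` tokens typeable directly into instrument software:

```{r}
id <- parse_identifier("strain:MG1655|media:M9|strain__plasmid:pTrc99a|rep:1")
id
```

Parsing and canonical serialization are exact inverses, so identifiers can be
stored, merged and compared as strings. Trials are *replicate-equivalent* —
grouped into one replicate trial — when they agree on every field except the
replicate index, the sample time and the analyte.

## Replicate statistics with missing data

Instrument dropouts and failed injections are routine, so every statistic is
computed per time point over the observations that exist, without imputation.
The bundled 3-replicate example shows the convention:

```{r}
e <- assemble_experiment(table1_fixture())
replicate_statistics(e$replicates[[1]])$OD600
```

The mean is defined wherever at least one observation exists (at 6 h it is a
single replicate's value); the standard deviation uses the sample (n−1)
denominator and is undefined (`NA`) below two observations. We chose the n−1
denominator because it reproduces 0.1 for the triple (0.5, 0.6, 0.4) at t = 0,
the value a bench scientist expects from a spreadsheet `STDEV`.

## Growth models

Exponential growth $dX/dt = \mu X \iff X = X_0 e^{\mu t}$ covers the log
phase and is fit exactly by ordinary least squares on $\log X$ — no
iteration, no initializer. Cultures with lag and stationary phases need a
sigmoid. We use the biologically parameterized generalized logistic

$$X(t) = \frac{A}{1 + \exp\!\left(\frac{4\mu_{max}}{A}(\lambda - t) + 2\right)}$$

and a five-parameter Richards curve

$$X(t) = X_0 + (A - X_0)\left[1 + \nu e^{1+\nu}
  e^{\frac{\mu_{max}}{A}(1+\nu)^{1+1/\nu}(\lambda - t)}\right]^{-1/\nu}$$

whose parameters are directly interpretable: $A$ the asymptote (same unit as
the data), $\mu_{max}$ the maximum specific growth rate (1/h, the slope of
the inflection tangent), $\lambda$ the lag time (h), and for Richards a shape
parameter $\nu > 0$ that skews the inflection point ($\nu = 1$ recovers a
logistic-type curve) plus a baseline $X_0$. Several Richards
parameterizations circulate in the predictive-microbiology literature; this
one was chosen so that every parameter keeps its biological meaning and the
logistic is nested at $\nu = 1$.

The sigmoid fits use bounded Levenberg–Marquardt least squares with a fixed,
data-driven initializer (asymptote = max value, $\mu_{max}$ = steepest
finite-difference slope, lag = intercept of the steepest tangent, $\nu$ = 1),
so a given course always produces the same fit:

```{r}
tt <- seq(0, 24, by = 0.5)
idb <- parse_identifier("strain:A|media:M9|analyte:OD600")
course <- analyte_course(idb, tt, growth_gen_logistic(tt, 2, 0.5, 1),
                         unit = "OD")
coef(fit_growth_model(course, "gen_logistic"))
```

Numerical rates use the second-order three-point finite-difference formula
for nonuniform grids (exact for quadratics at interior points, first-order
one-sided at the ends); missing values are dropped before differencing.
Rates divided by interpolated biomass give specific rates, converted to the
constraint-based-modeling unit mmol/gDW/h when a molar mass is supplied.
When two analytes live on different time grids the second is linearly
interpolated onto the first — never extrapolated; points outside the overlap
are dropped with a warning.

## Outliers, blanks, stages

Outlier replicates are screened by leave-one-out deviation: replicate $r$
scores $\rho_r = \mathrm{median}_t\, |y_r(t) - m_{-r}(t)| /
\max(|m_{-r}(t)|, \varepsilon)$ against the mean of the others, and is
flagged when $\rho_r > \tau$. The default $\tau = 0.5$ flags a replicate
whose typical deviation exceeds half the consensus signal — aggressive
enough to catch a mis-inoculated well, conservative enough to survive plate
noise; $\varepsilon = 10^{-6}$ only guards division where the consensus
crosses zero. At most $n - 2$ replicates are ever flagged, so the two
best-agreeing replicates always survive; with fewer than three replicates
the screen is inert. Note the guard is deliberately blunt: if *every*
replicate deviates (e.g. two inconsistent pairs), the cap keeps the two with
the lowest scores, which is a coherent but not magical choice.

Cell-free blank trials (`strain:blank`) are matched to sample trials sharing
media and environment, and their mean course (interpolated in time) is
subtracted; corrected values may legitimately go negative and are not
clipped. Stage slicing cuts every course on half-open intervals
$[b_k, b_{k+1})$ — the last stage closed — so that, e.g., a product yield
can be computed over the production stage only.

## Yields and the carbon balance

The endpoint yield is $(P_{end} - P_0)/(S_0 - S_{end})$ in the analytes' own
mass units (mass/mass was chosen over C-mol/C-mol so that no composition
assumptions enter; carbon-based accounting lives in the flux layer).
Measured specific rates then constrain a stoichiometric model at steady state
($Sv = 0$, bounds $lb \le v \le ub$, exchange flux > 0 = export), and the LP
optimum estimates what was not measured — canonically the CO₂ evolution
rate, which closes the carbon balance without off-gas analysis:

```{r}
m <- toy_model_fixture()
co2 <- estimate_co2(m, c(EX_glc = -10, EX_etoh = 20), "EX_co2")
co2
carbon_recovery(list(glucose = c(10, 6), ethanol = c(20, 2),
                     co2 = c(co2, 1)), substrates = "glucose")$recovery
```

Measured rates are applied as strict equalities by default; a `slack`
fraction relaxes them to symmetric bands when measurement noise warrants.
When the model has no objective, total absolute flux is minimized
(parsimonious fallback); on the toy network the CO₂ flux is uniquely
determined by the constraints either way, and the tests assert that
invariance. Biomass enters the carbon ledger via the standard elemental
composition CH₁.₈O₀.₅N₀.₂ (24.6 g per C-mol), configurable where a measured
composition exists.

The LP itself is solved by a dense two-phase primal simplex with Bland's
anti-cycling rule — deterministic and exact at the desk scale this package
targets (tens of reactions). It is not sized for genome-scale models; for
those, export the measured constraints and use a dedicated FBA toolchain.

## Synthetic data: what it does and does not emulate

The generator produces batch fermentations with closed-form ground truth:
logistic biomass on a baseline, substrate drawn down at yield $Y_{XS}$,
product formed at $Y_{PS}$ per substrate consumed (substrate-coupled, not
Luedeking–Piret, precisely so that yields are analytically exact), plus
additive Gaussian noise, missing-completely-at-random dropout, and
constant-background blanks. Defaults — A = 2 gDW/L, $\mu_{max}$ = 0.5 1/h,
$\lambda$ = 1 h, $X_0$ = 0.05 gDW/L, $S_0$ = 20 g/L, $Y_{XS}$ = 0.5,
$Y_{PS}$ = 0.4, 3 replicates, samples every 2 h to 24 h — describe an
unremarkable aerobic *E. coli*-like batch. All randomness flows from one
seed; equal configurations are byte-identical.

What it does **not** emulate: instrument drift, carryover between
injections, co-elution, growth-dependent (Luedeking–Piret) production
kinetics, diauxie, or death phase. Tests passing on this generator therefore
demonstrate correctness of the bookkeeping and the estimators under clean
assumptions, not robustness to every real-data pathology.

```{r}
g <- generate_experiment(synthetic_config(seed = 42))
e <- assemble_experiment(g$points)
s <- e$replicates[[1]]$singles[[1]]
compute_yield(s$courses$product, s$courses$glucose)$endpoint_yield  # = Y_PS
```

## Persistence

Experiments round-trip exactly through a single-file SQLite store
(normalized tables for strains, media, environments, trials, courses and
time points; a membership table lets one replicate trial serve several
experiments). Saves are idempotent upserts keyed on serialized identifiers;
an attempt to save *different* values under an identical identifier is
refused with a rollback rather than silently merged — distinguish such runs
with an `experiment:` key in the identifier. Missing values are stored as
SQL NULL. Computed features are never persisted: they are cheap to recompute
and would go stale when the correction pipeline changes.

## Numerical choices and degenerate inputs

* Duplicate (trial, analyte, time) observations — repeated HPLC injections —
  are averaged over their finite values, with a warning.
* Assembly is permutation-invariant and orders everything lexicographically
  on serialized identifiers, so outputs are reproducible row for row.
* Cumulative yields are undefined (NA) until net substrate consumption
  exceeds 10⁻⁹ concentration units, avoiding 0/0 at the first sample.
* Sigmoid fits stop at Levenberg–Marquardt tolerances of 10⁻¹⁴ with at most
  500 iterations; non-convergence is an error carrying the last iterate, not
  a silent best effort.
* The LP feasibility tolerance is 10⁻⁹; steady state is asserted to
  ‖Sv‖∞ ≤ 10⁻⁶ in the solution contract.
* Problem sizes in the test suite (24–49-point courses, 100-seed noise
  sweeps, 50 round-trip experiments, a 5-reaction network) were picked to
  exercise every code path while keeping the whole suite quick to run on a
  laptop.

## Known limitations

* One fitting window per course: no automatic phase segmentation or diauxic
  multi-model fitting; `slice_stages()` plus a `window` argument is the
  manual route.
* The plate reader parser expects the exported time × well matrix, not
  vendor-proprietary block formats; export to CSV/XLSX first.
* Yields are endpoint/cumulative ratios, not regression slopes; for noisy
  data, fit the courses first and compute yields from the fits.
* The simplex is dense and unscaled; it is deliberately not a genome-scale
  solver.
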