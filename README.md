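# dyde — Dynamical Differential Expression

`dyde` is an R package for asking a question that standard differential
expression cannot answer: **where does a chemical perturbation enter a gene
regulatory network?** In a feedback-rich system such as the circadian clock,
a drug that alters one regulatory interaction changes the expression of
*every* rhythmic gene downstream, so ranking genes by expression change
points at ripples, not at the entry point. `dyde` instead compares the
*dynamics of links* between two conditions.

It is aimed at systems biologists with short, uniformly sampled
two-condition expression time courses (the motivating regime: log-scale
microarray series, 12 samples at 4 h intervals, 2 replicates, e.g. plants
under constant light with and without a period-lengthening drug).

## Method

**Rhythmicity screen.** Circadian but non-sinusoidal profiles are modeled
with *pseudo-sinusoids*: half-cycles of two sinusoids with periods `p1` and
`p2` joined continuously, overall period `P = (p1 + p2)/2`. For each gene an
exhaustive grid search minimizes the residual 2-norm after removal of the
best straight line. Eight features (band-power ratio in the 18–32 h band,
pseudo-sine fit error, periodogram variance, fitted amplitude — each for the
replicate mean and for the best single replicate) feed a logistic
classifier; genes with posterior probability > 0.5 are called rhythmic.

**Link identification.** For every directed pair of genes (u = regulator,
y = target) a first-order linear time-invariant model

    dy/dt = a·u(t) − b·y(t) + c

is fitted by minimizing the simulation error (variable projection over the
decay rate `b`; `a`, `c`, `x0` profiled in closed form). Goodness of fit is

    fitness = 100 · (1 − ‖y − ŷ‖₂ / ‖y − ȳ‖₂)   [%]

and a link is validated when fitness reaches a threshold (46 % for the
clock-gene regime; 80 % / 60 % for genome-wide scans).

**Differential dynamics.** Links validated in both conditions are compared
with the **nu-gap** metric `δν ∈ [0, 1]` between the transfer functions
`P(s) = a/(s + b)` — by default restricted to the circadian frequency band
(periods 18–32 h), since the data constrain the models only there. Links
lost after treatment form the *regulation-loss network*, summarized per gene
as connectivity loss (% of its in+out links abolished). High nu-gap common
links and high connectivity-loss genes are the candidate entry points;
values above ~0.2 are conventionally significant.

## Worked example

Simulate the packaged two-condition benchmark (six genes, two rhythmic
modules, one perturbed link `D1 → G2` with weakened synthesis and faster
turnover, 5 % measurement noise), then run the full pipeline:

```r
library(dyde)
sim <- simulate_pair(synthetic_spec(seed = 1))
cfg <- dyde_config(fit_threshold_pct = 80, rng_seed = 1)
rep <- run_pipeline(sim$baseline, sim$perturbed, cfg = cfg)

rep$link_counts
#> $validated_A 9   $validated_B 9   $lost 0   $common 9   $gained 0

head(rep$top_nugap[, c("source","target","fitness_pct","fitness_pct_B","nugap")], 3)
#>   source target fitness_pct fitness_pct_B  nugap
#> 1     D1     G2        96.7          95.6 0.7047
#> 2     D2     G4        97.6          98.4 0.0199
#> 3     D2     G3        98.2          97.1 0.0164
```

Nine directed models clear the 80 % threshold in both conditions; the
perturbed link `D1 → G2` tops the nu-gap ranking at `δν = 0.70` — far above
the 0.2 significance guide — while every untouched link scores ≈ 0.02. The
underlying identified model for the true link:

```r
fit_first_order(average_replicates(sim$baseline, "D1"),
                average_replicates(sim$baseline, "G2"), sim$baseline$times)
#> first_order_model: dy/dt = 0.5145 u - 0.2603 y + 1.605, x0 = 22.03, fitness 96.7%
```

(generating parameters: a = 0.5, b = 0.25, c = 1.5).

A command-line interface wraps the same stages
(`exec/dyde <rhythm|fit|compare|nugap|scan|bench|simulate|run> [--flags]`).

## Package layout

- `R/`, `src/` — implementation (data model, rhythmicity, system
  identification, nu-gap, network analysis, benchmarking, synthetic data,
  pipeline/CLI)
- `vignettes/dyde-methods.Rmd` — model assumptions, parameter choices,
  numerical decisions, limitations
- `tests/testthat/` — unit, property and acceptance suites
- `inst/extdata/` — small plain-text fixtures (synthetic reference network)
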