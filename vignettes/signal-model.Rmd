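---
title: "Modeling STR capillary-electrophoresis signal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling STR capillary-electrophoresis signal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strsignal)
```

## The signal and its components

A capillary-electrophoresis (CE) STR profile is a collection of peaks per
locus, each with an allele designation, a fragment size in base pairs and a
height in relative fluorescence units (RFU). Against a known single-source
genotype, every peak is one of four components — a true (allelic) peak, a
reverse stutter (one repeat unit below its parent allele), a forward
stutter (one repeat above), or noise — and every *candidate position* at
which a component could have produced a peak but did not is a drop-out
event for that component. That gives an eight-component model: four
Gaussian peak-height components and four Bernoulli drop-out components.

Peak heights are modeled as `N(u(x), v(x))` where `x` is a peak-level
explanatory variable and `u`, `v` are parametric functions (affine,
exponential, or constant depending on the family). Drop-out is Bernoulli
with probability `p(x)`. The package ships a registry of 18 candidate
families (`model_families()`), distinguished by their functional form and
their choice of `x`: the qPCR template amount, its size-decayed version,
the undegraded per-dye amplitude, the *decayed amplitude*, or the parent
peak height (for stutter).

## Degradation and the decayed amplitude

Degradation nicks DNA at a rate `lambda` per base pair, so a target of
length `s` survives with probability `exp(-lambda * s)` and the expected
signal of an allele of size `s` is `H(s) = A * exp(-lambda * s)`. Rather
than relying on external qPCR measurements, the profile's own decay is fit
from its per-locus amplitudes: for each locus, the amplitude `H_l` is the
sum of observed peak heights and `s_l` the height-weighted mean allele
size; an exponential regression of `H_l` on `s_l` (exact interpolation for
two loci, log-space least squares otherwise) gives `(A_c, B_c)` per dye
color, or pooled across dyes. The decayed amplitude of a fragment of size
`s` is then `x = A_c * exp(B_c * s)` — the explanatory input of the
selected allelic and noise models. The qPCR Degradation Index `q` relates
to the decay rate through `log q = -delta * lambda` with `delta = 134` bp
(the difference between the 214 bp and 80 bp quantification targets); the
instrument convention reports `q >= 1` for degraded samples while the
negative-log relation implies `q <= 1`, so `di_to_lambda()` uses
`|log q| / delta` and records the convention.

```{r}
lad <- function(base) data.frame(allele = as.character(8:14),
                                 size = base + 4 * (0:6))
panel <- str_panel(list(
  list(name = "A", dye = "blue", repeat_len = 4, ladder = lad(96)),
  list(name = "B", dye = "blue", repeat_len = 4, ladder = lad(196))))
prof <- str_profile("ex", data.frame(
  marker = c("A", "B"), allele = "8", size = c(100, 200),
  height = c(2000, 1000)))
fit_decay(prof, panel, mode = "pooled")
```

## Likelihoods

For a component's observed heights the package maximizes the
heteroscedastic Gaussian log-likelihood

    L_h = -sum_i [ log v(x_i) + (h_i - u(x_i))^2 / (2 v(x_i)^2) ],

i.e. the exact Gaussian log-likelihood up to its additive
`-n log sqrt(2 pi)` constant, which cancels whenever families are compared
on identical data. Keeping the quadratic `1/2` makes `v(x)` exactly the
standard deviation of the generative peak model `N(u(x), v(x))` used by
the simulator and the evidence likelihood; an objective without it would
calibrate a scale function `sqrt(2)` larger than the distribution it is
later used to evaluate, breaking the coherence between calibration,
simulation and inference. Stutter-ratio models (`r = h / PPh`) use the same
form on the ratio scale; with `u = PPh * u_r` and `v = PPh * v_r` the two
scales obey `L_h = L_r - sum(log PPh)`, which puts ratio families on the
height scale for model comparison. Drop-out families maximize the
Bernoulli log-likelihood `sum log(p(x) y + (1 - p(x)) (1 - y))`;
`loglik_dropout()` returns that quantity (to be maximized) and attaches
its negation, the minimized form some references print, as attribute
`"L_DO"`.

Fits (`fit_component()`) use five deterministic moment-based starts
(least-squares of `h` on `x` for the mean, binned residual spread for the
scale, logistic regression for drop-out) followed by bounded L-BFGS-B with
per-parameter scaling. `v(x)` is floored at 0.001 RFU so the search never
leaves the likelihood's domain; the exponential drop-out family is
constrained to `a` in (0, 1.5], `b >= 0` with `p` clamped to 1, because
the raw form can exceed 1 near `x = 0`. The constant noise drop-out family
has the closed-form solution `a = mean(y)` and is fitted exactly.

## Cross-validation and the one-standard-error rule

Families competing for a component are compared by k-fold (default
`k = 10`) cross-validation separately per dataset (a dataset is one kit ×
injection-time condition): fit on `k - 1` folds, evaluate the held-out
log-likelihood `L`, and record the prediction error `L* = -L / N` with `N`
the number of held-out observations (likelihoods are observation-additive,
so observations — not profiles — are the natural unit for `N`). Folds
group by source profile so one sample's peaks never straddle the
train/test split. Reverse- and forward-stutter datasets are pooled, giving
stutter families twice the estimates. `select_model()` applies the
one-standard-error rule: among families whose mean error lies below
`mu(f_min) + sigma(f_min)`, the one with fewest parameters wins, with ties
broken by lower mean error and then by a fixed precedence order. The
selected set (`selected_model_set()`) is affine-on-decayed-amplitude for
allelic and noise peaks, affine-on-parent-height for both stutters,
exponential drop-out (on decayed amplitude for alleles, on parent height
for stutters) and a constant noise drop-out frequency.

## The simulator

`simulate_profile()` is the generative counterpart of the calibrated
model, and the package's test substrate. Each contributor carries two
allele copies per locus; a copy of size `s` contributes an amplicon pool
of expected decayed amplitude `x = phi * A * exp(-lambda * s)`, survives
allele drop-out with probability `1 - p(x)`, and emits a Gaussian height
`N(u(x), v(x))`. Contributions at shared positions are drawn independently
and summed — amplicon counts add, and signal is proportional to amplicons.
Stutter positions fire against the realized parent height; every remaining
candidate position (the locus ladder plus its one-repeat flanks) can emit
a noise peak. Heights are truncated at the analytical threshold (1 RFU) by
resampling (at most 100 draws, then the threshold itself) so that drop-out
remains governed solely by the calibrated Bernoulli component.

The default parameter bundle (`default_model_bundle()`) is synthetic —
chosen to look like a clean modern multiplex (heterozygous allele peaks
near half the locus amplitude, reverse stutter near 8% and forward stutter
near 2% of the parent, rare noise peaks at a 2% drop-in rate) — and the
built-in panel (`default_panel()`) is a nine-locus, three-dye
tetranucleotide layout spanning 80–420 bp. The simulator emulates
component structure, exponential decay, drop-out and (optionally) injected
pull-up; it does not emulate raw fluorescence traces, spectral bleed,
off-ladder microvariants, or inter-locus amplification imbalance, so
passing tests demonstrate internal consistency of the model pipeline, not
performance on laboratory data.

```{r}
panel <- default_panel()
set.seed(1)
g <- random_genotype(panel)
sim <- simulate_profile(sim_config(panel, list(g), amplitude = 3000,
                                   lambda = 0.003), "S1")
table(sim$truth$component, observed = sim$truth$h > 0)
fit_decay(sim$profile, panel, mode = "pooled")
```

## Classification and pull-up filtering

All position matching is by size window (default ±0.5 bp, half a CE sizing
bin), never by allele label, with precedence allele > reverse stutter >
forward stutter > noise at collisions. The noise-candidate universe is the
locus ladder plus its one-repeat flanks minus allele and stutter
positions; it is the minimal reproducible choice and can be extended to
half-repeat bins for loci that stutter at half repeats. Pull-up filtering
removes a peak when a taller cross-dye peak sits within ±0.6 bp at ≥
1/0.06 times its height; complex pull-up (checked first, as the more
specific diagnosis) requires tall peaks in at least two other dyes within
±0.3 bp plus a same-dye sister at ≥ 50% of the peak's height. The complex
rule is a reconstruction from its published thresholds; the exact rule
used by existing software is not documented.

## Posterior on the number of contributors

`app()` computes `P(N = n | E)` for `n = 1..N_max` by averaging the
evidence likelihood over a uniform prior on a discretized nuisance grid —
mixture fractions on a simplex grid of resolution `delta` (sorted
descending to collapse contributor relabelings) crossed with a finite grid
of per-contributor decay factors — multiplying locus likelihoods
(genotypes are independent across loci), and normalizing over `n`. At each
locus the likelihood given `(n, theta)` is estimated by Monte Carlo over
Hardy-Weinberg genotype draws; `brute_force_app()` replaces the sampling
with exact enumeration on small instances and is the estimator's oracle in
the tests.

Per candidate position, the reconstruction multiplies: for expected allele
positions, the drop-out mass `p(x_sum)` or the observed-peak density
`(1 - p(x_sum)) * N(h; u(x_sum), v_sum)` where `x_sum` sums the carrying
copies' decayed contributions and `v_sum^2` sums their per-copy variances
(independent amplicon pools); for stutter positions, the analogous terms
against the observed parent height when a parent peak exists, else the
expected parent height `u(x_sum)`; for all remaining positions, the noise
model at the profile-level decayed amplitude. Reverse stutter takes
precedence at collisions, matching the classifier. The amplitude scale `A`
of the profile under evaluation comes from its own pooled decay fit unless
overridden. Truncation of heights at the 1 RFU analytical threshold is
ignored in the density (negligible whenever `u >> 1` RFU). All
accumulation is log-space with log-sum-exp.

Numerical and design defaults: `delta = 0.1` and a decay grid spanning
realistic casework decay (`B` in [-0.012, 0] per bp) are appropriate for
production use; the examples and tests use coarser grids (`delta` = 0.25
to 0.5, 2-3 decay points) and `mc_iters` in the hundreds to thousands,
which keep the full posterior under a minute on a single core at the
problem sizes used here (6-9 loci, `N_max` = 3). Monte Carlo genotype
draws are deduplicated before evaluation, which is exact and typically
cuts the work several-fold at forensic allele counts.

```{r}
freqs <- lapply(panel$loci[1:6], function(l)
  setNames(rep(1 / nrow(l$ladder), nrow(l$ladder)), l$ladder$allele))
names(freqs) <- names(panel$loci)[1:6]
app(sim$profile, panel, freqs, N_max = 3, delta = 0.25,
    decay_grid = c(-0.002, 0), mc_iters = 300, seed = 21)
```

## Known limitations

* The calibration data path (classify → fit → select) assumes
  single-source profiles with known genotypes; mixtures enter only through
  the simulator and the posterior estimator.
* The per-position evidence factorization (stutter-of-stutter, allele /
  stutter collisions across contributors) is a documented reconstruction;
  collisions resolve by component precedence rather than explicit
  convolution of overlapping component densities.
* Degradation is a single exponential per dye (or pooled); severe
  inhibition with non-monotone size response is outside the model, and
  fits with positive decay factors are clamped at +0.01/bp and flagged.
* Parameter recovery accuracy quoted in the tests (5% at 10^4
  observations) holds at the simulator's signal-to-noise; very low
  template with heavy truncation at the analytical threshold biases the
  affine scale parameters.
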