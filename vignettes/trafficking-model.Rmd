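---
title: "A compartment model of raft-dependent secretory trafficking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A compartment model of raft-dependent secretory trafficking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rushkinetics)
```

## The model

Synchronized-release (RUSH) experiments follow a transmembrane cargo after
it is released from a hook organelle — the ER or the Golgi — and measure
the fraction of the cargo residing in each organelle over time. This
package models those kinetics with a linear five-state system:

- bulk ER and ER exit sites,
- a non-raft and a raft Golgi pool,
- an absorbing post-Golgi state.

Within each organelle the cargo partitions between the bulk and the minor
sub-compartment according to a concentration-ratio partition coefficient:
`kp_erex` for ER exit sites (a fitted parameter, one value per construct
class) and `kp_raft` for the Golgi raft pool (fixed per construct, taken
from GPMV phase-partitioning measurements). Transport between organelles
initiates only from the minor sub-compartments: exit sites feed the Golgi
at rate `k_a` (1/h) and the raft pool feeds the post-Golgi state at rate
`k_b` (1/h). There is no retrieval path and no delay compartment. Mass is
conserved: every column of the rate matrix sums to zero.

With a relative sub-compartment size `a`, a partition coefficient `kp`
puts an amount fraction

    f = kp * a / (kp * a + (1 - a))

into the minor pool. The package defaults to `a = 0.5` for both organelles,
so `f = kp / (kp + 1)` and GPMV-measured coefficients can be used
unchanged. Both size fractions are configuration, not biology we claim to
know.

## Rapid equilibrium and the closed form

Intra-organelle exchange is modeled as reversible first-order exchange
with forward rate `exchange_rate` (default 1e4 /h) and the backward rate
set by detailed balance against the partition equilibrium. At that default
the exchange is four orders of magnitude faster than fitted transport
rates, so sub-compartment occupancies track their equilibria and the
system reduces to effective single-exponential efflux with

    alpha = k_a * f(kp_erex)    (ER exit)
    beta  = k_b * f(kp_raft)    (Golgi exit)

For ER release the closed form is the standard two-step chain:
`ER(t) = exp(-alpha t)`,
`Golgi(t) = alpha/(beta - alpha) * (exp(-alpha t) - exp(-beta t))`, with
the confluent limit `alpha * t * exp(-alpha t)` when `alpha == beta`
(a removable singularity, switched to below a relative gap of 1e-12).
For Golgi release, `Golgi(t) = exp(-beta t)`.

Both the explicit five-state solution (`mode = "full_ode"`, evaluated by
matrix exponential, which is exact for a linear system) and the closed
form (`mode = "rapid_equilibrium"`) are provided. The test suite checks
that they agree to better than 1e-3 at the default exchange rate and that
the matrix-exponential solution matches an independent adaptive
integrator (`deSolve::lsoda`) to 1e-8. Fitting defaults to the closed
form: it is orders of magnitude faster and indistinguishable from the
full system in the regime the model is meant for. Whether the original
analysis solved the explicit exchange system or its reduction is not
something the model's outputs can distinguish in this regime, which is
precisely why both modes are exposed.

## Fitting

`fit_single_exponential()` extracts per-curve half-times
(`t_half = ln 2 / lambda`) by Levenberg–Marquardt least squares, with an
asymptotic 95% confidence interval and a classed failure (never silent
clipping) on non-decaying input. Plateaus are off by default because the
assay's curves decay to zero.

`global_fit()` fits the compartment model simultaneously to a collection
of efflux datasets — canonically eight: four constructs (raft-preferring
full-length and TMD-only, raft-depleted full-length and TMD-only) times
two release sites. The objective is the plain sum of squared residuals
over all datasets and points; inverse-variance weighting is available but
off by default. Free parameters are `k_a`, `k_b` and two ER-exit
partition coefficients (full-length, TMD-only); the five-parameter
variant gives one designated construct its own ER-exit coefficient.
`kp_raft` values are data, never fitted.

Optimization runs in log space (positivity without constrained
optimization), with multistart: each restart draws its start log-uniformly
over [1e-2, 1e2] in natural units, runs Levenberg–Marquardt (relative
tolerance 1e-10, at most 500 iterations), and the lowest chi-square wins,
ties broken by restart index so a fixed seed reproduces the result
bit-identically. Wide box bounds ([1e-8, 1e8], log space) keep the
optimizer inside finite floating-point territory. One thousand restarts
is the canonical protocol; the recovery tests use 25–100 restarts for the
well-behaved noiseless cases.

## What is identifiable — and what is not

The observable curves depend on the parameters only through `beta` for
each construct and `alpha` for each ER-exit class. Because `kp_raft` is
fixed from measurements, the Golgi side pins `k_b` uniquely (and
over-determines it across the two raft classes). The ER side does not:
any `k_a > alpha` can be paired with occupancies `f = alpha / k_a` to fit
the data exactly, so `(k_a, kp_erex_full, kp_erex_tmd)` form a
one-dimensional ridge of equivalent solutions. A multistart fit will land
anywhere on that ridge — typically at a box bound for one coefficient —
and the raw ER-exit coefficients (and their fold ratio) should therefore
not be interpreted. What is identified, and what the analysis scripts and
reports emphasize, is `k_b`, the effective rates `alpha` and `beta`, and
the fold between effective exit-site occupancies
`f(kp_erex_full) / f(kp_erex_tmd)`, which equals the fold between ER-exit
rates of the two classes. The nested-variant comparison is likewise
meaningful at the level of chi-square: a genuine ER-exit contrast between
two full-length constructs makes the shared-coefficient model measurably
worse, while on contrast-free data the extra parameter buys nothing.

## The synthetic generator

All inputs the pipeline consumes are generated in code, from a
`synthetic_truth` that fixes the generating parameters, probe panel,
sampling times, noise model and seed. Defaults were chosen once to match
the study conditions the published observations describe:

- `kp_raft` 1.8 for the raft-preferring probes and 0.4 for the
  raft-depleted ones — the GPMV scale for these probe families;
- `kp_erex` 4.5 (full-length) and 0.225 (TMD-only), a 20-fold contrast;
- `k_a = ln 2 / 0.7 / (4.5/5.5) ≈ 1.21` /h, anchoring the full-length
  ER-exit half-time at 0.7 h (TMD-only then falls at ≈ 3.1 h, a
  4.45-fold contrast);
- `k_b = ln 2 / 0.5 / (1.8/2.8) ≈ 2.16` /h, anchoring the raft probes'
  Golgi-exit half-time at 0.5 h (raft-depleted ≈ 1.12 h, a 2.25-fold
  contrast);
- sampling 0–8 h, denser early; intensity-readout noise sd 0.03 with
  three replicates averaged; population readout 20 cells per point.

Gaussian noise is clipped to [0, 1] and clipping events are counted;
binomial sampling draws ER-positive cells per replicate. The population
readout simulator draws per-cell rates from a mean-one lognormal
(default coefficient of variation 0.3, an artifact choice — single-cell
dispersion is not constrained by the data the model was built from). Its
positive-fraction curve is a sigmoid, not an exponential; fitting it with
a single exponential under the defaults (threshold 0.5, 0–4 h grid)
underestimates the single-cell half-time by about a third, a bias the
test suite quantifies against the closed-form curve. Half-time contrasts
between constructs survive this bias; absolute population-readout
half-times should be read with it in mind.

GPMV line scans are simplified to 1-D two-peak profiles whose
background-subtracted construct peak ratio is exactly the generating
coefficient, with the disordered-phase marker anti-correlated (4:1
contrast by default) and Gaussian intensity noise. Rendered cell images
place `golgi_fraction` of a fixed total signal in a Golgi disk inside a
cell disk at confocal-like signal-to-noise (default total 1e5 over ~1.6k
cell pixels against noise sd 2), so the positive-part background
subtraction of the measurement stays essentially unbiased. None of the
generators attempt photorealism: no point-spread function, no cisternal
structure, no vesicle-scale stochasticity. Passing round trips show the
procedures are correct and unbiased under these idealized conditions;
they do not validate segmentation or background estimation on real
micrographs.

## Quantification conventions

Per-vesicle raft partition coefficients are background-subtracted peak
ratios, peaks averaged over a 3-point window; the crossing with the lower
marker intensity is the raft phase; vesicles without two peaks above 20%
prominence, or with non-positive denominator, are rejected and counted.
Background defaults to the modal intensity of off-peak points when not
supplied. Summaries are hierarchical — vesicle, then experiment mean,
then grand mean — and group comparisons are Welch t-tests on experiment
means, treating the independent experiment, not the vesicle, as the unit
of replication. Colocalization is the Pearson correlation over in-mask
pixels (whole-image available by passing no mask). Organelle fractions
floor negative background-subtracted pixels at zero.

## Problem sizes

The shipped tests and the reproduction script use: 100 random parameter
draws for the solver-equivalence check; 100 (noiseless) and 1000 (noisy)
restarts for the global fits; 200 vesicles per partition-coefficient
round trip; 1e4 in-mask pixels for colocalization; 200 profiles for the
phase-assignment accuracy check; 100 repeats of the two-group power
simulation at 3 experiments x 15 vesicles. These sizes give Monte-Carlo
error comfortably below the tolerances asserted alongside them.

## Known limitations

- No Golgi-to-ER retrieval, no delay compartments, no intra-Golgi
  structure; the model is deliberately minimal.
- The ER-side partition coefficients are identified only through
  effective rates (see above); treat raw fitted values as coordinates on
  a ridge.
- Sub-compartment size fractions are conventions (0.5), not measurements;
  reported `kp` values scale accordingly.
- Synthetic imaging is idealized; quantification accuracy on real images
  depends on segmentation and background estimation quality outside this
  package's scope.
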