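---
title: "Temporal sequences, skew-symmetric fits, and the anatomy of 'rotational dynamics'"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal sequences, skew-symmetric fits, and the anatomy of 'rotational dynamics'}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 5)
library(rotdyn)
```

## The question

In studies of motor and premotor cortex, condition-averaged population
activity is often summarized by projecting it into a low-dimensional state
space. A widely used procedure, jPCA, fits the linear dynamical model

$$\dot{X} = M_{\mathrm{skew}}\,X, \qquad M_{\mathrm{skew}} = -M_{\mathrm{skew}}^{\top},$$

to PCA-reduced trajectories $X(t)$ and projects every condition onto the
plane of the strongest imaginary-eigenvalue pair of
$M_{\mathrm{skew}}$. Because a skew-symmetric matrix has purely imaginary
eigenvalues, the fitted flow rotates states about the origin; when all
conditions circle the same way in that plane, the result is read as
"rotational dynamics" and sometimes as evidence that the circuit operates
as a dynamical system rather than representing movement parameters.

This package implements every ingredient of that analysis from scratch —
the simulator, the PETH sequence analysis, the surrogate perturbations, the
skew-symmetric fit, and a Lissajous-curve regression — so that an
alternative, deflationary account can be tested end-to-end: *consistent
same-direction rotations appear whenever neurons reach their peak firing
rates in a temporal sequence that is conserved across conditions*, with no
further dynamical structure required. The package also reproduces two
methodological hazards of the procedure: an ill-conditioning failure caused
by its default preprocessing, and the fact that a generic linear readout
can extract essentially arbitrary target curves from the same data.

## The synthetic population

`simulate_wave()` generates one smoothed PETH per neuron per condition on a
uniform grid (default $-50$ to $550$ ms in 10-ms bins, 61 samples). Each
PETH is a Gaussian bump

$$r_{ic}(t) = a_{ic}\exp\!\big(-(t-\tau_{ic})^2 / w\big),$$

with width parameter $w = 50\ \mathrm{ms}^2$ (a standard deviation of
$\sqrt{w/2} = 5$ ms) and an amplitude $a_{ic}$ drawn once per (neuron,
condition) uniformly from $[0.2, 1.2)$. Peak times follow a fixed sequence:
neuron $i$ peaks `lag_ms` later than neuron $i-1$, and conditions are
partitioned into contiguous groups that share a base onset, so
$\tau_{ic} = \mathrm{onset}(g(c)) + (i-1)\cdot\mathrm{lag}$. The default
dimensions — 218 neurons and 108 conditions — match the motor-cortex
dataset around which these analyses were originally developed.

Parameters that matter, with defaults:

| parameter | default | meaning |
|---|---|---|
| `n_neurons`, `n_conditions` | 218, 108 | population dimensions |
| grid | $-50..550$ ms, 10-ms bins | analysis window |
| `lag_ms` | 1 ms | per-neuron peak delay (the "wave") |
| `onsets_ms` | 50 | base peak time per condition group |
| `amplitude_range` | $[0.2, 1.2)$ | uniform per-PETH amplitude |
| `kernel_width_param` | 50 ms² | Gaussian width parameter |

Two lag conventions are in circulation for this kind of simulation — a
1-ms delay per neuron, and one full 10-ms bin per neuron — and with 218
neurons they differ qualitatively (a 10-ms lag pushes most peaks outside a
600-ms window). The lag is therefore an explicit parameter rather than a
constant: the experiment runners default to 1 ms, while analyses that
measure order by grid argmax use one bin per neuron, since a sub-bin lag
cannot move a grid argmax. For sub-bin lags the amplitude-weighted centroid
(`centroid_times()`) is the appropriate peak-time estimate; on a 10-ms grid
the discrete centroid of a 5-ms-SD kernel is itself alias-distorted, so the
centroid-based checks in the test suite use a 1-ms grid.

What the generator deliberately does *not* emulate: trial-to-trial
variability (there are no trials, only condition means), directional tuning
or any motor-specific response model, multi-phasic responses, and — most
importantly — correlated across-neuron amplitude structure: amplitudes are
independent across neurons and conditions. Consequences of that last choice
are discussed below; in general, results on this synthetic population
demonstrate what a *temporal sequence alone* can produce, not what real
cortical data do produce.

## Sequence analysis

`average_across_conditions()` + `order_by_peak()` sort neurons by the grid
time of their average-PETH maximum (ties toward the earlier time, then the
lower index; an all-constant PETH is flagged degenerate and assigned the
first grid time). `split_subpopulations()` cuts the ranking into contiguous
near-equal blocks — 218 neurons in 3 groups gives sizes 73/73/72, with
remainders assigned to the earliest groups — and
`subpopulation_averages()` averages raw rates per group and condition.
Display normalization (`normalize_for_display()`, $(x-\bar x)/\max x$) is
exactly that: a display aid, never an analysis step.

`pairwise_correlation()` defaults to Pearson correlation of the
across-condition average time courses, which yields the one-number-per-pair
structure the corresponding summary figures show; correlation over all
conditions appended is available via `on = "appended"` since published
descriptions leave the choice open.

## Preprocessing, PCA, and the conditioning diagnostic

Two preprocessing paths are explicit. For plain PCA trajectory displays,
`standardize()` z-scores each neuron's appended series. The jPCA path
instead optionally applies `subtract_condition_mean()` — the procedure's
default preprocessing, in which each neuron's across-condition average PETH
is subtracted from all of that neuron's PETHs — followed by
`pca_reduce()`, an SVD of the column-centered (appended time $\times$
neurons) matrix with a deterministic sign convention (each loading's
largest-magnitude entry is made positive).

Mean subtraction is where the procedure can silently fail. If conditions
are identical, it leaves exactly zero; if conditions are identical up to a
per-condition amplitude scale — precisely what a single-onset-group
simulation produces — it leaves pure amplitude noise with no conserved
temporal structure, and the subsequent dynamics fit runs on that noise.
The `conditioning_report` therefore carries two numbers:

* `residual_fraction` — Frobenius norm after mean subtraction over the norm
  before; zero iff conditions are exactly identical;
* `rank1_residual_fraction` — the energy fraction remaining after removing
  each neuron's best rank-1 (scaled common time course) structure across
  conditions; zero iff each neuron's conditions are scalings of one
  profile.

Either falling below `tol = 1e-8` sets the `degenerate` flag. The flag does
not abort the fit — the degenerate fit is itself informative, producing the
characteristic "noisy traces" — but it propagates to the `jpca` object as
a prominent warning marking all downstream rotation summaries untrusted.
The second diagnostic is this package's own addition: the plain residual
fraction cannot detect the amplitude-scaled case, which is the one that
actually occurs in simulations with random amplitudes.

## The skew-symmetric fit

`finite_differences()` uses the forward first difference,
$\dot X_t = (X_{t+1}-X_t)/\Delta t$ paired with the left sample $X_t$ —
the simplest scheme consistent with published descriptions, whose
first-order convergence is verified in the test suite. All conditions are
pooled into a single regression, since "the same rotation in every
condition" is a single-fit property.

`fit_skew()` minimizes $\lVert \dot X - X M^{\top}\rVert_F^2$ twice: over
all $k\times k$ matrices (`M_best`, ordinary least squares) and over
skew-symmetric matrices (`M_skew`), the latter by parameterizing $M$ with
its $k(k-1)/2$ upper-triangle entries and solving the induced linear
least-squares problem. Antisymmetry therefore holds exactly by
construction, not by projection, and the constrained optimum satisfies the
stationarity (Lyapunov-type) equation
$A M + M A = \dot X^{\top} X - X^{\top}\dot X$ with $A = X^{\top}X$ — used
in the tests as an independent oracle, alongside direct numerical
minimization for $k \le 3$. Goodness of fit is the uncentered
$R^2 = 1 - \lVert\text{residual}\rVert^2 / \lVert\dot X\rVert^2$
(derivative data are already centered by construction after mean
subtraction), and $R^2_{\mathrm{skew}} \le R^2_{\mathrm{best}}$ always.
Rank-deficient designs fall back to the pseudoinverse with a warning rather
than failing, because degenerate inputs are a case the package must
exhibit, not avoid.

`rotation_planes()` pairs the eigenvalues $\pm i\omega_j$, orders planes by
$\omega$ descending, and builds each plane's orthonormal basis from the
real and imaginary parts of one eigenvector (QR-orthonormalized). For odd
$k$ the unpaired zero eigenvalue spans no plane. The basis orientation is
fixed so that the majority of conditions rotate counter-clockwise, making
plots reproducible. `project_and_summarize()` measures each condition's
rotation sign as the sign of the summed cross product
$\sum_t (x_t y_{t+1} - y_t x_{t+1})$ — twice the swept signed area — and
reports *direction consistency*, the fraction of conditions sharing the
majority sign. Consistency is the package's operationalization of
"rotating the same way in all conditions": 1.0 is a perfect rotational
signature, 0.5 is a fair coin.

## What the experiments show

Run at the default study conditions (218 neurons, 108 conditions, seed 1;
`run_experiment()` reproduces each bundle):

* A wave with two or three onset groups, analyzed with mean subtraction on,
  yields direction consistency 1.0 and a skew/best $R^2$ ratio well above
  0.5 — the temporal sequence alone produces textbook rotations.
* The same wave with a *single* onset group is flagged degenerate: after
  mean subtraction only amplitude noise remains, and the "rotations" that
  the fit still returns are noise. Shifting half of the conditions forward
  by 100 ms (`shift_half()`, constant initial padding) restores
  conditioning and the rotations, without changing the sequence.
* A synchronous population (`lag_ms = 0`, three onset groups) never
  rotates consistently: its direction split is statistically
  indistinguishable from a fair coin (binomial test at $\alpha = 0.01$),
  with or without mean subtraction.
* With mean subtraction off, every temporally spread dataset — including
  the per-neuron condition-shuffled surrogate — rotates with consistency
  1.0; the synchronous one still does not (its skew fit is numerically
  zero, so it has no rotation plane at all).

The acceptance thresholds used in the test suite (consistency $\ge 0.95$,
$R^2$ ratio $\ge 0.5$, chance-level via the binomial test) are artifact
constants chosen to separate these regimes decisively; they are not
estimates of any published quantity.

## Lissajous readout

`lissajous_target()` defines the circle
$x=\cos(2\pi t/T),\ y=\sin(2\pi t/T)$ and the figure-eight
$y=\sin(4\pi t/T)$, with $t$ measured from the window start and $T$
defaulting to the window duration (600 ms) so the circle closes once per
window. `lissajous_fit()` regresses each target coordinate separately on
the neuron-rate design matrix (appended time samples $\times$ neurons, plus
an intercept; the intercept is switchable since published conventions
vary), and `predict()` scores held-out conditions. The default
"half of the conditions" split is even/odd by index; a seeded random split
is available.

Design choices worth recording:

* The readout experiment uses a wave whose sequence tiles the whole window
  (onset $-50$ ms, `lag_ms = 600/218` ≈ 2.75 ms). The neurons' bumps act as
  a radial basis in time; a 1-ms-lag wave concentrates all basis functions
  in a ~217-ms span, structurally capping the fit over the rest of the
  window, which would say nothing about the regression itself. With full
  tiling, the circle is recovered with $R^2 \approx 0.97$ on training
  conditions and generalizes near-losslessly to held-out conditions — a
  deliberately arbitrary curve read out of "neural" data by ordinary least
  squares.
* The shuffle contrast uses the two-onset-group wave (onsets 50/200 ms,
  lag 1 ms). Because the generator's amplitudes are independent across
  neurons, per-neuron condition shuffling leaves the regression problem
  statistically almost unchanged — unlike in real data, where it destroys
  condition-coherent covariance. The degradation that does survive in this
  generator is specific to the figure-eight's second harmonic: held-out
  $R^2$ for the $y=\sin(4\pi t/T)$ output drops markedly after shuffling,
  and falls well below its training value. The test suite asserts exactly
  that contrast; a stronger, all-outputs degradation should not be expected
  from an amplitude-independent simulation, and observing it would require
  a generator with condition-coherent population structure.

## Numerical conventions and degenerate inputs

* Peak times: grid argmax, ties to the earliest time, then the lowest
  neuron index; all-constant PETHs flagged.
* Subpopulation sizes: ceil-first contiguous allocation (73/73/72 for
  218/3).
* PCA: SVD of the column-centered appended matrix; loadings sign-fixed;
  scores split back per condition.
* Skew fit: exact antisymmetry by parameterization; pseudoinverse fallback
  with warning on rank deficiency; $R^2$ `NA` when $\dot X$ is identically
  zero.
* `shift_half()` requires the shift to be a positive multiple of the bin
  width; padding uses each PETH's own first sample; samples pushed past the
  window are dropped.
* Zero-variance neurons make `standardize()` fail by name, and make
  `pairwise_correlation()` emit `NA` with a warning.
* All randomness (amplitudes, shuffles, random splits) is seeded and
  restores the caller's RNG state.

## Problem sizes

The test suite runs the full 218 × 108 × 61 pipeline for the acceptance
contrasts (a few seconds each) and much smaller populations — typically
5–40 neurons, 4–24 conditions — for unit and property checks, which keeps
the whole suite under a minute while exercising every code path at the
study dimensions where the scientific claims live.

## Limitations

The package analyzes condition-averaged rates only; nothing here speaks to
single-trial dynamics. The generator's independence assumptions make some
real-data phenomena (notably shuffle-induced degradation of readout
generalization) visible only in attenuated, shape-specific form. And the
package's deflationary demonstrations — that sequences suffice for
rotations and that arbitrary curves are linearly readable — bound what
rotational structure can prove; they do not show that any particular
recorded population lacks richer dynamics.
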