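---
title: "Correlated photon-counting histograms: models, estimators and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlated photon-counting histograms: models, estimators and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpch)
```

## The method

Fluorescence fluctuation spectroscopy watches single fluorophores wander
through a femtolitre observation volume and reads molecular properties out
of the fluctuations of the detected photon counts. Classical analyses use
one slice of the information at a time: fluorescence correlation
spectroscopy (FCS) uses the decay of the count autocorrelation with lag
time, which reports diffusion; photon-counting histograms (PCH) and
cumulant analyses (FCA) use the shape of the count distribution in a
single bin, which reports molecular brightness.

The correlated photon-counting histogram (cPCH) is the joint distribution
`p(n_x, n_y | tau)` of the counts in two bins of width `T` separated by a
lag `tau` (from one detector, or two spectrally distinct ones). Its shape
carries brightness information, and its change with `tau` carries
diffusion information, so mixtures of species differing in either property
can be resolved from a single dataset. FCS, PCH, dual-colour PCH and FCA
are exact special cases: the FCS curve is
`1 + (K)_{1,1}/((K)_{1,0}(K)_{0,1})` in terms of the joint factorial
cumulants, the PCH is the marginal over either axis (independent of the
lag), and the FCA cumulants are the `(n, 0)` orders.

### Closed-form building blocks

For 3D Gaussian observation volumes with radial and axial waists `r`, `z`
per channel, everything reduces to four families of factors:

* shape factors `gamma_{m,n}` — normalised spatial moments of the product
  of the two intensity profiles; `(m+n)^(-3/2)` for identical channels
  ([shape_factor()]);
* diffusion factors `kappa_{m,n}(tau, D)` — Lorentzian-type radial and
  square-root axial decays of the order-(m, n) two-point correlation
  ([diffusion_factor()]);
* flow factors `S_{m,n}` — Gaussian decay under uniform flow or scanner
  displacement ([flow_factor()]);
* binning functions `B_{m,n}(T, tau_d)` — corrections for motion during a
  counting bin comparable to the diffusion time, built as products of
  powers of the second-order function `B_2` ([binning_B2()],
  [binning_Bmn()]).

The factorial cumulants of a mixture are then linear in the species:
first order is `lambda + sum_i N_i eps_i T`, higher orders are
`gamma_{m,n} sum_i N_i (eps_i T)^(m+n) kappa_{m,n}(tau, D_i)
B_{m,n}(T, tau_i)` ([factorial_cumulant()]). Backgrounds are Poisson and
touch only the first order.

The shape-factor and `B_2` closed forms used here were derived directly
from their defining integrals (the per-axis Gaussian integrals are
elementary) and are verified against numerical quadrature in the test
suite, so no transcribed formula is trusted blindly.

### Full distributions

Three independent routes to `p_N(n_x, n_y | tau)` are implemented and
cross-checked to 1e-9 elementwise:

1. an alternating series for the single-molecule distribution in terms of
   its factorial moments ([p1_series()]), with adaptive truncation
   (hard cap 200 terms; very bright molecules are directed to the FFT
   route, where the compound-Poisson composition needs only the dim
   single-molecule input);
2. the compound-Poisson composition
   `exp(sum_q N_q (g1_q - 1) + background)` evaluated on a discrete
   Fourier grid ([pN_fft()]); the grid is a power of two chosen from a
   count-tail bound, doubled to suppress circular aliasing, and ringing
   below 1e-12 is clipped and renormalised (failure above 1e-6 is an
   error, not a warning);
3. a bivariate compound-Poisson recursion seeded at the (0,0) cell
   ([pN_recursion()]), filled along the two axes and then the interior.

The observation-to-experimental volume ratio is set to 1, the convention
under which the compound-Poisson composition is exact for mixtures.

## Estimation machinery

### Moment algebra

[convert_moments()] moves between raw moments, factorial moments,
cumulants and factorial cumulants with Stirling-number transforms per axis
and the bivariate exponential (Bell) recursion; closure of every
conversion chain is property-tested on random PMFs, and the definitions
are cross-checked against direct summation and numerical differentiation
of generating functions.

### Sampling variances

The delta-method ("moments of moments") variance of an empirical
(factorial) cumulant writes the cumulant as a closed-form polynomial in
the raw moments — built symbolically by a small internal polynomial engine
so the partial derivatives are exact — and contracts them with the
raw-moment covariances `(M_{x+u,y+v} - M_{xy} M_{uv})/N_d`
([mom_variance()]). This treats bin pairs as independent. Simulations show
this is accurate for the joint orders (mean squared z-scores of about 1)
but underestimates the variance of pure-channel orders by an order of
magnitude, because those are means of strongly autocorrelated series.
Two remedies are provided:

* an autocorrelation inflation `1 + 2 sum_k rho_k` for the marginal
  orders, estimated from the already-computed lagged moments (on by
  default in [empirical_cumulants()]); and
* replicate variances, which are the recommended fitting weights:
  across-segment variances for traces (contiguous segments much longer
  than any correlation time; `segments = 10` by default in
  [multitau_cumulants()]) and across-frame variances for image stacks
  (frames are separated by a full scan and retrace, far beyond the
  diffusion time; default in [spatial_cumulant_table()]).

With replicate weights, the cumulant fit energy evaluated at the true
parameters of simulated data sits near 1, as it should for a correctly
specified model with honest errors.

Because the pure-channel cumulants are lag-independent, the fitting tables
keep them at a single lag (`marginals_once`); repeating one perfectly
correlated statistic across the lag grid would only distort the energy.

### Fit energies and the nested-sampling optimiser

Both fit energies of the method are provided: the per-cell binomial-error
energy of the distribution ([energy_Ep()], cells with empirical
probability exactly 0 or 1 are excluded and counted) and the
variance-normalised sum of squares of the factorial cumulants
([energy_EK()]). Both are near 1 for a correct model.

[nested_sampling_fit()] minimises either energy with a population Monte
Carlo scheme: the worst of (typically) 100 live parameter sets is recorded
and replaced by a perturbed copy of another, updated one parameter at a
time with Gaussian (log-normal for diffusion) proposals. Everything below
an energy floor `E_min = 2` is always accepted, so the live set explores
the whole data-compatible region; above it a unit-temperature Metropolis
step is used (the temperature is a free design choice; unit temperature
is the simplest self-consistent one). Step sizes adapt per parameter,
growing by `exp(1/n_accepted)` when acceptances dominate and shrinking by
`exp(1/n_rejected)` otherwise, the standard convention. The point
estimate is the mean of the recorded sets that lie below `E_min` (with a
25% burn-in fallback when the run never settles); with two species a
label-switching symmetry is removed by enforcing `eps1 >= eps2`. Two-species
fits are initialised from the analytic inversion: each empirical 1D
cumulant is resampled within its estimated error, inverted in closed form,
and the physical solutions seed the live set ([sample_parameter_sets()]).

The analytic inversion itself ([invert_two_species()]) solves
`(K)_n = gamma_n (N1 eps1^n + N2 eps2^n)`, `n = 1..4`, as a two-point
Prony problem: the brightnesses are the roots of a quadratic whose
coefficients are ratios of Hankel-type determinants of `a_n = (K)_n /
gamma_n`, and the occupancies follow linearly. A fully expanded closed
form is algebraically fragile, so the implementation is validated by
exact round trips on 1000 random parameter draws; noisy cumulants yielding
complex or negative roots are flagged non-physical, and single-species
input (vanishing Hankel determinant) falls back to the one-species
solution.

## Synthetic data

[simulate_trace()] performs Brownian dynamics with photon emission:
molecules are placed uniformly in a periodic 4 x 4 x 8 um box with the
focus at the centre; at every step of length `dt` each molecule emits
Poisson photons with mean given by the 3D Gaussian intensity profile at
its current position (per channel), then positions advance by Gaussian
increments of variance `2 D dt` per axis with wrap-around. Emission
happens before the move within a step — the ordering within a step is a
convention, and its effect is bounded by keeping `dt << tau_d`. [simulate_image_stack()] extends this to raster scanning:
per pixel, counts are collected with the point-spread function centred on
the pixel, and line/frame retraces advance diffusion in dwell-sized steps.
The box spans four times the scanned region laterally.

Two implementation notes matter for interpretation:

* Far-field molecules are advanced by exact composed Brownian increments
  (scheduled on a timing wheel) instead of step by step. Brownian
  increments compose exactly and emission beyond the cut surface is below
  `exp(-17)` of the peak intensity, so photon statistics and the uniform
  occupancy are unchanged; only compute time is saved. The agreement of
  simulated cumulants with the closed forms, within calibrated errors, is
  itself part of the test suite.
* Because molecules are frozen within a step, counts binned at the
  simulation step carry no within-bin motion. Analyses of such data must
  disable the bin-time corrections (`binning = FALSE` in the fitters);
  the corrections apply — and are tested — on traces rebinned to bins much
  longer than the simulation step, where between-step diffusion dominates.

What the simulator does *not* emulate: triplet/blinking kinetics, detector
dead-time and afterpulsing, analog detection, open boundaries with
number fluctuations beyond the fixed total, and non-Gaussian observation
volumes. Passing tests therefore validate the statistical machinery, not
the absence of these artefacts in real data.

[cpch_preset()] freezes the simulation conditions used throughout the
package's validation: a single-species condition (occupancy 1, brightness
0.24448 counts per 10 us bin, diffusion time 175.7 us, structure factor
1.928), a two-species mixture differing threefold in brightness and
fivefold in diffusion time, a dim pair, a raster-scan condition
(256 x 256 pixels of 11.7 nm, 10 us dwell, 1 ms line retrace, occupancy
0.6, brightness 1.1 counts per dwell, D = 100 um^2/s), and a
ligand-receptor-like three-species preset (ligand, singly bound receptor
at equal brightness, doubly bound receptor at twice the brightness, with
receptors diffusing far slower). The beam waist is 265.1 nm everywhere,
chosen once as a typical confocal waist (it makes `tau_d = 175.7 us`
correspond exactly to `D = 100 um^2/s`). Durations in
examples and tests are desk-scale (tens of seconds, 4-10 frames), chosen
so the full validation runs on one CPU in minutes; estimator accuracy at
these sizes is the quantity the acceptance checks measure.

## Numerical choices

* `B_2` is evaluated by the closed form only where it is stable; a series
  branch (`alpha < 1e-5`) and a small-`beta` branch (`alpha^2 beta <
  1e-7`, the flat-axial limit with a first-order `beta` term) avoid
  catastrophic cancellation, and `beta` is clamped to `[1e-6, 1 - 1e-9]`
  against the `atanh` branch point as the structure factor approaches 1.
* The series route truncates when two consecutive terms fall below
  tolerance (alternating series) and refuses to continue past 200 terms.
* FFT grids use a mean + 10 sd + brightness-margin tail bound rounded to a
  power of two, with doubling padding; the unpadded tail mass is checked
  post hoc against 1e-7.
* Lag grids follow the multi-tau correlator convention (dense early lags,
  doubling spacing), optionally with bin times growing alongside the lag.
* Spatial fits use dense along-line pixel offsets plus a few
  line-crossing offsets. The line-crossing rows probe lags of several
  diffusion times at near-zero displacement — nearly pure time decay —
  which separates the diffusion coefficient from the beam waist (the two
  otherwise trade off along a ridge). Each frame contributes essentially
  one independent fluctuation to those rows, so they are only usable with
  across-frame replicate variances, which weight them honestly.
* In fits, `gamma_1 = 1` and `gamma_2 = 2^(-3/2)` are held fixed: they are
  degenerate with the amplitude parameters, while `gamma_3`, `gamma_4`
  are free in single-species calibration fits.

## Known limitations

* The product approximation for higher-order binning functions is accurate
  to third order; fourth-order cumulants at bins much longer than the
  diffusion time inherit its error. Their large statistical variance keeps
  the impact on fits small.
* The structure factor `s` is weakly identified from desk-scale data (a
  known property of the method; even long reference runs misestimate it by
  several percent); `tau_d`, `N` and brightness are robust.
* Delta-method variances assume independent bin pairs; use replicate
  (segment/frame) variances for fitting, as the defaults do.
* The dual-colour machinery is fully implemented in the theory layer, but
  the bundled simulation presets exercise mostly the single-channel case.
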