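# cpch — correlated photon-counting histograms

`cpch` resolves mixtures of fluorescent species **jointly by molecular
brightness and diffusion** from fluorescence-fluctuation data. It is aimed
at people doing fluorescence correlation spectroscopy (FCS),
photon-counting-histogram (PCH/FCA) brightness analysis, or raster image
correlation spectroscopy (RICS), who need both kinds of information from
one measurement — for example to count oligomeric states of a receptor
while also telling bound from free ligand.

## The method

The correlated photon-counting histogram is the joint distribution
`p_N(n_x, n_y | τ)` of photon counts in two bins of width `T` a lag `τ`
apart. For 3D Gaussian observation volumes its factorial cumulants have a
closed form, linear in the species of a mixture:

    (K)_{1,0} = λ_A + Σ_i N_i ε_{A,i}
    (K)_{m,n}(τ, T) = γ_{m,n} Σ_i N_i ε_{A,i}^m ε_{B,i}^n κ_{m,n}(τ, D_i) B_{m,n}(T, τ_{d,i})

with `N` the mean occupancy, `ε` the molecular brightness (counts/bin),
`γ_{m,n}` the shape factors of the observation volume
(`(m+n)^(-3/2)` for identical channels), `κ_{m,n}(τ, D)` the diffusion
decay, and `B_{m,n}` bin-time corrections for motion during long bins.
Classical analyses are exact special cases: FCS is
`G(τ) = 1 + (K)_{1,1}/((K)_{1,0}(K)_{0,1})`, the PCH is the marginal over
either axis, FCA uses the `(n, 0)` orders, and dual-colour PCH is the
`τ = 0` slice. A flow factor extends everything to raster-scanned images,
where pixel offsets encode lags (spatial cPCH), giving direct access to
the diffusion coefficient.

The package provides:

* closed-form theory: shape/diffusion/flow factors, binning functions,
  factorial cumulants of models (`factorial_cumulant()`);
* the full distribution by three cross-validated routes — series, FFT of
  generating functions, recursion (`p1_series()`, `pN_fft()`,
  `pN_recursion()`) — plus PCH marginals and dual-colour slices;
* moment algebra (`convert_moments()`) and moments-of-moments sampling
  variances with exact polynomial derivatives (`mom_variance()`);
* empirical machinery: arrival-time binning with sparse histograms,
  factorial-cumulant tables over multi-tau lag grids with honestly
  calibrated (replicate) variances, and the two fit energies
  (`empirical_cumulants()`, `energy_EK()`, `energy_Ep()`);
* spatial cPCH for image stacks (`offset_to_tau()`,
  `spatial_cumulant_table()`);
* an analytic two-species inversion and error-aware parameter sampling
  (`invert_two_species()`, `sample_parameter_sets()`);
* a nested-sampling fit-energy minimiser and ready-made fitters
  (`nested_sampling_fit()`, `fit_single_species()`, `fit_two_species()`,
  `fit_spatial()`);
* Brownian-dynamics photon-emission simulators for point and raster
  acquisition with known ground truth (`simulate_trace()`,
  `simulate_image_stack()`, `cpch_preset()`).

A thin command-line interface over the same functions ships at
`inst/cli/cpch` (subcommands `simulate`, `cumulants`, `hist`, `fcs`,
`pch`, `invert`, `fit`, `spatial`).

## Worked example

Simulate 20 s of a single species diffusing through a confocal volume
(occupancy 1, brightness 0.24448 counts per 10 µs bin, diffusion time
175.7 µs, structure factor 1.928), build its factorial-cumulant table,
and fit it:

```r
library(cpch)
opt   <- optical_config(r_A = 0.2651, z_A = 1.928 * 0.2651)   # um
model <- cpch_model(opt,
                    species_params(N = 1, eps_A = 24448, tau_d = 175.7e-6),
                    T_ref = 1e-5)
tr  <- simulate_trace(model, duration = 20, dt = 1e-5, seed = 1)
tr
#> cpch_trace: 20 s at dt=1e-05 s (2000000 bins), 1810 molecules, mean A=0.2443 counts/bin

tab <- empirical_cumulants(tr$A, T = 1e-5, tau_k = multitau_lags(256),
                           marginals_once = TRUE, segments = 10)
fit <- fit_single_species(tab, seed = 2, max_iter = 2000, binning = FALSE)
fit
#> cpch_fit: 2000 replacements, best energy 1.105
#>                N     eps      tau_d      s  gamma3   gamma4
#> estimate 0.99952 0.24331 0.00018735 1.9842 0.17718 0.140510
#> best     0.99644 0.24342 0.00023160 1.0519 0.17597 0.072713
```

The estimate row is the mean over all recorded parameter sets compatible
with the data (fit energy below 2): occupancy and brightness are recovered
to a fraction of a percent, the diffusion time to a few percent
(`1.87e-4` s vs the true `1.757e-4` s), and the higher-order shape factors
`γ₃`, `γ₄` sit near their Gaussian values 0.192 and 0.125 with the large
uncertainty expected at this trace length. A best-fit energy near 1 says
the model describes the data within its sampling errors. The same table
yields the FCS curve:

```r
head(fcs_from_cpch(tab), 3)
#>     tau    G    var_G
#> 1 1e-05 1.33 2.53e-05
#> 2 2e-05 1.31 3.85e-05
#> 3 3e-05 1.29 2.48e-05
```

(`G(τ→0) − 1 ≈ γ₂/N = 0.354` for one molecule in the volume.)

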