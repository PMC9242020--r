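# methbend

Tools for analysing how cytosine methylation (5-mC) changes the
bendability of double-stranded DNA, using D-shaped DNA nanostructures
read out by single-molecule FRET.

A D-shaped DNA construct is a 30 bp duplex whose ends are tied together
by a shorter single-stranded "string": the string's entropic elasticity
applies a controlled bending force to the duplex, and the dye-to-dye
distance between labels on the 4th and 27th base pairs reports the
degree of bending as a FRET efficiency *E*. Under weak bending,
methylation stiffens the duplex; under strong bending, a few central
base pairs can transiently denature into a flexible hinge (a *kink*)
that appears as a high-*E* subpopulation, and methylation shifts the
kink/non-kink balance. `methbend` is aimed at single-molecule
biophysicists who want to simulate, fit and interpret such experiments,
or to reuse any of the four self-contained pieces:

* **Loop simulator** — a discrete worm-like chain on a closed 38-node
  polygon (30 rigid dsDNA nodes at 0.34 nm, 8 flexible ssDNA nodes at
  0.7 nm), joint energy `E_i = (kappa_i/2) * theta_i^2` kT with
  `kappa = L_P / a`, sampled by crankshaft Metropolis Monte Carlo
  (compiled kernel), with optional denatured "kink" joints and sweeps
  over persistence length and local stiffness.
* **ALEX burst pipeline** — corrected FRET efficiency
  `E = F / (gamma*I_DD + F)` with `F = I_DA - l*I_DD - d*I_AA`, and
  stoichiometry `S = (gamma*I_DD + F) / (gamma*I_DD + F + I_AA)`;
  photon-rate and stoichiometry burst gates; 1D histograms; one/two
  Gaussian mixture fits; kink-fraction and centre-precision estimates.
* **Stiffness inference** — Förster conversion
  `R = R0 * (1/E - 1)^(1/6)`, worm-like-chain string force (Marko–Siggia
  interpolation, freely-jointed-chain alternative), origin-constrained
  regression of distance reduction ΔR on bending-force increment
  ΔF_bend, and relative stiffness `100 * (s_unmeth/s_meth - 1)` % from
  the inverse compliance slopes.
* **Melting analysis** — min-max normalised high-resolution melting
  curves, Tm at the maximum of −dF/dT.

Seeded synthetic-data generators emulate each measurement (burst
mixtures with forward-applied correction factors, D-shaped-DNA scenario
presets, logistic melting curves, construct tables generated from an
assumed stiffness ratio), so the entire pipeline is testable without
instrument data.

## Worked example

The headline stiffness arithmetic from measured compliance slopes
(nm/pN) of the ΔR-vs-ΔF_bend lines for 0, 1 and 2 methylation sites:

```r
library(methbend)

relative_stiffness(0.86, 0.80)   # one methylation site
#> [1] 7.5
relative_stiffness(0.86, 0.73)   # two methylation sites
#> [1] 17.80822
```

i.e. one methylation site on 30 bp stiffens the duplex by ~8%, two
sites by ~18–19%. A full synthetic round trip of the FRET pipeline:

```r
corr <- correction_factors(gamma = 1, leakage = 0.1, direct_excitation = 0.05)
bursts <- generate_kink_mixture(0.5, n_bursts = 5000, seed = 201,
                                corrections = corr)
kept <- select_bursts(compute_es(bursts, corr))
fit <- fit_gaussian_mixture(histogram_1d(kept$E), n_components = 2)
tidy(fit)
#> # A tibble: 2 × 6
#>   component center  width weight amplitude center_stderr
#>       <int>  <dbl>  <dbl>  <dbl>     <dbl>         <dbl>
#> 1         1  0.450 0.0539  0.489      443.      0.00115
#> 2         2  0.952 0.0240  0.511     1040.      0.000328
kink_fraction(fit)
#> [1] 0.511391
```

A half-kinked mixture is recovered as a ~0.51 kink fraction with the
two components at *E* ≈ 0.45 (weakly bent / end-melting form) and
*E* ≈ 0.95 (kink). And the stiffness chain run backwards and forwards:

```r
tbl <- generate_stiffness_table(true_percent_per_site = 8, seed = 101)
stiffness_analysis(tbl)
#> # A tibble: 3 × 4
#>   methylation_sites n_constructs slope_nm_per_pN percent_increase
#>               <int>        <int>           <dbl>            <dbl>
#> 1                 0            4           0.860             0
#> 2                 1            4           0.796             8.00
#> 3                 2            4           0.741            16.0
```

`autoplot()` methods exist for geometries, trajectories, sweeps,
histograms, mixture fits, melting curves and stiffness results;
`tidy()`/`glance()` follow the usual conventions.

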