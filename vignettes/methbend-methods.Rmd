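---
title: "Methods: modelling methylation-dependent DNA bending"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling methylation-dependent DNA bending}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methbend)
```

# The system

A D-shaped DNA nanostructure is a short double-stranded segment (here 30
bp) whose ends are connected by a shorter single-stranded "string".
Because the string's entropic elasticity resists stretching, it applies a
compressive, bending force to the duplex: the shorter the string, the
stronger the bend.  With a FRET donor and acceptor placed near the two
ends of the duplex (on the 4th and 27th base pairs), the degree of
bending is read out as a FRET efficiency, one molecule at a time, by
alternating-laser-excitation (ALEX) confocal burst spectroscopy.  Under
weak bending the duplex bends smoothly; under strong bending a few
central base pairs can transiently denature and act as a flexible hinge —
a *kink* — which collapses the dye separation and produces a distinct
high-FRET subpopulation.  Cytosine methylation (5-mC) perturbs both
regimes: it stiffens weakly bent DNA, and it shifts the balance between
the kinked and non-kinked forms depending on where the methyl groups sit.

`methbend` implements the four computational pieces needed to analyse
such experiments, each testable end to end on synthetic data: a
discrete worm-like-chain Monte Carlo simulator of the loop, an ALEX burst
pipeline with Gaussian-mixture histogram fitting, a stiffness inference
from FRET-derived distances against string force, and high-resolution
melting (HRM) analysis.

# The coarse-grained loop model

The loop is a closed polygon of 38 nodes: 30 *rigid* nodes for the base
pairs of the duplex (spacing $a_{ds} = 0.34$ nm) and 8 *flexible* nodes
for the nucleotides of the string (spacing $a_{ss} = 0.7$ nm).  Bending
is penalised at every joint by the discrete worm-like chain energy

$$E_i = \frac{\kappa_i}{2}\,\theta_i^2 \quad [kT],$$

where $\theta_i$ is the angle between the bond vectors entering and
leaving node $i$ and $\kappa_i$ is a dimensionless modulus.  Moduli
derive from persistence lengths: $\kappa = L_{P,ds}/a_{ds}$ (default
$50/0.34 \approx 147$) on joints flanked by two duplex bonds and
$\kappa = L_{P,ss}/a_{ss}$ (default $3/0.7 \approx 4.3$) elsewhere.  Two
choices are not dictated by the physics above and are therefore explicit
package decisions:

* **Junction joints and bonds.**  The two joints where the duplex meets
  the string sit on single-stranded backbone, so the junction bonds get
  the single-stranded spacing and the junction joints the single-stranded
  modulus.
* **The kink.**  A kink is represented by denaturing rigid-segment
  joints: they keep the duplex rise but bend with single-stranded
  flexibility, $\kappa = L_{P,ss}/a_{ds}$.  By default the two central
  joints (15 and 16 of 30) are denatured; both the joint set and the
  modulus are configurable (`kink_spec()`), since the number of melted
  base pairs in a real kink is not sharply defined.

The initial configuration places all nodes on a common circle whose
radius is solved so the chord-subtended angles of the declared bond
lengths sum to $2\pi$; construction is exact to $10^{-9}$ nm and is
re-checked by the class invariants.  The dsDNA bending energy reported by
`bending_energy()` and recorded by the sampler sums the joints strictly
inside the rigid segment, i.e. those flanked by duplex bonds on both
sides (including any denatured joints).

# The Monte Carlo sampler

Sampling uses single-node *crankshaft* moves: a uniformly random node is
rotated about the axis through its two neighbours by an angle uniform in
$\pm$`max_pivot_angle`.  The move preserves every bond length by
construction, so the chain never drifts off the constraint manifold; the
proposal is symmetric in the rotation angle, and acceptance follows
Metropolis, $\min(1, e^{-\Delta E})$ with energies in kT.  Only the three
joints touched by a move are recomputed; the incremental $\Delta E$ is
pinned against full recomputation in the tests, and running totals are
periodically refreshed to suppress floating-point drift.  The default
proposal half-width of 2.0 rad gives roughly 50% acceptance for the
reference loop and was fixed from that acceptance-rate window alone.

Correctness of the sampler is established two independent ways in the
test suite: on a square ring with moves restricted so the reachable shape
space is exactly parameterisable, the sampled joint-angle distribution is
compared with dense numerical integration of the Boltzmann weight
(Kolmogorov–Smirnov test at the 1% level); and on a 5-node ring the mean
energy is compared with an independently coded naive-move sampler
(Gaussian Cartesian perturbation re-projected onto the bond-length
constraint) within combined standard errors.

**Step counts and equilibration.**  The production preset
(`full_scale = TRUE`) uses $2\times10^7$ equilibration plus
$2\times10^7$ sampling steps.  The package default is a desk-scale
$2\times10^5 + 2\times10^5$, which the test suite and acceptance script
also use; sweeps use 5 replicate runs with seeds counted up from a base
seed.  A caveat documented here deliberately: relaxation of the *kinked*
loop from the circular start is slow — on the order of $10^6$ steps —
because curvature must migrate into the two soft joints through purely
local moves.  Desk-scale kinked runs therefore sample a late transient
rather than the strict equilibrium: their mean energies are
systematically above the long-run values and vary more between replicate
seeds.  Qualitative orderings (energies rising with persistence length,
kinked below non-kinked) already hold at desk scale, but
significance-style checks on individual steps of a sweep can fail there
by seed luck, and tight comparisons should use the full-scale preset.
The same slow relaxation is why the package does not assert the
local-stiffness sweep's curvature-migration trend at test scale: the
effect is directionally visible only at $10^7$-step scale and remains
within one standard error there.

`sweep_persistence_length()` runs kinked and non-kinked forms across a
persistence-length grid; `mean_dye_distance_vs_stiffness()` tracks the
4th-to-27th-node dye distance of the kinked form, which is expected to be
insensitive to duplex stiffness; `sweep_local_stiffness()` scales the
moduli of the non-denatured duplex joints and monitors the mean bending
angle of kink and non-kink regions.

# ALEX burst analysis

Each burst carries three photon counts: `I_DD` (donor emission, donor
excitation), `I_DA` (acceptor emission, donor excitation) and `I_AA`
(acceptor emission, acceptor excitation).  With detection-efficiency
ratio $\gamma$, leakage $l$ and direct excitation $d$, the corrected
acceptor signal is $F = I_{DA} - l\,I_{DD} - d\,I_{AA}$ and

$$E = \frac{F}{\gamma I_{DD} + F}, \qquad
  S = \frac{\gamma I_{DD} + F}{\gamma I_{DD} + F + I_{AA}}.$$

These are the standard ALEX correction forms; the three factors are
exactly the ones named by the experimental protocol.  Burst selection
keeps rates strictly above 30 photons/ms and stoichiometries strictly
inside $(0.2, 0.8)$, excluding donor-only ($S \to 1$) and acceptor-only
($S \to 0$) species.

FRET histograms default to 50 bins over $E \in [-0.1, 1.1]$ (bins
half-open on the right, last bin closed); the instrument software does not
expose its binning, and results in this package are insensitive to the choice
within a factor of two.  One- or two-component Gaussian fits minimise
unweighted least squares on bin counts (Levenberg–Marquardt), the common
practice for burst histograms; component weights are areas normalised to
unit total, and widths are bounded below at one bin width (a fit pressed
against the floor is flagged).  Two-component fits are initialised at the
two tallest well-separated histogram peaks: percentile-based starts were
found to put both centres inside the same peak for strongly skewed
mixtures (kink fraction around 0.8) and send the optimiser to a poor
optimum, while peak-based starts recover mixture weights to $\pm 0.02$
across the tested range.  The *kink fraction* is the total weight of
components whose centre exceeds 0.7 — a cutoff placed midway between the
weakly bent ($\approx 0.45$) and kinked ($\approx 0.95$) populations.
The statistical precision of a fitted centre is $\sigma/\sqrt{N}$; at
the reference construct's width and burst count this is $\approx 0.002$,
which is why construct-to-construct shifts of $\approx 0.03$ are easily
resolved.

One bias is worth knowing about: the per-burst corrected $E$ is a ratio
of noisy counts, so its mean carries an $O(1/N_{\text{photons}})$ bias
(about $-0.001$ at 100 photons/burst with $l = 0.1$, $d = 0.05$, worst
near $E = 0.95$).  This is negligible against the $\pm 0.01$
histogram-centre tolerances used throughout, but it dominates the
standard error of the mean once more than a few hundred bursts are
averaged, which is why the unbiasedness test runs in the
shot-noise-dominated regime.

# Stiffness inference

For weakly bent constructs the chain is: FRET efficiency to donor-
acceptor distance by the Förster relation $R = R_0 (1/E - 1)^{1/6}$
(default $R_0 = 6.5$ nm for the ATTO 550/ATTO 647N pair; configurable);
distance to string force by a worm-like-chain interpolation

$$F = \frac{kT}{L_{P,ss}}\left[\frac{1}{4(1 - x/L_c)^2} - \frac14 +
\frac{x}{L_c}\right], \qquad L_c = n_{nt}\, a_{ss},$$

with a freely-jointed-chain alternative (Kuhn length $2 L_{P,ss}$)
available as a pluggable strategy.  The force is evaluated at the
construct's own FRET-derived extension — a force-balance proxy: the
string spans the same gap as the duplex ends.  Because the dyes sit on
base pairs 4 and 27 (23 of the 29 base steps), the dye distance is
rescaled by $29/23$ to the full end-to-end distance before entering the
force; the true mapping depends on the bent shape, but for the shallow
arcs in the weak-bending regime the chord ratio is an adequate linear
proxy, and the final statistic (a ratio of slopes) is insensitive to any
common rescaling.

Relative to the 70-nt-string reference construct (where bending begins),
each construct contributes a point $(\Delta F_{bend}, \Delta R)$; a
least-squares line through the origin, $s = \sum xy / \sum x^2$, gives a
bending compliance per methylation group, and the stiffness increase of
a methylated group is $100\,(s_0/s_m - 1)$ percent, since compliance is
inverse stiffness.  Applied to the reference compliance slopes of this construct family
(0.86, 0.80, 0.73 nm/pN for 0, 1 and 2 methylation sites), this arithmetic gives 7.5% for one site and 17.8% for
two — the values behind the reported "approximately 8%" and "19%".
`extrapolate_by_density()` scales a per-site percentage measured on
30 bp linearly with CpG density (sites per 500 bp $\times$ 30/500); this
is the package's own declared model, the simplest one consistent with
per-site additivity, and it brackets genomic CpG densities of 7–39 per
500 bp to roughly 3–19% per-site-at-8%.

**Noise propagation.**  The reference construct's measured $E$ enters
every point of its group, so construct-level noise at the experimental
scale ($\sigma_E = 0.004$) produces recovered-percentage spreads of
several points for a single synthetic table; only the Monte-Carlo
average over many tables is tightly constrained (the acceptance checks
average 100 seeded tables).  Real analyses should likewise average
repeated measurements.

# Melting-curve analysis

HRM curves (fluorescence of a saturating dsDNA dye vs temperature,
60–95&deg;C in 0.1&deg;C steps) are min-max normalised — making the
result invariant under affine transforms of the raw signal — and
differentiated by central differences; the melting temperature is the
maximum of $-dF/dT$ (the dye signal falls on melting), with ties broken
to the lowest temperature and edge maxima flagged unreliable.  An
11-point centred moving average is applied to both the normalised curve
and its derivative.  The window was chosen on synthetic logistic
transitions (width 1.5&deg;C): both passes are symmetric, so noiseless
symmetric transitions keep their inflection exactly, while at noise
levels of 0.005 on the normalised signal the recovered $T_m$ stays
within $\pm 0.3$&deg;C in $\ge 95\%$ of seeded replicates — a 5-point
window leaves the derivative noise comparable to the peak's curvature on
a 0.1&deg;C grid and misses that target badly.  Grid resolution bounds
noiseless precision at half a step.

# Synthetic data: what it does and does not emulate

The generators provide the statistical structure the analyses assume,
with nothing downloaded and every draw seeded:

* **Bursts** (`generate_bursts()`, `generate_kink_mixture()`,
  `alex_presets()`): per burst, a species is drawn by abundance, the
  donor-excitation photon total is Poisson, its donor/acceptor split is
  binomial with probability $E_{true}$, and `I_AA` is Poisson.  Observed
  counts are then corrupted consistently with the correction factors
  (donor thinning by $1/\gamma$, binomial leakage and direct-excitation
  counts added to `I_DA`), so correcting with the same factors recovers
  the truth up to shot noise.  The built-in presets carry the published
  construct efficiencies (0.18 linear, 0.43 weakly bent, 0.95 kink, 0.53
  nicked, 0.47 methylated-beside-nick) and burst counts
  (4120/3236/3350), plus a donor-only fraction so stoichiometry gating
  is exercised.  Not emulated: diffusion-through-focus photophysics,
  blinking/bleaching, real burst-size distributions (fixed-mean Poisson
  is a declared stand-in), background counts (available but default 0).
* **Melting curves**: logistic decay plus i.i.d. Gaussian noise on the
  instrument grid.  Real curves have sloped baselines and multi-domain
  transitions; passing tests therefore demonstrate derivative-peak
  extraction, not baseline handling.
* **Construct tables** (`generate_stiffness_table()`): the exact inverse
  of the stiffness chain — an assumed per-site percentage sets each
  group's compliance, each construct's distance is solved from the
  self-consistent balance $R_{ref} - R = s\,(F(R) - F_{ref})$, and the
  Förster relation is inverted to a mean $E$.  Noiseless tables are
  recovered exactly by construction *of the physics*, not of the code
  path: generation inverts the relations point by point, while recovery
  refits a pooled slope, so agreement still verifies the chain's
  consistency.

Because the generators share the analysis pipeline's *assumptions*, a
passing suite demonstrates internal consistency and correct
implementation of the stated models — not that those models describe any
particular instrument's systematics.

# Problem sizes and determinism

Simulation tests and the acceptance script use the desk-scale sampler
defaults ($2\times10^5 + 2\times10^5$ steps, record every 100, 5
replicates, persistence-length grid 30/50/70 nm), 4000–5000 synthetic
bursts per histogram, 100-seed Monte-Carlo loops for noisy-recovery
checks, and the full 60–95&deg;C melting grid.  Every stochastic routine
takes an explicit integer seed; replicate seeds count up from a base
seed, so all results in the tests, README and acceptance output are
bit-reproducible.
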