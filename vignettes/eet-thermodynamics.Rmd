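---
title: "Stochastic thermodynamics of excitation energy transfer networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic thermodynamics of excitation energy transfer networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eetherm)
```

## The model

Excitation energy transfer (EET) in a pigment–protein supercomplex such as
Photosystem II (PSII) is modelled here as a continuous-time Markov chain on
exciton states. The input is a rate matrix $K$ whose element $k_{ij}$ is the
transfer rate from state $j$ to state $i$ in ps$^{-1}$; the diagonal holds
$-\sum_{i \ne j} k_{ij}$, so $K$ is the generator of the master equation

$$\frac{dP}{dt} = K P, \qquad P(t) = e^{Kt} P(0),$$

with $p_i(t)$ the probability that exciton state $i$ is excited. The closed
network satisfies detailed balance with respect to the Boltzmann
distribution at the bath temperature,
$k_{ij}/k_{ji} = e^{-(E_i - E_j)/k_B T}$, which is what licenses a
thermodynamic reading of the relaxation. Energies are wavenumbers
(cm$^{-1}$) and we use $k_B = 0.695035$ cm$^{-1}$ K$^{-1}$ throughout, so
$k_B T \approx 208.5$ cm$^{-1}$ at the default 300 K.

Open reaction centers (RCs) are modelled by attaching an irreversible,
phenomenological trap to the lowest-energy RC state of each monomer (the
charge-transfer state between Chl$_{D1}$ and Pheo$_{D1}$). Breaking detailed
balance this way is deliberate and is the only sanctioned one-sided
transition; the remaining closed part of the network must still pass the
pairwise detailed-balance check. Fluorescence (per-state rate proportional
to the squared transition dipole, with the state average fixed at the
reciprocal of a 16 ns lifetime) and uniform nonradiative decay (reciprocal
of 2 ns) are optional loss channels. All four drains — two traps,
fluorescence, nonradiative — are tracked as explicit absorbing sinks, so
total probability is conserved to round-off at every output time.

## Free-energy decomposition

Along the relaxation we decompose the free-energy change as
$\Delta G(t) = \Delta H(t) - T\,\Delta S(t)$ with the Shannon entropy
$S(t) = -k_B \sum_j p_j \ln p_j$ and the ensemble enthalpy
$H(t) = \sum_j p_j E_j$, both relative to the initial condition. For a
closed detailed-balanced network $G(t)$ equals
$k_B T\, D(p(t)\,\|\,\pi)$ up to a constant, where $D$ is the relative
entropy to the Boltzmann distribution $\pi$, so $\Delta G$ is
non-increasing (an H-theorem) and its long-time limit is
$-k_B T\, D(p(0)\,\|\,\pi)$. The test suite checks both properties.

Two derived times summarise each initial condition:

* the **population contraction time**, the time of the entropy maximum —
  before it the ensemble spreads over the near-degenerate antenna states,
  after it the distribution contracts toward the traps;
* the **enthalpy peak time**, the time of the $\Delta H$ maximum — the
  switch from net-uphill to net-downhill energy transfer. A purely downhill
  relaxation peaks at $t = 0$ with $\Delta H = 0$.

### Raw versus conditional entropy under traps

With irreversible traps the surviving excitonic population decays, and the
entropy of the *unnormalised* surviving populations ("raw" mode, the
default) rises and then falls back toward zero, which guarantees a
well-defined interior maximum. The alternative "conditional" mode
renormalises by the surviving mass first, i.e. reports statistics
conditioned on not yet being absorbed. Both are available because the
choice is genuinely open; raw mode is the default because the
rise-then-fall phenomenology — and hence the contraction time — is
guaranteed by construction. Sinks are excluded from $S$ and $H$ in both
modes.

### Numerical choices

* **Propagation** uses Padé scaling-and-squaring (`Matrix::expm`) once per
  grid interval, re-used across initial conditions by propagating a matrix
  of start vectors. This meets a $10^{-9}$ relative-accuracy contract on
  the analytic two-state relaxation and avoids eigendecomposition of the
  non-symmetric (possibly defective) open-system generator.
* After each interval the state-plus-sink vector is rescaled by its sum.
  The exact propagator conserves this sum identically, so the rescaling
  removes pure round-off drift; without it, drift of order $10^{-12}$
  multiplied by absolute energies of order $15000$ cm$^{-1}$ is visible in
  late-time $\Delta G$ increments.
* The default grid is $t = 0$ plus 600 log-spaced points over
  $[10^{-2}, 10^{5}]$ ps, spanning sub-ps intra-subunit equilibration
  through nanosecond loss channels.
* **Peak refinement**: the entropy/enthalpy argmax found on the grid is
  refined by golden-section search on the continuously propagated series in
  the bracketing interval, to ±0.1 ps (an order finer than the whole-ps
  precision at which contraction times are usually quoted); ties resolve to
  the earliest time. A maximum at the last grid point raises an error
  rather than guessing.
* Populations below zero by round-off (magnitude $\le 10^{-12}$) are
  clipped to zero before entropies are taken.
* **Absorption statistics** (splitting probabilities, mean first passage
  time, mean residence lifetime) use linear solves on the transient block,
  $p_s = r_s (-Q)^{-1} P(0)$ and $\tau = \mathbf{1}^T (-Q)^{-1} P(0)$,
  never long-time integration. The trapping time (MFPT) is defined with
  loss channels disabled; the function refuses a lossy generator rather
  than silently computing a different quantity.
* "Fluorescence lifetime" has no unique operational definition, so
  `excitation_lifetime()` reports both the mean residence time (default)
  and a single-exponential fit to the last decade of the survival tail.

## The synthetic-data generator

`generate_mimic()` builds networks with the statistical structure the
analysis assumes, so the whole pipeline is testable without any external
deposit:

* a dimeric layout of protein subunits (default: RC, CP43, CP26, three
  S-LHCII and three M-LHCII subunits, CP47, CP29, CP24 per monomer — 140
  states in total) with all-to-all couplings inside a subunit at scale
  2 ps$^{-1}$ and nearest-subunit couplings at scale 0.1 ps$^{-1}$ along a
  D1-side chain (RC–CP43–CP26–S-LHCII) and a D2-side chain
  (RC–CP47–CP29–CP24–M-LHCII), with the core interface and the M-trimers
  bridging the monomers;
* near-degenerate subunit mean energies around 15000 cm$^{-1}$ (the
  shallow-funnel/flat landscape characteristic of PSII, with the RC only
  slightly lowest), Chl *b* states in the LHCII trimers offset +600
  cm$^{-1}$, and Gaussian site disorder of SD 80 cm$^{-1}$ — a typical
  inhomogeneous-broadening width for chlorophyll in protein, exposed as a
  free parameter;
* rates $k_{ij} = c_{ij} e^{-(E_i - E_j)/2k_BT}$ with symmetric $c_{ij}$
  drawn log-uniform (factor 3) around the scale. The symmetric split makes
  detailed balance exact by construction, without claiming any microscopic
  rate theory. Metropolis-style rates would also balance but are not
  smooth in the energy gap;
* an exactly mirror-symmetric dimer by default: monomer 2 duplicates
  monomer 1's energies and couplings with reflected coordinates, so the
  monomer-swap permutation maps $K$ onto itself bit-for-bit — the basis of
  the symmetry tests;
* `generate_disorder_ensemble()` re-draws site energies over a shared
  topology (the reference analysis uses 500 realizations;
  `average_rate_matrices()` implements the averaged-matrix convention);
* `generate_control_landscape()` provides funnel (strictly downhill toward
  the trap) and flat (iso-energetic) chain controls for contrast tests.

What the mimic does **not** emulate: the real exciton delocalisation
pattern, per-pigment energy ladders fitted to spectra, distance-dependent
coupling decay, or the absolute magnitude of inter-complex rates. Passing
tests on mimics therefore validate the *machinery* (propagation,
thermodynamics, absorption statistics, symmetry handling) and the
*direction* of landscape effects — peripheral starts contract later than
core starts, closing one RC slows its own D1 side disproportionately,
funnels contract faster than flat landscapes — but not the numerical
timescales of any real supercomplex, which require its measured rate
matrix (see `read_network()`).

## Default problem sizes

Tests run on a reduced 64-state mimic (7 subunits per monomer) where only
machinery is exercised, and on the full 140-state default where dimeric
structure matters; propagation grids of 120–600 points and $10^4$
Gillespie trajectories give sub-minute runtimes per property while leaving
Monte Carlo standard errors well below the tolerances tested. The
brute-force oracles (survival quadrature, $10^5$-point dense-grid entropy
argmax) are implemented independently in the test helpers.

## Known limitations

* The trap rate is phenomenological (default 1 ps$^{-1}$ from each
  monomer's CT state, configurable); observables that depend on its exact
  value should be read comparatively, not absolutely.
* The mimic's inter-monomer connectivity is stylised; same-monomer
  trapping fractions on mimics are closer to 0.5 than measured PSII
  values.
* `free_energy_series()` treats the exciton basis as given; site-basis
  output requires a localization map (`project_to_sites()`), which for
  real complexes is an input artifact.
* No coherent (density-matrix) dynamics: the model is a classical master
  equation on exciton states.

## A worked example

```{r example, eval = FALSE}
net <- generate_mimic(mimic_spec(seed = 1))
sc  <- scenario(net)                       # both RCs open, no losses
gen <- build_generator(sc, require_absorbing = TRUE)

ic   <- initial_condition_for_pigment(net, "m1_CP43_3")
traj <- propagate(gen, ic)
th   <- free_energy_series(traj, net)
thermo_summary(th, gen, ic)

res <- sweep_initial_conditions(sc)
aggregate_by_subunit(res)
```
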