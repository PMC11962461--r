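# eetherm

Stochastic thermodynamics of excitation energy transfer (EET) networks in
light-harvesting pigment–protein supercomplexes, built for the Photosystem
II (PSII) dimer but applicable to any detailed-balanced excitonic rate
matrix.

PSII is not an energy funnel: the lowest levels of its antenna subunits are
nearly degenerate, so the driving force for transport to the reaction
center (RC) has a large entropic component. `eetherm` makes that component
measurable. Given a kinetic rate matrix `K` (`k_ij` = transfer rate from
exciton state *j* to state *i*, ps⁻¹) it propagates the master equation

    dP/dt = K P,    P(t) = exp(Kt) P(0)

and decomposes the ensemble relaxation into

    ΔG(t) = ΔH(t) − T·ΔS(t)

with the Shannon entropy `S(t) = −k_B Σ p_j ln p_j` and ensemble enthalpy
`H(t) = Σ p_j E_j`, both relative to the initial excitation. From these it
extracts, per initial condition:

* the **population contraction time** — the entropy maximum, where
  entropic spreading over the antenna turns into directed contraction
  toward the RC traps;
* the **enthalpy peak** — when transfer switches from net-uphill to
  net-downhill;
* **splitting probabilities** among the four absorbing channels (trap in
  either monomer, fluorescence, nonradiative loss) by committor-style
  linear solves;
* the **trapping time** (mean first passage time to an open RC) and the
  **excitation lifetime** under loss channels;
* a **kinetic Monte Carlo (Gillespie) cross-check** of all absorption
  statistics.

Scenarios turn the closed network into the open system of a given
experimental condition: irreversible RC traps fed by each monomer's
charge-transfer state, dipole-weighted fluorescence (state-average rate
1/16 ns⁻¹) and uniform nonradiative decay (1/2 ns⁻¹), closing one RC after
a charge separation, and removing antenna subunits (e.g. the M-LHCII
trimers and CP24, turning a C₂S₂M₂-type complex into C₂S₂).

A synthetic-data module (`generate_mimic()`, `generate_disorder_ensemble()`,
`generate_control_landscape()`) builds PSII-mimetic dimeric networks —
modular subunit clusters, near-degenerate energies, Gaussian site disorder,
exact detailed balance, mirror-symmetric monomers — so the entire pipeline
is testable without any external data. Measured rate matrices are read with
`read_network()` (dense TSV or Matrix Market, plus a per-state metadata
table).

## Worked example

```r
library(eetherm)

net <- generate_mimic(mimic_spec(seed = 1))   # 140-state PSII-mimetic dimer
sc  <- scenario(net)                          # both RCs open, no losses
gen <- build_generator(sc, require_absorbing = TRUE)

ic   <- initial_condition_for_pigment(net, "m1_CP43_3")
traj <- propagate(gen, ic)
th   <- free_energy_series(traj, net)
thermo_summary(th, gen, ic)
#> $contraction_time_ps  1.75
#> $entropy_max_kB       3.93
#> $enthalpy_peak_ps     0.0623
#> $enthalpy_peak_cm1    27.5

splitting_probabilities(gen, ic, monomer = 1)
#> <fate_summary> trap1 0.5489  trap2 0.4511  fluor 0  nonrad 0
#>   same-monomer trapping fraction: 0.549

mean_first_passage_time(gen, ic)
#> [1] 24.47876
```

The CP43 start spreads entropically for ~1.75 ps (entropy peak of 3.9 k_B ≈
e⁴ ≈ 50 effectively occupied states), climbs only 27 cm⁻¹ uphill (well under
k_BT ≈ 208 cm⁻¹ at 300 K), and is trapped in 24 ps on average, slightly
preferring its own monomer's RC. Sweeping every initial state and
aggregating by subunit shows the core/peripheral contrast:

```r
res <- sweep_initial_conditions(sc,
  state_subset = which(net$states$subunit %in% c("CP43", "M-LHCII-B")))
aggregate_by_subunit(res)
#>     subunit  n mean_contraction_ps sd_contraction_ps ... mean_same_monomer
#> 1      CP43 14                1.73            0.0239 ...             0.548
#> 2 M-LHCII-B 12                7.40            0.0355 ...             0.492
```

Peripheral M-LHCII excitations contract ~4× later than core CP43
excitations and are monomer-agnostic, while core excitations prefer their
own RC — the qualitative design signature the decomposition is meant to
expose. (Mimic timescales are not those of the real supercomplex; for those,
load a measured rate matrix with `read_network()`.)

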