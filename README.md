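# dissipath

Where does the energy go when an exciton hops through a pigment-protein
complex?  `dissipath` answers that question for Frenkel exciton models in
structured harmonic environments: alongside golden-rule population
dynamics it computes the **dissipation pathways** — the energy deposited
into (or borrowed from) the vibrational environment, resolved by mode
frequency ω, by chromophore, and by time.  It is aimed at researchers in
open quantum dynamics and photosynthetic light harvesting who want to
attribute energy flow to specific vibrations (protein phonons,
bacteriochlorophyll breathing modes, far-detuned intramolecular
stretches) without propagating the environment explicitly.

## The model in brief

Sites A with energies `E_A` and couplings `V_AB` relax by Fermi's
golden rule,

    dP_A/dt = Σ_B [ −K_BA P_A + K_AB P_B ],
    K_BA = (2|V_AB|²/ħ²) Re ∫₀^∞ exp[−it(E_B−E_A+Λ_A+Λ_B)/ħ]
                                exp[−g_A(t)−g_B(t)] dt,

with line-broadening functions `g_A(t)` and reorganization energies
`Λ_A = ∫ J_A(ω)/ω dω` built from each chromophore's spectral density
`J_A(ω)`.  The frequency-resolved energy flow during the A→B process is
governed by a *dissipative potential* `I_BA(ω)` (the same kernel with an
extra `cos(ωt/ħ) − i coth(βω/2) sin(ωt/ħ)` factor), from which
*dissipative spectral densities* `J^A_BA(ω) = (2|V|²/ħ²)(J_A/ω) I_BA(ω)`
and the accumulated field `E_A(ω, t)` follow.  The construction conserves
energy exactly — `∫E_Tot dω = Σ_A [P_A(0)−P_A(t)] E_A` — and obeys
detailed balance.  Negative dissipation is energy *absorbed* from the
bath, which is how uphill steps happen.

Non-Markovian slow bath components (below a cutoff ω\* = 20 cm⁻¹ by
default) are split off with a smooth C¹ filter and treated as
quasi-static Gaussian site-energy disorder of width
`σ² = ∫ J_slow coth(βω/2) dω`, averaged over an ensemble of
realizations that share all fast-bath quantities.

Units: energies/frequencies in cm⁻¹, time in fs
(ħ = 5308.8 cm⁻¹·fs, k_B = 0.695035 cm⁻¹/K).

## Worked example

A donor 200 cm⁻¹ above an acceptor, coupled at 50 cm⁻¹, each carrying a
Drude protein background (λ = 35, γ = 50 cm⁻¹) plus a sharp 180 cm⁻¹
vibration (λ = 15 cm⁻¹):

```r
library(dissipath)

model <- exciton_model(c(200, 0), matrix(c(0, 50, 50, 0), 2),
                       labels = c("donor", "acceptor"))
bath <- synthetic_bath_spec(35, 50,
          peaks = data.frame(center = 180, width = 10, lambda = 15))

cfg <- run_config(temperature_K = 300, n_modes = 1000,
                  t_max_rate_fs = 10000, t_end_dynamics_fs = 4000,
                  snapshot_times_fs = c(40, 4000))
setup <- prepare_baths(model, list(bath, bath), cfg)
rates <- build_rate_set(setup)
rates
#> <rate_set> 2 sites, 1000 frequencies
#> rate constants K[from, to] (fs^-1):
#>             donor acceptor
#> donor    0.000000 0.004777
#> acceptor 0.001831 0.000000

rates$K["donor", "acceptor"] / rates$K["acceptor", "donor"]
#> [1] 2.609567
exp(200 / (physical_constants(300)$kB * 300))   # Boltzmann factor
#> [1] 2.609567

traj <- propagate_populations(rates, c(1, 0), dt = 0.5, t_end = 4000)
field <- accumulate_dissipation(rates, traj, c(40, 4000))
field
#> <dissipation_field> 1000 frequencies, 2 sites, snapshots at 40, 4000 fs
#> net dissipated energy at 4000 fs: 144.6 cm^-1

band_summary(field, c(1, 800, 2000))
#>   band_lo band_hi        donor     acceptor        total
#> 1       1     800 7.229546e+01 7.229546e+01 1.445909e+02
#> 2     800    2000 2.678179e-04 2.678179e-04 5.356359e-04
```

Reading the numbers: the forward/backward rate ratio reproduces the
Boltzmann factor of the 200 cm⁻¹ gap to seven digits (detailed balance);
the 144.6 cm⁻¹ dissipated by 4 ps equals the electronic energy released,
`(P_donor(0) − P_donor(4 ps)) × 200 = (1 − 0.277) × 200 = 144.6` cm⁻¹
(energy conservation); and essentially all of it enters modes below
800 cm⁻¹ — frequencies near the electronic gap — while the band above
800 cm⁻¹ receives half a thousandth of a wavenumber despite carrying
real reorganization energy.

## The FMO-like preset and disorder ensembles

`fmo_like_model()` bundles an embedded 7-site FMO-style Hamiltonian
(`inst/extdata/fmo_hamiltonian.tsv`, a commented, versioned fixture) with
per-chromophore synthetic structured baths (protein background, a
breathing-mode analog near 200 cm⁻¹, a far-detuned peak above
800 cm⁻¹).  A disorder-averaged run:

```r
fm  <- fmo_like_model("bchl1")           # excitation starts on Bchl1
cfg <- run_config(temperature_K = 300, n_realizations = 200, seed = 1,
                  store_stride = 10)
res <- simulate_dissipation(model = fm$model, baths = fm$bath_specs,
                            config = cfg, output_dir = "out")
```

writes a result container under `out/`: `results.rds` (full payload),
`populations.tsv`, one `dissipation_snapshot_<t>fs.tsv` per snapshot,
`band_summary.tsv`, `site_dissipation.tsv`, and `meta.json` echoing every
effective parameter with units.  With this preset Bchl1 shows *negative*
accumulated dissipation at early snapshots — its first transfer step is
uphill, so it borrows thermal energy before the complex settles into net
dissipation dominated by the ~200 cm⁻¹ band at the low-energy sites.

The same pipeline is scriptable from a shell through the installed
`exec/dissipath` entry point:

```sh
dissipath=$(Rscript -e 'cat(system.file("exec","dissipath",package="dissipath"))')
Rscript "$dissipath" validate --config run.yaml
Rscript "$dissipath" simulate --config run.yaml --seed 7 --output out/
Rscript "$dissipath" band-summary --results out/ --bands 0.5,800,2000
```

where `run.yaml` either names a preset (`preset: bchl1` — an explicit
`temperature_K` is then required) or maps a `hamiltonian:` matrix file
and per-site `densities:` two-column text files, plus any `run_config()`
field.  Exit codes: 0 success, 2 validation failure, 3 unconverged rate
integrals.

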