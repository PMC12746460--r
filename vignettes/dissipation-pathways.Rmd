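---
title: "Dissipation pathways in excitonic energy transfer: models and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissipation pathways in excitonic energy transfer: models and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dissipath)
```

## The physical problem

When a pigment-protein complex such as the Fenna-Matthews-Olson (FMO)
antenna funnels an exciton from its absorption site toward the reaction
center, the electronic energy lost along the way is deposited into nuclear
motion: protein phonons and intramolecular vibrations of the
bacteriochlorophylls.  `dissipath` computes, within second-order
perturbation theory in the electronic couplings (Fermi's golden rule, FGR),
*where* that energy goes -- resolved by environmental mode frequency
$\omega$, by chromophore, and by time -- rather than only how the exciton
populations evolve.

The system is a Frenkel exciton model: site energies $E_A$ and couplings
$V_{AB}$ (an `exciton_model`), with each site coupled linearly to its own
harmonic environment described by a spectral density $J_A(\omega)$ (a
`spectral_density`).  All energies and frequencies are in cm$^{-1}$, time in
fs, with $\hbar = 5308.8$ cm$^{-1}$ fs and $k_B = 0.695035$ cm$^{-1}$/K.  A
tabulated "frequency" is the quantum of mode energy, so every oscillatory
factor appears as $\omega t/\hbar$ and every thermal factor as
$\coth(\beta\omega/2)$.  This placement of $\hbar$ is not a matter of
taste: it is pinned by requiring that the high-temperature FGR rate
reproduce the closed-form Marcus expression
$k = \frac{2\pi}{\hbar}|V|^2(4\pi\Lambda k_BT)^{-1/2}
\exp[-(\Delta E+\Lambda)^2/4\Lambda k_BT]$, which the test suite checks to
within 10% on a Drude dimer at 600 K.

## Model ingredients

**Reorganization energy.** $\Lambda_A = \int_0^\infty J_A(\omega)/\omega\,
d\omega$ (no $1/\pi$ prefactor; the synthetic generator uses the same
convention so its densities are self-verifying).

**Line-broadening function.** The second-cumulant
$$g_A(t) = \int_0^\infty J_A(\omega)\Big[\coth(\tfrac{\beta\omega}{2})
\tfrac{1-\cos(\omega t/\hbar)}{\omega^2} +
i\,\tfrac{\sin(\omega t/\hbar)-\omega t/\hbar}{\omega^2}\Big]d\omega$$
encodes dephasing by the bath.  $\mathrm{Re}\,g \ge 0$ grows with
temperature; $\mathrm{Im}\,g$ is temperature independent with long-time
slope $-\Lambda_A/\hbar$ (exposed as a convergence diagnostic by
`asymptotic_slope_check()`).

**Transfer rates.** The population master equation
$\dot P_A = \sum_{B\neq A}[-K_{BA}P_A + K_{AB}P_B]$ uses
$$K_{BA} = \frac{2|V_{AB}|^2}{\hbar^2}\,\mathrm{Re}\!\int_0^\infty
e^{-it(E_B-E_A+\Lambda_A+\Lambda_B)/\hbar}\,e^{-g_A(t)-g_B(t)}\,dt .$$
Forward and backward rates satisfy detailed balance,
$K_{BA}/K_{AB} = e^{-\beta(E_B-E_A)}$, which the suite verifies to 1% on
structured baths.

**Dissipation decomposition.**  The energy flow into a mode of frequency
$\omega$ local to chromophore $A$ during the $A\!\to\!B$ process is
governed by the *dissipative potential*
$$I_{BA}(\omega) = \mathrm{Re}\!\int_0^\infty
e^{-it(E_B-E_A+\Lambda_A+\Lambda_B)/\hbar}e^{-g_A(t)-g_B(t)}
\big[\cos(\tfrac{\omega t}{\hbar}) -
i\coth(\tfrac{\beta\omega}{2})\sin(\tfrac{\omega t}{\hbar})\big]dt,$$
from which the *dissipative spectral densities*
$J^A_{BA}(\omega) = \frac{2|V_{AB}|^2}{\hbar^2}\frac{J_A(\omega)}{\omega}
I_{BA}(\omega)$ (and $J^A_{AB}$ with $I_{AB}$) build the dissipation
function $D_A(\omega,t) = \sum_{B\neq A}[J^A_{BA}P_A + J^A_{AB}P_B]$ and
its running time integral $E_A(\omega,t)$, the accumulated dissipation
field.  Negative values are physical: they are energy *absorbed* from the
environment, which is how an exciton climbs an uphill step.

**Why this bookkeeping conserves energy.**  Integrating $I_{BA}$ against
$J_A(\omega)/\omega$ and integrating by parts in time (using
$\int d\omega\,(J_A/\omega)[\cos - i\coth\sin] = -i\hbar\,\dot g_A(t) +
\Lambda_A$) gives the identity
$$\frac{2|V_{AB}|^2}{\hbar^2}\Big[\int\frac{J_A}{\omega}I_{BA}\,d\omega +
\int\frac{J_B}{\omega}I_{BA}\,d\omega\Big] = K_{BA}\,(E_A - E_B),$$
i.e. the total frequency-integrated deposition rate of the $A\!\to\!B$
process -- into *both* local baths, both weighted by $I_{BA}$ -- equals the
transfer rate times the **bare** site-energy difference; the
reorganization shifts cancel between the phase factor and the boundary
term.  Two consequences fix design questions that the printed equations
alone leave open: the partner bath of a transfer uses the same potential
$I_{BA}$ (its reverse-process partner $I_{AB}$ enters only weighted by
$P_B$), and the global energy balance
$\int E_{\rm Tot}\,d\omega = \sum_A [P_A(0)-P_A(t)]E_A$ holds with bare
energies.  The suite checks the balance to 2% on two- and three-site
models; in practice it holds to $\sim 10^{-4}$.  A corollary worth knowing:
for a symmetric pair ($E_A = E_B$, identical baths) the dissipative
densities vanish *pointwise*, not merely on average -- emission and
absorption balance at every frequency.

## Non-Markovian correction: slow/fast splitting and static disorder

A golden-rule master equation assumes the environment relaxes quickly on
the transfer time scale.  Very slow bath components violate this, so each
density is split at a cutoff $\omega^\ast$ with the $C^1$ filter
$S(\omega,\omega^\ast) = [1-(\omega/\omega^\ast)^2]^2$ below the cutoff and
0 above: $J_{\rm slow} = S\,J$, $J_{\rm fast} = J - J_{\rm slow}$.  The
fast part enters the explicit dynamics; the slow part is frozen into
Gaussian site-energy disorder of width
$\sigma_{\rm slow}^2 = \int_0^\infty J_{\rm slow}(\omega)
\coth(\beta\omega/2)\,d\omega$, which reduces to the classical
$2\Lambda_{\rm slow}k_BT$ at high temperature (the convention check we
keep as a test).  Observables are averaged over independent realizations
of the disorder.  The default $\omega^\ast = 20$ cm$^{-1}$ aims to keep
the slow bath below a few percent of each chromophore's $\Lambda$;
`validate_baths()` reports the per-chromophore fractions and warns above
5%.

Design choices where the formulation is open:

* disorder is drawn independently per chromophore, each with its own
  $\sigma_{\rm slow}$ (the minimal assumption absent evidence for
  cross-site correlation);
* electronic couplings $V_{AB}$ are not modulated, only site energies;
* draws come from a counter-based 32-bit avalanche hash keyed on
  (seed, realization, site) mapped through the normal quantile, so any
  parallel schedule reproduces the serial stream bit for bit;
* realizations are reduced in fixed blocks of 25 in index order, making
  ensemble means byte-identical for any worker count.

## Numerical implementation

All frequency and time integrals are composite trapezoids on the tabulated
grids (densities arrive as dense tables; nothing is fitted).  The two
expensive kernels -- $g_A(t)$ on the rate grid and $I_{BA}(\omega)$ on the
mode grid -- are both uniform-to-uniform Fourier-type sums, which are
evaluated through a Bluestein chirp-z transform: three FFTs reproduce the
direct $O(N_\omega N_t)$ summation to floating-point roundoff (checked at
$10^{-10}$ in the tests), with no interpolation in either variable.  A
blocked direct evaluation remains available (`method = "direct"`) for
non-uniform grids and as the independent cross-check; results are
independent of its block size.  Per disorder realization only the phase
factor $e^{-it(\Delta E+\Lambda)/\hbar}$ changes, so one ensemble
realization costs a handful of FFTs per coupled pair; the envelopes
$e^{-g_A-g_B}$, the $\Lambda$'s and the mode discretization are computed
once and shared (their reuse is exact, not approximate).

Other numerical decisions:

* **Mode discretization.** $J_{\rm fast}$ is represented by `n_modes`
  (default 4000) equally spaced bins spanning the tabulated support;
  $\lambda_j$ is the bin integral of $J/\omega$ taken from the cumulative
  trapezoid, so $\sum_j\lambda_j = \Lambda$ holds to machine precision by
  telescoping, at any mode count.  Dissipation fields live on the bin
  centres, with $\lambda_j/\Delta\omega$ standing in for $J/\omega$ so the
  mode-resolved and frequency-resolved views are one object.
* **Rate integrals.** Step 0.5 fs to $T_{\max} = 30$ ps by default; the
  envelope $|e^{-g_A-g_B}|$ at $T_{\max}$ is compared against $10^{-6}$ of
  its peak -- a warning in one-shot calculations, a hard abort (with the
  offending pairs named) before an ensemble run, keeping long runs
  deterministic rather than silently self-extending.
* **$\omega \to 0$.** $J/\omega$, $J\coth(\beta\omega/2)$ and the
  $g$-integrand are finite for ohmic-like densities; grids that include
  $\omega = 0$ get the analytic limits (via the low-frequency slope of
  $J$), and $\coth(x)$ switches to its series $1/x + x/3$ below
  $x = 10^{-3}$.
* **Propagation.** Classical RK4 at the rate-grid step (0.5 fs).  The rate
  matrix conserves total population identically, so $\sum_A P_A$ stays at
  1 to accumulation roundoff, and halving the step moves results by
  $<10^{-4}$ (tested).  Population time-integrals $Q_A(t)$ are accumulated
  trapezoidally at full step resolution during propagation; because the
  dissipative densities are constant within a realization,
  $E_A(\omega,t) = \sum_B[J^A_{BA}Q_A(t) + J^A_{AB}Q_B(t)]$ -- the
  factorization is exact, not an approximation, and snapshot times between
  stored steps are interpolated linearly.
* **Interpolation.** $I_{BA}$ is linear-interpolated onto mode frequencies
  where needed (it is smooth on the bin scale); cumulative bath integrals
  are linear-interpolated at bin edges (preserving monotonicity, hence
  $\lambda_j \ge 0$).
* **Degenerate inputs.** Zero baths give $g \equiv 0$, $\sigma = 0$ and
  zero fields; uncoupled pairs give exactly zero rates and densities;
  $\sigma \equiv 0$ ensembles reduce bitwise to the deterministic
  pipeline.

## The synthetic environment generator and the embedded 7-site model

Real chromophore-specific spectral densities (from long MD trajectories)
are outside this package's scope; `synthetic_bath_spec()` emulates their
gross structure: a broad Drude background
$\frac{2}{\pi}\lambda_D\gamma_D\omega/(\omega^2+\gamma_D^2)$ for the
protein, plus sharp underdamped Brownian-oscillator peaks
$\frac{2}{\pi}\lambda_k\gamma_k\omega\omega_k^2/[(\omega^2-\omega_k^2)^2+
\gamma_k^2\omega^2]$ for intramolecular modes.  Both families contribute
exactly their nominal $\lambda$ to $\Lambda$, so every generated density
is self-verifying (a property test draws random specifications and checks
1% agreement).

The embedded reference system (`fmo_like_model()`) couples a 7-site
Adolphs-Renger-style FMO Hamiltonian (shipped as a commented, versioned
fixture; only its structural properties matter to any claim here) to one
synthetic bath per chromophore: $\lambda_D = 35$, $\gamma_D = 50$
cm$^{-1}$; an in-plane breathing-mode analog near 200 cm$^{-1}$
($\lambda = 15$, width 10, centre varying 196-208 cm$^{-1}$ across
sites); and a far-detuned peak at 1400-1520 cm$^{-1}$ ($\lambda = 10$) --
deliberately placed above every excitonic gap (the site-energy spread is
$\sim$420 cm$^{-1}$) so that the "high-frequency modes carry
reorganization energy but no dissipation" phenomenology is exercised.
Simulations run at 300 K with the excitation starting on Bchl1 (the
`bchl6` preset starts on Bchl6 for the robustness check).

What this emulation does *not* capture: the many overlapping vibronic
peaks of MD-derived densities, their chromophore-to-chromophore
variability beyond small centre shifts, and their suppressed
sub-20 cm$^{-1}$ weight -- a Drude tail is fatter there, which is why the
preset's slow-bath fraction ($\approx$8%) trips the 5% advisory warning;
$\sigma_{\rm slow} \approx 44$ cm$^{-1}$ is nonetheless a realistic
inhomogeneous width for FMO.  Passing tests therefore demonstrate the
correctness and thermodynamic consistency of the machinery on
FMO-*like* structured environments, not quantitative agreement with any
measured FMO observable.

With these inputs the pipeline reproduces the qualitative dissipation
map expected for FMO-like transport: dissipation overwhelmingly below
800 cm$^{-1}$ and concentrated around the $\sim$200 cm$^{-1}$ breathing
band, the far-detuned band contributing $<10^{-3}$ of the total; the
initial chromophore *absorbing* environmental energy at early times (its
first step is uphill) and remaining a net absorber while the sites near
the energy sink dominate the release.

## Problem sizes and runtimes

Production-style settings (4000 modes, 0.5 fs steps, 30 ps rate
integrals) are the package defaults.  The test suite exercises the full
pipeline at those settings with a 200-realization disorder ensemble
(about two minutes on one core; one realization costs roughly a second,
dominated by 84 chirp-z transforms across the 21 coupled pairs).  Unit
tests use shorter grids -- 2-6 ps rate integrals, a few hundred modes --
chosen to sit well inside the convergence regime of what they probe, as
verified by the envelope diagnostic and the step-halving test.

## Known limitations

* Golden-rule (weak electronic coupling) rates: no coherent
  site-off-diagonal dynamics, no polaron or multiphonon corrections; for
  strongly coupled dimers the rates and hence the pathway weights are
  semiquantitative.
* Harmonic, independent local baths with linear coupling; no shared or
  correlated environments.
* The slow-bath treatment is quasi-static: slow modes shift energies but
  exchange no energy themselves, so dissipation below $\omega^\ast$ is by
  construction absent from the fields.
* Dissipation is accumulated through rate constants that are themselves
  time-integrals to $T_{\max}$; transient ($t \lesssim$ bath correlation
  time) features carry the usual FGR ambiguity.
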