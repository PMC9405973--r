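---
title: "Linked-equilibria ITC analysis and structural energetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linked-equilibria ITC analysis and structural energetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itcthermo)
library(dplyr)
```

itcthermo turns raw ITC observables — an association constant
$K_b$ and a binding enthalpy $\Delta H_b$ per complex per temperature —
into a structural-energetic account of what the binding partners do:
how much surface rearranges, how many residues and rotatable bonds
change state, and how the couplings between ligands (here Mg²⁺,
guanine nucleotides and the effector protein Sdo1) partition into
enthalpic and entropic work. This vignette explains the models, the
assumptions they carry, the numerical choices, and what the test suite
does and does not establish.

## 1. State functions and units

Boundary units follow calorimetric table convention: temperatures in
°C, $K_b$ in mM⁻¹, energies in kcal mol⁻¹, entropies and heat
capacities in cal mol⁻¹ K⁻¹. Internally temperatures become Kelvin
(+273.15) and constants are converted to M⁻¹ against the 1 M standard
state, so $\Delta G_b = -RT\ln(10^3 K_b[\text{mM}^{-1}])$ with
$R = 1.9872$ cal mol⁻¹ K⁻¹ (the tables we emulate never state $R$;
this standard value is recorded in the constants file). The Gibbs
identity $\Delta G_b = \Delta H_b + (-T\Delta S_b)$ holds exactly for
every derived row — it is how $-T\Delta S_b$ is defined.

The heat capacity of binding is the slope of $\Delta H_b(T)$, fitted
by *unweighted* ordinary least squares (`fit_delta_cp()`). Unweighted,
because the emulated study reports a single enthalpy per temperature
with comparable errors, and because for three equally spaced
temperatures the OLS slope reduces to the transparent two-point form
$(\Delta H_3 - \Delta H_1)/(T_3 - T_1)$, which reproduces the
published heat capacities from the published enthalpies. A weighted
fit would quietly change those numbers. $\Delta C_{p,b}$ is assumed
constant over the 25–35 °C span — a 10 K window over which curvature
in $\Delta H(T)$ is not resolvable from three points.

## 2. Metal–nucleotide linked equilibria

Guanine nucleotides in Mg²⁺-containing buffer are a mixture: free G,
MgG, and (for triphosphates) Mg₂G. The protein binds G with $K_{EG}$
and MgG with $K_{EMG}$; Mg₂G is not recognised. `solve_ternary()`
solves the three mass balances over the species set
$\{E, G, Mg, MgG, Mg_2G, EG, EMG\}$.

Numerics: damped Newton iteration on the *logarithms* of the three
free concentrations, which keeps every species positive by
construction; the residuals are log-ratios of the mass-balance sides,
converged to $10^{-12}$ absolute (far inside the $10^{-10}$ relative
balance guarantee), with at most 200 iterations and step halving when
a full Newton step overshoots. The iteration starts from the
uncoupled solution (Mg–nucleotide speciation without protein, then
the protein equilibrated against the Mg-averaged apparent constant),
which in practice converges in a handful of steps. Degenerate totals
(zero protein, nucleotide or metal) short-circuit to the exact
lower-dimensional solutions rather than entering the solver.

The apparent association constant for total uncomplexed nucleotide,

$$K_{app}([Mg]) = \frac{K_{EG} + K_{EMG}K_{MgG}[Mg]}
  {1 + K_{MgG}[Mg] + K_{MgG}K_{Mg2G}[Mg]^2},$$

is what a one-site fit of a +Mg isotherm measures; the test suite
verifies this equivalence to 5% against fits of ternary-generated
data, and verifies the solver itself against a brute-force nested
bisection oracle to $10^{-6}$ on all species.

The Mg–nucleotide constants themselves are *required configuration*:
the study this package re-implements defers them to earlier
literature without printing values. The defaults
(`mg_constants_for()`: $K_{MgGTP}=10^4$, $K_{MgGDP}=10^{3.5}$,
$K_{Mg2GTP}=10^2$ M⁻¹) are placeholder magnitudes typical of
Mg–NTP/NDP chemistry and should be overridden for quantitative work.
Mg-binding enthalpies default to zero because blank subtraction
cancels the syringe-side speciation heat. The metal-free (EDTA)
condition is modelled as total Mg = 0, not as an explicit chelation
equilibrium: EDTA is used experimentally only to enforce that state.
Activity coefficients, ionic strength and proton linkage are out of
scope.

## 3. The forward injection model

`predict_injection_heats()` models a constant-volume perfusion cell:
each injected volume displaces cell liquid. We treat the perfusion as
continuous, so every cell total is an exact state function of the
cumulative injected volume $v$ — protein decays as $e^{-v/V_0}$,
syringe components relax toward their syringe concentrations (the
familiar half-volume $(1 \pm v/2V_0)$ correction factors are the Padé
approximant of this exponential). The heat of injection $i$ is

$$Q_i = \sum_s \Delta H_s\,\Big[V_0\,\Delta[s] +
  \int_{v_{i-1}}^{v_i} [s](v)\,dv - n_s^{syr}\Big],$$

counting complex formed in the cell, complex carried out with the
displaced liquid (5-point Gauss–Legendre per injection), and, for
Mg-nucleotide species, the moles delivered pre-formed from the
syringe. Two consequences are tested: cumulative heat is independent
of how the schedule is partitioned (merging injections changes it by
< 10⁻⁹ relative — a state-function property no discrete
per-injection expulsion rule has), and at ≥ 99% saturation the total
heat equals $n\,\Delta H\,[\text{protein}]_0 V_0$ within 1%, the
shortfall being protein expelled before it bound. In the
infinitesimal-injection limit the model converges on the closed-form
Wiseman differential isotherm. Raw thermogram integration, baseline
drift and multi-site models are out of scope: the unit of input is
the integrated, blank-subtracted injection heat.

Fitting (`fit_one_site()`, `fit_ternary()`) is Levenberg–Marquardt on
log-transformed positive parameters with three deterministic starts
(a $c \approx 5$ heuristic for $K$, halved and doubled); standard
errors are asymptotic, from the Jacobian at the optimum. The first
injection is discarded by default (syringe-tip diffusion during
equilibration — common practice; the flag is in the protocol).
Fits warn when the Wiseman $c$-value $nK[\text{cell}]$ leaves
$[0.1, 10^5]$, where $K$ is poorly identifiable. Whether the original
analysis floated or fixed $n$ is not recorded in the source tables;
both modes are exposed (`fix_n`), neither asserted. The joint ternary
fit requires a ±Mg pair at one temperature: the metal-free isotherm
pins $K_{EG}, \Delta H_{EG}$. Two entry points exist deliberately —
fit intrinsic constants jointly, or fit apparent constants one-site
and correct through $K_{app}$ — because it is not recorded which the
original analysis used.

## 4. Cooperativity cycles

For two ligands X and S on the same receptor,
$\kappa = K_{num}/K_{den}$, $\Delta g = -RT\ln\kappa$,
$\Delta h = \Delta H_{num} - \Delta H_{den}$,
$-T\Delta s = \Delta g - \Delta h$. κ is computed from unrounded
constants; reproduction of printed tables rounds only at presentation
(`present_tables()`, half away from zero), so printed cells are
matched within one unit of their last digit rather than exactly — the
published tables were themselves computed from rounded inputs.

`cycle_closure_check()` tests detailed balance on a four-edge square:
the product of constants along the two paths between the same end
states must agree ($\ln$-discrepancy 0), equivalently the effect of X
on S equals the effect of S on X. The default flag threshold of 0.2
ln-units reflects the 10–30% experimental errors on $K$. In the
packaged study this check surfaces a genuine internal conflict: the
measured MgGDP edges give κ(Sdo1 on MgGDP) ≈ 3.6 (enhancement) while
the accompanying narrative states a three-fold *decrease* of the
Sdo1 interaction by the diphosphate; the square built from both
claims misses closure by ≈ 2.4 ln-units. The package flags this, it
does not resolve it. One printed −TΔs cell (Sdo1-on-GDP, −Mg, 35 °C)
also contradicts its own row's Δg − Δh by 0.4 kcal mol⁻¹; the
comparison report shows it as the single out-of-tolerance cell, and
the tests assert the identity-consistent value instead.

## 5. Structural-energetic deconvolution

$\Delta C_{p,b} = \Delta C_{p,rb} + \Delta C_{p,conf}$, where the
rigid-body term $\Delta C_{p,rb} = \alpha\,\Delta ASA_{ap} +
\beta\,\Delta ASA_p$ ($\alpha = 0.45$, $\beta = -0.26$ cal K⁻¹ mol⁻¹
Å⁻²) prices the buried interface as if no rearrangement occurred.
Per-complex $\Delta C_{p,rb}$ values are *inputs* (a lookup per
ligand/metal state in `dcp_rigid_body.csv`); computing accessible
surface areas from coordinates is out of scope. The conformational
remainder converts to surface area through a coefficient for a
surface of average interface hydrophobicity $f_{ap} = 0.68$:

$$\Delta ASA_{conf} = \frac{\Delta C_{p,conf}}
  {\alpha f_{ap} + \beta\,(1-f_{ap})} =
  \frac{\Delta C_{p,conf}}{0.2228}.$$

The polar weight is $(1-f_{ap})$ so the apolar and polar fractions
tile the surface; the source's printed equation repeats $f_{ap}$ on
both terms, which would give 0.1292 and is inconsistent with every
tabulated area it accompanies (996 Å² = 222/0.2228, not 222/0.1292) —
we treat that as a typo, and a dedicated test asserts the corrected
coefficient reproduces the published areas while the literal one does
not.

The entropy splits as $\Delta S_b = \Delta S_{solv} + \Delta S_{r\!-\!t}
+ \Delta S_{conf}$ with $\Delta S_{solv} = \Delta C_{p,b}\ln(T/T_s)$,
$T_s = 385.15$ K (the temperature where solvation entropy
extrapolates to zero) and $\Delta S_{r\!-\!t} = -8$ cal mol⁻¹ K⁻¹ for
a bimolecular association. Residue and rotor equivalents divide by
47 Å² per residue and 1.7 cal mol⁻¹ K⁻¹ per rotatable bond and round
half away from zero on the magnitude. Both per-unit constants are
back-derived calibrations, not first-principles values: 47 Å²
reproduces 13 of 14 published residue counts exactly, and the implied
per-rotor entropy ranges 1.63–1.71 across published rows, so rotor
counts are asserted only to ±1. Both are configurable in the
constants file. Which residues move, and in which partner, is not
identifiable from calorimetry and is not claimed.

## 6. The synthetic generator

`generate_isotherm()` adds i.i.d. Gaussian noise to the raw
per-injection heats (µcal) — not to normalized heats, because
instrument noise arises in power integration per injection — plus an
optional constant blank offset; the blank titration gets independent
noise from the same seeded stream. The default protocol mirrors the
emulated experiments: 200 µL cell, 19 × 2 µL injections, 40 µM
protein, 2.5 mM ligand, and the default noise (0.05 µcal ≈ 1% of an
early injection heat) matches a well-behaved modern instrument.
Temperature series propagate truth with constant $\Delta C_p$ and the
integrated van't Hoff relation. All randomness flows from the single
seed via an isolated RNG scope (the global stream is untouched).

What passing recovery tests shows: the estimator chain is unbiased
and calibrated *under the model* — Gaussian injection noise, exact
blank schedule, no baseline drift, no injection-volume error, no
active-site titration error. Real isotherms violate all four at some
level; the generator deliberately does not simulate drift,
peak-shape, or concentration mis-calibration, so recovery here bounds
estimator error from below, not instrument error from above.

## 7. Reproduction tolerances

When `reproduce_tables()` is given a reference transcription it
reports per-cell deviations with tolerances that propagate the
rounding of the *inputs* it recomputes from: one unit of the last
printed digit for cells depending only on $K$; 1.5 units for
differences of two independently rounded enthalpic quantities;
for heat capacities, the larger of one unit and the printed standard
error (enthalpies printed to 0.1 kcal can move a 10 K slope by 10 cal
mol⁻¹ K⁻¹ — two published $\Delta C_p$ cells are reproducible only
through their printed errors, indicating the originals were fitted on
unrounded enthalpies); structural cells inherit the $\Delta C_p$
allowance through the decomposition algebra; counts compare after
rounding, ±1.

```{r tables}
fx <- load_efl1_fixtures()
tables <- reproduce_tables(fx$params, fx$cycles, fx$dcp_rb,
                           fx$constants, reference = fx$reference)
tables
filter(tables$comparison, !within_tolerance) |>
  select(table, effect_label, temperature_C, quantity,
         computed, reference)
```

## 8. Problem sizes and determinism

The test suite runs entirely on data built in code: speciation
oracles on 50 random parameter sets, 100 noisy one-site replicates
for coverage, 10,000 draws for the generator-mean check, and single
noise-free round trips for the ternary and temperature-series chains
— sizes chosen so each check is statistically decisive while the
whole suite stays interactive. Every stochastic test fixes its seed;
`reproduce_tables()` output is byte-identical across runs.

## 9. Known limitations

- The ternary fit assumes the Mg–nucleotide constants are known;
  errors in them propagate undiagnosed into $K_{EMG}$.
- No error propagation into derived quantities beyond the fitted
  standard errors (the source tables do not propagate either).
- The structural interpretation inherits the empirical
  surface/entropy coefficients; they are parameterizations, and the
  residue/rotor counts are equivalents, not structure assignments.
- Integrated heats are the input; no `.itc` thermogram parsing.
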