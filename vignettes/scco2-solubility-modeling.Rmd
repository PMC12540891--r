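---
title: "Modeling solid-drug solubility in supercritical CO2"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling solid-drug solubility in supercritical CO2}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scfsol)
```

## The problem

Supercritical CO2 (above 304.1 K and 7.38 MPa) is a tunable, residue-free
solvent used to micronize poorly water-soluble drugs. Rational design of
such processes needs the equilibrium solubility surface y2(T, P) of the drug
in the fluid, which for drug-like solids is a trace quantity (mole fractions
of 1e-6 to 1e-4) controlled by two competing effects: solvent density, which
falls with temperature at fixed pressure and carries the solvating power,
and the solid's sublimation pressure, which rises steeply with temperature.
Their competition produces the crossover phenomenon: below a crossover
pressure, heating *reduces* solubility; above it, heating *increases* it.

The package ships a 28-point gravimetric dataset for the antimigraine drug
sumatriptan in SC-CO2 (4 isotherms, 308.2--338.2 K, times 7 pressures,
12--30 MPa) and implements the three modeling families used to correlate
such data, each behind a small, testable surface.

## The bundled dataset

`load_dataset("sumatriptan")` returns the measured table: temperature,
pressure, CO2 density, solute mole fraction, its replicate standard
deviation, and an informational g/L column. Two transcription corrections
are documented in the provenance note shipped next to the fixture
(`system.file("extdata", "sumatriptan_provenance.md", package = "scfsol")`):
a run-on printed value read as P = 30 MPa at 338.2 K, and the 308.2 K /
18 MPa density, which duplicates the printed 15 MPa value and is replaced by
the spline interpolation of the isotherm's own remaining densities
(849.58 kg/m3). CO2 density is single-valued in (T, P), and every other
isotherm in the table is strictly increasing in pressure, so we treat the
duplicate as a printing artifact rather than data. The g/L column is carried
as metadata only; it is not an exact transform of the printed mole fractions
(deviations reach ~16% at the lowest pressures), which is one reason no fit
in this package ever uses it.

The densities themselves are inputs throughout: the package never computes
CO2 density from (T, P), mirroring how such tables are produced (densities
from a reference correlation, solubilities from the balance).

## Density-based correlations

Four classical three-parameter correlations link ln-solubility to solvent
density rho (kg/m3) and temperature T (K):

* Chrastil: `ln y2 = a0 + a1 ln(rho) + a2 / T` -- a1 is an apparent
  solvation (association) number, a2 carries the total heat of dissolution.
* Kumar-Johnston (K-J): `ln y2 = a0 + a1 rho + a2 / T` -- linear rather than
  logarithmic density dependence.
* Bartle: `ln(y2 P / P_ref) = a0 + a1 / T + a2 (rho - rho_ref)` -- the 1/T
  coefficient of the *fugacity-like* product y2 P estimates the sublimation
  (vaporization) enthalpy.
* Mendez-Santiago--Teja (MST): `T ln(y2 P) = a0 + a1 rho + a2 T` -- derived
  from a Helmholtz expansion at infinite dilution; data consistent with it
  collapse onto one straight line in density.

Pressure inside the Bartle and MST products is expressed in **bar** with
P_ref = 1 bar and rho_ref = 700 kg/m3. That is the dominant convention in
this literature, and it is corroborated here: the published MST parameter
triple reproduces its published deviation statistic only under the bar
convention. The unit is a `P_ref` field, not a hard-coded constant.

### Fitting

Every model is *exactly linear* in (a0, a1, a2) after a known transform of
y, so ordinary least squares in the transformed space is both the
`"sse_log"` objective's closed-form optimum and the anchor for the default
`"aard"` objective, which minimizes the average absolute relative deviation
on the mole-fraction scale -- the statistic used to rank these models.
Because AARD is piecewise-smooth, its surface develops shallow, elongated
valleys (notably in the Chrastil temperature coefficient); a single local
search from the least-squares start can land a few percent away in a2 at
nearly identical AARD. The fitter therefore runs a deterministic multi-start
Nelder-Mead: the least-squares start plus eight profile starts in which the
temperature coefficient is scaled over a fixed factor grid (0.8--1.3) with
the remaining coefficients re-solved by least squares, followed by restarts
from the incumbent until no improvement. No randomness is involved;
repeated calls agree bitwise.

R-squared statistics are computed on the linear y scale for every model,
including those fitted in log space, so the ranking table is uniform;
n_params = 3 for all density models.

### Enthalpies

With R = 8.314 J/mol/K, the refit coefficients give

* dH_total = -R a2(Chrastil): apparent total heat of dissolution,
* dH_vap = -R a1(Bartle): sublimation/vaporization enthalpy,
* dH_sol = dH_total - dH_vap: solvation heat, negative (exothermic) here.

The sign convention is dH = -R times the 1/T coefficient, which yields
positive (endothermic) dH_total and dH_vap for this system, consistent with
the reported values; the identity dH_sol = dH_total - dH_vap holds exactly
by construction.

### Crossover

`find_crossover()` reports the interval between adjacent grid pressures at
which the Spearman correlation of y with T flips from negative to positive.
For the bundled data that interval is 15--18 MPa. The result is deliberately
an interval, not an interpolated point: the data sit on a 3-MPa pressure
grid, and a single crossover pressure would overstate the resolution.

## Solid-fluid equilibrium with cubic equations of state

The rigorous route equates the solid's fugacity with its fugacity in the
fluid:

y2 = (P_sub / P) (1 / phi2(T, P, y)) exp[v_s (P - P_sub) / RT],

with the saturated-vapor fugacity coefficient taken as 1 (P_sub is of order
1e-8 to 1e-6 Pa here) and the exponential the Poynting correction for the
compressed solid (v_s = 305.2 cm3/mol). phi2 comes from Peng-Robinson or
Soave-Redlich-Kwong with two-parameter van der Waals mixing rules: quadratic
composition sums for both a (geometric mean scaled by 1 - k_ij) and b
(arithmetic mean scaled by 1 - l_ij).

Numerical choices:

* **Root selection.** Both EoS are solved as cubics in Z (Cardano, no
  iteration); among real roots Z > B the root of minimum Gibbs energy is
  selected by direct comparison -- the unambiguous criterion when a
  low-density and a high-density root coexist.
* **Fugacity closed form.** Quadratic b-mixing makes the covolume
  composition-dependent, so the textbook ln phi expression (written for
  linear b-mixing) does not apply verbatim. The implemented expression uses
  the partial-molar covolume `bbar_i = 2 sum_j y_j b_ij - b_m` and is derived
  from the mole-number derivative of the residual Helmholtz energy. It is
  not trusted: the test suite integrates the defining volume integral by
  adaptive quadrature on random states and requires agreement to 1e-8.
* **Solubility iteration.** y2 appears on both sides through phi2(y); a
  fixed-point iteration from y2 = 1e-8 converges in a handful of steps
  because phi2 is nearly constant at trace dilution. Oscillation triggers a
  0.5 damping factor; tolerance 1e-10 relative, 200-iteration cap.
* **Sublimation pressure.** ln P_sub is linear in 1/T through the two
  anchor points (308.2 K, 2.88e-8 Pa) and (338.2 K, 3.45e-6 Pa); the
  intermediate isotherms use this interpolation -- the one input to the
  per-isotherm tables that is not printed directly. Evaluation more than
  5 K outside the anchors is refused rather than extrapolated.
* **Regression.** Per isotherm, (k_ij, l_ij) minimize AARD within
  [-1, 1]^2 by deterministic multi-start Nelder-Mead from a fixed 5x5
  interior grid. The l_ij at the hottest isotherm sits essentially at the
  -1 bound, as the published fits also approach (-0.94); widening the box
  further has no physical motivation.

A known tension is carried, not hidden: the enthalpy implied by the two
sublimation-pressure anchors (~138 kJ/mol) is far steeper than the
Bartle-derived 59.8 kJ/mol. The per-isotherm interaction parameters absorb
this between isotherms -- which is precisely why both k_ij and l_ij trend
more negative with temperature -- but within the hottest isotherms the
deviation statistics remain the largest.

## PC-SAFT

The perturbed-chain SAFT equation of state is implemented in its
non-associating form: reduced residual Helmholtz energy
`a_res = a_hc + a_disp` with the temperature-dependent segment diameter,
Boublik-Mansoori hard-sphere mixture term, site-site contact value of the
hard-sphere pair correlation for the chain term, and the dispersion power
series I1, I2 in packing fraction eta with the published universal constant
tables and the C1 compressibility correction. Combining rules are the
arithmetic mean for sigma_ij and the geometric mean scaled by (1 - k_ij)
for eps_ij.

Everything downstream uses **analytic** derivatives: Z = 1 + eta
d(a_res)/d(eta), and ln phi_k from the composition gradient of a_res at
fixed temperature and total number density. The test suite holds both to
finite-difference oracles (1e-7 for Z, 1e-6 for ln phi) on 100 random
states, and holds a_res itself to an independently written term-by-term
re-implementation. Density at given (T, P) is found by bracketed root
finding in eta (warm-started secant steps inside iterative loops), with the
phase hint selecting the low- or high-density bracket when multiple
mechanical roots exist.

**Solute parameters.** CO2 uses the standard literature non-associating set
(m = 2.0729, sigma = 2.7852 A, eps/k = 169.21 K); with it the model
reproduces the dataset's tabulated CO2 density at 308.2 K / 30 MPa within
1.3%. No published PC-SAFT parameters exist for sumatriptan, so the package
ships a clearly-labelled synthetic estimate (m = 11.0, sigma = 3.80 A,
eps/k = 180 K): the total segment volume is matched to the solid molar
volume at a solid-like packing (~0.6), and the segment energy was fixed once
by a coarse deviation scan against the bundled data with k_ij = 0. With
these parameters the per-isotherm k_ij fits are negative and decrease with
temperature, reproducing the published qualitative trend; their absolute
magnitudes (and the per-isotherm deviation statistics) are not comparable
with the published table, whose underlying solute parameters are
unrecoverable.

The k_ij regression uses a seeded differential-evolution search over
[-0.5, 0.5] followed by a deterministic golden-section polish; the global
stage runs in an isolated RNG stream (caller RNG untouched), and different
seeds agree after the polish.

## Synthetic data

`generate_synthetic()` evaluates any of the three forward models (density
correlation, cubic EoS, PC-SAFT) on a (T, P, rho) grid -- by default the
bundled 28-point grid -- and applies multiplicative lognormal noise,
`y = y_true exp(e)`, `e ~ N(0, sigma)` with `sigma = sqrt(log(1 + rsd^2))`
so the relative standard deviation of replicates equals the requested
`noise_rsd` exactly. Multiplicative noise is the right structure for a
quantity spanning an order of magnitude that must stay positive; the
gravimetric replicates behind the real data report relative SD below 5%,
and the default here is 3%. Generation is deterministic under a seed.

What the generator does *not* emulate: the measurement chain (balance
error, CO2 retention in the solid, equilibration kinetics), temperature- or
pressure-dependent error structure, and correlated errors within an
isotherm. Passing recovery tests therefore demonstrate identifiability of
the models under idealized noise, not robustness to instrument systematics.

At the study's own conditions (28-point grid, 3% noise, 200 replicates) the
median relative bias of every refitted density-model coefficient is well
below 3%, and noiseless self-generated data return the generating
coefficients to four significant figures for all four models, and the known
(k_ij, l_ij) / k_ij of the EoS routes to 1e-3.

## Problem sizes and runtime

All fits operate on the 28-point dataset or its 7-point isotherms. The
density-model stage is instantaneous; one cubic-EoS isotherm regression
(25 Nelder-Mead starts over a 2-D box, each objective evaluation solving
seven fixed-point equilibria) takes ~30 s; a PC-SAFT isotherm regression
(1-D differential evolution, population 10, 15 generations, plus polish)
takes ~10 s. The recovery study uses 200 replicates per model. These sizes
were chosen to keep the full pipeline and its tests in the minutes range on
a single core while leaving every statistic stable to well below its
acceptance tolerance.

## Limitations

* Scope is binary solid-solute / SC-CO2 equilibrium: no cosolvents, no
  volume-translated cubics or advanced mixing rules, no association or
  polar PC-SAFT variants, no uncertainty quantification on fitted
  parameters.
* The solute's critical constants and acentric factor are group-contribution
  estimates; with Tc = 1160 K, the cubic alpha-functions operate far below
  Tr = 0.3 where they are weakly validated. The k_ij/l_ij values absorb
  much of that error, which is why they are per-isotherm quantities.
* The sublimation-pressure curve rests on two anchor points; its slope
  disagrees with the Bartle-derived enthalpy (see above), and both are
  carried as printed without reconciliation.
* PC-SAFT solute parameters are a constructed estimate; only the sign and
  temperature trend of the fitted k_ij are interpretable.
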