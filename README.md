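# scfsol

Thermodynamic modeling of solid-drug solubility in supercritical carbon
dioxide, built around a bundled 28-point equilibrium dataset for the
antimigraine drug **sumatriptan** in SC-CO2 (four isotherms, 308.2--338.2 K,
seven pressures, 12--30 MPa, measured gravimetrically).

The package is aimed at thermodynamic/process modelers working on
supercritical-fluid particle engineering who need to correlate and predict
trace solid solubilities y2(T, P). It implements three modeling families
behind one dataset abstraction:

1. **Density-based correlations** -- Chrastil
   (`ln y2 = a0 + a1 ln rho + a2/T`), Kumar-Johnston
   (`ln y2 = a0 + a1 rho + a2/T`), Bartle
   (`ln(y2 P/P_ref) = a0 + a1/T + a2 (rho - rho_ref)`), and
   Mendez-Santiago--Teja (`T ln(y2 P) = a0 + a1 rho + a2 T`), fitted by
   deterministic AARD minimization, plus the derived enthalpies
   dH_total = -R a2(Chrastil), dH_vap = -R a1(Bartle),
   dH_sol = dH_total - dH_vap.
2. **Cubic equations of state** -- Peng-Robinson and Soave-Redlich-Kwong
   with two-parameter van der Waals mixing rules (k_ij on the energy,
   l_ij on the covolume), closed-form mixture fugacity coefficients, and
   solid-fluid equilibrium
   `y2 = (P_sub/P) (1/phi2) exp[v_s (P - P_sub)/RT]`
   with per-isotherm (k_ij, l_ij) regression.
3. **PC-SAFT** (non-associating, hard-chain + dispersion) with analytic
   packing-fraction and composition derivatives, a density solver, and
   seeded per-isotherm k_ij regression.

A synthetic-data generator (forward model + multiplicative lognormal noise
at a prescribed relative SD) makes every fitting stage testable by
parameter recovery, and `run_analysis()` chains all stages into one report.

## Worked example

```r
library(scfsol)

d <- load_dataset("sumatriptan")
find_crossover(d)$interval
#> [1] 15 18

fit <- fit_density_model("kj", d)           # best-ranked correlation
fit
#> kj fit (objective aard): a0 = -0.804779, a1 = 0.00656815, a2 = -4826.59
#> AARD = 7.40%, R2 = 0.9746, R2_adj = 0.9715 (N = 28, p = 3)

e <- derive_enthalpies(fit_density_model("chrastil", d),
                       fit_density_model("bartle", d))
e
#> dH_total = 41.23, dH_vap = 60.26, dH_sol = -19.03 kJ/mol
```

The crossover interval (15--18 MPa) is where heating switches from
suppressing solubility (solvent-density effect) to enhancing it
(sublimation-pressure effect). The Kumar-Johnston correlation describes the
data to an average absolute relative deviation of 7.4%; the Chrastil and
Bartle 1/T coefficients give an endothermic overall dissolution
(+41.2 kJ/mol), a sublimation enthalpy of 60.3 kJ/mol, and an exothermic
solvation heat of -19.0 kJ/mol.

The equation-of-state stages are driven the same way, e.g.

```r
fit_cubic_isotherm("pr", d, sumatriptan_properties(), co2_properties(),
                   T_iso = 308.2)
#> PR isotherm fit at 308.2 K: k_ij = -0.1019, l_ij = -0.5224
#> AARD = 11.61%, R2 = 0.8799, R2_adj = 0.8198 (N = 7, p = 2)
```

## Analysis workflow

The `analysis/` directory holds the numbered drivers that reproduce the
study's tables from the package functions, writing their outputs under
`results/`:

| script | output |
|---|---|
| `01_dataset_overview.R` | dataset, crossover trend |
| `02_density_models.R` | correlation coefficients, AARD/R2_adj, enthalpies, MST consistency |
| `03_cubic_eos.R` | per-isotherm (k_ij, l_ij), AARD/R2_adj, mean rows (PR, SRK) |
| `04_pcsaft.R` | per-isotherm PC-SAFT k_ij and statistics |
| `05_synthetic_recovery.R` | coefficient-recovery bias under 3% noise |

Run them in order with `Rscript analysis/01_dataset_overview.R`, etc.

## Notes on the bundled data

Two transcription corrections to the printed table (a run-on pressure/
density value and a duplicated density) are documented in
`inst/extdata/sumatriptan_provenance.md`. The reported g/L column is
carried as informational metadata only and is never used as fit input.
Sumatriptan's PC-SAFT pure-component parameters are not published; the
shipped set is a clearly-labelled synthetic estimate (see the methods
vignette), so PC-SAFT k_ij values are interpretable in sign and
temperature trend, not magnitude.
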