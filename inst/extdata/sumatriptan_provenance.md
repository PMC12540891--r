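# Provenance: sumatriptan / SC-CO2 solubility fixture

Source: the published equilibrium solubility table for sumatriptan in
supercritical CO2 measured gravimetrically over 4 isotherms (308.2, 318.2,
328.2, 338.2 K) x 7 pressures (12-30 MPa), three replicates per point with
relative standard deviation below 5%.

Transcription notes:

1. Temperatures are stored as 308.2/318.2/328.2/338.2 K, the values used in
   the running text and abstract; the table header prints "308.0" etc. The
   0.2 K difference is negligible for every fit in this package.
2. The printed mole-fraction column is scaled by 1e4 and the standard
   deviation column by 1e6; both are stored here unscaled (actual mole
   fractions).
3. The 338.2 K final row prints a run-on value "300809.68"; transcribed as
   P = 30 MPa, rho = 809.68 kg/m3 (grid consistency with all other isotherms).
4. The 308.2 K / 18 MPa row prints rho = 816.10 kg/m3, duplicating the value
   printed for 15 MPa. CO2 density is single-valued in (T, P) and strictly
   increasing in pressure along every other isotherm of the table, so the
   duplicate is a transcription artifact. The value stored here, 849.58
   kg/m3, is the cubic-spline interpolation of the isotherm's own remaining
   printed densities at 18 MPa (and agrees with standard CO2 property tables
   to ~0.1%). The printed duplicate was 816.10.
5. The g/L column is informational: it reflects the printed (rounded)
   mole-fraction values and is never used as a fit input.
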