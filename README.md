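# quenchkin

In vitro characterisation of reversible enzyme inhibitors, packaged as a
reproducible analysis pipeline. The motivating system is the inhibition of
xanthine oxidase (XO) — the enzyme whose product, uric acid, absorbs at
290 nm and whose over-activity drives hyperuricemia and gout — by a
polyphenol inhibitor, but every stage applies to any UV-rate /
fluorescence-quenching inhibitor study.

## What it computes

**Activity & reversibility.** Initial rates are OLS slopes of OD290
progress curves; relative activity is RA(%) = 100·R_i/R_c, and the IC50 is
fitted with a two-parameter log-logistic model
RA = 100 / (1 + ([I]/IC50)^h). Reversibility is tested from velocity-vs-
[enzyme] lines: a reversible inhibitor gives lines through the origin with
slopes decreasing in [I].

**Mixed-inhibition kinetics.** The rate law

    v = Vmax [S] / ( Km (1 + [I]/Ki) + [S] (1 + [I]/Kis) )

is analysed by the classical Lineweaver–Burk route: per-[I] double-
reciprocal lines, then secondary plots of slope and intercept against [I]
whose intercept/slope ratios give Ki (free enzyme) and Kis (enzyme–
substrate complex), plus a direct nonlinear fit as a cross-check and a
competitive / uncompetitive / noncompetitive / mixed classification.

**Fluorescence quenching.** Titration intensities are inner-filter
corrected (F_c = F_m·e^((A1+A2)/2)), then fitted with the Stern–Volmer
equation F0/F = 1 + Ksv[Q] (and Kq = Ksv/τ0 compared against the
diffusion-collision limit 2×10¹⁰ L mol⁻¹ s⁻¹ to call static vs dynamic
quenching) and with the double-log binding model
log[(F0−F)/F] = log Ka + n·log[Q].

**Binding thermodynamics.** Van't Hoff analysis of Ka(T),
log₁₀Ka = −ΔH/(2.303RT) + ΔS/(2.303R), gives ΔH and ΔS; ΔG = ΔH − TΔS per
temperature; the signs of ΔH and ΔS classify the driving forces (default
rule: ΔH<0 with ΔS>0 → hydrogen bonding + hydrophobic interaction).

**Synthetic assays.** A seeded forward simulator generates every input
table (rate grids, enzyme series, progress curves, dose–response tables,
cumulative-dilution titrations with inner-filter distortion, two-peak
emission spectra) with multiplicative Gaussian instrument noise, enabling
exact round-trip parameter-recovery tests. `rel_sd = 0` reproduces each
forward model to machine precision.

## Worked example

```r
library(quenchkin)
report <- run_pipeline(scenario = read_scenario())  # bundled scenario
print(report)
```

prints

```
quenchkin pipeline report
  IC50 = 22.97 umol/L (Hill 1)
  reversibility: reversible
  mixed inhibition: Ki = 10.6, Kis = 57.24 umol/L
  298 K: Ksv = 1.881e+05 L/mol, Ka = 1.67e+04 L/mol, n = 1.183
  304 K: Ksv = 1.661e+05 L/mol, Ka = 1.21e+04 L/mol, n = 1.236
  310 K: Ksv = 1.455e+05 L/mol, Ka = 1.17e+04 L/mol, n = 1.308
  quenching mechanism: static
  dH = -22.9 kJ/mol, dS = 3.636 J/(mol K): hydrogen bonds + hydrophobic
```

The bundled scenario simulates noiseless assays at the reference
constants, and every stage recovers its generating parameter: an IC50 of
22.97 μmol/L; mixed-type inhibition with Ki = 10.6 μmol/L ≪
Kis = 57.24 μmol/L (the inhibitor prefers free enzyme); Stern–Volmer
constants that decrease with temperature while Kq ≈ 1.5–1.9×10¹³
L mol⁻¹ s⁻¹ stays three decades above the collisional limit (static
quenching, i.e. ground-state complex formation); and an exothermic,
spontaneous binding (ΔH < 0, ΔG < 0) with a small positive ΔS, classified
as hydrogen bonding plus hydrophobic interaction.

The same pipeline runs on measured CSV tables
(`run_pipeline(inputs = list(rates = "rates.csv", ...))`) or from the
command line:

```sh
# source tree: exec/quenchkin; installed: system.file("exec", "quenchkin")
Rscript exec/quenchkin reproduce --outdir out/
Rscript exec/quenchkin kinetics --rates rates.csv --outdir out/
```

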