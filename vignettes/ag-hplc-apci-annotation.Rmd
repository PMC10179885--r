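---
title: "Annotating cuticular hydrocarbons from silver-ion HPLC/APCI-MS runs"
author: "agHC authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating cuticular hydrocarbons from silver-ion HPLC/APCI-MS runs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agHC)
```

## The analytical problem

Insect cuticular hydrocarbons (HCs) are mixtures of long-chain alkanes and
alkenes, many of them semiochemicals. Gas chromatography struggles with the
heaviest species (low volatility, thermal degradation) and MALDI cannot
separate isomers. Silver-ion (argentation) HPLC offers an alternative: the
pi electrons of C=C bonds complex reversibly with immobilized Ag⁺, so
retention grows with the number of double bonds, depends on their position,
and is weaker for trans than for cis geometry (sterically hindered
complexation). Coupled to atmospheric pressure chemical ionization mass
spectrometry (APCI-MS), each chromatographic peak yields ions that identify
the molecular weight and therefore the carbon number (CN) and double-bond
count (DB) — the CN:DB shorthand used throughout (e.g. C41:2).

This package implements the full data-analysis side of that experiment:

* **chemistry** — hydrocarbon formula/mass arithmetic
  (CnH~2n+2−2d~), a registry of the seven APCI ionization channels,
  isotope patterns, and reverse lookup from an observed m/z to candidate
  (species, adduct) pairs;
* **simulation** — a seeded generator of centroided LC-MS runs with a
  class-based retention model, mobile-phase-dependent adduct spectra,
  unsaturation-dependent response, isotope envelopes and noise, emitting
  standard mzML plus its ground truth;
* **annotation** — reconstruction of summed-ion chromatograms, peak
  detection/integration, CN:DB and cis/trans assignment, and within-class
  relative quantification in the layout of published profile tables;
* **fixtures** — machine-readable, digest-checked copies of the published
  class-apex table and of two complete insect profiles (a 136-species flesh
  fly profile and a 44-species cockroach profile) that anchor the test
  suite.

Because the raw chromatograms behind the published profiles are not
publicly archived, the simulator is the package's test instrument: it
encodes the documented behavior of the physical system, and the annotation
pipeline is validated by round trips against its ground truth.

## Ion chemistry

APCI of aliphatic HCs produces, depending on the mobile phase:
deprotonated molecules [M−H]⁺ (dominant for saturated species), protonated
molecules [M+H]⁺ (dominant for unsaturated species at moderate toluene
content), radical molecular cations M⁺·, and solvent-derived adducts:
[M+C₃H₃]⁺ (+39, hexane plasma), [M+C₄H₉]⁺ (+57, isooctane),
[M+C₆H₁₃]⁺ (+85, hexane), and protonated-toluene adducts [M+C₇H₉]⁺ (+93).
All seven ship in `adduct_registry()`, are user-extensible, and are
serialized to a plain-text config (`inst/extdata/adducts.tsv`).

```{r}
adduct_registry()[, c("name", "nominal_offset", "monoisotopic_offset",
                      "source_solvent")]
ion_mz(hc_species(39, 2), "[M+H]+")   # the C39:2 protonated molecule
```

Monoisotopic cation masses subtract one electron mass; nominal masses use
integer C = 12, H = 1, matching the unit-resolution ion-trap data the
method was developed on. The default matching tolerance is ±0.3 Da
(configurable; the vendor software's tolerance was never published, so this
is a documented package choice), with a monoisotopic mode available for
high-resolution inputs.

A structural subtlety drives much of the design: an alkane's [M−H]⁺ and
the corresponding alkene's [M+H]⁺ are the *same ion formula*
CnH~2n+1~⁺. Mass alone cannot separate them; the chromatographic
unsaturation class can, which is why annotation is window-driven
(`candidates_for_mz()` is always restricted to the class of the retention
window containing the peak).

## The retention model

Species elute in class blocks ordered by DB count. The model is

> Rt = apex(system, T, DB) + s~DB~ · (CN − CN_ref~DB~) − Δtrans~DB~ +
> k · spacing

* `apex` — the class apex retention time for the (solvent system, column
  temperature) pair, shipped for all nine published combinations
  (`load_fixture("table2")`). The published row for system I at 15 °C has
  tied di-/tri-unsaturated apexes; the fixture keeps it verbatim and the
  model refuses to use it (class windows would be degenerate).
* `s_DB < 0` — within a class, heavier chains elute slightly earlier (a
  residual normal-phase mechanism). Defaults −0.005/−0.08/−0.25/−0.6
  min/carbon reproduce the printed within-class Rt spans (the saturated
  cluster spans ~7 s; the diene region several minutes).
* `CN_ref` — the class anchor, set to the most abundant species per class
  of the fly profile (C30:0, C39:1, C41:2, C43:3), because the published
  apex table reports "the most abundant peak" of each class.
* `Δtrans > 0` — all-trans species elute ahead of their cis counterparts.
  Defaults 6/14/20 min for 1–3 double bonds: large enough to produce the
  separated trans clusters reported for trace trans species, small enough
  that trans peaks stay inside their own class window.
* `k · spacing` — positional isomers sharing CN:DB are opaque
  elution-order slots spaced 0.4 min apart (the typical diene-region
  spacing), centered on the most abundant isomer. Double-bond *positions*
  are deliberately never named; localizing them needs MS/MS and is out of
  scope.

Peak shapes are Gaussian with class sigmas 0.02/0.04/0.08/0.12 min. The
saturated value reproduces the few-second saturated cluster; the upper
values were chosen to keep 0.4-min isomer spacing near baseline-separated,
as the published diene chromatograms show — wider peaks would fuse every
isomer pair, contradicting the observed resolution.

Run-to-run reproducibility is modeled as a run-level multiplicative drift
(sd 0.5 %, inside the published ~1 % same-day RSD) plus a small
per-species jitter (sd 0.02 min).

## The response model

APCI response grows with unsaturation, which is exactly why the package
(like the original method) only reports relative areas *within* a
double-bond class. Relative response defaults are 1:3:5:7 for 0–3 double
bonds (only the direction of the effect is documented; the magnitude is a
package choice and cancels out of all within-class quantities).

Adduct fractions over the hexane/toluene gradient are piecewise-linear in
%toluene with knots at 0/10/25/50/75/100 %. The knots are free
configuration; their defaults encode only the documented qualitative
shape: +39 dominates in pure hexane, [M+H]⁺ rises to a maximum at 40–60 %
toluene and declines after, saturated species are always [M−H]⁺-dominated,
and di-/tri-unsaturated species gain M⁺· and [M+93]⁺ at high %toluene.
Systems I and II use fixed profiles (analytes elute in nearly pure
hexane/isooctane). Each species also emits a low-mass CnH~2n+1~⁺ fragment
ladder below m/z 350 at 8 % of its adduct current, and intensities carry
multiplicative log-normal noise (sd 5 %) over a sparse random baseline.
No absolute intensity scale is modeled — the published work gives none —
so simulator units are arbitrary.

## The annotation pipeline

`annotate_run()` mirrors the published procedure:

1. **Class windows.** The time axis is split at midpoints between class
   apexes (`calibrate_class_windows()`); windows are configuration, not
   clustering, mirroring the known elution order.
2. **Summed-ion chromatograms.** For every candidate CN in the search grid
   crossed with the window's DB class, the chromatogram of the three
   quantification channels [M−H]⁺ + M⁺· + [M+H]⁺ is reconstructed
   (`extract_eic()`). Solvent adducts are identification evidence only —
   areas always come from these three ions.
3. **Peak detection.** Local maxima above a floor set relative to the
   strongest class signal (default 0.2 %), with three noise guards: an
   odd moving-average smoother sized to ~0.8 of the class peak sigma is
   used for apex/boundary finding only, apexes separated by valleys
   shallower than 60 % of the lower apex are fused, and peaks narrower
   than ~3 sigma of the class width are rejected as spikes. Areas are
   trapezoidal integrals of the **raw** trace between the boundaries.
4. **Ghost rejection.** Every annotation must show signal in at least two
   of the three quantification channels across the peak. Genuine species
   always do (the isotope envelope cross-feeds the three adjacent
   channels), whereas the one systematic in-window alias — the M+2
   isotope of a [M+39] adduct landing in the [M−H]⁺ channel of the
   species three carbons up — populates exactly one channel and is
   dropped. All other solvent-adduct aliases change the apparent DB class
   by ±1 or ±2 and are excluded by the window itself.
5. **Geometry.** Per class, a boundary retention time (default: class
   apex minus half the trans offset, i.e. between the trans and cis
   sub-clusters) splits trans calls from cis calls. An independent
   one-liner, `geometry_from_allylic_shift()`, encodes the NMR rule that
   distinguishes the isomers chemically: the allylic ¹³C resonates near
   32.6 ppm for trans and 27.2 ppm for cis (a −5.4 ppm steric upfield
   shift), split at the 30 ppm midpoint.
6. **Quantification and reporting.** Within-class relative areas
   (`quantify_within_class()`) always sum to 100 per class and are never
   compared across classes. Species below the reporting threshold
   (default 0.1 % — the published tables also excluded trans traces below
   an unstated threshold) move to a traces section; with `traces = TRUE`
   the detection floor drops to 10⁻⁵ of the class maximum so that
   trace-level trans counterparts (~10⁻³ of their cis partners) are still
   integrated, which is how the overall cis:trans area ratio is
   estimated.

```{r}
comp <- composition_from_report(load_fixture("table4"))
run <- simulate_run(comp, seed = 1)
ann <- annotate_run(run)
ann
head(ann$report[, c("cn", "db", "geometry", "rt_min", "rel_area_pct")])
evaluate_recovery(ann, run)[c("precision", "recall", "geometry_accuracy",
                              "area_rmse")]
```

## Numerical and design choices

* **Tolerances.** m/z matching ±0.3 Da (nominal mode) by default; the
  simulator places centroids at exact monoisotopic masses, so matching is
  insensitive to anything below ~0.5 Da. Fixture validators accept ±0.5
  around 100 for printed within-class sums (rounding of the published
  values), ±0.1 elsewhere.
* **Isotopes.** Patterns come from the exact convolution of the ¹³C
  (0.0107) and ²H (0.000115) binomials; three peaks per channel by
  default. The first-order M+1 approximation nC·0.0107 + nH·0.000115 is
  accurate to ~1 % for the relevant chain lengths.
* **Degenerate inputs.** Compositions must sum to 100 ± 0.1 within class
  and across class shares; species eluting outside the run are truncated
  with a warning and recorded in the run metadata; an empty run annotates
  to an empty report with a warning; a zero-area class is an error rather
  than a silent NaN.
* **Tie-breaks.** Candidate ranking is by |mass error|, then fewer double
  bonds, then lower CN — deterministic output for degenerate matches.
* **Determinism.** All randomness flows from explicit seed arguments; the
  global RNG stream is saved and restored, and equal seeds give
  byte-identical runs and artifacts.
* **Problem sizes.** The test suite simulates the full 44-species
  cockroach profile (about 16,000 scans at 2 Hz over ~137 min) once
  noiselessly and across ten seeds at default noise, and the 136-species
  fly profile with ~110 injected trans traces across five seeds for the
  cis:trans estimate; these sizes exercise every code path at full
  realism while keeping a complete check run in a few minutes.

## What the simulator does and does not establish

The generator reproduces the *documented, qualitative* behavior of the
physical system — class separation, trans-before-cis, carbon-number drift,
solvent-dependent adduct chemistry, unsaturation-dependent response,
isotope envelopes, noise and retention drift. Passing round-trip tests
therefore shows that the annotation logic correctly inverts every one of
those mechanisms at realistic signal levels.

It does not establish performance on real instruments: actual peak shapes
tail, adduct fractions vary in ways the piecewise-linear defaults only
sketch (the published intensity-vs-toluene curves were never tabulated),
co-eluting isobars can be worse than simulated, branched (methyl-alkane)
species — isobaric with straight chains and not resolved by the original
method either — are absent, and absolute sensitivities are arbitrary.
Fragment-ion spectra are modeled only as a featureless low-mass floor.

## Known limitations

* Geometry calls rely on the configured per-class boundary; mixed
  cis/trans species ("mixed" geometry) are not called, only all-cis vs
  all-trans.
* The cis:trans area ratio is estimated from raw summed areas across
  classes, as in the original report; it inherits the cross-class
  response caveat and is best read as an order of magnitude.
* Deconvolution beyond the class-window rule (e.g. true co-elution of
  same-class isobars) is out of scope, as is MS/MS interpretation and
  absolute quantification.
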