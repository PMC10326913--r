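---
title: "Methods: multi-attribute MRM quantitation for a cysteine-inserted antibody"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-attribute MRM quantitation for a cysteine-inserted antibody}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmqa)
```

## The assay this package models

A C239i antibody is an IgG1 engineered with an extra cysteine at position 239
of each heavy chain, used for site-specific drug conjugation. During
manufacture that inserted cysteine adopts several thiol states — both free
(2xSH), singly or doubly cysteinylated (1xSH/1xCys, 2xCys), or forming an
extra interchain disulfide between the two inserted cysteines (iDSB) — and
the molecule additionally varies in Fc N-glycosylation, interchain-disulfide
integrity, and polypeptide backbone fragmentation in the C~H~2 domain.

The monitoring method is a short, targeted LC-MS assay on a triple
quadrupole: free thiols are capped with N-ethylmaleimide (NEM,
+125.047679 Da) to freeze the thiol state, the protein is digested
non-reductively with Lys-C, and a panel of 36 MRM transitions (a Q1
precursor filter, a Q3 fragment filter, and a retention-time window each)
quantifies all four attributes relatively, in one injection. This package
implements everything downstream of the instrument: the chemistry that
defines each transition, panel construction and validation, relative
quantitation with ionization-bias correction, calibration, and a synthetic
data generator that makes the whole pipeline testable without an instrument.

## Mass engine

Peptide species are defined chemically: residue sequence, positioned
modifications (NEM, cysteinylation +119.004099 Da), an optional N-glycan
expressed in monomer counts (Hex 162.052824, HexNAc 203.079373, dHex
146.057909, NeuAc 291.095417 Da), and disulfide cross-links that remove
2.015650 Da each. All masses are monoisotopic; m/z uses the proton mass
1.007276 Da and the isotopologue spacing 1.003355 Da (the ^13^C–^12^C
difference). Fragment ions are standard b/y ions; when a fragment of a
cross-linked pair contains a linked cysteine the entire partner peptide
(less 2 H per link) rides along on the fragment — this is what makes e.g.
the y2 of the lambda-linked pair sit near 658 m/z rather than 209.

Aggregated (nominal-mass) isotopologue patterns are computed by convolving
per-element multinomial distributions built from natural abundances, with
exponentiation-by-squaring over atom counts. Numerical choices: patterns are
truncated at a caller-chosen maximum neutron offset and renormalized;
truncation is exact for retained offsets because convolution coefficients at
offset *k* are unaffected by discarding higher offsets. Argmax ties break
toward the lower offset. The test suite checks the convolution against an
exhaustive enumeration over all isotope assignments for molecules up to six
atoms, at 1e-12.

Two species needed interpretation:

* **The glycopeptide.** The panel's glycopeptide is taken as the 29-mer
  `TKPREEQYNSTYRVVSVLTVLHQDWLNGK` (H289–H317, sequon at N297). A 28-mer
  reading that drops the tyrosine of the `EEQYNSTYR` motif does not
  reproduce the panel's glycopeptide Q1 values; the 29-mer does, to
  within a few hundredths of an m/z at the appropriate isotopologue.
  Isoleucine/leucine are isobaric and are represented as leucine.
* **G1F-GN+NAc.** No tested composition back-calculates to the stored Q1
  (1291.4) within half an m/z; this compound is carried with its empirical
  Q1 only and is excluded from computed-mass validation.

## The panel: empirical versus computed m/z

Instrument-tuned Q1/Q3 values are authoritative for matching acquisition
exports: several precursors are acquired one to four neutrons above
monoisotopic (the 4+ hinge-dimer thiol states sit near the top of a broad
isotope envelope), and a few channels show sub-0.1-m/z quad-tuning offsets.
The panel therefore stores the empirical values, and `validate_panel()`
treats computed m/z as advisory: each defined species must have some
isotopologue k ≤ 5 within ±0.5 m/z of its stored Q1. For the NEM-capped
hinge dimer the k = 3 and k = 4 isotopologues are nearly tied as the
envelope maximum (they differ by under two percent in relative abundance),
so validation deliberately checks envelope membership rather than a
particular argmax.

Cross-talk validation flags compound pairs within `q1_tol` (default 2.0 m/z,
a unit-resolution quad plus the width of a 4+ isotope envelope) and `q3_tol`
(default 0.7 m/z) whose retention windows overlap. The default panel
intentionally reports the three cysteinylation-related 4+ precursors
(1476.7/1478.2/1479.7) as needing chromatographic separation — the assay
resolves them by gradient, not by mass — and these are findings, not
failures.

## Quantitation

All four statistics are ratios of corrected areas within one sample, so they
are invariant to total abundance:

* **Thiol state:** each state's corrected signal over the summed corrected
  signal of all four states, as a percentage (sums to 100 by construction).
* **Partial reduction:** per bond, reduced / (reduced + linked). The
  heavy–light bond uses the kappa or lambda C-terminal peptide pair
  (isotype auto-selected from whichever linked compound carries signal);
  the heavy–heavy bond uses the reduced hinge peptide against the summed
  hinge-dimer thiol-state signal, which is the assembled-molecule
  denominator for that bond.
* **Glycoforms:** conversion-corrected areas renormalized to 100, plus the
  summed sialylated percentage (G1FS, G2FS, G2FS2, G1F-GN+NAc).
* **Fragmentation:** sites with an intact parent peptide in the panel are
  reported as frag / (frag + parent); sites on the multiply-cleaved
  glycopeptide region are reported relative to the conserved C~H~3 standard
  peptide. The vs-standard ratio is not bounded by 100 and is flagged,
  because multiple fragments of one molecule can be counted.

Correction conventions are explicit in the `correction_model` class:
blend-derived response factors *divide* raw areas (they encode relative
ionization propensity with the reference at 1), while orthogonal-bridge
glycan conversion factors *multiply* raw areas before renormalization. The
provenance field ("blend-fit", "equimolar-mix", "orthogonal-bridge") keeps
the direction unambiguous in serialized models. Missing denominator
compounds are hard errors; quantitation never silently renormalizes around
an absent reference.

Transitions of the same analyte (two Q3 channels for most peptides) are
summed before quantitation; compound ids are `"<analyte>.<fragment label>"`
so the grouping is visible in every table.

## Calibration

* `fit_expected_observed()` regresses measured on expected proportions,
  linearly or with a quadratic term. "Second order" is implemented as a
  second-degree polynomial: the curvature induced by modest response-factor
  differences between blended states is well captured by the quadratic term,
  and nesting guarantees its R² is at least the linear one.
* `estimate_response_factors()` estimates relative ionization propensity
  from a blend series. Because measured *shares* are ratios
  (RF~i~e~i~ / Σ~j~RF~j~e~j~), a share-on-share slope is biased; the
  implemented estimator is the slope through the origin of the share ratio
  (compound over reference) against the expected ratio, which is exact under
  the proportional-response model, scale-invariant, and recovers a simulated
  factor of 0.90 to three decimals on noiseless data. Factors are
  normalized to the reference compound. An intercept-free ratio fit was
  chosen deliberately: the factor is a ratio of sensitivities and must pass
  through the origin.
* `equimolar_mix_factors()` implements the 1:1 reduced:nonreduced mix: in an
  equimolar sample the area ratio of a bond's reduced and linked compounds
  *is* their relative response, and applying it forces the mix to quantify
  at 50 %.
* `derive_glyco_conversion()` bridges to a released-glycan method by the
  per-glycoform mean (or median, for outlier-robust use) of
  orthogonal-to-raw percentage ratios over training lots.
* `fit_response_surface()` fits an ordinary least-squares quadratic surface
  (linear + quadratic + pairwise interactions) over electrospray source
  parameters, centered and scaled to a coded [-1, 1] cube internally, with
  raw per-coefficient t-test p-values — raw, because the DoE practice being
  mirrored reports unadjusted p-values, and the type-I error of that choice
  is itself verified in the test suite.

## The synthetic data generator

The simulator exists so that every downstream stage has an exact oracle; its
defaults are the study conditions the method was developed under, not tuning
knobs:

* Ground truth: exclusively oxidized thiol states with iDSB near 20 % (the
  level observed across clones in bioreactor material), a complex
  biantennary glycan profile with ~20 % sialylated species (the elevated
  sialylation that motivated monitoring it), low single-digit partial
  reduction, and percent-level site fragmentation.
* Instrument: per-analyte response factors (reference 1), optional
  second-order bias (response = RF·x + c2·x²), multiplicative lognormal
  noise at a default CV of 1 % (areas are positive; the CV parameterization
  makes noiseless and noisy runs directly comparable), retention-time jitter
  (SD 0.02 min) truncated so a peak apex never leaves its integration
  window, and Gaussian peaks of SD 0.05 min.
* In-source fragmentation: a fraction f of each sialylated glycoform's area
  moves one step down a decomposition chain (G2FS2 → G2FS → G2F,
  G1FS → G1F; one NeuAc per step), conserving total glycoform area exactly.
  f is a scaled logistic in desolvation temperature plus linear terms in
  desolvation gas flow and capillary voltage, monotone in temperature, with
  a ceiling of 0.30. The ceiling and coefficients are modeling choices (the
  assay's optimized operating point makes the real leak negligible, so no
  magnitude is available to match); they are chosen so a response-surface
  fit recovers temperature and gas flow as the dominant, significant
  factors, which is the qualitative behavior the DoE is meant to surface.

What the simulator does *not* emulate — and therefore what passing tests do
not show about real data: chromatographic interference between transitions
(areas are generated per compound, so cross-talk findings are structural,
not simulated), matrix effects and carry-over, isotope-resolved traces,
drift across batches, and real TargetLynx integration behavior. Round-trip
identity on simulated data validates the algebra of the pipeline, not the
chromatography.

## Problem sizes and determinism

The test suite runs the quantitation invariants on 1000 randomly drawn
simulated samples, calibration on 11-level blend series, glycan bridging on
8 lots (4 training, 4 held out, nine glycoforms), fragmentation titrations
on 7 levels, and the type-I-error calibration of DoE coefficient tests on
500 pure-noise designs — sizes chosen to make the statistical checks sharp
while keeping the suite quick on a laptop. All simulation entry points take
a single integer seed; identical seeds give byte-identical peak tables,
chromatograms, and reports, which the suite asserts end-to-end.

## Known limitations

* Absolute quantitation (moles or milligrams) is out of scope; everything is
  relative within a sample.
* The vs-standard fragmentation ratio can double-count molecules fragmented
  at several sites; it is reported unbounded and flagged rather than capped.
* Isotope patterns are aggregated by nominal mass; fine structure within an
  isotopologue is not modeled, and quad tuning offsets below ~0.3 m/z are
  treated as empirical rather than explained.
* mzML support covers reading SRM chromatogram lists (plus a minimal writer
  used to exercise that path); vendor raw files and acquisition-method
  export are out of scope.
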