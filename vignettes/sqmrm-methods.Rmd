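---
title: "Targeted MRM quantification of sulfoquinovosyl lipids: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted MRM quantification of sulfoquinovosyl lipids: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sqmrm)
```

## The analytical problem

Sulfoquinovosyldiacylglycerols (SQDGs) and their mono-acyl counterparts
(SQMGs) are sulfolipids of photosynthetic membranes: a glycerol backbone
carrying one or two esterified fatty acids and a sulfoquinovose headgroup
(6-deoxy-6-sulfo-glucose, with a stable C–S bond). They occur in
cyanobacteria such as *Arthrospira* (spirulina), in microalgae, and in leafy
vegetables, and their nutritional and pharmacological role is debated —
which makes species-resolved quantification, rather than a sum parameter,
the analytically interesting problem.

The strongly acidic sulfonate makes these lipids excellent negative-mode
electrospray analytes: they deprotonate to \[M−H\]⁻ quasi-molecular ions,
and collision-induced dissociation produces two informative fragment
families. Headgroup fragments (nominal m/z 81, 125, 153, 165, 225, 255) are
shared by all sulfoquinovosyl lipids and identify the class; neutral losses
of the fatty acids (as free acid or ketene) differ between acyl
compositions and identify the chains. A triple-quadrupole instrument
monitoring fixed precursor→product pairs (multiple reaction monitoring,
MRM) combines both: the sulfonate ion (m/z 80–81) as quantifier and further
headgroup ions as qualifiers, with liquid chromatography adding the
separation that distinguishes species whose fragments barely differ.

`sqmrm` implements the in-silico side of such a method end to end: the mass
model, fragment prediction, the transition panel, peak processing on MRM
traces, internal-standard calibration with validation statistics, and a
simulator that generates every input with known ground truth.

## The mass model

A species is assembled from the sulfoquinovosyl-glycerol core
C~9~H~18~O~10~S plus one (SQMG) or two (SQDG) acyl chains, minus one water
per ester bond. A chain "C:D" (total carbons : double bonds) contributes
the free-acid composition C~n~H~2n−2d~O~2~. Two mass scales are kept
strictly separate:

* **monoisotopic** m/z, from standard monoisotopic atomic masses, with
  \[M−H\]⁻ = M − 1.00783 (the electron mass is ignored; the error is below
  1 mDa, far below unit resolution);
* **nominal** m/z, from integer mass numbers, never by rounding the
  monoisotopic value. The distinction matters: SQDG(16:0/18:2) has
  monoisotopic \[M−H\]⁻ 817.51, which would round to 818, while its nominal
  mass is 817.

Display names follow the panel convention `<class> <nominal [M−H]⁻>`
("SQDG 815" is 16:0/18:3). The commercially available standard is sold
under its neutral nominal mass ("SQDG 816"); that vendor name is stored as
an alias so both conventions resolve to the same species.

Because unit-resolution MRM cannot separate isobaric acyl combinations,
`enumerate_species()` lists every unordered chain combination from a
configurable fatty-acid pool that reaches a given nominal precursor mass
(815 → 16:0/18:3 and 16:1/18:2). The default pool
(14:0, 15:0, 16:0, 16:1, 17:0, 18:0, 18:1, 18:2, 18:3, 18:4, 20:4, 20:5,
22:6) collects chains common in cyanobacterial, microalgal and plant
glycolipids; it is an argument everywhere because the biologically
admissible set depends on the matrix. Chain pairs are unordered: precursor
mass carries no positional information, and sn regiochemistry is handled at
the fragmentation level, where the loss of the sn1 fatty acid gives the
more intense fragment (`rank_sn_assignment()`; ties or missing intensities
are reported as ambiguous rather than guessed).

Two of the six diagnostic ions (m/z 125 and 255) have no established
elemental assignment; they are implemented with plausible formulas
(C~2~H~5~O~4~S⁻, palmitate C~16~H~31~O~2~⁻) but flagged
`assignment_uncertain`, and candidate matching in `annotate_precursor()`
uses only nominal values for the diagnostic family. Acid/ketene-loss
fragments are matched on monoisotopic m/z, since they carry the
discriminating evidence. No fragment intensities are predicted — there is
no defensible intensity model at this level — so candidate ranking uses
match counts with total absolute mass error as tie-break.

## The transition panel

The bundled reference panel (`sq_reference_panel()`) holds 27 analytes × 3
transitions: 25 SQDGs, one SQMG (555, the single-chain solution 16:0), and
a sulfogalactosylceramide internal standard (ISD). Panel CSVs use a fixed
schema and are validated on load (three transitions per analyte, exactly
one quantifier, precursor > product > 0, positive dwell times) with the
offending line reported. Product ions carry instrument-tuned decimals
(80.6–81.1 for the sulfonate ion), so matching uses a 0.5 m/z tolerance
instead of exact equality, and the 224/225 variation is treated as the same
dehydrated-sulfoquinovose ion with a tuning offset. Two analytes (867, 871)
have no retention time; they are screening-only entries, skipped by
retention-time assignment and by the simulator (with a warning). The ISD's
printed molar mass (794 g/mol) and precursor (792.0) are both kept as
printed.

## Peak processing

Traces are long tables (channel, time in minutes, intensity); mzML
chromatogram lists are read through `mzR` with seconds converted on read.
Detection per channel is deliberately simple and fully deterministic:

* smoothing: 5-point centred moving average (configurable, width 1 = off);
* baseline: rolling minimum over a 2-min window — simple, reproducible,
  and adequate for well-separated MRM peaks;
* noise: median absolute deviation of the baseline-corrected trace, so a
  noise-free peak has effectively infinite signal-to-noise ratio;
* peaks: local maxima above `min_snr` (default 3, the conventional
  detection floor), boundaries at the nearest valley or where the signal
  falls below 1% of apex height;
* area: trapezoidal integration of the baseline-subtracted signal. On a
  densely sampled Gaussian this reproduces the closed form A·σ·√(2π)
  within 1%, which is also the acceptance bar for the simulator round
  trip.

Peaks are assigned to their channel's analyte when the apex lies within
`rt_tolerance_min` (default 0.5 min) of the panel retention time; multiple
peaks in a window resolve to the largest area with a flag, never silently.
Co-eluting isomer deconvolution and cross-batch retention-time alignment
are out of scope.

## Calibration, quantification, validation

The method quantifies against an internal standard at constant
concentration: the response of a level is the analyte/ISD area ratio, which
cancels run-to-run ionisation drift. `fit_calibration()` regresses response
on concentration by ordinary least squares (1/x weighting available, but
unweighted is the default design); the reference design is 10 equidistant
levels over 1–10 µg/mL with ISD at 5 µg/mL.

Limits are derived from the regression statistics (the
calibration-curve method): LOD = 3.3·σ/S, LOQ = 10·σ/S with σ the residual
standard deviation and S the slope, so LOQ/LOD = 10/3.3 identically. The
formula choice is recorded in the fitted object (`lod_method`), since
several national-standard variants of the calibration method exist and
differ in constants.

Back-calculation inverts the line, floors negative estimates at zero and
flags them `<LOD`; content per dry weight is concentration × extract volume
× dilution / sample mass, and composition shares are percentages of the
summed content over analytes at or above the LOQ. Analytes without an
authentic standard are quantified on the one available SQDG curve
(single-standard surrogate calibration) — the report marks this, because
response factors of other species are not guaranteed equal.

Validation statistics follow bioanalytical practice: per QC level, CV =
sample SD (n−1) / mean × 100 within a day (intra-day, averaged over days)
and pooled over all replicates of all days (inter-day); accuracy = mean
back-calculated / nominal × 100; a level passes when both CVs are below the
threshold (default 15%, the FDA precision bound). Recovery is
(c~sample~ − c~endogenous~)·100/c~spiked~ and is affine-invariant under
common rescaling, as CV is scale-invariant — both properties are tested.

## The simulator

Every pipeline stage is testable without instrument data because the
simulator generates the study designs with ground truth attached:

* `simulate_run()`: per transition, a Gaussian peak (σ default 0.15 min) at
  the panel retention time, area = response factor × concentration, with
  qualifiers at fixed fractions (0.4/0.2) of the quantifier. The default
  response factor, 2·10⁴ counts per (µg/mL), puts the ISD at 5 µg/mL at an
  integrated 10⁵ counts, a realistic triple-quadrupole scale. The run is 52
  min at 0.01-min sampling, covering the full LC program (gradient ramp,
  34-min hold, re-equilibration) and therefore all panel retention times up
  to 36 min.
* area noise is multiplicative lognormal, parameterised by its exact CV and
  mean-one, matching the heteroscedastic behaviour of LC-MS peak areas
  (the constant-CV regime) rather than additive noise; baseline noise is
  additive Gaussian, clamped at zero intensity. This choice is a model of
  convenience: real noise has additional structure (spikes, drift, ion
  suppression) that is deliberately not simulated.
* `simulate_calibration()` and `simulate_validation_study()` generate the
  10-point calibration and the QC designs at the response level. QC
  defaults are four levels (2, 4, 6, 8 µg/mL) spanning the calibration
  range with five replicates per day over three days; the level count is
  an argument since validation protocols vary. Day effects are a shared
  lognormal multiplier per day, so inter-day CV exceeds intra-day CV
  exactly when a day effect exists.

All generators take a `seed` and restore the RNG state afterwards; the same
seed reproduces the same data bit for bit.

What passing tests on simulated data do and do not show: they verify the
algebra and the processing chain (peak areas within 1% of configured truth
at zero noise; concentrations within 5% of truth at 1% noise above the
LOQ; sample-CV estimates averaging 4–6% at 5% generative noise over 200
seeds, the small-sample bias of the SD estimator included), not
chromatographic reality — matrix effects, co-elution, carryover and
ion suppression are outside the simulator, so real-sample figures of merit
(LOQ, recovery) must come from bench validation, not from this package.

## Numerical choices and problem sizes

* Formula arithmetic is exact integer bookkeeping over C, H, N, O, S;
  monoisotopic masses are double precision.
* Nominal masses are computed from mass numbers, never rounded (see above).
* Matching tolerances default to 0.5 m/z (unit-resolution quadrupoles) and
  0.5 min retention time; both are arguments.
* Degenerate calibration inputs (constant concentration or constant
  response) raise singular-fit errors instead of returning meaningless
  coefficients; LOD/LOQ require a positive slope.
* Zero-chain ("core only") species are representable in the formula model
  but rejected by fragment prediction, which has nothing to lose.
* Tests run the enumeration oracle over all precursors 500–900 and full
  simulated runs over the 25 analytes with retention times (75 channels ×
  5201 points); the complete suite and the acceptance script each finish in
  a few minutes on one CPU.

## Known limitations

* Fragment intensities, collision-energy dependence, and positive-mode
  adducts are not modelled.
* Oxidised/hydroxylated or cyclopropane acyl chains are outside the chain
  grammar.
* Surrogate calibration assumes equal response factors across species;
  reported concentrations for species without standards inherit that
  assumption.
* The rolling-minimum baseline under-corrects slow drifts comparable to
  the window width; the window is configurable.
* mzML support covers chromatogram lists (SRM traces), not spectra.
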