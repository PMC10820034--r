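---
title: "Linking EI fragment spectra to soft-ionization molecular ions"
author: "ionlink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking EI fragment spectra to soft-ionization molecular ions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionlink)
```

## The problem

Electron ionization (EI) at 70 eV produces rich, reproducible fragment
spectra with excellent library support, but frequently no molecular ion:
the molecular mass of an unknown is simply not in the spectrum. Soft
techniques — chemical ionization (CI) with methane, or APCI — preserve the
molecular species as [M+H]+ plus characteristic reagent-gas adducts, but
fragment too little to identify a compound. Running both on a GC-HRMS
system yields two separate datasets per sample, and connecting "this EI
fragment spectrum" to "that CI molecular ion" is normally manual, per-peak
expert work: retention times shift between runs, per-compound response
differs between sources, and a CI pseudospectrum can contain many ions of
which at most one is the molecular species of interest.

ionlink automates that assignment. Its inputs are the deconvoluted peak
lists of both runs (any pipeline that exports feature m/z, retention time,
intensity, and pseudospectrum membership will do — XCMS/CAMERA, vendor
tools, ...), optionally the raw mzML/mzXML files, and optionally a table of
retention-time standards. Its output is, per EI pseudospectrum, a ranked
list of molecular-ion candidates with probability scores and, where
resolvable, a molecular formula.

## The procedure

1. **Size filter.** Pseudospectra with fewer than `min_features` features
   (default 20 in both runs) carry too little information and are removed.
2. **Isotopologue flagging.** Within each pseudospectrum, features sitting
   0.9970–1.0100 u (M+1) or 1.9940–2.0100 u (M+2) above a strictly more
   intense feature are flagged. Flagged features are excluded from formula
   work and from candidate seeding, but are retained as isotope-pattern
   evidence.
3. **Retention-time correction and matching.** If standards are given, the
   molecular-ion run's time axis is mapped onto the fragment run's by
   linear interpolation through the standard pairs (constant shift beyond
   the outermost pair). Every CI pseudospectrum whose corrected time lies
   within `rt_tolerance` (default 0.05 min, inclusive) of an EI
   pseudospectrum is attached to it.
4. **Candidate search.** An unflagged CI feature X becomes a molecular-ion
   candidate when at least `min_found` (default 2) of the configured m/z
   differences d (default +28.03130, +40.03130, −16.03130: the methane-CI
   [M+C2H5]+/[M+C3H5]+ adducts and the CH4 loss) have a matching ion at
   X + d within `ppm` (default 3). Satellites are looked up in the
   pseudospectrum first and, failing that, in the raw file — adduct ions
   are often too weak for deconvolution but plainly visible in raw scans.
5. **Candidate reduction.** Per EI pseudospectrum the pooled candidates are
   cut to the `top_x` (default 10) highest m/z — in soft ionization the
   highest-mass signals are the most plausible molecular ions. With APCI
   data, where molecular ions dominate intensity, ranking by intensity is
   available instead; the cut can also be disabled.
6. **Formula enumeration and filtering.** Candidate and fragment formulas
   are enumerated under the element constraints (default C, H, N, O, S, Si,
   P, each 0–50) within `ppm`, then filtered by common-range element-ratio
   heuristics and an RDBE floor, and finally vetoed if a required S/Cl/Br
   A+2 isotope peak is absent (see below).
7. **Bottom-up chained assignment.** EI fragments are processed in
   ascending m/z. Because mass accuracy is relative, small ions usually
   admit a single formula; each resolved small fragment then disambiguates
   larger ones: an ambiguous fragment adopts the formula best supported by
   the summed weights of previously resolved fragments that are subformulas
   of it.
8. **Scoring and ranking.** Each candidate formula F is tested as its
   [M+H]+ composition; its probability score is the percentage of resolved
   fragment evidence it explains (weighted as below). Candidates are ranked
   by score.

## The weight and the score

A fragment of m/z $m$ and base-peak-relative intensity
$I_\mathrm{rel} \in (0, 1]$ contributes

$$w = m \times \ln(I_\mathrm{rel} \cdot 100 + 1).$$

The logarithm stops one or two dominant fragments from deciding everything;
the m/z factor rewards heavy fragments, which constrain the molecular
composition far more than light ones even when weak. With $D$ the sum of
$w$ over all *resolved* fragments, a candidate's score is
$100 \cdot \sum_{\text{supported}} w / D$, the percentage of resolved,
weighted intensity whose formulas fit inside the candidate's [M+H]+
composition. Unresolved fragments (several formulas, none supported — e.g.
noise, or a fragment introducing an element unseen below it) contribute
neither to any numerator nor to $D$, which keeps the score a well-defined
fraction in [0, 100].

Ties are broken towards higher m/z, then towards smaller formula mass
error. The high-m/z tie-break is deliberate: a heavier co-eluting compound
whose composition contains the true molecular ion's fragments scores at
least as high, and the tool prefers to surface it explicitly (see
Limitations) rather than hide the ambiguity.

## Conventions and numerical choices

* **Ion mass conventions.** EI fragments are enumerated as generic cations
  (composition mass minus one electron mass, 0.00054858 u); CI candidates
  as protonated molecules (neutral + H − e−), and the reported formula is
  the neutral M. At m/z 180 and 3 ppm the electron mass is the same order
  as the tolerance window, so the convention matters and is applied
  consistently on both sides of every comparison.
* **RDBE floor −0.5.** Ring-and-double-bond equivalents
  $C - (H + \mathrm{Cl} + \mathrm{Br})/2 + N/2 + P/2 + \mathrm{Si} + 1$
  must be ≥ −0.5 so that both odd-electron (radical) and even-electron
  fragment cations pass. Bromine counts as a halogen exactly like chlorine.
* **Ratio bounds.** H/C ∈ [0.1, 6], N/C ≤ 4, O/C ≤ 3, P/C ≤ 2, S/C ≤ 3,
  Si/C ≤ 1, Cl/C ≤ 2; applied only when carbon is present. These are
  common-range heuristics for small molecules, with silicon given room for
  TMS-derivatized analytes; all bounds are configurable.
* **Isotope veto is presence-only.** S, Cl and Br have strong, cleanly
  separated A+2 isotopologues (offsets 1.99580, 1.99705, 1.99796 u). A
  formula containing one of these elements is vetoed only when the A+2
  companion is missing — no abundance-ratio fit is attempted, so a poor
  intensity estimate can never falsely rule an element out. The check
  prefers raw data (deconvolution often drops weak isotope peaks) and falls
  back to the pseudospectrum's features, where flagged M+2 peaks count as
  evidence.
* **Isotope windows.** The M+1/M+2 flagging windows ([0.9970, 1.0100] and
  [1.9940, 2.0100] u) cover the 13C, 15N, 18O, 34S and 37Cl spacings.
* **RT model.** The inter-run shift is modelled as piecewise linear through
  the standards — the minimal model consistent with several standards — and
  inverted exactly by interpolating the inverse map; the correction is
  exact at every standard, and an affine distortion spanned by two
  standards is recovered to numerical precision. Window comparisons are
  inclusive with a 1 ns epsilon so printed settings behave predictably.
* **Subformula slack.** Fragments are tested against the [M+H]+ composition
  (neutral + 1 H), granting exactly one hydrogen of slack relative to M and
  no more; adduct chemistry during fragmentation is out of scope.
* **Enumeration cap.** The bounded nested search visits at most 1e7 count
  assignments (heaviest element outermost, suffix-mass pruning); wider
  windows raise a resource error instead of running unbounded.
* **Candidate deduplication.** The same ion found in several matched CI
  pseudospectra (same m/z within ppm, retention time within tolerance) is
  reported once, keeping the most intense record.
* **Resolver tie-break.** When several formulas of an ambiguous fragment
  receive identical support, the one with the smallest mass error is
  assigned; when all receive zero, all are retained and the fragment stays
  unresolved.

## The synthetic study

Real validation of this kind of tool needs instrument files and a
deconvolution pipeline; for development and regression testing the package
instead ships a generator whose defaults define a fixed synthetic study:

* 50 compounds (element pool C/H/N/O/S, masses 120–450 u, RDBE 1–6),
  12–16 fragments each, carved from the [M+H]+ composition by chains of
  common neutral losses, so the subformula assumption holds by
  construction;
* full methane-CI satellite patterns on every compound, M+1 peaks on
  intense carbon-rich fragments, exact-offset A+2 companions for S/Cl
  compounds;
* 5% noise features (Poisson-placed, rejected near positions that could
  fake adduct evidence), pseudospectra padded to 20 features as busy
  deconvolution exports are the norm;
* 20% of compounds carry a deliberately mass-ambiguous fragment (≥2
  formulas within 3 ppm under the default constraints — e.g. the
  C4H8S/C3H8OSi twin at 0.23 mu) to exercise the chain resolver; the
  remaining fragments are verified unique within the pool by enumeration;
* an affine retention-time distortion between the runs, corrected through
  standards;
* raw runs rendered as centroided scans with a Gaussian elution profile.

Under these conditions the true molecular ion is recovered at rank 1 for
essentially every compound, and the acceptance script
(`scripts/acceptance.R`) recomputes exactly that. Difficulty knobs —
satellite omission, co-elution injection of a heavier companion compound
(+C4H8O), higher noise — reproduce the known failure classes: omitted
satellites yield an empty candidate list ("no molecular ion found"), and a
heavier co-eluting compound whose composition subsumes the truth outranks
it via the high-m/z tie-break while the truth stays in the top handful.

What the generator does **not** emulate: chromatographic peak-shape
artifacts and deconvolution errors (split or merged pseudospectra), mass
calibration drift, detector saturation, real CI gas-phase chemistry beyond
the configured differences, and spectra whose fragments violate the
subformula assumption (rearrangements with adduct incorporation). Passing
the synthetic study therefore demonstrates the correctness of the
machinery, not field performance on any particular instrument; the
test-suite problem sizes (50-compound study, 200-instance enumeration
oracle sweep, 15-compound co-elution set) were chosen as the smallest that
exercise every code path with comfortable statistical margin.

## Limitations

* If ionization produces no molecular species or none of the configured
  differences, the candidate list is empty by design; no algorithm can
  conjure the molecular ion back.
* Co-eluting heavier compounds can legitimately outrank the true molecular
  ion (tie-break above); treat the top few candidates as a shortlist, not
  a verdict.
* Scores compare candidates within one fragment pseudospectrum; they are
  not calibrated probabilities and should not be compared across spectra.
* The tool ranks molecular-ion *candidates*; formula assignment for the
  winner can still be ambiguous (near-isobars such as C+S vs Si+O at
  0.23 mu survive all filters when both elements are allowed).
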