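# ionlink

Automated assignment of molecular ions to fragment spectra across the two
runs of a complementary-ionization GC-HRMS experiment.

Electron ionization (EI) gives fragment-rich, library-searchable spectra
that often lack the molecular ion; soft ionization (methane CI, APCI)
preserves the molecular species as [M+H]+ with characteristic adducts but
barely fragments. Identification workflows need both: the molecular mass to
query compound databases, and the fragments to confirm. ionlink connects
the two deconvoluted datasets automatically — per EI pseudospectrum it
returns a ranked list of molecular-ion candidates from the soft-ionization
run, with probability scores and molecular formulas.

The method, per fragment pseudospectrum:

1. drop undersized pseudospectra, flag M+1/M+2 isotopologue peaks;
2. match pseudospectra between runs by retention time (±0.05 min default),
   after piecewise-linear correction through retention-time standards;
3. find candidate ions displaying the expected adduct/neutral-loss pattern
   (defaults: ≥2 of +28.03130, +40.03130, −16.03130 within 3 ppm — the
   methane-CI [M+C2H5]+/[M+C3H5]+ adducts and CH4 loss), searching raw
   mzML/mzXML scans for satellites the deconvolution missed; keep the
   top 10 candidates by m/z;
4. enumerate elemental formulas for fragments and candidates under element
   constraints (C,H,N,O,S,Si,P 0–50 by default) at 3 ppm, filtered by
   element-ratio heuristics, an RDBE floor, and a veto on S/Cl/Br formulas
   whose diagnostic A+2 isotope peak is absent;
5. resolve fragment formulas bottom-up in ascending m/z — each resolved
   small fragment disambiguates larger ones through the subformula
   relation — with every fragment weighted by

   w = m/z × ln(Int_rel × 100 + 1);

6. score each candidate as the percentage of resolved, weighted fragment
   evidence whose formulas fit inside its [M+H]+ composition, and rank.

## Worked example

Everything is testable without instrument data: the package ships a
generator for paired EI/CI datasets with known ground truth.

```r
library(ionlink)

dir <- tempfile()
fx <- makeFixtureDataset(dir, n = 6, seed = 1, ambiguityRate = 0.2,
                         render = list(rtShift = c(1, 0.03), noiseRate = 0.05))
std <- file.path(dir, "standards.csv")
write.csv(data.frame(ei = c(4.2, 6.3), ci = c(4.23, 6.33)), std,
          row.names = FALSE)

cfg <- runConfig(ei_peaks = fx$ei_peaks, ci_peaks = fx$ci_peaks,
                 out = file.path(dir, "results.csv"), rt_standards = std)
res <- runPipeline(cfg)
#> read: 169 EI features in 6 pseudospectra; 121 CI features in 6 pseudospectra
#> size filter (>=20/20 features): 6 EI and 6 CI pseudospectra kept
#> RT correction through 2 standard pairs
#> RT matching (±0.05 min): 6 of 6 EI pseudospectra have CI partners
#> ranking: 6 EI pseudospectra assigned candidates, 0 without molecular ion
#> results written to .../results.csv

head(subset(res, rank == 1))
#>   ei_group_id rank candidate_mz candidate_rt assigned_formula probability_score
#> 1      EI_001    1      147.117      4.36357           C11H14          100.0000
#> 2      EI_002    1      165.055      4.68485           C9H8O3           94.5636
#> 3      EI_003    1      218.154      5.05068         C14H19NO           79.2072
#> 4      EI_004    1      197.117      5.38440         C11H16O3           87.7375
#> 5      EI_005    1      143.143      5.72803           C9H18O          100.0000
#> 6      EI_006    1      249.258      6.11693           C18H32          100.0000
```

Each row is the best molecular-ion candidate for one EI pseudospectrum:
its m/z and corrected retention time, the neutral formula it resolves to,
the probability score (percentage of weighted, formula-resolved fragment
evidence consistent with that composition), and the adduct differences that
identified it. All six recovered formulas match the generator's ground
truth (`read.csv(fx$truth)`). Spectra whose soft-ionization chemistry
produced no adduct pattern are reported with no candidates rather than a
guess.

The same run is available from the shell:

```sh
inst/scripts/ionlink run --ei-peaks ei_peaks.csv --ci-peaks ci_peaks.csv \
    --rt-standards standards.csv --out results.csv --ppm 3 --top-x 10
```

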