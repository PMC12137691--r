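# tracerMID

Quantitative stable-isotope tracing of carbon metabolism in anaerobic,
hydrocarbon-degrading cultures. The package asks — and answers, for
simulated or measured GC-MS data — the question posed by
naphthalene-degrading sulfate reducers such as culture N47: is anabolic
acetyl-CoA taken directly from substrate degradation (heterotrophy), or is
the substrate oxidized to CO2 and biomass carbon re-fixed from the
inorganic pool (chemoorganoautotrophy)?

It is written for microbial physiologists and isotope-tracing
practitioners who have SIM (selected-ion-monitoring) intensities of TBDMS
amino acid fragments and fatty-acid McLafferty fragments from dual-tracer
experiments ([U-¹³C₁₀]substrate vs. H¹³CO₃⁻) and need the complete chain
from raw channel intensities to a metabolic verdict.

## The models at the core

**Binomial labeling.** If each of a molecule's *n* carbons is ¹³C with
probability *p*, the M+*k* isotopologue has probability
*p*<sub>*k*</sub> = *p*<sup>*k*</sup>(1−*p*)<sup>*n*−*k*</sup> C(*n*,*k*).
Independent fixation from a 10 atom% CO2 pool therefore gives an acetyl
unit only ~1% M+2 ("statistical coupling"), while direct transfer of
intact acetyl units from a 10 mol% uniformly labeled substrate gives 10%
M+2 — the fingerprint that separates the two lifestyles.

**Pool mass balance.** Bottle enrichment bounds come from
¹³C / (C<sub>naphthalene</sub> + C<sub>bicarbonate</sub> +
C<sub>headspace</sub>): 0.45/8.75 = 5.1% under the bicarbonate tracer,
0.345/8.75 = 3.9% for fully oxidized substrate tracer.

**Three-step MID correction.** Measured spectra are deconvolved by
non-negative least squares in three steps: (1) fit the
derivatization-reagent mass-shift vector against an unlabeled standard,
(2) remove it from the enriched sample to get the absolute skeleton
isotopologue distribution, (3) remove skeleton natural abundance
(lower-triangular binomial matrix — a labeled carbon cannot also shift
naturally) to get ¹³C excess per isotopologue.

**Scenario inference.** Predicted metabolite MIDs under direct
assimilation, chemoorganoautotrophy, carboxyl exchange, or any mixture;
least-squares estimation of the autotrophic fraction *f* of anabolic
acetyl-CoA with a bootstrap interval; rule-based classification of the
metabolism from both tracer settings.

A seeded synthetic-data generator (3×3 replicates, 0.3 pp biological sd,
2.5% technical cv) and spectrophotometric enzyme-assay reduction
(Beer–Lambert, nmol min⁻¹ mg⁻¹ protein) complete the pipeline.

## Worked example

```r
library(tracerMID)

demo <- runDemo(seed = 7)
demo$classification$label
#> [1] "chemoorganoautotrophic"
round(demo$mixtureFit$f, 3)
#> [1] 0.982
head(demo$summary, 4)
#>             tracer  fragment predicted_M1 observed_M1 predicted_M2 observed_M2
#> 1 naphthalene_U13C   alanine     10.91419    10.96596    0.4479948   0.1720988
#> 2  bicarbonate_13C   alanine     13.88244    13.36610    0.7526624   0.9000573
#> 3 naphthalene_U13C aspartate     13.97848    13.70992    0.8606621   0.9138247
#> 4  bicarbonate_13C aspartate     17.55798    16.92731    1.4279081   1.3626279
```

`runDemo()` simulates both tracer settings plus an unlabeled control under
the chemoorganoautotrophic scenario at the reference bottle pools,
corrects the SIM intensities, and reports predicted vs. observed excess
(percent M+1/M+2 per fragment), the classification, and the fitted
autotrophic fraction (here f̂ ≈ 0.98 with truth 1; the bootstrap interval
is in `demo$mixtureFit$ci`). M+1 exceeds M+2 for every fragment under both
tracers — the qualitative signature of acetyl-CoA built from CO2 — while
direct assimilation would have put ~10% M+2 on the naphthalene-tracer
rows.

Single quantities work the same way:

```r
round(100 * binomialPk(0.051, 3, 1), 1)            # alanine M+1 at 5.1%
#> [1] 13.8
round(100 * poolMaxEnrichment(0.345, referencePools()), 1)
#> [1] 3.9
classifyMetabolism(table2ExcessResults())$label    # bundled excess table
#> [1] "chemoorganoautotrophic"
```

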