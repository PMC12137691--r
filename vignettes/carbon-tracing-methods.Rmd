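---
title: "Methods: isotopologue models and MID correction for dual 13C-tracer studies"
author: "tracerMID"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isotopologue models and MID correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tracerMID)
```

## The scientific question

Anaerobic naphthalene degraders such as the sulfate-reducing enrichment
culture N47 pose a carbon-routing puzzle: the substrate is degraded through
acetyl-CoA, yet the organism may either assimilate that acetyl-CoA directly
(ordinary heterotrophy) or oxidize it fully to CO2 via the Wood--Ljungdahl
pathway (WLP) and rebuild anabolic acetyl-CoA from CO2 — a
chemoorganoautotrophic lifestyle in which the organic substrate serves only
as electron donor. The two strategies leave different isotopic fingerprints
when either the substrate ([U-13C10]naphthalene at 10 mol%) or the
inorganic pool (H13CO3- at 10 atom%) is labeled:

* **Direct assimilation** transfers intact two-carbon units, so ~10% of
  acetyl units are doubly labeled (M+2) under the substrate tracer.
* **CO2 fixation** labels acetyl carbons independently at the CO2-pool
  enrichment $p$: singly labeled (M+1) species dominate and the
  statistically coupled M+2 is only $p^2$ (~1% at 10 atom%, ~0.2% at the
  realistic pool enrichments below).
* **Carboxyl exchange** (CO-dehydrogenase-catalyzed exchange of the
  acetyl-CoA carboxyl with CO2) retains the methyl label only, giving M+1
  at the tracer fraction under the substrate tracer.

The package implements the full quantitative chain that discriminates these
scenarios: pool mass balance, binomial labeling models, the three-step
correction of GC-MS mass isotopomer distributions (MIDs), scenario
prediction and inference, a synthetic-data generator, and enzyme-assay
reduction.

## Labeling models

The probability of $k$ labeled positions among $n$ carbons, each labeled
independently with probability $p$, is the binomial
$p_k = p^k (1-p)^{n-k} \binom{n}{k}$ (`binomialPk()`; coefficients via
`lchoose` so molecules beyond 20 carbons do not overflow). Two worked
settings recur throughout: alanine ($n=3$) at $p = 0.051$ gives
$M{+}1 = 13.8\%$ and at $p = 0.039$ gives $10.8\%$.

The pool enrichments come from the mass balance of the 150 mL culture
bottle (`referencePools()`, `poolMaxEnrichment()`): naphthalene-derived carbon
3.45 mmol, bicarbonate 4.5 mmol (30 mM), headspace CO2 0.8 mmol. A 10%
labeled bicarbonate pool carries 0.45 mmol 13C, bounding the bottle-wide
enrichment at $0.45/8.75 = 5.1\%$; complete oxidation of 10% labeled
naphthalene yields $0.345/8.75 = 3.9\%$. Percentages are reported to one
decimal to match those printed figures. `co2EnrichmentTimecourse()` models
the rise of the inorganic enrichment as oxidation proceeds, as
instantaneous well-mixed pool mixing — no isotope fractionation and no
headspace/aqueous disequilibrium, consistent with referencing all ratios
to total bottle CO2. The default *effective* CO2 enrichment for scenario
predictions is the full-oxidation bound (3.9% under the substrate tracer);
a time-averaged value can be supplied where partial oxidation matters.

Two auxiliary conversions round out the module: delta notation to
isotope-amount fraction, $x = R/(1+R)$ with
$R = R_\mathrm{VPDB}(1 + \delta/1000)$ and $R_\mathrm{VPDB} = 0.0111802$
(the standard definition; the underlying study names VPDB-calibrated
reference gases without printing a formula), and the yield bound
`biomassYield()` (3 ATP per naphthalene at 10 g biomass/mol ATP and
128.17 g/mol gives 0.23 g biomass per g substrate).

## Three-step MID correction

GC-MS fragments carry isotopes from three sources: artificial 13C label on
the analyte skeleton, natural 13C on unlabeled skeleton positions, and the
isotopes of everything else in the ion (Si and C of the TBDMS
derivatization reagent, H, N, O). The correction removes the last two:

1. **Reagent fit** (`fitReagentVector()`). The spectrum of an unlabeled
   standard is the convolution of the skeleton's natural-abundance
   binomial with the unknown non-skeleton mass-shift distribution. Solving
   that convolution by non-negative least squares (NNLS) yields the
   "reagent vector" empirically — no theoretical isotope model of the
   reagent atoms is assumed.
2. **Absolute enrichment** (`fitAbsoluteEnrichment()`). The enriched
   sample's spectrum is deconvolved against the Toeplitz matrix of the
   reagent vector; the normalized solution is the absolute skeleton
   distribution (natural + artificial 13C).
3. **Excess** (`computeExcess()`). Natural abundance is deconvolved with
   the skeleton matrix of step 1 — column $j$ is the binomial of the
   $n-j$ *unlabeled* positions shifted by $j$, because a labeled carbon
   cannot also shift naturally — and components $k \ge 1$ are the excess.

Numerical choices: NNLS (via `pracma::lsqnonneg`) with post-normalization,
because the unknowns are physical fractions and unconstrained fits go
negative at low signal; channel count $K = n + 4$ mass shifts to span
TBDMS Si/C isotopes; natural abundance 1.11% by default; label and natural
abundance treated as independent convolutions (the standard approximation —
it ignores the vanishing possibility that a labeled position's isotope
"shifts twice", and is exact in the forward model used here, so the
round trip closes to numerical precision). The reagent fit's relative
residual above 0.05 flags a mis-specified fragment; control subtraction
below -0.02 flags a control/sample mismatch.

The unlabeled-control subtraction ("each measurement minus the control")
is applied on the **excess scale** by default: the control passes through
the same three steps and its residual excess is subtracted
component-wise. The intensity-level alternative — subtracting the
control's deviation from its own model reconstruction before correction —
is available via `correctDataset(subtractControl = "intensity")`; the two
agree when the control is well behaved, and the excess-scale form is the
one that cancels estimator bias shared with the control.

Replicates follow the reference design: triplicate cultures measured in
technical triplicates; technical replicates are averaged within a culture,
the mean and sd are taken over cultures (`aggregateReplicates()`); pooled
samples (the fatty acids) report no sd.

## Scenario inference

`predictAcetylMID()` encodes the three provenance hypotheses for the
acetyl unit and their convex mixture
$f \cdot \mathrm{autotrophic} + (1-f) \cdot \mathrm{direct}$.
`predictMetaboliteMID()` composes the acetyl distribution with independent
CO2-derived carbons by discrete convolution over an atom-provenance map.
The default maps place the acetyl pair plus one CO2 carbon in alanine
(via pyruvate), plus two in aspartate (via oxaloacetate), plus three in
glutamate (via 2-oxoglutarate under the reductive-TCA reading of the
pathway), and the bare pair in the fatty-acid McLafferty fragment. No
per-position table exists for glutamate in the source material; the map is
data and overridable. Aspartate's acetyl carbons are taken as one intact
unit by default (`acetylCoupling = "intact"`); the independent coupling is
exposed because partial heterotrophy could decouple them. Carryover of
unlabeled pre-culture biomass — a real feature of this extremely
slow-growing culture — is modeled, when requested, as a uniform dilution
factor on predicted excess (default 1, i.e. none).

`fitMixtureFraction()` estimates $f$, the autotrophic share of anabolic
acetyl-CoA, by least squares on the measured M+1/M+2 excess over all
fragments and both tracers. The mixture prediction is linear in $f$, so a
coarse grid (step 0.01) brackets the optimum and golden-section search
refines it; a seeded bootstrap over biological replicates (default 1000
resamples) yields a percentile interval. All-zero observations are flagged
unidentifiable rather than fitted.

`classifyMetabolism()` operationalizes the qualitative argument. Each rule
compares observations to the *prediction of its scenario under the actual
tracer configuration*, not to idealized constants: under complete carboxyl
exchange, for example, the expected M+1 is the tracer fraction only if the
CO2 pool is unlabeled — with the pool at its 3.9% bound the prediction
shifts to ~13%, and the small coupled M+2 (~0.4 pp) is likewise part of
the signature. "Approximately equal" means within 2 combined sd or 20%
relative, whichever is larger (configurable); "consistent with the pool
enrichment" means clearly nonzero, at least 30% of the binomial
prediction, and not above it beyond tolerance — the prediction is an upper
bound that pre-culture dilution pulls observations below. The exchange
signature logically implies the generic "M+1 > M+2" pattern, so the more
specific rule takes precedence; genuinely contradictory evidence returns
`"ambiguous"`.

```{r classify}
cls <- classifyMetabolism(table2ExcessResults())
cls$label
```

## The synthetic-data generator

`generateDataset()` emulates the reference experiment: both tracer
settings plus an unlabeled control, four fragments (alanine 260, aspartate
418, glutamate 432, McLafferty 74), 3 biological x 3 technical replicates.
Biological variation is Gaussian on the excess scale (sd 0.3 percentage
points, the replicate spread of the published excess table), truncated at
zero and applied only to components with incorporated label — a culture
cannot vary biologically in a label it does not incorporate, and jittering
structurally zero components would manufacture phantom excess in unlabeled
material. Technical noise is multiplicative Gaussian per channel (cv
0.025, the upper end of the 0.0--2.5% reproducibility range) on an
arbitrary intensity scale. The reagent vectors are free parameters of the
simulator (plausible TBDMS and methyl-ester shift distributions shipped as
defaults) and are co-emitted in the run manifest together with the
realized per-replicate true excess, so recovery tests are self-consistent.
The generator is strictly seeded: identical seed and configuration give
byte-identical tables. It does not simulate chromatography, peak shapes,
detector saturation or drift, and biological jitter is independent across
fragments (the correlation structure within a culture is unknown); passing
tests therefore validate the correction and inference machinery, not
instrument physics.

What the simulation does and does not show about real data: planted-excess
round trips close to 1e-6 noise-free and the correction is unbiased to
within 0.2 pp per component at reference noise (judged against the realized
truth over 20 simulated experiments of 3x3 replicates), but real spectra
add effects outside the noise model — proton loss/gain in fragmentation,
concentration-dependent detector response — that only measured standards
can control.

## Enzyme assays

`linearSlope()` extracts an OLS slope with closed-form standard error over
the assay's evaluation window; `specificActivity()` applies Beer--Lambert:
activity $= \mathrm{sign}\cdot(s - s_0) \cdot 1000 V / (\varepsilon l
\cdot V \phi c_\mathrm{prot})$ in nmol min$^{-1}$ mg$^{-1}$ protein.
Extinction coefficients are standard literature values (NADH/NADPH 340 nm
6.22, reduced methyl viologen 600 nm 13.7, TNB 412 nm 14.15, fumarate
250 nm 1.45 mM$^{-1}$cm$^{-1}$), path 1 cm, volume 1 mL; all overridable.
The published "~1.0 mg/l total protein" is dimensionally implausible for
the printed activities and is interpreted as mg total protein in the 1 mL
assay. `auditActivityUnits()` verifies dimensionally that every shipped
configuration reduces to nmol min$^{-1}$ mg$^{-1}$. Uncertainty combines
the replicate sd with the relative protein-measurement error in quadrature.
Coupled assays (aconitase + isocitrate dehydrogenase; fumarase + malate
dehydrogenase) report the coupled rate with a flag — attribution between
the enzymes is undefined. The published activity table serves only to
parameterize the trace simulator; its raw traces are not deposited and the
values are not reproducible targets.

## Problem sizes and design choices in the tests

The test suite runs the generator at the reference design (3x3 replicates,
four fragments, both tracers): 200 simulated studies for mixture-fraction
recovery at $f = 0.8$ (requiring $|\hat f - f| \le 0.1$ in at least 90%),
60 seeded studies per scenario for classification (at least 95% correct
labels), 20 studies per fragment for the noise-level round-trip bias
bound, and $2\times10^5$-molecule Monte-Carlo checks of the analytic
predictions. These sizes give standard errors comfortably below the
tolerances they police while keeping the default run lightweight.

## Known limitations

* The convolutional reading of the three-step procedure is validated by
  self-consistency (round trips, simulation), not against the original raw
  spectra, which are not deposited.
* The mixture fraction $\hat f$ for the bundled excess table has no
  published ground truth; it is reported, not checked.
* Scenario predictions ignore isotope fractionation and kinetic effects;
  the effective CO2 enrichment is a bound, not a trajectory average,
  unless one is supplied.
* The classifier's thresholds are heuristics tuned to the dual-tracer
  design at 10 atom%; very different tracer fractions warrant revisiting
  them.
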