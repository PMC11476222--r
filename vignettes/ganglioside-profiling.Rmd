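---
title: "Targeted ganglioside profiling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted ganglioside profiling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gangliotk)
library(dplyr)
```

## The problem

Gangliosides are glycosphingolipids: a ceramide (a sphingoid base
amide-linked to a fatty acyl chain) carrying a glycan headgroup with one
or more sialic acids. In negative-mode LC-MS they appear as singly and
doubly deprotonated ions, and a single composition class (say GD1) is
spread over many m/z values because the ceramide varies in chain length
and saturation, while linkage isomers (GD1a/GD1b) share an exact mass
and separate only chromatographically. Targeted profiling therefore
needs (i) an exact theoretical m/z database across ceramide variants and
charge states, (ii) narrow-tolerance extracted ion chromatograms with
isotope-envelope verification, (iii) internal-standard calibration, and
(iv) rule-based cleanup of search-engine exports. gangliotk implements
that chain end to end on tabular (tibble) data.

## Mass model

Every quantity derives from elemental compositions. A sphingoid base
`x c:d` (x = m/d/t for 1/2/3 hydroxyls) has formula
C~c~H~2c+3-2d~NO~h~; a fatty acyl `c:d` is counted as the free acid
C~c~H~2c-2d~O~2~ (plus any `+nO` oxygens); amide condensation removes
one water. Glycan residues are added in condensed form: Hex
(C~6~H~10~O~5~, 162.052824 Da), HexNAc (C~8~H~13~NO~5~, 203.079373 Da),
NeuAc (C~11~H~17~NO~8~, 291.095417 Da), plus HPO~3~ and SO~3~ for
phosphorylated and sulfated classes. The class registry (a data TSV, not
code) encodes the biosynthesis-pathway arithmetic — GM2 = GM3 + HexNAc,
GM1 = GM2 + Hex, and one NeuAc per additional sialylation step up to
GQ1 — which the test suite asserts as exact mass identities.

Deprotonated ions use m/z = (M − n·m~p~)/n with the electron-corrected
proton mass m~p~ = 1.00727646 Da by default. Some legacy tables subtract
the neutral hydrogen-atom mass instead; the two conventions differ by
less than 0.8 ppm above 700 m/z, and every function that computes ion
m/z takes `convention = "proton"` or `"hydrogen"` so either style of
reference value can be matched byte-for-byte. Published reference m/z
values for these classes mix the two conventions, which is why the
golden checks in the test suite assert 1 ppm agreement rather than
digit-for-digit equality.

```{r mass-model}
species_mz("GD2(d18:1_18:0)", "-2H")
parse_species("Hex1Cer(d17:0_18:2+2O)-H")
```

Isotope distributions are computed by per-element convolution of
single-atom isotopologue distributions, aggregated into nominal-mass
bins (A, A+1, A+2, ...) with abundance-weighted centroid masses. Fine
structure within a bin is deliberately not resolved: at the 120k
resolving power typical of these acquisitions the bins are what the
instrument sees. The default truncation threshold is 1e-4 of the base
peak. Correctness is pinned by a brute-force oracle that enumerates
every isotopologue of small (≤ 12 atom) formulas and agrees with the
convolution to 1e-9 in probability. Deuterated internal standards
(GM1-d3) are ordinary compositions in which three hydrogens are swapped
for the pure label element D.

## Extraction and integration

`extract_xic()` sums centroid intensities within a ppm window (default
10 ppm, the usual Orbitrap tolerance) per MS1 scan, zero-filling empty
scans. Profile-mode input is rejected rather than silently centroided.
Peak detection walks outward from each local maximum until the signal
falls to max(baseline, 1% of apex) or starts climbing into a
neighbouring peak; small noise upticks on a flank do not terminate the
walk, and the bound is placed at the valley. A factor-of-two rise above
the running minimum is treated as "climbing into a neighbour" — with
Gaussian-shaped peaks this only triggers in a genuine valley, and it
makes bounds robust to a few percent of multiplicative scan noise.
Integration is trapezoidal; on a Gaussian sampled at σ/10 it recovers
the analytic area `apex·σ·√(2π)` to well under 1%, and cutting the tails
at 1% of apex forfeits about 0.2% of area, which is why the end-to-end
tests use a 2% band.

When a target's retention-time window (default half-width 0.5 min)
contains several detected peaks, the largest-area candidate is
quantified and the number of candidates is reported, so isomer windows
that accidentally capture a neighbour are visible. Isotope verification
is a cosine between the theoretical envelope (first three isotope peaks,
spacing 1.0034/z) and the observed intensities in the apex scan; the
per-target `score` column is 1 − cosine so that it shares the
keep-if-smaller semantics of search-engine scores downstream.

## Calibration and summaries

Calibration regresses the response ratio (analyte area / internal
standard area) on concentration by unweighted OLS — with an optional
1/x weighting for wide ranges — over the six-level 30–1000 ng/µL design
used for ganglioside standards. LOD and LOQ use the ICH-style 3.3·s/m
and 10·s/m with s the residual standard error and m the slope; with
noiseless input R² is 1 to machine precision and LOD collapses to 0.
Percent relative abundance normalizes each replicate to 100% before
averaging, so replicate totals never leak into the profile; an all-zero
replicate is an error naming the replicate rather than a silent NaN.

Post-search filtering keeps rows with RT strictly greater than 2 min,
area strictly greater than 1000 and score strictly less than 0.5 —
strict inequalities chosen to match "more than / greater than / less
than" wording, pinned by boundary tests at exactly 2 / 1000 / 0.5. The
"t-score" of search-engine exports is proprietary, so it is treated as a
generic keep-if-smaller score with a configurable column name. Filters
are pure (input untouched, report attached as an attribute), idempotent
and monotone in their thresholds; all three properties are tested.

## What the simulator does and does not emulate

`simulate_run()` builds centroided negative-mode MS1 runs: each species
elutes as a Gaussian (default σ = 0.05 min on a 25-min run sampled every
0.005 min ≈ 3 Hz), contributes its first three isotope centroids at
charge-scaled spacing, and can be degraded with multiplicative intensity
noise, ppm mass jitter and random noise centroids. The envelope is
scaled so the monoisotopic centroid carries the configured apex
intensity, making `apex·σ·√(2π)` the exact truth area for the XIC at the
monoisotopic m/z. The default panel mirrors a concordant reference set
(hexosylceramides through GT1) with GD1a before GD1b as on ZIC-HILIC,
and GM3 earliest among the gangliosides. Apex intensities (4.5×10⁵ to
2×10⁶ counts) and the noise defaults are plausible Orbitrap MS1 scales;
they are a fixed modelling choice, not fitted to any instrument.

The simulator does *not* model chromatographic tailing, carryover,
co-eluting matrix interference, detector saturation or MS2 spectra.
Passing the end-to-end tests therefore demonstrates that the extraction,
integration and summarization arithmetic is correct under controlled
conditions — not that real biological matrices will behave as cleanly.

```{r pipeline, eval = FALSE}
sim <- simulate_run(sim_config(seed = 1, mult_sd = 0.01, mz_noise_ppm = 1))
targets <- targets_from_species(sim$truth$name, sim$truth$adduct,
                                rt_center = sim$truth$true_rt,
                                rt_halfwidth = 0.4)
res <- run_pipeline(pipeline_config(sim$run, targets, min_height = 1000))
res$profile
```

## Numerical and design notes

* Atomic masses and abundances are a versioned TSV shipped with the
  package, so results are reproducible offline and the provenance of
  every constant is inspectable.
* The enumeration defaults (bases d18:1, d18:0, d17:0, t18:0, m17:1;
  acyl 12–26 carbons, 0–2 double bonds; −2H added for classes with ≥ 2
  sialic acids; 500–2000 m/z window) cover the commonly reported species
  while keeping databases small; published methods rarely state their
  enumeration ranges, so these are a documented package choice.
* Compositions are canonically ordered named integer vectors; addition
  is commutative by construction and mass is additive to 1e-12,
  property-tested over random compositions.
* m/z matching works on ion m/z, not neutral mass, matching instrument
  tolerance semantics; ties are broken by fewer sialic acids, then name.
* The pipeline is single-run per replicate and joins replicates on
  species name; there is no cross-run retention-time alignment. That is
  a known limitation, acceptable because HILIC class separation puts
  isomer windows far apart relative to typical RT drift.
* Test problem sizes (14-min simulated runs at 0.005-min scans, 300–1000
  Monte-Carlo calibration fits) were chosen as the smallest sizes at
  which the statistical assertions are stable.
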