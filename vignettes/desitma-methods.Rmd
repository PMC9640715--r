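---
title: "Methods: high-throughput DESI-MS tissue-microarray analysis with desitma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: high-throughput DESI-MS tissue-microarray analysis with desitma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(desitma)
```

## The experiment being modelled

High-density tissue microarrays (TMAs) for ambient mass spectrometry are
built by pin-tool transfer of nanogram tissue amounts from 384-well source
plates onto a coated slide: up to 16 plates, hence up to 6144 spots, at a
1.1 mm center-to-center pitch with ca. 800 µm spots. A DESI (desorption
electrospray ionization) stage then rasters the array spot-to-spot while the
mass spectrometer acquires continuously — full-scan negative-mode spectra
for untargeted lipid profiling (about five 100-ms scans per spot), or a
targeted MS/MS experiment per spot for IDH genotyping. Because acquisition
is continuous, nothing in the data stream says which scan belongs to which
spot; the link is made afterwards from the stage log (time, position) and
from the user's plate map (which biopsy sat in which well).

`desitma` implements that downstream analysis end to end, plus a synthetic
acquisition generator with full ground truth so every stage can be validated
quantitatively.

## Array geometry and calibration

A layout enumerates every occupied well of every source plate, replicated
`replicates` times. The published experiments report only totals (384 wells,
four replicates, a 1536-position grid, 6144 maximum) and the pitch; the
physical arrangement of plate blocks on the slide is not public. We fix a
deterministic convention: each source plate occupies a contiguous 16-row ×
(24 × replicates)-column block, replicate spots of one well sit at adjacent
columns, and plate blocks tile left-to-right wrapping at 96 grid columns.
Spot indices are the row-major raster order of the final grid, which makes
the index ↔ (row, col) map a bijection and keeps replicates at consecutive
indices. Any other convention would serve; this one is easy to test and to
invert.

Stage coordinates are calibrated from three reference marks near the plate
corners: three point pairs determine an affine map exactly (six unknowns,
six equations), so `fit_calibration()` solves the linear system directly and
refuses collinear marks, for which the system is singular.

## Spectral processing

**Assignment.** A scan at time *t* belongs to the stage-log entry with
*t* ∈ [t_arrive, t_leave). Half-open windows make the assignment a
partition; scans acquired while the stage was moving fall in no window and
are counted as discarded rather than split between neighbours.

**Resampling.** Scans are interpolated onto a common equally spaced m/z
grid (default 100–1000 at 0.01) so that spectra can be averaged point-wise.
Linear interpolation of the (m/z, intensity) profile is the default;
nearest-grid-point binning, which is area-preserving for centroided stick
spectra, is available via `method = "nearest"` and is what the MS/MS
averager uses (see below). Grid points outside a scan's range are zero.

**Averaging and normalization.** The order of operations is fixed: raw
scans are averaged per spot, the spot spectrum is normalized to its base
peak, and the normalized spot spectra of a biopsy's replicates are averaged
into the biopsy profile, with no re-normalization afterwards.
Base-peak normalization makes all downstream statistics invariant to the
overall intensity scale, which drifts with spray conditions and transfer
amount; this invariance is enforced by tests.

**Quality control.** Pin-tool transfers occasionally fail, mostly for old,
repeatedly freeze-thawed or necrotic tissue. No published rule exists, so
the package flags spots whose pre-normalization total ion current falls
below `min_tic_fraction` (default 0.1) of the median spot TIC, and excludes
them from biopsy averaging. At the simulator's failure model (transfers
scaled to 1%), this threshold recovers planted failures with sensitivity 1
while healthy spots under 30% log-normal scale variation essentially never
fall 10-fold below the median.

## The IDH mutation score

IDH-mutant gliomas accumulate 2-hydroxyglutarate (2HG, precursor m/z 147)
while glutamate (Glu, m/z 146) is typically reduced. Both precursors are
co-isolated in one 3-unit window centered at m/z 146.5 and fragmented
together; the water-loss fragments land at nominal m/z 129 (2HG) and 128
(Glu). The score is the corrected ion ratio

    score = (I129 − 0.061 × I128) / I128

where I128 and I129 are 1-m/z-unit bin totals from the averaged scan and
the 6.1% term removes the ¹³C-Glu isotope contribution to the 129 bin.
A biopsy is called IDH-mutant when the score exceeds `call_threshold`
(default 0.1, strict inequality; scores at the threshold stay wildtype).
Mutant and wildtype populations separate by an order of magnitude, so the
call is insensitive to the exact threshold; it is nevertheless exposed in
the configuration and recorded with every result.

Numerical conventions: product bins are half-open with the shared edge at
m/z 128.5 assigned upward, so the two bins partition the axis; bin totals
use summation by default (`statistic = "max"` is available); the
isotope-correction constant is fixed at 0.061 rather than re-derived from
isotope abundances (theory for C₅H₆NO₃⁻ gives ≈ 5.9–6.0%; the published
empirical 6.1% is used as-is). MS/MS scans are averaged after
nearest-grid-point binning onto a 0.001-unit grid rather than linear
interpolation: centroided product spectra are isolated sticks, and linear
interpolation between distant sticks would manufacture triangular ramps
across the empty region between the bins.

## Untargeted profiling

Biopsy profiles are row-wise standard-normal-variate (SNV) normalized
(each spectrum to mean 0, sd 1 — the spectroscopy convention; the axis is
per sample, not per m/z), then decomposed by column-mean-centered PCA via
SVD with no column scaling. Components are sign-fixed so the
largest-magnitude loading is positive, making reports reproducible under
PCA's sign indeterminacy. `n_components` defaults to the rank limit
min(n − 1, p); for a 36-sample cohort that is 35 components, which is also
the feature count used downstream. Columns whose intensity never reaches
1e−4 of the base peak in any sample are dropped first to keep matrices at
desk scale.

Classification uses stratified six-fold cross-validation — appropriate for
cohorts of a few dozen samples — with three algorithms behind one surface:
bagged trees (random forest with `mtry = p`, 100 trees), boosted trees
(gradient boosting, 100 rounds, depth 3) and a soft-margin linear SVM
(C = 1). Hyperparameters are fixed at these conventional values;
per-dataset Bayesian hyperparameter searches are deliberately out of
scope. Fold assignment and classifier randomness derive from one seed, so
a report is reproducible bit-for-bit. Classes smaller than the fold count
are stratified best-effort with a warning. Per-class AUCs are one-vs-rest
on the pooled out-of-fold probabilities.

Markers are ranked by the signed loading coefficients of a chosen
component, reporting both extremes: with the sign convention above, the
two ends of PC1 correspond to the two clusters the component separates
(e.g. gray/white-matter lipids versus glioma-associated lipids).

## Lipid annotation

Peaks are matched to a built-in panel of brain-tissue markers by exact
mass within 5 ppm, the usual QTOF criterion. Monoisotopic masses are
computed from most-abundant-isotope masses (IUPAC values, ≥ 6 decimals,
hard-coded in the source); adduct m/z uses proton 1.007276, chloride
34.968853 and water 18.010565. Panel formulas are sum-composition level:
glycerophospholipid "C:D" is total acyl carbons:double-bonds (PS 36:1 =
C₄₂H₈₀NO₁₀P), sphingolipids assume a d18:1 backbone (ST 24:1 =
C₄₈H₉₁NO₁₁S), plasmenyl-PE is the 1-O-alk-1'-enyl ether. Each entry
records the 1-dp literature m/z; the computed adduct mass rounds to it for
22 of 24 species. The two exceptions — PI 38:4 (computed \[M−H\]⁻
885.5499 → 885.5 vs printed 885.6) and plasmenyl-PE 40:6 (774.5443 →
774.5 vs printed 774.6) — are shipped flagged rather than forced to match,
since the discrepancy lies in the printed values, not the arithmetic.

## The acquisition simulator

The simulator is first-class, tested code; it generates the same artifacts
a real campaign produces (mzML runs, stage-log CSV, plate-map YAML/CSV)
plus a ground-truth manifest, all byte-deterministic given a seed.

What it emulates, and the defaults chosen as study conditions:

* **Class templates.** Noise-free centroid spectra built from the marker
  panel: lower-TCP species form the "normal" template, higher-TCP species
  the "tumor" template, and a glioma biopsy with tumor-cell percentage
  (TCP) *t* is the linear mix *t*·tumor + (1 − *t*)·normal, base peak 1.
  Non-cancerous brain parenchyma is the pure normal template. Meningioma
  and pituitary templates are synthetic inventions (no published marker
  list), distinct from both.
* **Noise.** Per-peak multiplicative log-normal noise with CV 0.2;
  per-spot log-normal transfer scale with CV 0.3 (transfer efficiency and
  blood content vary spot to spot); m/z jitter 2 ppm; optional baseline
  peaks. Five scans per spot in full-scan mode (≈ 500 ms at 100 ms/scan),
  25 scans per spot for MS/MS (≈ 6 s).
* **MS/MS channels.** Glu fragment at m/z 128.0353 with area G (halved in
  mutants, whose Glu is depleted — the reduction factor 0.5 is a
  configurable choice, as no quantitative value is published); a ¹³C-Glu
  fragment at 129.0386 with area 0.061 G, fully correlated with the Glu
  channel as real isotopologues are; and the 2HG fragment at 129.0193
  with area (Glu level × true ratio) under independent noise. With noise
  off, the recovered score equals the planted ratio exactly.
* **Reporting resolution.** Emitted centroid m/z are rounded to the
  analysis grid step (instruments report finite precision), and each
  stick carries zero-intensity flanking points one grid step either side,
  so the noiseless pipeline round-trip reproduces templates exactly at
  peak positions. Profile-mode peak shapes are not simulated.
* **Cohorts.** `brain_cohort_sheet()` is a 36-biopsy screening set
  (14 parenchyma, 13 glioma with TCP spread evenly over 0.2–0.95 of which
  6 IDH-mutant and 7 wildtype, 5 meningioma, 4 pituitary), mirroring the
  composition of a banked brain-tissue TMA. `idh_cohort_sheet()` is a
  40-biopsy genotyping set: 20 mutants with true 2HG:Glu ratios uniform
  in [0.5, 3] and 20 wildtypes at ratio 0.

What it does **not** emulate: isotope envelopes beyond the single ¹³C-Glu
crosstalk term, chemical background and matrix effects, spray instability
and drift within a run, peak-shape and resolution effects, or biological
within-class heterogeneity beyond the TCP mix. Passing tests therefore
demonstrate that the *computational* pipeline is correct and well
calibrated under the stated statistical model — not that classification
accuracies of this magnitude would be achieved on real biopsies, whose
class structure is far less clean.

## Problem sizes and numerical tolerances

The test suite runs the full pipeline at desk scale: a 500–1000 m/z grid
at 0.05 spacing for end-to-end tests (0.01 for the noiseless fidelity
check), 36- or 40-biopsy cohorts, 2–5 scans per spot for full scans and
10–25 for MS/MS, and 20 independent seeds for the genotyping study. These
sizes were chosen so the whole suite completes in about a minute while
every stage is still exercised through real files. Oracle comparisons use
1e−9 (interpolation), 1e−8 (PCA eigenstructure) and 1e−12 (means,
invariances); mzML round-trips are checked to float-encoding precision
(intensities are stored as 32-bit floats).

## Known limitations

* The plate-block arrangement on the slide is a package convention, not
  the published robot layout; layouts are interoperable only through the
  serialized CSV, not by assuming the convention.
* The stage log is required to carry dwell windows (arrive, leave). Logs
  that record arrival times only must be converted by adding a fixed
  dwell before ingestion.
* `read_msms_runs()` keys runs by spot index encoded in file names; other
  vendor naming schemes need a custom regex.
* Classifier hyperparameters are fixed; on real data some tuning would
  ordinarily be warranted.
* The marker panel is a static snapshot; it is not a database query
  interface, and annotations are tentative exact-mass matches, not
  MS/MS-confirmed identifications.
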