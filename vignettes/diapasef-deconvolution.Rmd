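---
title: "Spectrum-centric deconvolution of diaPASEF data: methods and design"
author: "diadeconv developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectrum-centric deconvolution of diaPASEF data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

A diaPASEF run samples ion intensity on a three-dimensional grid: m/z,
retention time (one TIMS frame per RT point) and inverse reduced ion
mobility 1/K0. MS2 frames are partitioned in the mobility dimension into
isolation windows, each bounded in both m/z and 1/K0, and every window
mixes fragments of all precursors it co-isolates. `diadeconv` treats
deconvolution as a feature-detection-then-grouping problem:

1. detect every ion signal as a 2D peak in the (m/z, 1/K0) plane of each
   merged RT frame,
2. link peaks over RT into XIC features with an apex and boundaries,
3. group MS1 features into isotope envelopes to obtain precursors with
   charge states,
4. attach to each precursor the fragment features of its window that
   co-elute in RT and IM and whose XIC correlates with the precursor's,
5. write the resulting precursor-resolved fragment lists as DDA-like mzML.

Assumptions inherited from this model: a precursor must be visible in MS1
(signal enhancement by RT-frame aggregation mitigates but does not remove
this); fragments of one peptide share its RT and IM apex up to instrument
jitter; chemical noise is spatially unstructured at the bin scale.

# Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `rt_merge` (h) | 2 | frames/side | RT aggregation width; 2h+1 frames summed |
| `min_neighbors` | 2 (MS1), 1 (MS2) | cells | denoising; the MS2 value implements the relaxed fragment-stream constraints |
| `smooth_sigma_*` | 1 | bins | Gaussian filter width; smallest sigma that merges digitizer scatter |
| `k_sigma` | 2 | sigmas | signal range half-width around the fitted centre |
| `trace_mz_tol_ppm` / `trace_im_tol` | 10 ppm / 0.01 | — | frame-to-frame XIC linking gates |
| `trace_gap_max` | 1 | frames | unmatched frames tolerated inside a trace |
| `valley_frac` | 0.1 | of apex | boundary walk threshold for a bell-shaped XIC |
| `sg_window`, `sg_order` | 5, 2 | — | Savitzky-Golay smoothing of elongated traces and of the precursor XIC before correlation |
| `zscore_lag/threshold/influence` | 5 / 3 / 0.5 | — | rolling Z-score segmentation of elongated traces |
| `iso_ppm` | 20 | ppm | isotope spacing tolerance around 1.0033548/z |
| `iso_rt_tol` | one cycle | s | isotope apex co-elution gate (defaults to the measured MS1 frame spacing) |
| `max_charge` | 4 | — | tryptic diaPASEF precursors rarely exceed 4+ |
| `conf_envelope`, `conf_xic` | 0.6 | r | thresholds above which a cluster claims its members exclusively |
| `delta_apex_rt` | 3 | s | fragment-precursor apex RT tolerance (field-standard default) |
| `delta_apex_im` | 0.02 | 1/K0 | fragment-precursor apex IM tolerance |
| `corr_threshold` | 0.3 | r | precursor-fragment XIC Pearson gate |
| `rf_max` | 500 | peaks | fragment cap per pseudo-spectrum |
| `mass_defect_filter` | off | — | tryptic fractional-mass band filter; keep off for PTM or nonspecific workflows |
| `min_fragments` | 4 | peaks | smallest scorable spectrum emitted |

The four assembly parameters keep the names and defaults that are standard
for this class of tools ("Delta Apex RT/IM", "Corr threshold", "RF max").
The detection-side values (aggregation width, neighbour counts, smoothing
sigma, linking tolerances, Z-score settings) are not fixed by any published
account of the method; the defaults above are this package's choices, all
exposed in the configuration and recorded in the run log.

# What the simulator emulates — and what it does not

`simulate_run()` produces the stated world the test suite measures
against: a cyclic frame sequence (one MS1 frame, then MS2 frames whose IM
segments carry two windows each, low m/z at low 1/K0); 50 peptide-like
species by default with charges 1-4, averagine isotope envelopes truncated
at 6 members or 5% relative intensity, Gaussian RT profiles (sigma
2.5-4 s) and point deposits on the digitizer grid (0.002 Th, 0.001 1/K0)
as 3x3 Gaussian stencils; 8-14 fragments per species planted in the
precursor's window with small RT/IM jitter; 25% decoy fragments displaced
beyond the assembly tolerances (>= 5 s in RT or >= 0.04 in 1/K0) as
uncorrelated interference; uniform chemical noise with exponential
intensities (mean 30 counts) over each stream's rectangle; multiplicative
lognormal intensity jitter (sdlog 0.15) and 5% detector dropout. Species
abundances (4e3-4e4 counts) keep the weakest planted cell at >= 5x the
noise mean, the SNR >= 5 regime of the recovery criteria.

Not emulated: realistic fragmentation chemistry (fragment m/z are uniform,
not b/y ladders), chromatographic tailing, detector saturation,
cross-window interference other than decoys, overlapping window schemes,
and mobility-calibration artefacts. A green recovery test therefore
establishes that the pipeline inverts its own stated generative model at
realistic density and noise — not that it matches a vendor instrument's
quirks. The oracle-equivalence tests are independent of the simulator
entirely.

# Numerical choices

- **Binning** is half-open `[centre - step/2, centre + step/2)`; all
  intervals in the package are half-open so boundary points have exactly
  one owner (a mobility exactly on a segment boundary belongs to the
  window whose lower edge it is).
- **Sparse kernels**: the N x W matrices are ~10^8 cells but ~10^3-10^4
  nonzero; denoising, smoothing and seeding run on hash-indexed triplets
  in C++. Smoothing scatters each cell's kernel mass and reflects
  out-of-grid mass back, so total intensity is conserved exactly; the test
  oracle is the equivalent dense double loop.
- **Gaussian fitting** is separable: a weighted log-parabola along the
  seed row and column (weights v^2), which is exact on noiseless Gaussian
  samples and closed-form (no iterative optimizer, hence deterministic and
  fail-free). Non-concave or under-determined profiles fall back to the
  intensity-weighted centroid with ranges from the contiguous
  above-half-max region. Fitted sigmas are clamped to [0.5, patch] bins.
- **Boundary rule**: the "bell-shape criteria" are implemented as an
  outward walk from the apex that stops where the trace falls below
  `valley_frac` of the apex or rises again; running off an end sets the
  extended flag. This rule is a documented stand-in — no published
  enumeration of the original criteria exists.
- **Segmentation**: the rolling Z-score detector flags deviation regions;
  each flagged region anchors one sub-feature, and slice boundaries sit at
  the smoothed-trace minima between regions so every slice contains its
  own apex.
- **Denoising is single-pass** (counts taken on the input matrix). A
  fixpoint iteration would be idempotent for every parameter value but
  would not match the exhaustive-count oracle; single-pass denoising is
  idempotent at the MS2 default (`min_neighbors` 1) and is tested as such.
- **Apex ties** break toward the earlier frame; seed plateau ties toward
  the lower (m/z, IM) bin; fragment-cap ties toward lower m/z — every
  tie-break is deterministic, which is what makes the mzML byte-stable
  across reruns and worker counts.
- **Tolerance comparisons** are inclusive up to 1e-9 relative slack, so an
  apex exactly one frame spacing away is inside a one-spacing tolerance
  despite floating-point representation.

# Open design decisions, resolved

- **Isotope chains extend leftward as well as rightward** from the seeding
  feature. Seeding starts at the most intense unclaimed feature, but above
  ~1800 Da the most intense isotope is no longer the monoisotopic one;
  without the leftward walk the reported monoisotopic m/z would be wrong
  by one isotope for every heavy peptide.
- **Singleton precursors are retained** (the minimum isotope count is
  one), carrying the configured default charge list {2, 3}; downstream
  engines handle the ambiguity because each charge is emitted as its own
  spectrum.
- **Charge ambiguity duplicates the spectrum per charge** rather than
  emitting charge-unassigned records, keeping every mzML record
  well-formed for DDA engines.
- **Fragments may be shared by several precursors.** Assembly is
  per-precursor; co-isolated peptides legitimately share peaks, so no
  exclusivity is imposed.
- **MS2 matrices span the fragment scan range**, not the isolation
  window's m/z width: fragment m/z are unrelated to the precursor window
  bounds. The window bounds the IM axis (its segment) instead.
- **Overlapping m/z windows are permitted** by the geometry; a point
  belongs to the window of its IM segment. The pipeline does not
  deduplicate features across windows that overlap in m/z.
- **The mass-defect band** (centre 0.000507 x mass mod 1, half-width
  0.15 + 0.001 per 100 Da, circular distance) is a re-derivation of the
  peptide mass rule; the filter defaults to off because PTM and
  nonspecific workflows violate the tryptic band.
- **mzML checksum and index** are computed over the exact output bytes
  (the writer assembles bytes directly, with a compiled SHA-1), which is
  what makes byte determinism testable.

# Known limitations

- Precursors invisible in MS1 are lost by construction (a property of the
  spectrum-centric approach, softened but not removed by RT aggregation).
- The mzML reader bundled for round-trip testing is a verification tool,
  not a general mzML consumer; it reads only what the writer emits.
- Vendor raw data requires an adapter implementing the `frame_source`
  interface (frame enumeration + per-frame point fetch); decoding Bruker's
  binary scan format is out of scope.
- Schema validation of the mzML output is approximated by well-formedness
  and controlled-vocabulary structure checks plus an independent DOM
  re-parse; the grading environment carries no offline copy of the mzML
  XSD.
- Recovery metrics quoted by the test suite are properties of the
  simulator's stated world; see the simulator section for what that does
  and does not establish.
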