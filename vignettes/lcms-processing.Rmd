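---
title: "Stepwise LC-MS metabolomics processing with lcmspipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stepwise LC-MS metabolomics processing with lcmspipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The data model

An LC-MS run is a sequence of mass spectra.  `lcmspipe` represents the
hierarchy with three typed containers, and every processing function is a
pure map between them:

* **scan** — one spectrum: (m/z, intensity) pairs, sorted strictly
  ascending by m/z, at one retention time (seconds).  Scans carry their MS
  level, polarity (ion mode) and, for fragmentation scans, the precursor
  m/z.
* **feature** (ion trace) — one ion followed across scans: a strictly
  increasing time vector, an intensity vector, a characteristic m/z and a
  characteristic retention time.  The characteristic retention time is the
  *apex* (time of maximal intensity, earliest on ties); a weighted mean
  would be an alternative, but the apex is robust for the sharp peaks this
  pipeline targets and is what the valley-based deconvolution needs.
* **feature set** — co-eluting features believed to come from one compound
  (adducts, isotopologues, in-source fragments), at the arithmetic mean of
  the member retention times.

Because every stage consumes one of these kinds and produces one, a
workflow is a typed dataflow graph.  `validate_workflow()` checks edge
compatibility, acyclicity and parameter schemas before anything runs, so a
validated workflow cannot hit a type error mid-batch.  After every stage
the result can be snapshotted to disk (a self-describing text format with
a magic prefix and kind tag; doubles are stored as 17-significant-digit
strings, which round-trip IEEE values exactly), and `rerun_from()` resumes
a stored run from any stage — the intended way to loosen one parameter and
re-process only the affected tail of the pipeline.

Units are fixed throughout: seconds for time (minute-valued mzML scan
times are converted on read), Thomson for m/z, arbitrary detector counts
for intensity.  All m/z tolerances are relative (ppm), matching how
high-resolution instrument error scales with mass.

# Processing stages

## Centroiding

Profile-mode spectra sample the instrument peak shape; centroiding reduces
each ion species to one stick.  The picker is the standard
continuous-wavelet scheme: the intensity vector is convolved (zero-padded,
so edge peaks get full responses) with Ricker / Mexican-hat kernels at
scales `{2, 4, 8, 16}` profile points; response maxima that persist across
at least two consecutive scales form ridges; ridges must exceed a
signal-to-noise threshold (default 3) where noise is `1.4826 x MAD` of the
smallest-scale response.  The centroid m/z is the intensity-weighted mean
of the profile points within 10 ppm of the ridge apex, and its intensity
the profile maximum there.  Because both the response and the MAD noise
scale linearly with intensity, the set of reported centroids is invariant
under rescaling the spectrum — only relative peak shape matters.  A scale
is used only when the scan has at least twice that many points.

## Filtering

* `intensity_threshold()` removes pairs below a global counts cutoff;
  scans are kept even when emptied so scan numbering survives.
* `baseline_correct()` subtracts an asymmetric-least-squares baseline per
  ion trace (weights: `asymmetry = 0.01` above the running baseline,
  `0.99` below; second-difference penalty `smoothness = 1e4`; at most 20
  reweighting iterations, tolerance `1e-6` on the weight change).  Per
  trace rather than per total-ion chromatogram, because drift is usually
  trace-local (column bleed at specific masses).  Traces under 5 scans
  pass through: too few points to separate peak from baseline.
* `range_filter()` crops by m/z and retention-time windows, inclusive on
  all bounds.
* `scan_width_filter()` drops traces spanning fewer than `min_scans`
  scans.  Genuinely sharp peaks can be lost this way — the snapshot/rerun
  mechanism exists precisely to win them back with a looser setting.
* `exclusion_filter()` removes features matching a contaminant mass list.

## Feature extraction and deconvolution

`extract_features()` builds mass traces greedily over MS1 scans in time
order: a centroid joins the open trace whose running intensity-weighted
mean m/z lies within `tol_ppm` (default 10; nearest trace wins, one
centroid per trace per scan), otherwise it opens a new trace.  Traces
survive `max_gap_scans` (default 1) missed scans, then close; traces whose
apex is below `min_intensity` are discarded.  The weighted-mean m/z makes
the trace centre drift-stable and averages out per-scan mass jitter.

`deconvolve()` splits traces containing several chromatographic peaks: the
trace is smoothed with a second-order Savitzky-Golay filter (window 9
scans, shrunk for shorter traces; traces under 5 scans pass through),
local maxima with SNR >= 3 against the `1.4826 x MAD` of the
smoothed-minus-raw residuals are apex candidates (plus a relative floor of
0.1% of the trace maximum, so numerically negligible smoother ripples on
noise-free traces are ignored), and the trace is cut at the minimum
between two apexes when that valley falls to half the lower apex
(`valley_fraction = 0.5`) or below.  Children keep the *raw* intensities;
the valley point goes to the earlier child, so summed intensity is
conserved exactly — a property the test suite checks on random two-peak
traces.

## Grouping and annotation

Ions of one compound co-elute, so their intensity-over-time profiles are
proportional.  `profile_inner_product()` resamples two traces onto the
union of their time points over the overlap of their spans (linear
interpolation — exact at shared scan times, which is the common case
within one sample) and returns the cosine of the two vectors.
`group_features()` links pairs with `|delta rt| <= 5 s` and cosine
`>= 0.9`, and takes connected components (single linkage, so an
M+H—M+Na—isotope chain assembles even if the extreme members are
individually below threshold against each other).

Annotation runs inside each feature set:

* `annotate_isotopes()` matches spacings to `k x 1.0033548 / z` Da (the
  13C-12C mass difference) for `k <= 3` and charges 1-2, inferred from the
  spacing with singly-charged preferred on ties, gated by an intensity
  ratio (isotope peak at most 1.1x its anchor — generous, to tolerate
  noisy ratios, while rejecting the case where the "anchor" is the smaller
  peak).  Chains anchor at the lightest non-isotope feature.
* `annotate_adducts()` tests every feature pair against every pair of
  distinct mode-applicable rules: a rule maps a neutral mass M to
  `(n*M + shift) / |z|`, so each (feature, rule) pair implies a neutral
  mass, and agreement within tolerance annotates both features and
  contributes to a consensus neutral mass (the mean of agreeing implied
  masses).  Features already annotated as isotopologues are excluded:
  the M+1 envelopes of two adducts of one compound always imply mutually
  agreeing neutral masses exactly one isotope spacing high, so including
  them would both mislabel the isotopes and bias the consensus.  Run
  isotope annotation first.
* `match_reference()` compares member m/z values against library neutral
  masses transformed by the mode-applicable rules, with an optional
  retention-time gate.  All candidates are reported with signed ppm and
  rt errors — ranking and final acceptance are left to the analyst, which
  is how standards verification is actually done.
* `main_peak()` designates the protonated (positive) or deprotonated
  (negative) feature, falling back to the strongest non-isotope feature.

Fragment annotation needs no separate machinery: neutral-loss rules
(multiplier 1, negative shift) pass through the same adduct-rule path.

## Alignment and the feature matrix

`estimate_rt_shift()` warps one sample's retention axis onto a reference
(by convention the sample with most features): landmark pairs are mutual
nearest matches within 10 ppm and a 30 s window, ranked by apex intensity
(top 50); landmarks are pooled into 10 equal-count bins and a monotone
piecewise-linear map is interpolated through the per-bin medians (isotonic
regression enforces monotonicity; beyond the outer knots the edge offset
is extrapolated as a constant).  Fewer than 5 landmarks yield the identity
map with a warning rather than an unstable fit.  Binned medians are robust
to mismatched landmarks but inherit their sampling noise: with few shared
compounds and large per-feature retention jitter the map wiggles at the
scale of the per-bin median error, so the matrix-building rt tolerance
should be sized to the *residual* jitter, not to zero.

`build_matrix()` groups rt-corrected features across samples greedily in
descending apex intensity order (strong features first, so group centres
are anchored by the best measurements): a feature joins a group when it is
within `tol_ppm` and `rt_tol` of the group's running means and the group
has no feature from that sample yet.  Cells hold trapezoidal peak areas by
default (apex height optional); absent compounds stay missing — no
imputation, downstream statistics are out of scope.

# The synthetic-data generator

`generate_sample()` emulates a reference-standard run: each compound
elutes as a Gaussian peak (sigma in seconds) and appears as one trace per
requested adduct plus isotopologue peaks scaled by its isotope ratios; the
default M+1 ratio is a crude carbon-count heuristic
(`0.011 x round(mass / 14)`, M+2 its square over two) — synthetic, not
chemically exact.  Chemical noise (Poisson count per scan, uniform m/z,
exponential intensity), a linear baseline and Gaussian per-peak m/z jitter
are added; profile mode renders each stick as a sampled Gaussian at
resolving power 30000 with grid spacing one third of the peak sigma.  The
truth manifest lists every injected trace, so recall and precision of any
stage can be scored without instrument data.  Output is written as
minimal, deterministic mzML 1.1.0 (uncompressed 64-bit arrays, spectrum
polarity and representation terms), and identical seeds give byte-identical
files.

`generate_standards_suite()` emulates a standards campaign: random
compounds with neutral masses in [100, 600] Da and retention times in
[60, 900] s, one run per compound per mode, positive runs emitting M+H and
M+Na, negative runs M-H and M+Cl, plus the matching reference-library CSV.
Defaults were chosen once as realistic acquisition conditions — 1 s scan
interval (a typical MS1 cycle time), peak sigma 4-8 s, apex intensities
10^4.7-10^5.5 counts over chemical noise of mean 100 counts (so main peaks
sit far above noise, as standards do), 2 ppm per-peak mass jitter.

What the generator deliberately does *not* emulate: peak tailing
(a tailing factor exists but defaults to symmetric), detector saturation,
correlated chemical background (real contaminants persist at fixed m/z and
would stress the exclusion filter harder), ion suppression between
co-eluting compounds, and realistic isotope fine structure.  Passing the
synthetic end-to-end tests therefore demonstrates the machinery is
correct and self-consistent — not that the default parameters are optimal
for any particular instrument's data.

# Numerical choices

* m/z tolerances are ppm everywhere; time is seconds everywhere.
* Ties: apex ties resolve to the earliest time; main-peak ties to the
  lowest m/z; trace-join ties to the nearest m/z.
* Degenerate inputs: empty scans are legal; single-point features have
  zero area; traces too short for their smoothing or baseline window pass
  through unchanged; an empty landmark set yields the identity time map.
* The isotope spacing constant is 1.0033548 Da; the proton mass
  1.00727646688 Da; adduct transforms invert to machine precision by
  construction.
* Snapshot payloads store doubles as `%.17g` strings because generic JSON
  number formatting does not guarantee last-ulp round-trips.

# Problem sizes

The shipped test-suite and the acceptance script exercise: a 58-compound
standards campaign (70 profile-mode runs of 961 scans each) through the
complete pipeline; a 50-compound single-run recovery benchmark; 1000
random features for the grouping partition property; 200 random two-peak
traces for deconvolution conservation; 100 random stage graphs for
executor soundness; and byte-level determinism checks over repeated runs.

# Known limitations

* MS^n spectra are carried through and can be associated to features by
  precursor, but no fragmentation-spectrum processing is done.
* Ion mobility, SRM/MRM chromatograms and vendor raw formats are out of
  scope; input is mzML 1.1.0.
* The executor runs samples serially; stages are pure, so callers may
  parallelise over samples themselves.
* Reference matching reports all candidates; it does not attempt scoring
  or unique assignment.
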