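---
title: "Methods: from slice electrophysiology to treatment response in mosaic cortical malformations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from slice electrophysiology to treatment response in mosaic cortical malformations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimosaic)
```

## Scope

Focal cortical dysplasia type II (FCDII) is a mosaic cortical malformation:
a small subset of neurons carries a somatic mTOR-pathway mutation, becomes
cytomegalic and mTOR-hyperactive (pS6+), and clusters inside otherwise
normal cortex. `epimosaic` implements the quantitative chain that links
this cellular mosaic to epilepsy readouts:

1. detection of interictal-like discharges (IILDs) and multi-unit activity
   (MUA) on multi-electrode-array (MEA) recordings of acute cortical
   slices, and classification of electrodes by activity type;
2. registration of the electrode grid onto histology images and
   dysmorphic-neuron (DN) density per electrode-activity class;
3. segmentation and counting of marker-positive cells in histology images,
   senescence co-labeling fractions, and conversion of variant allele
   frequency (VAF) to mutant-cell fraction;
4. ictal-event detection on longitudinal EEG and phase comparisons of
   daily seizure frequency under treatment;
5. exact small-sample two-tailed Mann-Whitney statistics used throughout.

Every stage is exercised on a seeded synthetic-data generator with known
ground truth, because the original human slice recordings and mouse
cohorts are not publicly deposited. The generators encode the study
conditions (rates, densities, probabilities) as defaults; they are the
test bed, not a biophysical simulation.

## Event detection on MEA recordings

### The detection statistic

Each channel is detrended (optional mains notch available), band-pass
filtered with a zero-phase order-2 Butterworth filter — 1–40 Hz for the
IILD band, >250 Hz for MUA — then squared, smoothed into a short energy
envelope, and z-normalized over the entire recording. Supra-threshold
regions become events.

Two deliberate choices deserve justification:

* **Filter family.** Acquisition hardware typically applies causal Bessel
  filters; for offline analysis we filter forward–backward
  (`signal::filtfilt`), which removes phase distortion so that detected
  peak times are unbiased. Under zero-phase application the Bessel
  family's linear-phase advantage is moot, so an order-2 Butterworth (the
  standard digital design) is used; at this order the magnitude responses
  are very close.
* **Threshold units.** The user-defined thresholds (defaults: IILD 3 SD,
  MUA 5 SD) are interpreted in *amplitude* SD units of the band-filtered
  signal, implemented on the squared scale as
  `envelope >= mean(envelope) * k^2` (i.e. `|x| >= k × RMS`). Interpreting
  `k` directly as SDs of the squared signal would put the 5 "SD" MUA
  threshold at only 2.84 amplitude SDs — about 45 false spikes per second
  per channel of pure Gaussian noise at 10 kHz — which no practitioner
  would accept. The amplitude convention is the field's standard for MUA
  amplitude thresholds. Reported `peak_z` values remain on the
  z-normalized squared scale and always meet the z-equivalent of the
  threshold used.

The energy envelope is a centred moving average of the squared signal over
the expected event timescale (0.5 ms for spikes — half the spike width —
and 10 ms for IILDs). For a 5-SD amplitude threshold, requiring the mean
of ~5 squared noise samples to exceed `25 σ²` has probability ~1e-25 per
sample, so isolated noise excursions essentially never trigger, while a
genuine spike concentrates its energy inside the window and passes with a
wide margin.

### From threshold crossings to events

For IILDs, supra-threshold runs closer than 200 ms merge into one event
(an IILD is biphasic, so its squared trace dips mid-event); merged events
with less than 40 ms of *total* supra-threshold time are discarded (this
minimum-duration gate suppresses chains of brief band-limited noise
crossings, which individually last well under 40 ms); event bounds extend
to the half-threshold crossings. For MUA, crossings within a 1 ms
refractory window collapse to one spike. Times are seconds from trace
start, samples 0-based, event intervals half-open `[onset, offset)`.

Because the normalization spans the entire recording, channels bearing
large discharges normalize against an event-inflated variance; this
raises their effective threshold, which costs nothing in practice (IILD
peaks sit far above it) and suppresses false positives as a side effect.

### Discriminating discharges from spikes

`classify_event()` compares band energies in a window around the event
(padded to ≥100 ms so the slow band is spectrally resolved): an event is
an IILD when the slow (<40 Hz) fraction of slow + fast (100–500 Hz)
energy reaches 0.5, otherwise it is an isolated spike. A short-time
spectrogram of the window is returned for visual review, mirroring the
semi-automatic workflow the procedure automates.

### Electrode classes and network events

An electrode is `IILD_MUA` with ≥2 detected IILDs, `MUA_ONLY` with ≥10
spikes, otherwise `SILENT` (`DEFECTIVE` from layout metadata). These
count thresholds are this package's own operational definitions — activity
maps are usually drawn without numeric criteria. Synchronous IILDs whose
peaks fall within 50 ms on grid-adjacent (8-neighbourhood) electrodes are
grouped by single linkage into network events.

## The synthetic MEA generator

The generator lays a core / surround / silent activity gradient over the
grid: core electrodes carry network IILDs (default 2/min, shared time ±10
ms uniform jitter across all core channels) plus Poisson MUA at 0.74 Hz;
surround electrodes Poisson MUA at 0.05 Hz; the rest only noise. The
high-K+ (pro-convulsive bath) condition multiplies every MUA rate by 5
while leaving IILD placement untouched — the generator draws all IILD
randomness before any MUA randomness so the toggle provably cannot move a
discharge.

Waveforms and amplitudes are free parameters fixed at typical
extracellular magnitudes: white noise SD 10 µV; 1 ms biphasic spikes
(sine cycle under a Hann window) peaking at 75 µV; IILD slow component of
300 ms and 300 µV peak with an amplitude-modulated ripple burst (100–500
Hz, 20 µV) riding on the main deflection. Two shape choices matter:

* The IILD slow component is a *double Gaussian with a dominant first
  deflection* (sharp negative wave, slower opposite rebound), as in real
  interictal discharges. A symmetric biphasic template would have two
  equal-magnitude lobes and the detected energy peak would flip between
  them from noise alone (±45 ms at 300 ms duration), leaving no
  well-defined ground-truth time to score detections against.
* The ripple is kept at ~2 noise SD. Ripple components above 250 Hz
  survive the MUA high-pass, so a large ripple would register as bursts
  of spurious spikes during every discharge and contaminate the MUA rate
  contrast the recordings are supposed to exhibit.

What the generator does *not* emulate: spike waveform diversity and
sorting ambiguity, electrode drift, 1/f and mains noise (a notch and the
detrend exist but default recordings are white-noise based), state
transitions, or any biophysical network mechanism. Passing recovery tests
therefore shows the detector implements its specification faithfully on
signals with the assumed statistical structure — not that it is robust to
every artifact of real rigs.

### Problem sizes

A full 120-electrode, 600 s, 10 kHz recording occupies ~5.8 GB as double
precision, so the packaged tests and reference runs use a reduced grid
(4×5 electrodes at 1 mm pitch: 4 core, 12 surround, 4 silent) and 60–300 s
durations, with every rate, amplitude and zone parameter at its default.
Rate-calibration checks, which need no traces, run on the event generator
at the full 600 s duration.

## Electrode-to-histology co-registration

Registration is landmark-based affine only (the original overlays were
manual/visual; no intensity-based registration is attempted). `fit_affine`
solves the least-squares mapping from ≥3 non-collinear landmark pairs and
is exact (residual ≤1e-9 µm RMS) whenever the pairs are affine-consistent.

Each non-defective electrode claims its Voronoi cell in image space,
clipped to the analysis field; class regions are unions of same-class
cells. Region areas are integrated on a 400×400 grid over the field —
nearest-electrode assignment of grid points and of cells uses the same
metric, so the class regions partition the field and every qualifying
cell is counted exactly once (cell *counts* are exact; only areas carry
the ~0.25% grid discretization). A cell qualifies as a DN when pS6+ ∧
NeuN+ ∧ soma diameter >25 µm; balloon cells (pS6+/NeuN−) are deliberately
excluded from DN counts.

## Histology quantification

Segmentation follows the colorimetric/fluorescence counting recipe:
threshold (a fixed, transferable value, or Otsu for automation) →
binarize → optional distance-transform watershed to split touching somata
→ 8-connectivity connected components → discard objects with area ≤25 px²
(the gate is kept in pixel units on purpose, because that is how such
counting rules are stated; a physical-size gate is available through the
µm-per-px metadata and the reported `diam_um`). Marker positivity of an
object in another channel is called when its mean intensity exceeds that
channel's Otsu cut — an automated stand-in for by-eye calls.

The synthetic cell maps place cells by homogeneous Poisson processes per
zone (core 53.6 DN/mm², surround 11.7 DN/mm² by default, balloon cells in
a gray–white band, small pS6− normal neurons everywhere). Because somata
are placed independently, a few percent of cells overlap almost
concentrically and are unresolvable by any segmentation — image-based
counts run ~2–3% below ground truth at 50 cells/mm². Real somata exclude
each other spatially, so this is a conservative artifact of the test bed,
accounted for by comparing pooled estimates against 95% Poisson bands.

Marker semantics in the spatial generator: the *type-defining* markers
are deterministic given cell type (DN = pS6+/NeuN+, BC = pS6+/NeuN−,
normal = pS6−/NeuN+); cytomegalic cells are SAβGal+ with probability 0.9;
and each SAβGal+ cytomegalic cell draws the senescence panel (p53 0.92,
p16 0.85, SMI311 0.88, VIM 0.95, p21 0.81, nuclear-Hmgb1 loss 0.92,
nuclear-LaminB1 loss 0.84) independently. Drawing pS6/NeuN from their
panel probabilities (0.89/0.98) *inside the spatial map* would contradict
the type identities and silently deflate DN densities by ~13%; those two
conditional probabilities are instead exercised by `gen_colabel_panel()`,
which simulates SAβGal+ cells directly — matching how co-label
percentages are defined (fraction of SAβGal+ cells positive for each
marker). Co-label fractions carry Clopper–Pearson 95% intervals.

Under heterozygosity each mutant cell contributes one variant allele, so
`mutant_cell_fraction` reports `min(1, 2·VAF)` and flags VAF >0.5 as
inconsistent with a heterozygous variant.

## Longitudinal EEG

`morlet_power` convolves the trace with L2-normalized complex Morlet
wavelets (7 cycles) at 50 log-spaced frequencies in 1–50 Hz. Seizure
detection sums band power in 1 s bins, z-scores the binned power over the
recording, and keeps supra-6-SD runs lasting ≥10 s, merging across gaps
<5 s.

The z-over-recording normalization has a structural consequence worth
stating: if ictal activity occupies a fraction *d* of the recording, the
burst z-score saturates at √((1−d)/d) regardless of amplitude, so no gain
can reach 6 SD once bursts cover more than ~2.7% of the trace. Real
recordings sit far below this (a few seizures of tens of seconds per day
is ~0.1–0.5% duty), and the synthetic traces follow suit (~1–1.7% duty:
e.g. four 15 s bursts per 90 min segment). The synthetic EEG is
band-limited Gaussian noise (0.5–70 Hz acquisition band) with broadband
bursts at 8× background amplitude and 1 s cosine ramps; it emulates the
power signature of ictal runs, not their electrographic morphology, so
detector calibration results speak to the thresholding logic only.

Daily seizure frequency normalizes each session to 24 h
(`n/hours × 24`) and averages per animal — discontinuous 72 h sessions
are handled by that same rule. Phase comparisons (pre / end of treatment /
post) use the unpaired exact Mann-Whitney test; a paired design would
arguably fit a longitudinal study better, but the unpaired test is what
such figure legends report, so it is the default. Quantiles use linear
interpolation between order statistics (`quantile` type 7); with a single
observation, `sd`/`sem` are reported as `NA`, never 0.

## Exact Mann-Whitney statistics

`mann_whitney_exact` computes U by rank summation (midranks for ties).
For tie-free samples with `choose(n1+n2, n1) ≤ 2e5` it enumerates every
group assignment and doubles the smaller tail (capped at 1) — the rule
that yields the complete-separation floors `2/choose(n,k)`: 2/70 ≈ 0.0286
for 4 vs 4 and 2/924 ≈ 0.0022 for 6 vs 6. Ties or larger samples route to
a seeded Monte-Carlo permutation test with the same two-sided rule; the
permutation stream is canonicalized over group order, so `p(a,b) = p(b,a)`
holds exactly on both paths. An alternative two-sided rule (probability of
outcomes at least as far from the null mean of U) is available behind the
`two_sided_rule` flag. No normal approximation is used anywhere — sample
sizes in this setting are tiny, which is the point of exact floors.

## Reproducibility and limitations

All generator randomness flows from one explicit seed per call, and the
caller's RNG state is restored afterwards; identical configs are
bit-reproducible. Known limitations, besides those noted above: no
spike sorting (MUA is aggregate by design); no ictal detection on slices;
region boundaries for density quantification are Voronoi-based where the
original outlines were drawn by hand, so absolute densities on real
overlays depend on that regioning convention; and the 400 µm slice is
treated as a projected 2-D field (no z-geometry).
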