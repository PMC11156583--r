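# epimosaic

Analysis toolkit for linking epileptiform activity in acute cortical
slices to the topography of pathological cells in mosaic cortical
malformations (focal cortical dysplasia type II and related
mTORopathies), and for quantifying treatment response in longitudinal
EEG studies.

In FCDII a somatic mTOR-pathway mutation produces a sparse cluster of
cytomegalic, mTOR-hyperactive (pS6⁺) dysmorphic neurons inside otherwise
normal cortex. The package implements the quantitative chain around that
biology:

* **Slice electrophysiology** — interictal-like discharge (IILD) and
  multi-unit activity (MUA) detection on multi-electrode-array
  recordings. Each channel is zero-phase band-pass filtered (1–40 Hz for
  IILDs, >250 Hz for MUA), squared, smoothed into an energy envelope and
  z-normalized over the recording; supra-threshold regions become events
  (user thresholds in amplitude SD: IILD 3, MUA 5). Electrodes are
  classified (`IILD_MUA` / `MUA_ONLY` / `SILENT`), discharges are
  discriminated from spikes by their slow-band energy fraction, and
  synchronous IILDs on adjacent electrodes group into network events.
* **Spatial mapping** — landmark-based affine registration of the
  electrode grid onto histology images and dysmorphic-neuron density
  *d* (cells/mm², with DN = pS6⁺ ∧ NeuN⁺ ∧ soma >25 µm) per
  electrode-activity class over Voronoi class regions.
* **Histology quantification** — threshold / watershed / 25 px²
  size-gate segmentation, marker co-labeling fractions with
  Clopper–Pearson intervals (senescence panel: SAβGal, p53, p16, p21,
  SMI311, VIM, nuclear Hmgb1/LaminB1 loss), and mutant-cell fraction
  from variant allele frequency (`min(1, 2·VAF)` under heterozygosity).
* **Longitudinal EEG** — Morlet (1–50 Hz) band-power seizure detection,
  daily seizure frequency per animal, and pre / end / post treatment
  phase comparisons.
* **Exact statistics** — two-tailed exact Mann–Whitney rank-sum test by
  full enumeration (`p = 2 × min(tails)`, capped at 1), with a seeded
  permutation fallback for ties or large samples. Complete separation
  gives the exact floors `2/choose(n1+n2, n1)` — 0.0286 at 4 vs 4,
  0.0022 at 6 vs 6.

Seeded synthetic-data generators (MEA recordings, histology cell
maps/images, EEG seizure studies) emulate the statistical structure of
the original data with known ground truth, so the whole chain is
testable without any external download. See the methods vignette
(`vignettes/epimosaic-methods.Rmd`) for the model assumptions and design
choices.

## Worked example

Simulate a recording with a core (IILDs + MUA) / surround (MUA only) /
silent gradient, detect events, and compare MUA on IILD⁺ vs IILD⁻
electrodes:

```r
library(epimosaic)

lay <- mea_layout(4, 5, pitch_h_um = 1000, pitch_v_um = 1000)
cfg <- mea_sim_config(seed = 42, duration_s = 300, layout = lay)
sim <- gen_mea_recording(cfg)
det <- detect_recording(sim$recording)

table(det$activity$cls)
#> IILD_MUA MUA_ONLY   SILENT
#>        4       10        6

iild_pos <- det$activity$mua_rate_hz[det$activity$cls == "IILD_MUA"]
iild_neg <- det$activity$mua_rate_hz[det$activity$cls == "MUA_ONLY"]
round(c(mean(iild_pos), mean(iild_neg)), 3)
#> [1] 0.681 0.051

mann_whitney_exact(iild_pos, iild_neg)
#> Mann-Whitney rank-sum test (permutation_mc)
#>   U = 40 (n1 = 4, n2 = 10), two-sided p = 0.00212
```

The detected rate contrast (0.68 vs 0.05 Hz) recovers the configured
core/surround MUA rates (0.74 vs 0.05 Hz), and the rank-sum test
confirms that IILD-bearing electrodes carry significantly more MUA.
(Two surround electrodes fell below the 10-spike classification
minimum and were labelled silent; tied rates route the test to the
seeded permutation path.)

Co-labeling and mutant load:

```r
panel <- gen_colabel_panel(seed = 42, n = 300)
colabel_fraction(panel, "SABGAL", "P53")
#> SABGAL+P53+ / SABGAL+: 275 / 300 = 91.7% (95% CI 87.9-94.5%)

mutant_cell_fraction(0.42)
#>    vaf cell_fraction heterozygous_consistent
#> 1 0.42          0.84                    TRUE
```

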