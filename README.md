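# sxreduce

Lossy data reduction and merging-quality metrics for serial crystallography
frame stacks.

Serial crystallography (SX/SFX) experiments collect up to millions of
detector frames per dataset. Most frames contain no crystal diffraction,
and even hits are dominated by smooth background around sparse, bright
Bragg peaks — while the quantity that actually matters, the merged
reflection intensities, is an average over thousands of redundant noisy
observations. Far less precision needs to be stored than detectors record.
`sxreduce` is for beamline and data-analysis scientists who want to measure
that trade-off: every standard lossy reduction operator, lossless-codec
compression accounting, and the split-half merging statistics that price
the information loss — all exercisable end to end on a built-in synthetic
diffraction-data generator, no downloads required.

## What it implements

**Reduction operators** (all tie-breaking is round-half-away-from-zero,
fixed for bit-reproducibility):

| operator | function | effect |
|---|---|---|
| vetoing | `vetoNonHits()` | drop frames without ≥ `minPeaks` detected Bragg peaks; hits kept bit-identically |
| binning | `binFrame()`, `binStack()` | sum b×b pixel blocks (photon-conserving); mask-aware |
| peak remapping | `remapPeaks()` | `new = (old + 0.5)/b − 0.5`, exactly invertible |
| peak-only retention | `peakOnlyMask()` | keep windows around peaks (to demonstrate its cost) |
| uniform quantization | `quantizeUniform()` | nearest multiple of a step in ADU |
| photon conversion | `aduToPhotons()` | `round((v − offset)/gain)`, negatives allowed |
| MSB rounding | `msbRound()` | nearest value with k ∈ {1,2,3} significant binary digits; relative error ≤ 2⁻ᵏ |
| minifloat8 | `toMinifloat8()` | 1/5/2-bit float re-encoding; equals `msbRound(·, 3)` for integer magnitudes ≥ 4, clamps at 114688 |

**Metrics** (`splitHalf()`, `mergeObservations()`, `mergingMetrics()`):
R_split = (1/√2)·Σ|I_A − I_B| / (½·Σ(I_A + I_B)), CC½ (Pearson on
half-dataset merged intensities), CC\* = √(2·CC½/(1+CC½)), CC_ano (Bijvoet
difference correlation), mean I/σ(I) and completeness, overall and in
equal-volume (1/d)³ resolution shells.

**Storage** (`writeStack()`, `readStack()`, `codecSurvey()`): a chunked,
self-describing container with gzip/bzip2/xz codecs and byte/bit-shuffle
pre-filters, CXI-style padded peak arrays (`writePeaks()`), and
compression-ratio accounting against the payload bytes.

**Simulator** (`simulateFrame()`, `simulateDataset()`,
`simulateObservations()`): Poisson photon noise on a smooth radial
background with Gaussian Bragg peaks (counting or integrating detector,
gain/offset/readout noise, configurable hit rate), and reflection
observation tables with known truth, lognormal scale jitter and optional
anomalous signal. Fully deterministic per (seed, frameId).

## Worked example

```r
library(sxreduce)

cfg <- frameSimConfig(seed = 7)              # 128x128 counting detector, 30% hit rate
sim <- simulateDataset(cfg, nFrames = 50)
sum(sim$truth$isHit)
#> [1] 10

veto <- vetoNonHits(sim$stack, cfg@geometry, peakFindParams(), minPeaks = 10L)
veto$report
#> ReductionReport: 50 -> 10 frames | chain: veto | 139 distinct values | max abs err 0, max rel err 0

red <- runReductionChain(veto$stack, c("bin:2", "msb:2"))
writeStack(red$stack, tempfile(), codecSpec("gzip", shuffle = "byte"),
           chain = red$report@chain)
#> CompressionReport: 10 frames [photon_count_integer], gzip lvl6/byte: 163840 -> 14813 bytes (CR 11.06)
```

Against the raw 50-frame stack (3.3 MB uncompressed, codec-only CR 8.2),
the full chain — veto the 40 non-hits, bin 2×2, keep 2 significant bits —
stores 14.8 kB: an end-to-end compression ratio of about 221. The
information cost is measured on the merging side:

```r
obs <- simulateObservations(obsSimConfig(nUniqueHkl = 1500L, seed = 7))
qualityVsReduction(obs, list(raw  = list(),
                             msb2 = list(quantizationSpec("msb", keepBits = 2))))
#>   chain rSplit ccHalf ccStar    ccAno nCommon
#> 1   raw 0.1314 0.9586 0.9894 -0.10575    1458
#> 2  msb2 0.1397 0.9540 0.9882 -0.02444    1458
```

Keeping 2 significant bits moves R_split from 13.1% to 14.0% and CC\* by
one part in a thousand on this synthetic dataset — the characteristic
result: aggressive non-uniform quantization costs little merged quality
because the quantization error tracks the counting noise.

A thin CLI wraps the same functions for shell use
(`inst/cli/sxreduce simulate|reduce|metrics|study --config cfg.yaml`), with
YAML configs, provenance sidecars and machine-readable TSV outputs.

## Package layout

- `R/` — S4 classes (`DetectorFrame`, `FrameStack`, `PeakList`,
  `ObservationTable`, `MergedTable`, `QuantizationSpec`, `CodecSpec`, ...),
  operators, metrics, I/O, pipeline.
- `tests/testthat/` — unit, property and end-to-end acceptance tests.
- `vignettes/data-reduction-methods.Rmd` — the models, parameter choices,
  numerical conventions and limitations, in detail.
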