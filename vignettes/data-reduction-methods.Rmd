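---
title: "Lossy data reduction for serial crystallography: models and methods"
author: "sxreduce"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lossy data reduction for serial crystallography: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sxreduce)
```

# The problem

A serial crystallography (SX/SFX) experiment fires X-ray pulses at a stream
of micro-crystals and records one detector frame per pulse, accumulating
from hundreds of thousands to millions of frames per dataset. Only a
fraction of frames — the *hit rate*, often between 0.1% and 10% — contain
crystal diffraction at all, and even a hit is dominated by a relatively
smooth background surrounding sparse, bright Bragg peaks spanning several
orders of magnitude in intensity. Because the final structure is obtained by
*merging* very many redundant, noisy observations of each reflection, the
per-pixel precision actually needed is far below what detectors record. That
opens the door to lossy reduction schemes whose information cost can be
measured directly with merging statistics.

`sxreduce` implements the standard operator families —

* **vetoing**: discard frames without detectable crystal diffraction,
  keeping hits in raw form;
* **binning**: sum b x b pixel blocks, remapping previously found peak
  coordinates into the binned frame;
* **peak-only retention**: keep only windows around found peaks (supported
  so its damage can be demonstrated — it discards the weak inter-peak signal
  that merging would recover);
* **quantization**: uniform steps, ADU-to-photon conversion, rounding to
  1–3 most-significant bits (MSB), and an 8-bit minifloat re-encoding —

together with lossless-codec compression accounting and the split-half
metrics (R~split~, CC~1/2~, CC\*, CC~ano~, I/σ, completeness) that quantify
what each operator costs.

# The synthetic data generator

Nothing in the package needs real beamline data: `simulateFrame()` /
`simulateDataset()` generate frames with the statistical structure that
matters to the operators, and `simulateObservations()` generates unmerged
reflection tables with known truth.

**Frame model.** The expected photon image is a smooth radial background,
a Gaussian bump of amplitude `bgAmplitude` (b0) and width `bgWidth` over a
floor `bgFloor` (b1), plus — on hit frames — `nPeaks` Gaussian Bragg peaks of
width `peakSigma`. Peak total intensities are exponentially distributed with
mean `peakMeanIntensity`, attenuated by a Wilson-type factor
exp(−2·B·(1/(2d))²); the exponential law and the B-factor are modelling
choices made to produce the multi-order-of-magnitude dynamic range seen in
practice (no specific law is canonical). Pixel values are Poisson draws of
the expected image; integrating detectors then apply `gain` ADU/photon, an
`offset`, and Gaussian readout noise, which is why their calibrated values
are real-valued and can be negative. Peak *positions* are rejection-sampled
uniformly with a minimum pairwise separation (default 8 px, in the 5–10 px
range where binning keeps peaks distinguishable) rather than projected from
a crystal lattice: indexing is out of scope, so lattice geometry would add
realism the operators never see. One rectangular panel is simulated;
multi-panel tiled detectors are not.

**Default study conditions.** A 128 x 128 panel of 200 µm pixels at 80 mm
and 12.398 keV (1 Å wavelength), background ~5 photons/px at the beam center
falling to 1, 25 peaks per hit of mean 400 photons, Wilson B = 15 Å²,
hit rate 0.3. These are fixed, deliberately modest desk-scale conditions; a
real 16-megapixel dataset differs in scale, not in the statistical features
the operators exploit. The veto and study checks use 2000 x (64 x 64) and
60 x (96 x 96) frames respectively — sizes chosen so the full pipeline runs
end to end on one CPU in minutes while keeping every rate estimate inside
its stated statistical band.

**Reproducibility.** A single root seed governs everything. Each frame
draws from child streams derived from (seed, frameId) — separate salted
streams for the hit flag, background photons, peaks and readout noise — so
any frame is reproducible in isolation and a hit frame differs from its
non-hit twin only by added peak photons (an exact, tested invariant).

**Observation model.** Unique reflections take integer hkl from a lattice
ball scaled to the resolution range. True intensities are exponential with
a Wilson-mean falloff. Each observation is `scale * I + ε` with a lognormal
scale (SD `scaleJitterSd`, default 0.3 — the dominant SX error source,
standing in for unknown partiality and shot-to-shot scale) and Gaussian ε
with σ(I) = sqrt(σ0² + (f·I)²). Friedel mates get I·(1 ± anomalousFraction/2)
with a random sign per reflection. What this does *not* model: real
partiality profiles, spatial detector artefacts, indexing ambiguities,
non-isomorphism. Passing tests therefore demonstrate the operators' and
metrics' correctness and directional behaviour, not beamline-grade absolute
numbers.

# The quantizers

All quantizers share one tie rule — **round half away from zero** — fixed
globally so results are bit-reproducible (no canonical rule exists for
these operators; one had to be chosen).

**Uniform** (`quantizeUniform`): nearest multiple of `step` ADU.

**Photon conversion** (`aduToPhotons`): round((v − offset)/gain). With the
default gain 73.14 ADU/photon, 1024 ADU becomes 14 photons. Negative
outputs are allowed (dark-subtracted integrating detectors go below zero);
the sign convention is: quantize the magnitude, restore the sign.

**MSB rounding** (`msbRound`): the non-uniform, relative-precision
quantizer. The representable set for k kept bits is {0} ∪ {m·2^e} with m
carrying at most k significant bits; each value maps to the nearest member.
Levels are dense at low counts and sparse at high ones, in proportion to
counting noise — weak high-resolution reflections keep nearly full
precision. The relative error is bounded by 2^−k; the tests verify this
exhaustively over ±65535 against a brute-force enumeration oracle, along
with idempotence. A truncation variant (zero all bits below the kept ones)
is provided for comparison.

**Minifloat8** (`toMinifloat8`): 1 sign / 5 exponent / 2 mantissa bits,
exponent bias 15, exponent field 0 reserved for subnormals, and *no*
infinity or NaN codes — all 31 remaining exponent values are numeric. This
choice maximizes usable codes and covers a 16-bit dynamic range: the
largest magnitude is 1.75·2^16 = 114688, where encoding clamps. For integer
magnitudes ≥ 4 (implicit leading 1 + 2 mantissa bits = 3 significant bits)
requantization equals `msbRound(x, 3)` exactly — verified exhaustively.

Operator chains have a canonical order (veto → bin → photon/uniform →
msb/minifloat8); `runReductionChain()` honors any declared order but warns
when it deviates, since e.g. quantizing before vetoing can change which
frames survive. Whether MSB rounding is applied before or after photon
conversion is legitimately instrument-dependent; both orders work.

# Binning and peak remapping

`binFrame()` **sums** b x b blocks rather than averaging, so photon counts
are conserved exactly (a tested invariant) and counting statistics stay
interpretable. An output pixel is usable only if *all* its inputs were
usable; when b does not divide a dimension the trailing rows/columns are
dropped with a warning. A factor equal to the panel size is allowed (the
frame collapses to one pixel); only factors exceeding a dimension error.
Peak positions found before binning are remapped with the pixel-center
convention `new = (old + 0.5)/b − 0.5` — exactly invertible, with the panel
corner (−0.5, −0.5) as fixed point — so full-precision peak coordinates ride
along with the binned stack.

# Peak finding and vetoing

The finder follows the local-annulus-statistics design used across SX
pipelines: candidate pixels exceed the local background by `snrMin` robust
sigmas (σ = 1.4826·MAD, resistant to contamination of the annulus by
neighboring peaks), 8-connected components sized within `[minPix, maxPix]`
become peaks, and per-peak background/σ are re-estimated from a Chebyshev
annulus excluding candidate pixels. Candidate screening uses per-tile
medians (tiles of ~2·outer radius + 1 px), which track the smooth radial
background; the final statistics are annulus-local. Components touching the
panel edge are kept and flagged rather than discarded, which would bias hit
finding on small panels. Masked pixels never enter any statistic. The
defaults (snrMin 6, 2–40 px components, ≥ 10 peaks for a hit) are
config-exposed because real experiments tune them per dataset.

`vetoNonHits()` keeps hit frames *bit-identically* — raw retention — so
improved calibrations can be applied later; only the non-hits are lost.

# Merging metrics

`splitHalf()` assigns patterns to halves by parity of the rank of their
pattern id: deterministic, independent of row order (a seeded random split
is available behind a flag). Merged intensities are plain means; the merged
sigma is the sample SD of the mean for multiplicity ≥ 2 and the input sigma
for singletons.

R~split~ = (1/√2)·Σ|I_A − I_B| / (½·Σ(I_A + I_B)) over reflections common
to both halves; CC~1/2~ is the Pearson correlation of the same pairs;
CC\* = sqrt(2·CC~1/2~/(1 + CC~1/2~)); CC~ano~ correlates Bijvoet
differences between halves. Overall values are computed over *all* common
reflections, not averaged over shells, matching the convention of the
standard merging tools. Resolution shells are equal-volume in (1/d)³ (no
canonical shell scheme exists; this one is configurable). Undefined results
— zero denominators, CC~1/2~ ≤ 0 under CC\*, shells with < 3 reflections —
propagate as explicit `NA`/"n/a", never silently as 0.

# Storage and compression accounting

Stacks are stored in the package's chunked container format (magic `SXC1`):
a JSON header describing every dataset, then per-chunk codec-compressed
payloads, one frame per chunk by default so frames stay individually
addressable during vetoing. Codecs are gzip, bzip2 and xz (the codecs base
R exposes; the recorded `level` is informational — the library default,
which for gzip corresponds to level 6, is what runs), optionally preceded
by an in-package byte- or bit-shuffle pre-filter that regroups equal-order
bytes/bit-planes across elements. Peak lists use the CXI-style padded
layout (`nPeaks`, `peakXPosRaw`, `peakYPosRaw`, `peakTotalIntensity`, ...).
Compression ratios are quoted against the payload dataset only, so masks
and metadata never distort them, and `runStudy()` quotes all CRs against
the *original* raw payload so spatial reduction contributes to the ratio as
it does in practice. The lossy chain applied upstream is recorded verbatim
in the file metadata: provenance of lossy steps is never lost.

# A worked degradation study

```{r study, eval = FALSE}
study <- runStudy(list(
  seed = 11,
  frames = list(n_frames = 60L, seed = 11, hit_rate = 1,
                geometry = list(n_fast = 96L, n_slow = 96L,
                                pixel_size = 2e-4, detector_distance = 0.08)),
  observations = list(n_unique_hkl = 1500L, seed = 11)))
study
```

The ladder raw → bin → bin+msb3 → bin+msb2 → bin+msb1 yields strictly
decreasing stored size and non-decreasing R~split~ — the central trade-off:
each kept bit dropped buys compression and costs a measurable amount of
half-dataset agreement. The same monotone direction appears when the
observation set shrinks along 1 → 1/4 → 1/16 of patterns, reflecting the
1/√N behaviour of merging statistics.

# Numerical and degenerate-input choices

* Tie-breaking: away from zero, everywhere.
* `msbRound`/`toMinifloat8` require integer-valued input and say so;
  convert or quantize reals first.
* Exact powers of two are fixed points of MSB rounding; `floor(log2())` is
  guarded against off-by-one floating-point landings.
* Empty peak lists have undefined (NA) per-pattern resolution, not 0.
* A frame whose mask excludes every pixel is an error, as is a peak-packing
  request that cannot satisfy the separation constraint (bounded rejection
  sampling, error names the constraint).
* Merged tables join on exact integer hkl; reflections present in one half
  only are excluded and counted.

# Known limitations

* One rectangular panel; no tiled geometries, no per-panel gain maps.
* No lattice/Ewald geometry, indexing, profile fitting or structure
  refinement — quality is judged by merging statistics only, which is
  exactly the regime the toolkit targets.
* The container format is package-specific (self-describing and stable, but
  not HDF5); zstd/lz4/blosc codecs are not available through base R and are
  therefore out of the codec set.
* Simulated backgrounds are radially smooth by construction; real frames
  add jet streaks, ice rings and shadows that a production peak finder must
  also handle.
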