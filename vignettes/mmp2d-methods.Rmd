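---
title: "Compressing surface EMG as images: the mmp2d codec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compressing surface EMG as images: the mmp2d codec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmp2d)
```

## The problem

Surface electromyography (SEMG) records muscle electrical activity through
skin electrodes, typically at 2000–2048 Hz with 12-bit quantization.
Records are long, channels are many, and archival or wireless transmission
calls for compression that preserves the waveform (and hence the clinical
content).  One productive family of methods rearranges the 1-D record as a
2-D array — one fixed-length segment per column — and hands the "image" to
a two-dimensional coder, hoping inter-segment correlation shows up as
vertical coherence.  SEMG images are noise-like, however: their energy is
spread across the whole band, which is hostile to transform–quantization
coders.  `mmp2d` instead implements a recurrent-pattern-matching codec — a
modified two-dimensional multiscale parser (MMP) — that makes no spectral
assumption and adapts its dictionary to the signal being coded, plus two
preprocessing algorithms (PDS and SbS) that make off-the-shelf image
coders work better on the same matrices.

## Matrix formation

`segment_to_matrix()` fills a `K x L` matrix column by column; `K` is the
segment length.  Without preprocessing, `K = ceiling(sqrt(n))` yields a
matrix as square as padding allows (`L` is `K` or `K - 1`).  The trailing
shortfall is padded with zeros — the mean of the zero-centered signal, so
the padding injects minimal energy into the last column — and the true
sample count rides in the container header, making `matrix_to_record()`
an exact inverse.  Samples are stored zero-centered: an unsigned 12-bit
acquisition is shifted by 2048 at load and the offset travels in the
header.  Prediction residues and the symmetric dictionary range `[-X, X]`
both assume signed data, which is why the shift happens at the boundary
of the package rather than inside the codec.

## The codec

### Scales and the dictionary

Blocks of `M x N` samples, `M, N` powers of two up to 16, are indexed by a
scale `1..25` (`scale_index()`): `1x1` is scale 1, `16x16` is scale 25.
Each scale has its own subdictionary.  Scale 1 initially holds **every**
integer in `[-X, X]`, where `X` is the largest absolute value of the
current image (carried in the header); this exhaustive base alphabet is
what makes `lambda = 0` exactly lossless.  Every other scale starts with
homogeneous blocks whose levels climb from `-X` in magnitude-dependent
steps (`dict_level_step()`): 1 up to magnitude 10, then 4, 8 and 13 —
densest near zero, where residues concentrate.

When a coded block is segmented, the concatenation of its two children's
reconstructions becomes a new pattern, resampled to all 25 geometries by
a separable transform (`scale_transform()`: box averaging on contraction,
linear interpolation on expansion) and appended to each scale's partition
for the originating scale — but only if its mean squared difference per
sample to every existing entry exceeds the redundancy threshold
`d(lambda)` (`redundancy_threshold()`: 20/40/60/80 over the lambda
bands).  "Distance" is not further specified in the MMP literature for
this codec; per-sample MSE was chosen because it is scale-free across the
25 geometries.  Initial entries are constructed before the threshold
applies and are exempt.  A per-scale cap (default 50 000 entries,
`mmp_options(cap = )`) bounds memory.  Note one consequence of the
exhaustive scale-1 alphabet: scale 1 never grows, since every candidate
collapses onto an existing value.

Two features of the MMP-II lineage are treated as options: the *additive
symmetric* (inserting `-pattern` alongside `pattern`) is implemented and
off by default; *norm equalization* is named in the lineage but not
specified for this codec, so it exists only as a configuration stub that
refuses to switch on.

### Rate-distortion optimization

Each 16x16 block is coded by the tree minimizing the Lagrangian cost
`J = D + lambda * R` (`D` = sum of squared differences, `R` = bits).  A
node either matches a single dictionary entry (flag 0), splits its
residue vertically or horizontally (flags 1/2 — a vertical cut halves the
width), or, at scales 25 down to 9, splits through the hierarchical
prediction layer (flags 3/4).  A parent is split only when the children's
total cost is *strictly* lower; ties keep the parent, which both matches
the cost model (fewer flags) and makes the choice deterministic.

Rates come from the adaptive arithmetic-coding models *frozen at the
start of the block's optimization*; actual emission then updates them.
Dictionary updates collected while coding a block are likewise applied
when the block completes.  Both freezes exist for decoder symmetry: the
decoder can reproduce the exact rate/dictionary trajectory without ever
running the optimizer, and the package asserts encoder/decoder state
equality after every block as its central test.

### Prediction

Prediction follows HEVC intra coding: 33 angular modes with the standard
displacement table and 1/32-sample interpolation, planar (the average of
a horizontal and a vertical linear interpolation), and MFV — the modal
value of the reference vectors — in place of DC.  Two reference vectors
serve all scales: the *vertical* vector (corner, left and lower-left
boundary) feeds modes 2–17 and the *horizontal* vector (corner, above and
upper-right) feeds modes 18–34, each `2 max(M, N) + 1` samples long.
Unavailable references are substituted by propagation, with 0 (the signal
mean) as the last resort.  Reference smoothing is deliberately omitted:
SEMG images are noise-like and low-pass filtering the references would
only bias the predictions.  No prediction is attempted at scales 1–3;
planar is limited to the square scales 4, 9, 16, 25; MFV and the angular
modes are available everywhere above scale 3 (the gating of MFV at
non-square scales is not specified anywhere we know of, so it is left
ungated).  Rounding of interpolated values is half-away-from-zero, the
symmetric choice for signed data.

### Bitstream grammar

The optimal tree serializes top-down, left/upper subtree first: flag 0 is
followed by (mode, if the node carries one, then) a dictionary index,
coded as origin partition plus index-within-partition; flags 1–4 are
followed by their two subtrees.  The canonical predicted example
serializes to `3 0 M1 i0 2 M2 0 i1 2 0 i2 0 i3`.

One grammar point is underdetermined by the flag list alone: when the
decoder meets flag 0/1/2 at a prediction-eligible node, it must know
whether a mode symbol follows, and a block must also be codable *without*
prediction — residues of a predicted block can leave `[-X, X]`, so
mandatory prediction would break the lossless limit.  `mmp2d` resolves
this by making every flag-0/1/2 node of the prediction layer open a
"region" whose mode alphabet contains an extra **"no prediction"** id
(35) beside planar/MFV/angular; inside a region only flags 0/1/2 occur
and carry no modes.  The grammar is deterministic to parse, reproduces
the canonical string above, and degrades gracefully: choosing id 35
everywhere is exactly classic unpredicted MMP.

### Entropy coding

All symbols pass through one 32-bit arithmetic coder with adaptive
frequency tables: separate per-scale tables for prediction-layer flags,
residue flags and modes, a per-scale partition table, and a growing
per-(scale, partition) index table.  Counts start at 1, increase by 1,
and rescale at a total of 2^14 (or twice the alphabet size for the large
index alphabets, which would otherwise rescale on every symbol).  The
layer is exactly lossless; the only loss in the system is dictionary
approximation.  The PDS permutation is coded by the same coder over the
`0..L-1` alphabet and byte-aligned into the header.

### Encoder search effort

Testing all 35 mode candidates at every eligible node, as the exhaustive
search does, multiplies encoding time by an order of magnitude for
fractions of a percent in rate.  The default `search = "fast"` therefore
ranks modes by the SAD of their prediction against the block and fully
evaluates only the best `n_full_modes` (default 2) plus "no prediction";
`search = "thorough"` restores the exhaustive search.  This is an
encoder-side heuristic in the spirit of HM's fast mode decision: the
bitstream format, the decoder and all correctness properties are
unaffected.  Similarly, the scale-1 dictionary search exploits the fact
that partition 0 is the contiguous integer alphabet and scans outward
from the nearest value with a lower-bound cutoff; the result is
cost-equivalent to the exhaustive scan (tie-breaking among equal-cost
values may differ, which is immaterial because the chosen index is coded
explicitly).

## Preprocessing

**PDS** (`pds_sort()`) greedily reorders columns: the minimum-variance
segment first (population variance; ties to the lowest original index),
then repeatedly the unplaced segment minimizing the percentage difference
`PD(x, m) = sum((x - m)^2) / sum(x^2)` to the last placed one.  `PD` is
implemented literally, without a factor 100 — the name notwithstanding,
only the argmin matters.  A zero-energy reference would make `PD`
undefined; the greedy scan then falls back to the unnormalized numerator,
which preserves the ordering intent.  The permutation is arithmetic-coded
into the header.

**SbS** (`sbs_select_length()`) instead chooses the segment length:
candidates `N = 16 n`, `n = 2..64`, are scored by the mean `PD` between
adjacent segments (in original signal order), and the smallest-scoring
`N` wins, ties to the smallest `N`.  The trailing partial segment is
excluded from scoring rather than padded, so all scored pairs have equal
length.  SbS operates on the 1-D record before matrix formation — matrix
formation and preprocessing collapse into one step, and no side
information is needed.

## Metrics

`prd()` implements the percent root-mean-square difference
`100 sqrt(sum((x - xhat)^2) / sum(x^2))` on the restored 1-D integer
signal (no mean removal — the definition is applied literally), and
`cf()` the compression factor `100 (B_o - B_c) / B_o` with `B_o = 12 n`
bits and `B_c` the container size in bits, byte padding included.
`rd_sweep()` drives the full pipeline across a lambda grid (default
`{0, 2, 4, 8, 16, 32, 64, 128}`, spanning all redundancy-threshold
bands); CF grows and PRD grows with lambda, monotone up to occasional
single inversions caused by the input-dependent dictionary adaptation.

## Synthetic signals

No public corpus accompanies the acquisition protocols this package
targets, so `gen_isometric()` and `gen_dynamic()` generate statistically
matched stand-ins: band-limited (10–500 Hz, 4th-order zero-phase
Butterworth — the band is prescribed, the filter family is the package's
choice) noise with Gaussian amplitudes (forceful isometric contractions;
near-Laplacian for light force, both offered), quantized to 12 bits at
2000 Hz; the dynamic variant modulates the carrier with a raised-cosine
burst envelope (default 30 contraction cycles/min, ±10% amplitude and
±5% period jitter) at 2048 Hz before filtering.  Records occupy about
70% of the signed 12-bit range — enough headroom to avoid clipping while
exercising every dictionary step band.  The generators reproduce
amplitude distribution, bandwidth, dynamic range and burst structure;
they have no motor-unit physiology, electrode artifacts or fatigue
drift, so green tests certify codec correctness and qualitative
rate-distortion behavior, not clinical performance on real records.

## Problem sizes and numerical choices

The test suite runs entirely on generated data at desk scale: records of
256–512 samples (one to four 16x16 blocks per encode), 64x64 matrices
for the state-synchronization checks, and an 8-point lambda sweep on a
fixed 512-sample record — sizes chosen so the whole suite completes in a
few minutes while touching every code path, including partial edge
blocks, all three preprocessing modes and both synthetic protocols.

Collected numerical conventions: pad value 0; rounding
half-away-from-zero in prediction and scale transforms; strict-inequality
split rule with ties to the parent; best-match ties to the lowest
partition, then lowest index; MFV ties to the smallest value; population
variance for the PDS seed with ties to the lowest index; SbS ties to the
smallest length; dictionary levels generated in one pass from `-X`
(not mirrored, so the positive end may stop short of `+X`); signal-domain
update patterns clipped to `[-X, X]` on insertion.

## Limitations

The encoder is exhaustive in segmentation but heuristic in mode search by
default; 32x32 input blocks are deliberately unsupported (the extra
scales do not pay off on noise-like images); there is no error
resilience or streaming in the container; and PRD is a waveform metric —
no claim is made about diagnostic-quality measures beyond it.
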