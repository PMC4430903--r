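---
title: "Detecting rare tumor cells on tiled immunofluorescence slides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting rare tumor cells on tiled immunofluorescence slides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctcscan)
```

## The problem

Circulating tumor cells (CTCs) are epithelial-origin cells found in blood
at extreme rarity — on the order of one per million leukocytes. Slide-based
detection spreads the nucleated blood fraction as a monolayer, stains four
fluorescence channels (nuclear dye; cytokeratin, CK; CD45; an auxiliary
epithelial marker such as EpCAM or EGFR) and scans the slide as a grid of
overlapping camera fields of view. The computational task is to find every
CK-positive, nucleated, CD45-negative object across thousands of tiles,
reject stain artifacts and contaminants, merge duplicate sightings from
tile overlaps, and hand back slide coordinates precise enough for
single-cell retrieval. `ctcscan` implements that pipeline plus the
statistics used to validate such platforms with spike-in experiments, and
a slide simulator that provides exact ground truth.

## The image model and the simulator

The simulator emulates a buffy-coat spread, not optics: there is no PSF,
no z-dimension, no staining-chemistry variation. Cells are smooth radial
intensity profiles on a 16-bit scale:

* every disk is a truncated Gaussian with `sigma = radius / 2`, cut at
  `2.5 sigma`. The profile peaks at the cell's per-channel amplitude, and
  its integral has the closed form
  `2 * pi * sigma^2 * A * (1 - exp(-2.5^2 / 2))`, which the tests use as a
  numerical oracle;
* the surface-marker channel of a tumor cell is rendered as a Gaussian
  annulus peaking on the cytoplasm radius (membrane-like);
* background is `background_level` plus a linear drift
  (`background_gradient`, counts per mm of slide x + y), noise is additive
  Gaussian (`noise_sd`), clipped at zero and rounded to integer counts.
  Poisson shot noise is deliberately omitted: it is not needed to exercise
  any algorithm in the pipeline.

Four populations cover what the detector must separate: tumor cells
(nucleated, CK disk, marker rim, CD45-negative), leukocytes (nucleated,
CD45 only), squamous venipuncture contaminants (large CK area, small
nucleus relative to it, CD45-negative) and anucleate CK debris fragments.
Default geometry (µm radii, nucleus/cytoplasm): tumor 5/6, leukocyte
4.5/5, squamous 10/18, debris fragments of radius 2. Default amplitudes
put every stained channel 2 orders of magnitude above the noise floor,
which matches a well-stained slide; dim-cell sensitivity is tunable but is
not a default study condition.

Leukocytes are placed uniformly with overlaps allowed — crowding is part
of the conditions being emulated. Rare cells are rejection-resampled until
their centre is at least `max(min_separation_um, r_a + r_b + 5)` µm from
every previously placed cell (rendered extents `r`; default
`min_separation_um` 30), and inset from the slide edge by their rendered
extent. The radius-sum term matters for the large squamous population:
without it a squamous cell can coalesce with a tumor cell into a single CK
component, which is a different (cluster-like) scenario than the
contaminant study intends. Declared tumor clusters are exempt among their
members.

The default slide is a 3×3 grid of 900 px tiles at 0.65 µm/px with 50 µm
overlap (≈1.66 × 1.66 mm, ≈2.7 mm² — a desk-scale stand-in for the
~2500-tile production scan), carrying 2000 leukocytes and the
single-digit-spike contaminant scenario (3 tumor + 2 squamous). At these
defaults a slide renders in a few seconds and the whole scan runs in
seconds on one core; tests use smaller grids (1–2 × 2 tiles of 240–400 px)
for the same reason. Identical configuration and seed give bit-identical
slides; rendering consumes no randomness (debris shapes derive from the
cell id), so tiling the same extent differently changes nothing about the
ground truth.

What passing tests on this simulator do *not* show: robustness to focus
drift, uneven staining, autofluorescence, red-cell carryover, or touching
cell clumps beyond declared clusters. Those belong to instrument
validation, not to this artifact.

## Adaptive thresholding

The tile-level background model is `median + k * 1.4826 * MAD`, default
`k = 6`, computed per channel over the whole tile. The published
description of the platform names only "an adaptive auto-threshold
algorithm"; the median/MAD form is this package's choice, made because the
objects of interest are sparse (so robust location/scale is unbiased by
them) and per-tile estimation absorbs illumination drift. `k = 6` puts the
cut at six noise SDs: on a 900² tile (~0.8 M pixels) the expected number
of noise pixels above threshold is ≪ 1, and single-pixel excursions are
removed by the 20 µm² area gate anyway. The nuclear channel is excluded
from detection thresholding; its threshold is computed identically but
used only for the nuclear-overlap and N:C measurements. A constant plane
(MAD = 0) is flagged degenerate rather than hidden.

Segmentation uses strict `>` (a degenerate threshold on a constant plane
selects nothing); per-object positivity uses `>=` so ties at a cutoff
resolve positive. Both conventions are deliberate and tested.

## Features and classification

Objects are 8-connected supra-threshold CK components, hole-filled,
area-gated at 20–2000 µm². The upper gate is generous so clusters pass;
separating single cells from oversized objects is the morphology gate's
job, downstream, where the decision is recorded with a reason. The CD45
correlation is Pearson *r* between CK and CD45 over the mask dilated by
2 px — the dilation captures membrane CD45 ringing a CK object. If either
channel is constant over that footprint, *r* is defined as 0 (no evidence
of co-staining), a convention that also covers noise-free synthetic
tiles.

The decision table, in order: (1) *r* ≥ `corr_reject_r` (default 0.5) and
CD45-positive → `NOT_A_CELL`, reason `cd45_correlation`; (2) CK+,
nucleated, CD45− → candidate; `CELL` if area ≤ 700 µm² and N:C ratio
≥ 0.15, else `NOT_A_CELL`, reason `morphology`; (3) CK+ and CD45+ below
the correlation cutoff → `INDETERMINATE`; (4) CK+, anucleate,
marker-positive → `INDETERMINATE`; (5) otherwise `NOT_A_CELL`. The
candidate flag is kept separate from the final label so "presented for
review" and "confirmed" counts can be compared — that distinction is what
makes the squamous-contaminant episode measurable (5 candidates, 3
confirmed). The auxiliary marker never vetoes a `CELL`: epithelial marker
expression varies biologically and is interpretive only. There is no
published numeric value for "highly correlative"; 0.5 is this package's
default, exposed in `rule_config()` for sensitivity analysis.

Two measured fractions deserve a note. The nuclear overlap fraction and
the N:C ratio are both computed as nuclear supra-threshold pixels within
the mask over mask area; they are reported under both names because they
gate different rules (nucleated-ness at 0.2; morphology at 0.15), and
because a future refinement could legitimately compute N:C from segmented
nuclear components instead. With the current identical definition, the
nucleated gate (0.2) binds first; the morphology gate separates squamous
contaminants by *area*. Consequently the simulated squamous population is
given a nucleus large enough (10 µm in an 18 µm cytoplasm, measured
fraction ≈ 0.3) to pass the nucleated gate, as real skin squamous cells on
these slides do — they are presented for review and rejected on size, not
silently dropped at detection. An alternative design with a
nucleus-relative overlap measure was considered and rejected because the
fraction-of-mask definition is directly testable with constructed masks.

The auxiliary `n_nuclear_components` column counts distinct nuclear blobs
inside a mask. Clusters of touching tumor cells segment as one object by
design (no watershed in this version); whether a cluster should count as
one event or per-cell is left to the analyst, and the column carries the
information needed for either convention.

## Geometry, deduplication, retrieval

Tile `(r, c)` origins sit on a stride of
`tile_px * pixel_pitch - overlap_um`; pixel (0,0) of tile (0,0) is the
slide origin, intervals are half-open, pixel indices 0-based with x along
columns. The 50 µm overlap guarantees any cell up to ~45 µm across is
imaged whole in at least one tile. Duplicates are merged by
single-linkage clustering at 15 µm — under half the overlap, and larger
than centroid jitter for 10–20 µm cells; each group keeps the member
farthest from its own tile border (the least truncated copy), ties broken
by object id, and `group_size` accumulates so deduplication is idempotent.
One knowable limitation: a cell much larger than ~30 µm straddling a tile
border can leave a *truncated* fragment whose centroid is beyond 15 µm
from the intact copy's; such fragments carry little of the nucleus, so
they surface as extra `NOT_A_CELL` rows, never as extra candidates or
cells, and the tiling-invariance property (identical `CELL` count whether
a slide is scanned as one tile or 2×2) holds and is tested. Pathological
chains longer than the radius merge into one group; accepted and
documented.

Chromatic aberration is estimated per channel against the nuclear
reference by FFT cross-correlation with parabolic sub-pixel refinement
(beads recover injected shifts to well under 0.5 px), and compensated by
bilinear translation. The simulator's default shift is zero — tiles are
modelled as already co-registered, the state after instrument-side
compensation — and tests inject non-zero shifts explicitly.

The picklist keeps only `CELL` rows and orders them serpentine (bands of
slide y at one stride, alternating x direction) to minimise stage travel;
the order is a pure function of coordinates, hence stable under input
permutation.

## Recovery statistics

`percent_recovery` is `100 * identified / spiked` at full precision;
tally-style reports floor the displayed percent (22 of 27 prints as 81%).
Per-line SDs use the sample (n−1) form; with a single experiment per line
the SD is reported as 0 with a `degenerate_sd` flag rather than NA, so
summaries stay machine-readable. The grand mean is reported both as the
unweighted mean of line means and as the pooled mean over experiments —
with balanced designs they coincide, and reporting both avoids committing
to one reading of "average recovery". The identified-on-spiked regression
is ordinary least squares via `lm()`; `n_identified` may exceed
`n_spiked` (contaminants), which is why recovery is not clamped at 100%.

The binomial simulator draws spike counts uniformly on 70–210 and
identifies each cell independently with probability `p` (default 0.905,
the observed mean recovery of such platforms; 20 experiments = 4 lines ×
5 replicates). Independence per cell is an idealisation — it ignores
slide-level loss correlation — but it reproduces the regression quality
(R² ≳ 0.98) and the unbiasedness of the recovery estimator, which is what
the statistics module is validated against.

## Numerical and degenerate-input choices

* Intensity scale unsigned 16-bit; planes are integer counts after
  rendering, so TIFF round trips are lossless.
* Empty inputs: an all-zero configuration yields an empty truth manifest
  and background-only tiles; a blank tile segments to zero objects; an
  empty detection table round-trips with its header; zero spiked cells is
  an explicit error, not NaN.
* Determinism: every stochastic step (placement, amplitudes, noise,
  binomial draws) flows from a single integer seed; scans of the same
  tiles are byte-identical.
* Problem sizes: default 3×3 × 900 px slides for end-to-end runs, 2×2 ×
  240–400 px in unit tests, 25 seeds for the regression-quality check —
  chosen as the smallest sizes at which the studied effects (crowding,
  overlap duplication, contaminant rejection) are all present.

## Known limitations

No optics model, single focal plane, no watershed splitting of touching
cells, no machine-learned detection, no interactive review tooling. The
morphology gate's area criterion assumes roughly disk-like single cells;
genuinely large CTC clusters would be candidates rejected as oversized
and should be assessed via `n_nuclear_components` and the raw detections
rather than the `CELL` tally.
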