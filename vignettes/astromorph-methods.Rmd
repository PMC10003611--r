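---
title: "Quantifying astrocyte number and branching: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying astrocyte number and branching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(astromorph)
```

## The measurement problem

Astrocytes express glial fibrillary acidic protein (GFAP), and both the
number of cells and the length and count of their processes increase
with activation (astrogliosis). In DAB-stained brightfield sections
photographed at ~20×, quantifying these by eye is slow and
user-dependent: cells are numerous, processes overlap, and DAB staining
is not stoichiometric, so absolute intensity carries little meaning.
`astromorph` implements a semi-automatic alternative: convert each
photomicrograph into a binary mask of stained structure, reduce the mask
to one-pixel skeletons, read each 8-connected skeleton as one putative
cell, measure its branches, and then apply a simple data-trimming rule —
a "cell" with a single branch is not an astrocyte — before aggregating
per image, per anatomical zone, and per treatment group.

The quantities the pipeline reports are *relative* markers: branches per
cell, cells per area, branch length per cell, the cell-normalized
branch-length histogram, and a per-cell (branch count, total length)
scatter that serves as a virtual cell size. They are designed to be
compared across groups processed identically, not to be stereological
estimates.

## Pipeline stages and their parameters

### Calibration

All geometry is computed in pixels and converted with a single scalar
`um_per_px` (from a scale-bar measurement:
`calibrate_from_scale_bar(length_px, known_um)`); images are never
resampled. The calibration is global to a batch, mirroring how a
microscope session is calibrated once.

### FFT bandpass

The filter retains spatial structure between `bandpass_small_px` (3 px,
noise scale) and `bandpass_large_px` (40 px, illumination scale). The
transfer function is a difference of Gaussian low-passes evaluated at
integer frequency radius $r$ on the padded $N \times N$ grid:

$$H(r) = e^{-(r\,d_{small}/N)^2} - e^{-(r\,d_{large}/N)^2},$$

so attenuation reaches $1/e$ at the frequency whose period equals the
stated structure size. The image is padded to a square power-of-two side
by edge replication before the FFT and cropped after, which suppresses
wraparound artifacts. This explicit form is part of the contract: the
test suite rebuilds it with explicit DFT matrices and requires agreement
within one intensity level.

Two numerical choices here are deliberate and consequential:

* **Sharpness.** The $1/e$-at-$d$ width suppresses sub-3-px noise more
  strongly than a softer Gaussian would. Residual pixel noise competes
  with the stained structures during thresholding (below); the sharper
  band measurably stabilizes threshold placement on sparse scenes.
* **Autoscale without saturation.** After filtering, the result is
  linearly rescaled to 0–255 between its minimum and maximum
  (`bandpass_saturate_pct = 0`). A fixed-percentage tail clip is
  implemented and available, but it is a poor default for this
  application: in a sparsely stained field the stained class may hold
  ~1% of pixels, so clipping even 0.5% per tail collapses much of that
  class into the zero bin. A one-bin class has near-zero Shannon
  entropy, and the maximum-entropy criterion then prefers to split the
  broad background instead of separating stain from background. Densely
  stained fields are insensitive to this choice; sparse ones fail
  catastrophically with clipping (measured: 0–10 of 25 synthetic scenes
  recover their cell count with 1–5% clipping, 25 of 25 without).

### Unsharp mask and despeckle

The unsharp mask computes $(I - w\,G_\sigma(I))/(1-w)$ with
$\sigma = 1$ px and $w = 0.6$, clipped to 0–255; it restores local
contrast of thin processes that the bandpass attenuates. Despeckle is a
3×3 median with replicated edges, applied to the grayscale image before
thresholding and to the binary mask after it. A median filter is *not*
exactly idempotent: on random binary masks a second pass keeps eroding
boundary configurations (measured: a second pass changes up to ~15% of
pixels on dense masks, and even sparse salt occasionally leaves 2–4 px
clusters that a second pass removes). The tests therefore assert what is
true — a single pass leaves ≥ 99.5% of pixels at their fixed-point value
on speckle-like masks, and iteration reaches an exact fixed point —
rather than exact idempotence.

### Maximum-entropy threshold

Kapur's criterion: choose $t$ maximizing $H_{[0,t]} + H_{[t+1,255]}$,
each term the entropy of the class-normalized histogram. Zero bins
contribute nothing; candidates are restricted to levels where **both
classes carry mass**. The restriction matters: with the convention that
an empty class contributes zero entropy, the degenerate empty/full split
would otherwise dominate any histogram whose two populations are
single spikes (the empty-side entropy of 0 plus the full two-spike
entropy beats 0 + 0 for every separating level). Restricting candidates
recovers the standard behavior: for a two-spike histogram every
separating level ties and the tie-break (smallest $t$) selects the first
one. The implementation is verified against exhaustive evaluation of the
criterion on 200 random histograms, exact integer equality.

Stained structures are dark on a bright background, so foreground is
`pixels <= t` (`dark_foreground = TRUE`). The mask convention is fixed —
foreground = stained = 1 — regardless of any display-time black/white
background option, which removes a genuine ambiguity in how such options
are usually described.

### Mask cleanup

Order is part of the contract: threshold → despeckle → close →
remove-outliers, each step repairing what the previous can leave.
Closing uses a 3×3 square element, `close_iterations` dilations then as
many erosions; out-of-image counts as background for dilation and
foreground for erosion, which keeps closing extensive and idempotent at
the borders. Outlier removal computes the median over the disk of radius
2 (pixels with center distance ≤ radius, center included; the median of
an even count is the mean of the two central order statistics) and
replaces a pixel deviating by more than 50 in the bright direction —
on the mask's 0/255 display representation, so the printed threshold
applies unchanged. Polarity is configurable (`"dark"` available).

### Skeletonization

Thinning is a two-subiteration scheme: candidate border pixels are
marked on the frozen image with the classic conditions
($2 \le B(p) \le 6$, crossing number $A(p) = 1$, alternating directional
products), then deleted *sequentially*, each deletion re-checked with an
8-simple test (one foreground 8-component and one background
4-component in the pixel's ring). The hybrid exists because each pure
strategy fails an invariant this package promises:

* purely parallel deletion removes an isolated 2×2 square entirely
  (all four pixels satisfy the marking conditions simultaneously),
  changing the component count;
* purely sequential deletion cascades along diagonal bands — each
  deletion re-exposes the next pixel as a deletable "tail" — consuming
  whole arms.

Marking on the frozen image blocks the cascade (mid-curve pixels have
$A(p) = 2$); sequential simple-point re-checking preserves topology
pixel by pixel. Two post-passes follow. First, every remaining 8-simple
non-endpoint pixel is deleted, which converges to a minimally
8-connected skeleton: without it, shallow curves keep redundant
staircase corner pixels whose neighbours then look like junctions,
shredding one arm into strings of 1–2 px "branches". Second, residual
2×2 blocks are resolved; the irreducible case is a diagonal X-crossing
whose four arms attach at the four corners, and it is repaired by
rewiring one corner through an orthogonal bridge pixel taken from the
original mask (so the skeleton stays a subset of the mask and the
component count is preserved). The cost of this scheme is tip rounding:
ends of a thick bar lose up to ⌈thickness/2⌉ + 1 pixels, which the
length tolerances account for. Pixel-exact agreement with any
particular legacy thinner is explicitly not claimed; the contract is
topological: skeleton ⊆ mask, no 2×2 block, component count preserved.

### Branch extraction

Skeleton pixels classify by 8-neighbour count: endpoint (1), slab (2),
junction (≥ 3). Adjacent junction pixels merge into one node; a branch
is a maximal slab path between nodes, a direct node–node adjacency, or
an isolated cycle; length is the chain sum (1 per orthogonal step,
√2 per diagonal) times `um_per_px`. Isolated pixels and node-only
components yield one zero-length record so every component appears in
the table.

One further merging rule is a declared convention of this package: a
$k$-way crossing cannot be represented by a single pixel, so the
skeleton of a cell with 5–6 processes necessarily contains short
junction-to-junction connectors spanning the crossing zone. Their length
is set by process thickness and soma size (≈ 8 px at 0.5 µm/px), not by
biology, so junction nodes linked by a slab path of ≤ `junction_merge_px`
(default 8, configurable, 0 = raw graph) are treated as one node region
and the connector produces no record. Endpoint-terminated branches are
never dropped: there is no spur pruning anywhere, so genuine short
processes are kept.

### Data trimming and aggregation

The raw branch table (skeleton id, branch length) is filtered by the
duplicate rule — ids occurring once are removed — exactly the
spreadsheet filter-on-duplicates step it replaces; the per-skeleton
COUNTIF/SUMIF aggregation follows, and both are verified against an
independent scan-and-accumulate oracle on random tables. Image summaries
bin all branch lengths into configurable intervals (defaults 0, 5, 10,
15, 20, 30, 50, ∞ µm — the interval choice is not canonical and is
therefore exposed, not hidden), divided by the cell count; the final bin
is closed on the right. The histogram itself is reported (with the
modal bin as `modal_bin`), since the distribution, not its argmax, is
what the downstream plots use. Zone summaries *pool*: counts, lengths
and areas are summed and the normalized histogram is recomputed from
pooled counts — never averaged across images, so images with more cells
weigh more, exactly as if all branches had been measured in one sitting.
Group rows compute branches/cell, cells/area (µm²) and length/cell, with
`NA` and a warning when a zone has no cells. Area defaults to the full
field (width × height × `um_per_px`²) unless the manifest supplies a
per-image `area_um2`.

## The synthetic world

`synth_generate()` draws star-shaped cells — a dark disk soma plus
straight dark arms at random angles (minimum separation 0.5 rad) — on a
bright noisy background, plus isolated short bars ("singleton
fragments") that the duplicate filter must discard. Defaults describe
the test world: 1024×1024 px at 0.5 µm/px, 3–6 arms of 10–30 µm drawn
3 px thick, background 200, foreground 60, Gaussian noise sd 8, five
fragments (4–8 µm), cells placed with centers at least twice the maximum
arm length apart. Ground-truth arm length is measured from the soma
boundary to the tip — what skeletonization can in principle recover,
since thinning collapses the soma to the cell's central junction.

Choices the stated world leaves open, decided once:

* **Soma radius 3 px.** The generator exists to provide *recoverable*
  ground truth. A large soma thins to an internal junction web whose
  connectors inflate branch counts beyond any fixed tolerance, and it
  offsets recovered branch lengths by its radius. A soma comparable to
  process thickness (3 px ≈ a 3 µm apparent perinuclear core) keeps the
  central junction compact; the junction-merge rule absorbs what
  remains.
* **Fragment length 4–8 µm** — long enough to survive segmentation as a
  one-branch skeleton, short enough to be unambiguous non-cells.
* **Arms are straight**; curvature would complicate exact length truth
  without exercising any additional contract.

What a green end-to-end test establishes: on well-separated, uniformly
stained star cells with moderate Gaussian noise, the pipeline recovers
the number of cells exactly (40/40 seeds), per-cell branch counts within
±1 (≈ 99% of cells), and per-cell total length within 20% (tip rounding
and soma traversal are the systematic parts). What it does not
establish: behavior under overlapping arbors, uneven DAB development,
vignetting, tissue texture, or out-of-focus planes — none of which the
generator emulates. Real-image performance rests on the per-stage
contracts, not on the synthetic result.

## Determinism and reproducibility

The analysis path contains no randomness; all randomness lives in the
generator, which takes an explicit seed and restores the caller's RNG
state. A batch run writes its effective configuration as JSON next to
its outputs, and re-running from that snapshot reproduces every table
byte for byte. Per-image failures are logged and skipped; the exit
status reports partial failure so schedulers notice.

## Known limitations

* Touching or overlapping cells merge into one skeleton: no watershed
  splitting is attempted (deliberately — the upstream workflow performs
  none), so crowded fields under-count cells and over-count
  branches-per-cell.
* The threshold is global per image; strong illumination gradients
  surviving the bandpass can bias it.
* JPEG input is supported because brightfield cameras commonly export
  it, but block artifacts around thin processes make PNG/TIFF
  preferable.
* Branch counts depend on the junction-merge scale at crossings; the
  parameter is exposed and its default documented, but cross-study
  comparisons should hold it fixed.
* Statistical comparison between groups is out of scope; the exported
  tables are designed to feed external tests.
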