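---
title: "Aligning multi-tag microscopy stacks: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning multi-tag microscopy stacks: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The registration model

A multi-tag stack holds `N` image pairs: a fluorescence image of one tag
and a phase-contrast image of the same field, acquired in one
staining/bleaching cycle. Drift between cycles is translational; rotation
and deformation do not occur at the time scales and magnifications of this
acquisition mode, so the model is one 2-vector `(dx, dy)` per image. The
phase-contrast images carry tag-independent structure and drive the
estimation; the fluorescence images receive the estimated translations.

Coordinates: origin top-left, `x` along columns (rightward), `y` along rows
(downward). `apply_translation(img, c(dx, dy))` moves content by `dx`
columns and `dy` rows (`out[r, c] = in[r - dy, c - dx]`); pixels with no
source data become 0 — translated images show blank rows/columns at the
edges the content moved away from. The translation stored for a
(reference, target) pair is the one that, applied to the target, aligns it
with the reference. Everything downstream (shift matrices, the overlap
objective, re-alignment) uses this one convention.

## Mutual information and its estimation

Two phase images of the same field under different staining states have
locally different contrast but shared structure, which is why mutual
information rather than intensity difference scores alignment:

    MI = H(A) + H(B) - H(A, B)

estimated from the joint histogram of intensities at co-located pixels.
Design choices:

* **Entropy flavour.** Shannon entropy in bits is the default; Hartley
  entropy (log of the number of occupied histogram cells) is available via
  `measure = "hartley"` in `pattern_search_config()`, `entropy()` and
  `mutual_information()`. The joint-histogram construction ("sharp, nearly
  diagonal when aligned") is the standard Shannon-MI registration
  framework, and Shannon is what the MI-registration literature this
  follows uses; Hartley is kept because it is occasionally named in this
  context and costs nothing to provide.
* **Binning.** `nb = 64` bins per image, linear over each image's intensity
  range on the evaluated region. 64 bins keeps the histogram well populated
  for blocks of 200×200 px (≈10 counts/cell on average in the joint
  histogram) while resolving 8–16-bit microscopy contrast after
  normalization. Constant images collapse into one bin rather than erroring
  (their entropy is 0).
* **Overlap handling.** MI is always computed on the geometric overlap of
  the two (sub)images under the candidate translation, never on zero-filled
  padding, so the score is not biased by the changing intersection size.
  An empty overlap is an error at the API level and `-Inf` to the
  optimizer.

## Pattern search

The optimizer is a compass pattern search over translations: poll the four
axis neighbours of the incumbent at distance `mesh`; on improvement move
and multiply the mesh by `expand_factor`, otherwise multiply by
`contract_factor`; stop when the step between consecutive accepted points
(equivalently, the mesh) falls below `theta_dtau`, or after `max_iter`
polls (reported as `converged = FALSE`, never an exception). Sub-pixel
candidate shifts are evaluated with Keys bicubic interpolation (kernel
parameter −1/2), the standard choice with cubic accuracy on smooth signals;
kernel taps beyond the frame use edge replication, and any output pixel
whose source centre leaves the frame is 0.

Defaults: `theta_dtau = 0.01` px (the accuracy/runtime compromise used for
the headline experiments; smaller thresholds buy accuracy roughly linearly
in extra iterations), `initial_mesh = 4` px, `expand_factor = 2`,
`contract_factor = 0.5`, `max_iter = 200`. Only `theta_dtau` is
methodologically prescribed; the rest are conventional pattern-search
settings and the results are insensitive to them within reason.

The search is only run bounded: within a block's search window the poll is
clamped to `±margin`. An unbounded MI search from a cold start is a random
walk across the flat similarity floor and is not part of the framework;
`pattern_search_register()` therefore clamps to half the image size by
default and expects a sensible `t0` or bound from the caller.

## Block registration, outliers and confidence

`K` disjoint square blocks of side `S` are taken from the reference on a
`ceiling(sqrt(K))` grid, each registered independently inside a window of
side `S + 2 * margin` at the same position in the target. Benefits: local
damage (tears, floating debris, bleaching artifacts) corrupts some blocks
but not the consensus; and the spread of the `K` translations measures
reliability.

* **Outlier rule.** Block `k` is an outlier iff its translation is farther
  than `omega` from every other block's translation (pairwise Euclidean
  distances). `omega = 1` px is the default. Outliers are excluded from the
  consensus only when they are a minority (fewer than `K/2`); a majority of
  outliers means there is no consensus to trust, and exclusion would just
  pick an arbitrary cluster.
* **Confidence.** `sigma` is the standard deviation of the non-outlier
  shift vectors about their mean, pooled over both components with `M - 1`
  degrees of freedom. The registration accuracy cannot meaningfully beat
  `sigma`, which estimates the intrinsic measurement error.
* **Retry and flagging.** If half or more blocks are outliers or
  `sigma > sigma_threshold` (default 1 px), the registration repeats once
  with a jittered block layout; a second failure flags the pair
  (best-effort consensus is still reported). `sigma_threshold = 1` px says:
  a spread of more than a pixel across blocks is no longer drift, it is a
  bad or unregistrable image.
* **Layout and jitter.** Windows are packed at their minimal disjoint
  spacing and the grid is centred, leaving the frame's free slack
  available; a retry shifts the whole grid diagonally by `S/4` px, clamped
  to that slack, so retries are deterministic and layouts always valid. (A
  grid spread to the frame edges would leave no room to jitter at all,
  which is why packing is preferred to spreading.)
* **Defaults `K = 9`, `S = 200`, `margin = 20`.** Nine 200×200 blocks are
  the accuracy/runtime compromise for 1056×1027 fields: mean absolute
  errors around 0.1 px at `theta_dtau = 0.01`. Block sides of ~100 px cost
  roughly 4× the error; 300×300 blocks gain little and cost 2× the time.
  `margin = 20` covers the ±10 px drift regime with headroom; it also
  bounds the recoverable shift, so stacks drifting farther need a larger
  margin. Small blocks (≲64 px) narrow the MI basin and, at shifts close to
  the margin, the search can fail to lock — the failure is caught by the
  sigma/outlier machinery, but the cure is bigger blocks.

## The shift metric and RIMO selection

Footprints of aligned images are `h × w` rectangles offset by their
translations. The distance between two footprints is the area (or, on
integer grids, the pixel count) of their symmetric difference:

    d = 2 (h |dx| + w |dy| - |dx| |dy|)   if |dx| < w and |dy| < h
    d = 2 h w                             otherwise (disjoint)

`d` is a metric (symmetry and identity are immediate; the triangle
inequality comes from the measure-theoretic construction of `d` as
`mu(A Δ B)`), and it is exactly the information lost by aligning one image
to the other. Dropping the cross term gives the scaled l1 approximation
`2(h|dx| + w|dy|)`, which over-estimates by exactly `2|dx||dy|` — negligible
when shifts are small relative to the frame. The exact form is the default
(`mode = "exact"`) since it costs the same at this scale; `"l1"` is provided
for parity.

The `N - 1` measured translations to an arbitrary reference complete into
`N × N` shift matrices via `delta_jk = delta_rk - delta_rj` (upper triangle
computed, lower triangle reflected with a sign flip, so skew-symmetry and
path independence are exact by construction, not within tolerance). The
RIMO (reference image with maximal overlap) is the candidate minimizing
`sum_j d(C_r, C_j)`; ties break to the smallest index for determinism.
Re-alignment to the RIMO reads translations straight from the matrices — no
re-registration.

Reporting: per-image shift magnitude relative to the RIMO; per-image loss
percentage `100 * d / (2hw)` (identical to lost pixels over the frame area,
since each image loses `d/2` of its own pixels); and a `flagged_distant`
set, by default images more than 10 px from the RIMO — candidates for
temporary exclusion from co-localization analysis.

## The RMS composite diagnostic

`rms_channel_difference(r, g, b)` is
`sqrt((sum((R-G)^2) + sum((G-B)^2) + sum((R-B)^2)) / (3B))` with `B` the
pixel count — zero iff the channels agree, permutation-invariant; on a
composite of three phase images it quantifies the colour fringing that
misalignment produces. When comparing before/after alignment (as
`cmd_apply()` does), the package evaluates it on the rectangle covered by
every aligned image (`overlap_region()`): translated images carry
zero-filled borders that are missing data, not misalignment, and including
them would penalize the aligned stack for its own bookkeeping.

## The synthetic generator

`generate_stack()` emulates the drift experiment used for validation:
crops of a single source image displaced by uniform real-valued shifts in
`[-shift_range, +shift_range]²` (default 10 px — the observed drift
regime), sampled with bicubic interpolation at sub-pixel centres so the
recorded truth is exactly the translation that re-aligns each crop to the
central reference crop. About a quarter of the images get a gamma contrast
change (`gamma ~ U(0.5, 2)` applied on range-normalized intensities), a
disjoint quarter a Gaussian blur (sigma 1, 5×5 kernel), and the rest are
untouched — mimicking illumination/contrast perturbation across staining
cycles. Everything derives from one seed; identical configurations generate
bit-identical stacks.

The default base image is a procedural two-octave texture (Gaussian-
smoothed white noise at sigma 2 and sigma 8, mixed 0.65/0.35 and min-max
scaled), giving a histogram entropy well above 3 bits at 64 bins and an MI
landscape with both a sharp peak and a long-range gradient. It emulates the
*statistics* that matter for MI registration — texture at cell scale,
smooth large-scale variation, non-degenerate histogram. It does not emulate
phase-contrast halos, periodic tissue structure, uneven illumination, or
focal-plane blur, so passing synthetic tests demonstrates the estimation
machinery, not robustness to every real-world artifact; a user-supplied
real phase image can replace it anywhere a base image is accepted. Crops
default to 768×768 (the smallest round size accommodating the 3×3 grid of
240 px search windows that `K = 9, S = 200, margin = 20` needs) from an
800×800 base.

## Validation problem sizes

The shipped test suite validates: the closed-form metric against exhaustive
pixel counting for every integer shift at all sizes up to 50×50; metric
axioms on 10⁴ random footprint triples; RIMO selection against exhaustive
minimization on 10³ random graphs with up to 20 images; exact recovery of
50 random integer shifts in `[-10, 10]²` at the standard parameter set; the
outlier rule against a brute-force restatement on 10³ random translation
sets; and the full synthetic protocol at `n = 100` images (shift range 10,
25%/25% corruption, `K = 9`, `S = 200`, `theta_dtau = 0.01`), where the
per-axis mean absolute error lands around 0.003 px — comfortably inside the
~0.1 px regime this parameter set is expected to deliver. `n = 100` keeps
the full-protocol run to a couple of minutes; accuracy at `n = 500` is
statistically indistinguishable since errors are i.i.d. across images.

## Known limitations

* Translations only, by design; adapting to other acquisition systems may
  require small rotations, which this model does not fit.
* The recoverable shift is bounded by `margin`; drifts beyond it need a
  larger window, at quadratic cost in search area.
* Non-uniform focus (autofocus failures) degrades MI and is only *detected*
  (via sigma/flagging), not corrected.
* Block sides below ~64 px narrow the MI basin and raise the failure rate
  near the margin bound; prefer larger blocks and let the outlier rule
  handle local damage.
* The RMS diagnostic compares channels on their common overlap; it is a
  misalignment indicator, not a general image-quality measure.
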