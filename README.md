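# mtalign

Robust alignment of multi-tag fluorescence microscopy image stacks.

## The problem

Sequential-staining microscopes (toponome imaging and similar multi-tag
systems) image one specimen through many incubate–image–bleach cycles. Each
cycle `j` yields a fluorescence image `F_j` of one molecular tag together
with a phase-contrast image `I_j` of the same field. Over a run lasting
hours, mechanical drift, temperature changes and repeated washes shift the
field of view, so the images of one stack are translated relative to each
other — and any per-pixel co-localization analysis across tags becomes
meaningless until the stack is registered. Rotations and non-rigid
deformation do not occur in this setting; the alignment model is a pure
translation per image, estimated from the tag-independent phase-contrast
images and applied to the fluorescence images.

`mtalign` implements the full pipeline for stacks of `N` phase/fluorescence
pairs:

1. **Pairwise registration.** The translation between two phase images is
   found by maximizing mutual information, `MI = H(A) + H(B) - H(A, B)`,
   computed from the joint intensity histogram of the overlap, over
   translations with a derivative-free compass pattern search (mesh expands
   on success, contracts on failure, stops when the step drops below
   `theta_dtau`). Sub-pixel shifts use Keys bicubic interpolation.
2. **Confidence.** Registration runs independently on `K` disjoint square
   blocks (side `S`), each searched inside a larger window of the target
   (`S + 2 * margin`). A block whose translation lies farther than `omega`
   pixels from *every* other block is an outlier; the consensus translation
   is the mean of the non-outlier blocks and the standard deviation `sigma`
   of their shift vectors is a confidence value. High `sigma` triggers one
   retry with a jittered block layout, then flags the image as
   unregistrable.
3. **Reference selection (RIMO).** The `N - 1` consensus translations to an
   arbitrary reference are completed into skew-symmetric `N x N` shift
   matrices by vector composition (`delta_jk = delta_rk - delta_rj`). The
   distance between two image footprints is the area of their symmetric
   difference, in closed form `d = 2(h|dx| + w|dy| - |dx||dy|)` (or `2hw`
   when disjoint) — a true metric. The reference image with maximal overlap
   is the one minimizing `sum_j d(C_r, C_j)`; the stack is then re-aligned
   to it straight from the matrices, with no further registration.

A seeded synthetic-stack generator (uniform drifts in `[-10, 10]` px,
gamma-contrast and Gaussian-blur corruption) provides ground truth for
validation.

## Worked example

```r
library(mtalign)

base <- make_base_image(360, 360, seed = 11)            # procedural texture
cfg  <- synthetic_config(n_images = 4, shift_range = 6,
                         crop_size = c(320L, 320L), seed = 12)
syn  <- generate_stack(base, cfg)
round(syn$truth[, 2:3], 3)
#>   true_dx true_dy
#> 1  -5.168  -3.968
#> 2   3.813  -5.593
#> 3   5.311  -3.855
#> 4  -2.767   1.700

st  <- syn$stack
reg <- register_stack(st, reference = 1, K = 4, S = 96, margin = 20)
reg$pairs[["syn002"]]
#> block registration: consensus (8.9727, -1.6328) px, sigma 0.0119
#>   K = 4 blocks, outliers: none, flagged: FALSE, retried: FALSE

rimo <- select_rimo(reg$matrices, st$h, st$w)
rimo
#> RIMO: image 3 ('syn003'), objective 17475.1 px^2 (exact mode)
#>   distant images: syn001
round(rimo$objective)
#> [1] 18669 17617 17475 22574

aligned <- realign_stack(st, reg$matrices, rimo$rimo_index)
round(aligned$translations, 3)
#>           dx     dy
#> [1,] -10.469 -0.109
#> [2,]  -1.496 -1.742
#> [3,]   0.000  0.000
#> [4,]  -8.070  5.570
```

Reading the output: the consensus for `syn002` is its shift relative to tag
1 — the truth is `(3.813 - (-5.168), -5.593 - (-3.968)) = (8.98, -1.63)`,
recovered to about 0.01 px with `sigma` ≈ 0.01 and no outliers. Image 3 has
the smallest total symmetric-difference distance (17475 px² versus up to
22574 for the other candidates), so it becomes the reference; the final
translations align every image to it (image 1, more than 10 px away, is
flagged as distant). Across this stack the re-alignment reproduces the true
relative shifts to better than 0.02 px.

A command-line interface wrapping the same functions is installed at
`inst/cli/mtalign` (subcommands `simulate`, `register`, `select-rimo`,
`apply`, `report`).

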