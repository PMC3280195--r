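#' Symmetric-difference area between two translated image footprints
#'
#' The shift metric: the area of the symmetric difference of two `h x w`
#' rectangular footprints whose origins differ by `(dx, dy)`. In closed
#' form, with `ax = |dx|`, `ay = |dy|`:
#' `d = 2 (h * ax + w * ay - ax * ay)` when the footprints intersect
#' (`ax < w` and `ay < h`), and `d = 2 h w` otherwise (disjoint
#' footprints). This is the area lost when aligning one image to the other,
#' and it is a metric on footprints (identity, symmetry and the triangle
#' inequality follow from the measure-theoretic construction).
#'
#' @param t translation `c(dx, dy)` between the two origins (either a
#'   single translation or an `n x 2` matrix for vectorized evaluation).
#' @param h,w footprint height and width in pixels (equal for both images).
#' @return non-negative area in px^2 (vectorized over rows of `t`).
#' @examples
#' symmetric_difference_area(c(2, 3), h = 10, w = 10)  # 88
#' @export
symmetric_difference_area <- function(t, h, w) {
    tm <- if (is.matrix(t)) t else matrix(as_translation(t), 1)
    ax <- abs(tm[, 1]); ay <- abs(tm[, 2])
    d <- 2 * (h * ax + w * ay - ax * ay)
    d[ax >= w | ay >= h] <- 2 * h * w
    d
}

#' Scaled l1 approximation to the shift metric
#'
#' Drops the `|dx| * |dy|` cross term of the exact symmetric-difference
#' area, giving `2 (h |dx| + w |dy|)`: a scaled l1 norm of the shift. In
#' the overlapping regime it over-estimates the exact distance by exactly
#' `2 |dx| |dy|`, which is negligible when shifts are much smaller than the
#' image (the regime the approximation is intended for).
#'
#' @inheritParams symmetric_difference_area
#' @return non-negative value (vectorized over rows of `t`).
#' @export
l1_shift_distance <- function(t, h, w) {
    tm <- if (is.matrix(t)) t else matrix(as_translation(t), 1)
    2 * (h * abs(tm[, 1]) + w * abs(tm[, 2]))
}

#' Symmetric difference by pixel counting
#'
#' Brute-force rasterized count of the pixels lying in exactly one of two
#' `h x w` footprints with integer origins (the counting-measure version of
#' the shift metric; an oracle for [symmetric_difference_area()] at integer
#' shifts).
#'
#' @param t integer translation `c(dx, dy)` between the two origins.
#' @param h,w footprint dimensions in pixels.
#' @return integer pixel count.
#' @export
pixel_count_symmetric_difference <- function(t, h, w) {
    t <- as_translation(t)
    if (any(t != round(t))) stop("pixel counting requires integer origins")
    dx <- as.integer(t[1]); dy <- as.integer(t[2])
    # canvas large enough for both footprints
    H <- h + abs(dy); W <- w + abs(dx)
    A <- matrix(FALSE, H, W); B <- matrix(FALSE, H, W)
    r0 <- if (dy >= 0) 0L else -dy
    c0 <- if (dx >= 0) 0L else -dx
    A[r0 + seq_len(h), c0 + seq_len(w)] <- TRUE
    B[r0 + dy + seq_len(h), c0 + dx + seq_len(w)] <- TRUE
    sum(xor(A, B))
}
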