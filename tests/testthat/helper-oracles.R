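# Independent oracles and fixture builders used across the suite.

# Small textured image for registration tests (smoothed white noise,
# built here without the package's generator so fixtures are independent).
texture_image <- function(h, w, seed = 1) {
    set.seed(seed)
    z <- matrix(rnorm((h + 8) * (w + 8)), h + 8, w + 8)
    k <- stats::dnorm(-3:3, sd = 1.2)
    for (i in seq_len(nrow(z))) z[i, ] <- stats::filter(z[i, ], k, sides = 2)
    for (j in seq_len(ncol(z))) z[, j] <- stats::filter(z[, j], k, sides = 2)
    z <- z[5:(h + 4), 5:(w + 4)]
    (z - min(z)) / (max(z) - min(z))
}

# Direct (non-separable) Keys bicubic interpolation oracle: samples img at
# (r - dy, c - dx) by explicit 4x4 convolution, edge-replicated taps, 0
# outside. Written independently of the package's C++ path.
keys_w <- function(s) {
    s <- abs(s)
    ifelse(s <= 1, (1.5 * s - 2.5) * s^2 + 1,
           ifelse(s < 2, ((-0.5 * s + 2.5) * s - 4) * s + 2, 0))
}
bicubic_shift_oracle <- function(img, dx, dy) {
    h <- nrow(img); w <- ncol(img)
    out <- matrix(0, h, w)
    for (r in seq_len(h)) {
        ys <- r - dy
        if (ys < 1 || ys > h) next
        iy <- floor(ys); fy <- ys - iy
        for (c in seq_len(w)) {
            xs <- c - dx
            if (xs < 1 || xs > w) next
            ix <- floor(xs); fx <- xs - ix
            acc <- 0
            for (m in -1:2) for (n in -1:2) {
                rr <- min(max(iy + m, 1), h)
                cc <- min(max(ix + n, 1), w)
                acc <- acc + keys_w(m - fy) * keys_w(n - fx) * img[rr, cc]
            }
            out[r, c] <- acc
        }
    }
    out
}

# Shannon MI (bits) of two equal-size images, computed from scratch with
# base-R table() on linearly binned intensities.
mi_oracle <- function(a, b, nb = 64) {
    bin <- function(x) {
        rng <- range(x)
        if (rng[2] <= rng[1]) return(rep(1L, length(x)))
        pmin(as.integer((x - rng[1]) / (rng[2] - rng[1]) * nb), nb - 1L) + 1L
    }
    H <- function(counts) {
        p <- counts[counts > 0] / sum(counts)
        -sum(p * log2(p))
    }
    ia <- bin(a); ib <- bin(b)
    H(table(ia)) + H(table(ib)) - H(table(ia, ib))
}

# Pixel-count oracle for the symmetric difference of two h x w integer-shift
# footprints, enumerated per axis: the per-axis overlap is counted by
# intersecting the actual index sets, and the 2-D count follows from the
# product structure of a rectangle of pixels.
sdiff_pixel_oracle <- function(dx, dy, h, w) {
    nx <- length(intersect(seq_len(w), seq_len(w) + dx))
    ny <- length(intersect(seq_len(h), seq_len(h) + dy))
    2L * h * w - 2L * nx * ny
}

# Brute-force restatement of the outlier rule: k is an outlier iff its
# distance to every other translation exceeds omega.
outlier_oracle <- function(tm, omega) {
    K <- nrow(tm)
    out <- integer(0)
    for (k in seq_len(K)) {
        far <- TRUE
        for (l in seq_len(K)[-k]) {
            if (sqrt(sum((tm[k, ] - tm[l, ])^2)) <= omega) { far <- FALSE; break }
        }
        if (far) out <- c(out, k)
    }
    out
}

# Build a tiny stack of shifted copies of one texture (nearest-neighbour
# integer shifts so the truth is exact). Row j of `shifts` is the alignment
# translation of image j, i.e. the content is moved by -shifts[j, ].
shifted_stack <- function(img, shifts) {
    pairs <- lapply(seq_len(nrow(shifts)), function(j) {
        s <- apply_translation(img, -shifts[j, ], "nearest")
        tag_image_pair(paste0("t", j), s, s)
    })
    image_stack(pairs)
}
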