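#' Lay out K disjoint registration blocks
#'
#' Places `K` square reference blocks of side `S` on a near-uniform
#' `ceiling(sqrt(K))` grid (row-major), each centred in a larger search
#' window of side `S + 2 * margin` taken from the target image. Windows are
#' packed at their minimal spacing and the whole grid is centred in the
#' frame, which leaves the remaining slack available for a deterministic
#' diagonal `jitter` used when a registration is retried with "a slightly
#' different set" of blocks. Requested jitter is clamped to what fits; the
#' layout is always disjoint and fully inside the image.
#'
#' @param h,w image dimensions in pixels.
#' @param K number of blocks (>= 2).
#' @param S block side length in pixels.
#' @param margin half-width of the extra search border of each target
#'   window, in pixels; the per-block search is bounded by this.
#' @param jitter diagonal offset in pixels applied to the whole grid.
#' @return object of class `block_layout`: list with `K`, `S`, `margin`,
#'   `jitter` (the applied, possibly clamped, value), `block_corner`
#'   (`K x 2`, top-left row/col of each S-block, 1-based), `window_corner`
#'   (`K x 2` for the windows), `centers` (`K x 2`, block centres).
#' @export
make_block_layout <- function(h, w, K = 9L, S = 200L, margin = 20L,
                              jitter = 0) {
    K <- as.integer(K)
    if (K < 2L) stop("K must be >= 2 (pairwise block distances are needed)")
    if (S < 4L || margin < 2L) stop("S and margin too small")
    W <- S + 2L * margin
    g <- ceiling(sqrt(K))
    if (g * W > h || g * W > w)
        stop("infeasible layout: ", g, "x", g, " windows of side ", W,
             " do not fit in ", h, "x", w)
    place <- function(n, gg) {           # 1-based corners along one axis
        free <- n - gg * W
        base <- floor(free / 2) + 1L
        j <- max(min(jitter, free - (base - 1L)), -(base - 1L))
        base + round(j) + (seq_len(gg) - 1L) * W
    }
    rows <- place(h, g)
    cols <- place(w, g)
    grid <- expand.grid(c = cols, r = rows)  # row-major: column varies fastest
    wc <- as.matrix(grid[seq_len(K), c("r", "c")])
    colnames(wc) <- c("row", "col")
    bc <- wc + margin
    centers <- bc + (S - 1) / 2
    applied <- rows[1] - (floor((h - g * W) / 2) + 1L)
    structure(list(K = K, S = as.integer(S), margin = as.integer(margin),
                   jitter = applied, block_corner = bc, window_corner = wc,
                   centers = centers, h = h, w = w),
              class = "block_layout")
}

#' Register each block of a layout independently
#'
#' For every block, runs a pattern search maximizing the mutual information
#' between the reference block (side `S`) and the sub-pixel-sampled patch of
#' its larger target window, over translations bounded by the window margin.
#' Returns the per-block translations in the global frame (the translation
#' aligning the target to the reference).
#'
#' @param ref,tgt numeric matrices of equal dimensions.
#' @param layout a [block_layout][make_block_layout()] valid for both images.
#' @param cfg a [pattern_search_config()].
#' @return list with `t` (`K x 2` matrix of translations, columns `dx`,
#'   `dy`), `mi` (per-block final MI), `converged` (per-block logical).
#' @export
register_blocks <- function(ref, tgt, layout, cfg = pattern_search_config()) {
    check_grey_image(ref); check_grey_image(tgt)
    if (!identical(dim(ref), dim(tgt))) stop("dimension mismatch")
    if (layout$h != nrow(ref) || layout$w != ncol(ref))
        stop("layout was built for a different image size")
    K <- layout$K; S <- layout$S; m <- layout$margin
    hart <- cfg$measure == "hartley"
    tmat <- matrix(NA_real_, K, 2, dimnames = list(NULL, c("dx", "dy")))
    mi <- numeric(K); conv <- logical(K)
    for (k in seq_len(K)) {
        br <- layout$block_corner[k, 1]; bcol <- layout$block_corner[k, 2]
        wr <- layout$window_corner[k, 1]; wcol <- layout$window_corner[k, 2]
        B <- ref[br:(br + S - 1), bcol:(bcol + S - 1)]
        Wn <- tgt[wr:(wr + S + 2 * m - 1), wcol:(wcol + S + 2 * m - 1)]
        f <- function(t) {
            v <- cpp_mi_shift(B, Wn, t[1], t[2], m, m, cfg$nb, hart)
            if (v[2] == 0) -Inf else v[1]
        }
        res <- pattern_search_core(f, c(0, 0), cfg, bound = m)
        tmat[k, ] <- res$t
        mi[k] <- res$value
        conv[k] <- res$converged
    }
    list(t = tmat, mi = mi, converged = conv)
}

#' Mark outlier block translations
#'
#' Computes all pairwise Euclidean distances `d_kl` between the per-block
#' translation vectors; block `k` is an outlier iff `d_kl > omega` for
#' every other block `l` (it agrees with nobody). `omega = 1` pixel works
#' well in practice.
#'
#' @param per_block `K x 2` matrix of block translations.
#' @param omega distance threshold in pixels (> 0).
#' @return integer vector of outlier block indices (possibly empty).
#' @export
detect_outliers <- function(per_block, omega = 1) {
    per_block <- as.matrix(per_block)
    K <- nrow(per_block)
    if (K < 2L) stop("need at least 2 block translations")
    if (omega <= 0) stop("omega must be positive")
    d <- as.matrix(stats::dist(per_block))
    diag(d) <- Inf
    unname(which(apply(d > omega, 1L, all)))
}

#' Consensus translation and confidence
#'
#' The pairwise consensus is the component-wise mean of the non-outlier
#' block translations. The confidence is the standard deviation of those
#' shift vectors combined over both components,
#' `sigma = sqrt(sum((dx_k - mean_dx)^2 + (dy_k - mean_dy)^2) / (M - 1))`
#' over the `M` non-outlier blocks (0 when `M == 1` or all identical).
#' Small `sigma` means the blocks agree and the rigid-translation model
#' fits; large `sigma` flags an image that cannot be registered well.
#'
#' @param per_block `K x 2` matrix of block translations.
#' @param outliers integer indices to exclude.
#' @return list with `consensus` (translation) and `sigma` (pixels).
#' @export
consensus_and_confidence <- function(per_block, outliers = integer(0)) {
    per_block <- as.matrix(per_block)
    keep <- setdiff(seq_len(nrow(per_block)), outliers)
    if (length(keep) == 0L) stop("all blocks are outliers")
    sel <- per_block[keep, , drop = FALSE]
    mu <- colMeans(sel)
    M <- nrow(sel)
    sigma <- if (M < 2L) 0 else
        sqrt(sum(sweep(sel, 2L, mu)^2) / (M - 1))
    list(consensus = c(dx = unname(mu[1]), dy = unname(mu[2])), sigma = sigma)
}

#' Robust pairwise registration with retry and flagging
#'
#' Orchestrates one reference/target registration: block layout, per-block
#' pattern search, outlier detection, consensus and confidence. Outliers
#' are excluded from the consensus only when they are a minority (fewer
#' than `K/2`). If half or more blocks are outliers, or the confidence
#' `sigma` exceeds `sigma_threshold`, the registration is retried once with
#' a jittered block layout; if it still fails, the result is flagged as a
#' potentially bad-quality image (best-effort consensus is still returned).
#'
#' @param ref,tgt numeric matrices of equal dimensions.
#' @param K,S,margin block layout parameters, see [make_block_layout()].
#' @param cfg a [pattern_search_config()].
#' @param sigma_threshold confidence threshold in pixels.
#' @param omega outlier distance threshold in pixels.
#' @return object of class `block_registration_result`: list with
#'   `per_block` (`K x 2`), `outliers`, `consensus`, `sigma`, `flagged`,
#'   `retried`, `converged` (per-block), `layout`.
#' @export
robust_pairwise_register <- function(ref, tgt, K = 9L, S = 200L, margin = 20L,
                                     cfg = pattern_search_config(),
                                     sigma_threshold = 1, omega = 1) {
    attempt <- function(jit) {
        layout <- make_block_layout(nrow(ref), ncol(ref), K = K, S = S,
                                    margin = margin, jitter = jit)
        reg <- register_blocks(ref, tgt, layout, cfg)
        out <- detect_outliers(reg$t, omega = omega)
        majority_bad <- length(out) >= K / 2
        use_out <- if (majority_bad) integer(0) else out
        cc <- consensus_and_confidence(reg$t, use_out)
        list(layout = layout, reg = reg, outliers = out,
             consensus = cc$consensus, sigma = cc$sigma,
             failed = majority_bad || cc$sigma > sigma_threshold)
    }
    a1 <- attempt(0)
    retried <- FALSE
    best <- a1
    if (a1$failed) {
        retried <- TRUE
        a2 <- attempt(round(S / 4))
        best <- if (!a2$failed || a2$sigma <= a1$sigma) a2 else a1
    }
    structure(list(per_block = best$reg$t, outliers = best$outliers,
                   consensus = best$consensus, sigma = best$sigma,
                   flagged = best$failed, retried = retried,
                   converged = best$reg$converged, layout = best$layout),
              class = "block_registration_result")
}

#' @export
print.block_registration_result <- function(x, ...) {
    cat(sprintf("block registration: consensus (%.4f, %.4f) px, sigma %.4f\n",
                x$consensus[1], x$consensus[2], x$sigma))
    cat(sprintf("  K = %d blocks, outliers: %s, flagged: %s, retried: %s\n",
                nrow(x$per_block),
                if (length(x$outliers)) paste(x$outliers, collapse = ",")
                else "none", x$flagged, x$retried))
    invisible(x)
}
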