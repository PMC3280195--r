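#' Complete the registration graph into shift matrices
#'
#' Given the `N - 1` consensus translations that align every non-reference
#' image to an arbitrarily chosen reference `r`, fills the full `N x N`
#' pairwise shift matrices by vector composition along the registration
#' graph: `delta_jk = delta_rk - delta_rj`. Only the upper triangle is
#' computed; the lower triangle is its reflection with a sign flip, so
#' skew-symmetry (and a zero diagonal) holds exactly by construction. No
#' further image registrations are needed to change the reference later.
#'
#' @param base `(N-1) x 2` matrix (or list of translations), row `j` being
#'   the translation aligning the `j`-th non-reference image (in stack
#'   order, skipping `r`) to the reference.
#' @param r index of the reference image used for the base registrations.
#' @param tags optional character labels, length `N`.
#' @return object of class `shift_matrices`: list with `dx`, `dy`
#'   (`N x N`, entry `[j, k]` = shift aligning image `k` to image `j`),
#'   `ref_index`, `tags`.
#' @export
build_shift_matrices <- function(base, r, tags = NULL) {
    bm <- if (is.matrix(base)) base else do.call(rbind, lapply(base, as_translation))
    N <- nrow(bm) + 1L
    if (r < 1L || r > N) stop("reference index out of range")
    if (is.null(tags)) tags <- paste0("tag", seq_len(N))
    if (length(tags) != N) stop("need ", N, " tags, got ", length(tags))
    if (any(!is.finite(bm))) stop("base translations must be finite")
    dxv <- dyv <- numeric(N)
    dxv[-r] <- bm[, 1]
    dyv[-r] <- bm[, 2]
    fill <- function(v) {
        m <- matrix(0, N, N)
        for (j in seq_len(N - 1L)) {
            k <- (j + 1L):N
            m[j, k] <- v[k] - v[j]
        }
        m - t(m)                       # reflect upper triangle, sign-flipped
    }
    structure(list(dx = fill(dxv), dy = fill(dyv), ref_index = as.integer(r),
                   tags = as.character(tags)),
              class = "shift_matrices")
}

#' @export
print.shift_matrices <- function(x, ...) {
    cat("shift_matrices:", length(x$tags), "images, reference index",
        x$ref_index, "\n")
    invisible(x)
}

#' Total non-overlap objective per candidate reference
#'
#' For each candidate reference `r`, sums the shift-metric distance from its
#' footprint to every other image's footprint,
#' `sum_j d(C_r, C_j)`, using the exact symmetric-difference area (default)
#' or its scaled l1 approximation. Minimizing this objective over `r` gives
#' the reference image with maximal overlap.
#'
#' @param mats a [shift_matrices][build_shift_matrices()] object.
#' @param h,w image dimensions in pixels.
#' @param mode `"exact"` (closed-form symmetric-difference area) or `"l1"`.
#' @return numeric vector of length `N`, the objective per candidate.
#' @export
rimo_objective <- function(mats, h, w, mode = c("exact", "l1")) {
    mode <- match.arg(mode)
    N <- length(mats$tags)
    f <- if (mode == "exact") symmetric_difference_area else l1_shift_distance
    vapply(seq_len(N), function(r) {
        sum(f(cbind(mats$dx[r, ], mats$dy[r, ]), h, w))
    }, numeric(1))
}

#' Select the reference image with maximal overlap (RIMO)
#'
#' Evaluates [rimo_objective()] for every candidate reference and returns
#' the argmin (ties broken by the smallest index), together with per-image
#' reporting quantities: the shift magnitude of each image relative to the
#' RIMO, the percentage of frame area lost per image
#' (`100 * d(C_rimo, C_j) / (2 h w)`, equivalently lost pixels over `h w`),
#' and the set of images flagged as distant from the RIMO (candidates to
#' exclude from downstream co-localization analysis).
#'
#' @inheritParams rimo_objective
#' @param distant_threshold flag images whose shift magnitude relative to
#'   the RIMO exceeds this many pixels.
#' @return object of class `rimo_result`: list with `objective` (length-N),
#'   `rimo_index`, `rimo_tag`, `per_image_shift_magnitude`, `loss_percent`,
#'   `flagged_distant` (indices), `mode`, `h`, `w`, `tags`.
#' @export
select_rimo <- function(mats, h, w, mode = c("exact", "l1"),
                        distant_threshold = 10) {
    mode <- match.arg(mode)
    obj <- rimo_objective(mats, h, w, mode)
    r <- which.min(obj)                  # which.min takes the first minimum
    mag <- sqrt(mats$dx[r, ]^2 + mats$dy[r, ]^2)
    loss <- 100 * symmetric_difference_area(
        cbind(mats$dx[r, ], mats$dy[r, ]), h, w) / (2 * h * w)
    structure(list(objective = obj, rimo_index = r, rimo_tag = mats$tags[r],
                   per_image_shift_magnitude = mag, loss_percent = loss,
                   flagged_distant = which(mag > distant_threshold),
                   mode = mode, h = h, w = w, tags = mats$tags),
              class = "rimo_result")
}

#' @export
print.rimo_result <- function(x, ...) {
    cat(sprintf("RIMO: image %d ('%s'), objective %.1f px^2 (%s mode)\n",
                x$rimo_index, x$rimo_tag, x$objective[x$rimo_index], x$mode))
    if (length(x$flagged_distant))
        cat("  distant images:", paste(x$tags[x$flagged_distant],
                                       collapse = ", "), "\n")
    invisible(x)
}

#' Re-align a stack to the RIMO
#'
#' Applies the translation `(dx[rimo, j], dy[rimo, j])` read from the shift
#' matrices to both the phase and fluorescence images of every tag (bicubic
#' interpolation); the RIMO image itself is returned unchanged. No
#' re-registration is performed: the registration graph already contains
#' every pairwise shift.
#'
#' @param stack an [image_stack()].
#' @param mats a [shift_matrices][build_shift_matrices()] for the stack.
#' @param rimo_index the reference index to align to (e.g.
#'   `select_rimo(...)$rimo_index`).
#' @return list with `stack` (the aligned [image_stack()]) and
#'   `translations` (`N x 2` matrix applied per image).
#' @export
realign_stack <- function(stack, mats, rimo_index) {
    N <- length(stack$pairs)
    if (length(mats$tags) != N) stop("shift matrices do not match the stack")
    tr <- cbind(dx = mats$dx[rimo_index, ], dy = mats$dy[rimo_index, ])
    pairs <- lapply(seq_len(N), function(j) {
        p <- stack$pairs[[j]]
        if (j == rimo_index || all(tr[j, ] == 0)) return(p)
        p$phase <- apply_translation(p$phase, tr[j, ], "bicubic")
        p$fluorescence <- apply_translation(p$fluorescence, tr[j, ], "bicubic")
        p
    })
    list(stack = image_stack(pairs), translations = tr)
}

#' Register every image of a stack to an arbitrary reference
#'
#' Runs [robust_pairwise_register()] between the reference phase image and
#' each of the other `N - 1` phase images, and completes the results into
#' skew-symmetric shift matrices.
#'
#' @param stack an [image_stack()].
#' @param reference index of the (arbitrary, good-quality) reference image.
#' @param K,S,margin block layout parameters.
#' @param cfg a [pattern_search_config()].
#' @param sigma_threshold,omega confidence and outlier thresholds (pixels).
#' @return list with `matrices` (a `shift_matrices`), `pairs` (per-target
#'   `block_registration_result`s, named by tag), `reference`, `flagged`
#'   (tags whose registration was flagged).
#' @export
register_stack <- function(stack, reference = 1L, K = 9L, S = 200L,
                           margin = 20L, cfg = pattern_search_config(),
                           sigma_threshold = 1, omega = 1) {
    N <- length(stack$pairs)
    ref_img <- stack$pairs[[reference]]$phase
    targets <- setdiff(seq_len(N), reference)
    results <- vector("list", length(targets))
    base <- matrix(0, length(targets), 2)
    for (i in seq_along(targets)) {
        j <- targets[i]
        res <- robust_pairwise_register(ref_img, stack$pairs[[j]]$phase,
                                        K = K, S = S, margin = margin,
                                        cfg = cfg,
                                        sigma_threshold = sigma_threshold,
                                        omega = omega)
        results[[i]] <- res
        base[i, ] <- res$consensus
    }
    names(results) <- stack$tags[targets]
    flagged <- stack$tags[targets][vapply(results, `[[`, logical(1), "flagged")]
    mats <- build_shift_matrices(base, reference, stack$tags)
    list(matrices = mats, pairs = results, reference = reference,
         flagged = flagged)
}
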