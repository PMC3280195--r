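#' Joint intensity histogram of two images
#'
#' Bins each image's intensity range linearly into `nb` bins over co-located
#' pixels. The joint histogram is the workhorse of mutual-information
#' registration: when two images are well aligned it is sharp and close to
#' diagonal; misalignment spreads the mass. A constant image collapses into
#' a single bin (not an error).
#'
#' @param a,b numeric matrices of identical dimensions.
#' @param nb number of intensity bins (>= 2).
#' @return object of class `joint_histogram`: list with `counts`
#'   (`nb x nb` matrix, rows index `a` bins), `nb`, `n` (total count,
#'   equal to the pixel count).
#' @export
joint_histogram <- function(a, b, nb = 64L) {
    check_grey_image(a); check_grey_image(b)
    if (!identical(dim(a), dim(b))) stop("dimension mismatch")
    nb <- as.integer(nb)
    if (nb < 2L) stop("nb must be >= 2")
    ia <- bin_index(a, nb)
    ib <- bin_index(b, nb)
    counts <- matrix(tabulate((ia - 1L) * nb + ib, nbins = nb * nb),
                     nrow = nb, ncol = nb, byrow = TRUE)
    structure(list(counts = counts, nb = nb, n = length(a)),
              class = "joint_histogram")
}

# Linear binning of an image's own range into nb bins; constant image -> bin 1.
bin_index <- function(x, nb) {
    rng <- range(x)
    if (rng[2] <= rng[1]) return(rep.int(1L, length(x)))
    idx <- as.integer((x - rng[1]) / (rng[2] - rng[1]) * nb)
    idx[idx >= nb] <- nb - 1L
    idx + 1L
}

#' Entropy of a histogram
#'
#' Shannon entropy (in bits) of the normalized histogram, with the
#' convention `0 * log 0 = 0`; or Hartley entropy, `log2` of the number of
#' occupied cells. Accepts 1-D (marginal) or 2-D (joint) count arrays.
#'
#' @param hist non-negative numeric vector/matrix of counts, or a
#'   `joint_histogram`.
#' @param measure `"shannon"` (default) or `"hartley"`.
#' @return non-negative scalar in bits; 0 iff a single cell is occupied.
#' @export
entropy <- function(hist, measure = c("shannon", "hartley")) {
    measure <- match.arg(measure)
    if (inherits(hist, "joint_histogram")) hist <- hist$counts
    if (!is.numeric(hist) || any(hist < 0))
        stop("hist must be a non-negative count array")
    n <- sum(hist)
    if (n <= 0) stop("all-zero histogram has no entropy")
    p <- hist[hist > 0] / n
    if (measure == "hartley") log2(length(p)) else -sum(p * log2(p))
}

#' Mutual information between two images under a translation
#'
#' Shifts the target by `t` (bicubic sub-pixel interpolation) and computes
#' `MI = H(A) + H(B) - H(A, B)` from the joint intensity histogram over the
#' geometric overlap only, so the changing size of the intersection does not
#' bias the score. `mutual_information(img, img, c(0, 0))` equals the
#' entropy of `img`.
#'
#' @param ref,tgt numeric matrices (equal dimensions).
#' @param t translation `c(dx, dy)` applied to `tgt`.
#' @param nb number of intensity bins.
#' @param measure `"shannon"` (default) or `"hartley"` entropy.
#' @return scalar MI in bits (non-negative up to floating tolerance).
#' @export
mutual_information <- function(ref, tgt, t = c(0, 0), nb = 64L,
                               measure = c("shannon", "hartley")) {
    check_grey_image(ref); check_grey_image(tgt)
    if (!identical(dim(ref), dim(tgt))) stop("dimension mismatch")
    t <- as_translation(t)
    measure <- match.arg(measure)
    v <- cpp_mi_shift(ref, tgt, t[1], t[2], 0, 0, as.integer(nb),
                      measure == "hartley")
    if (v[2] == 0) stop("empty overlap at t = (", t[1], ", ", t[2], ")")
    v[1]
}

#' Pattern search configuration
#'
#' Parameters of the compass pattern search used to maximize mutual
#' information over translations. The search polls the four axis
#' neighbours of the incumbent at distance `mesh`; a poll that improves MI
#' moves the incumbent and expands the mesh, otherwise the mesh contracts.
#' It stops when the step between consecutive accepted points (equivalently
#' the current mesh size) drops below `theta_dtau`, or at `max_iter`.
#'
#' @param theta_dtau stopping threshold on the translation step between
#'   consecutive iterations, in pixels (> 0).
#' @param initial_mesh initial mesh size in pixels.
#' @param max_iter maximum number of poll iterations.
#' @param expand_factor mesh multiplier after a successful poll (> 1).
#' @param contract_factor mesh multiplier after a failed poll (in (0, 1)).
#' @param nb intensity bins for the MI objective.
#' @param measure entropy flavour, `"shannon"` or `"hartley"`.
#' @return list of class `pattern_search_config`.
#' @export
pattern_search_config <- function(theta_dtau = 0.01, initial_mesh = 4,
                                  max_iter = 200L, expand_factor = 2,
                                  contract_factor = 0.5, nb = 64L,
                                  measure = c("shannon", "hartley")) {
    measure <- match.arg(measure)
    stopifnot(theta_dtau > 0, initial_mesh > 0, max_iter >= 1,
              expand_factor > 1, contract_factor > 0, contract_factor < 1)
    structure(list(theta_dtau = theta_dtau, initial_mesh = initial_mesh,
                   max_iter = as.integer(max_iter),
                   expand_factor = expand_factor,
                   contract_factor = contract_factor,
                   nb = as.integer(nb), measure = measure),
              class = "pattern_search_config")
}

# Core compass search over translations maximizing an objective f(c(dx, dy)).
# `bound` clamps both components to [-bound, bound]; polls outside it are
# skipped. Returns the best point, value, trace, and a convergence flag.
pattern_search_core <- function(f, t0, cfg, bound = Inf) {
    t_cur <- as_translation(t0)
    f_cur <- f(t_cur)
    if (!is.finite(f_cur)) stop("objective not finite at the start point")
    mesh <- cfg$initial_mesh
    converged <- FALSE
    tr <- vector("list", cfg$max_iter)
    for (it in seq_len(cfg$max_iter)) {
        polls <- rbind(t_cur + c(mesh, 0), t_cur - c(mesh, 0),
                       t_cur + c(0, mesh), t_cur - c(0, mesh))
        ok <- abs(polls[, 1]) <= bound & abs(polls[, 2]) <= bound
        best_v <- f_cur; best_i <- 0L
        for (i in which(ok)) {
            v <- f(polls[i, ])
            if (is.finite(v) && v > best_v) { best_v <- v; best_i <- i }
        }
        moved <- best_i > 0L
        tr[[it]] <- c(iter = it, dx = t_cur[[1]], dy = t_cur[[2]],
                      value = f_cur, mesh = mesh, moved = as.numeric(moved))
        if (moved) {
            step <- mesh
            t_cur <- c(dx = polls[best_i, 1], dy = polls[best_i, 2])
            f_cur <- best_v
            if (step < cfg$theta_dtau) { converged <- TRUE; break }
            mesh <- mesh * cfg$expand_factor
        } else {
            mesh <- mesh * cfg$contract_factor
            if (mesh < cfg$theta_dtau) { converged <- TRUE; break }
        }
    }
    trace <- as.data.frame(do.call(rbind, tr[!vapply(tr, is.null, logical(1))]))
    list(t = t_cur, value = f_cur, trace = trace, converged = converged,
         iterations = nrow(trace))
}

#' Register two images by pattern search over translations
#'
#' Maximizes [mutual_information()] between `ref` and the translated `tgt`
#' with a compass pattern search (bicubic sub-pixel shifting). The result
#' never has lower MI than the start point; non-convergence within
#' `max_iter` is reported through the `converged` flag, not an error.
#'
#' @param ref,tgt numeric matrices of equal dimensions, overlapping at `t0`.
#' @param cfg a [pattern_search_config()].
#' @param t0 starting translation.
#' @param bound clamp for both shift components (pixels); defaults to half
#'   the smaller image dimension so polls always keep a non-empty overlap.
#' @return list with `t` (the translation), `mi`, `trace` (data frame of
#'   iterations: incumbent, MI, mesh, moved), `converged`, `iterations`.
#' @export
pattern_search_register <- function(ref, tgt, cfg = pattern_search_config(),
                                    t0 = c(0, 0), bound = NULL) {
    check_grey_image(ref); check_grey_image(tgt)
    if (!identical(dim(ref), dim(tgt))) stop("dimension mismatch")
    if (is.null(bound)) bound <- floor(min(dim(ref)) / 2)
    hart <- cfg$measure == "hartley"
    f <- function(t) {
        v <- cpp_mi_shift(ref, tgt, t[1], t[2], 0, 0, cfg$nb, hart)
        if (v[2] == 0) -Inf else v[1]
    }
    res <- pattern_search_core(f, t0, cfg, bound = bound)
    list(t = res$t, mi = res$value, trace = res$trace,
         converged = res$converged, iterations = res$iterations)
}
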