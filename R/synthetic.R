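# Evaluate a function with a locally seeded RNG, restoring global state.
with_seed <- function(seed, code) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(code)
}

# 2-D Gaussian convolution with an explicit square kernel (separable,
# normalized to unit sum), replicated boundary.
gaussian_filter <- function(img, sigma, size = 2L * ceiling(3 * sigma) + 1L) {
    half <- (size - 1) / 2
    g <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
    kern <- outer(g, g)
    kern <- kern / sum(kern)
    out <- EBImage::filter2(img, kern, boundary = "replicate")
    if (inherits(out, "Image")) out <- EBImage::imageData(out)
    out
}

# Power-law (gamma) intensity transform on intensities normalized to [0, 1]
# by the image's own range, then rescaled back.
apply_gamma <- function(img, gamma) {
    rng <- range(img)
    if (rng[2] <= rng[1]) return(img)
    ((img - rng[1]) / (rng[2] - rng[1]))^gamma * (rng[2] - rng[1]) + rng[1]
}

#' Procedural textured base image
#'
#' Deterministic band-limited texture standing in for a real phase-contrast
#' field: two octaves of Gaussian-smoothed white noise (fine cell-scale
#' detail plus coarser structure), min-max scaled to `[0, 1]`. The texture
#' has a non-degenerate histogram (entropy well above 3 bits at 64 bins),
#' which mutual-information registration needs.
#'
#' @param h,w image dimensions in pixels.
#' @param seed integer RNG seed; identical seeds give identical images.
#' @return numeric `h x w` matrix in `[0, 1]`.
#' @export
make_base_image <- function(h = 800L, w = 800L, seed = 1L) {
    with_seed(seed, {
        fine <- gaussian_filter(matrix(rnorm(h * w), h, w), sigma = 2)
        coarse <- gaussian_filter(matrix(rnorm(h * w), h, w), sigma = 8)
        img <- 0.65 * fine / stats::sd(fine) + 0.35 * coarse / stats::sd(coarse)
        rng <- range(img)
        (img - rng[1]) / (rng[2] - rng[1])
    })
}

#' Synthetic stack configuration
#'
#' Parameters of the synthetic drift experiment: a stack of `n_images`
#' crops of a base image, each displaced by a uniform real-valued shift in
#' `[-shift_range, +shift_range]` per axis, with about a quarter of the
#' images gamma-corrected (gamma uniform in `gamma_range`), a disjoint
#' quarter Gaussian-blurred (`blur_sigma`, `blur_kernel` square taps), and
#' the remaining half left untouched.
#'
#' @param n_images number of shifted images in the stack.
#' @param shift_range half-width of the uniform shift distribution, pixels.
#' @param crop_size `c(h, w)` of each crop, pixels.
#' @param frac_gamma,frac_blur corrupted fractions (sum at most 1).
#' @param gamma_range `c(lo, hi)` of the gamma exponent.
#' @param blur_sigma Gaussian blur bandwidth, pixels.
#' @param blur_kernel blur filter side length, pixels.
#' @param seed integer RNG seed for shifts and corruption.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_images = 500L, shift_range = 10,
                             crop_size = c(768L, 768L), frac_gamma = 0.25,
                             gamma_range = c(0.5, 2), frac_blur = 0.25,
                             blur_sigma = 1, blur_kernel = 5L, seed = 1L) {
    stopifnot(n_images >= 1, shift_range > 0, length(crop_size) == 2,
              frac_gamma >= 0, frac_blur >= 0, frac_gamma + frac_blur <= 1,
              gamma_range[1] > 0, gamma_range[2] >= gamma_range[1],
              blur_sigma > 0, blur_kernel >= 3)
    structure(list(n_images = as.integer(n_images), shift_range = shift_range,
                   crop_size = as.integer(crop_size), frac_gamma = frac_gamma,
                   gamma_range = gamma_range, frac_blur = frac_blur,
                   blur_sigma = blur_sigma, blur_kernel = as.integer(blur_kernel),
                   seed = as.integer(seed)),
              class = "synthetic_config")
}

#' Generate a ground-truthed synthetic stack
#'
#' Draws `n_images` real-valued shifts uniformly from
#' `[-shift_range, shift_range]^2` and crops, for each, a window of the
#' base image sampled with bicubic sub-pixel interpolation so that the
#' translation aligning crop `j` back to the central reference crop is
#' exactly the recorded truth `(dx_j, dy_j)`. Random disjoint subsets of
#' about `frac_gamma` and `frac_blur` of the images are gamma-corrected and
#' Gaussian-blurred respectively; the rest are only translated. Fully
#' reproducible from `cfg$seed`.
#'
#' @param base numeric matrix, the source image (see [make_base_image()]);
#'   must exceed the crop by `shift_range` plus interpolation headroom on
#'   each side.
#' @param cfg a [synthetic_config()].
#' @return list with `stack` (an [image_stack()] of phase-only pairs, the
#'   fluorescence slot mirroring the phase image), `reference` (the
#'   uncorrupted zero-shift central crop), and `truth` (data frame: `tag`,
#'   `true_dx`, `true_dy`, `corruption`, `gamma`).
#' @export
generate_stack <- function(base, cfg = synthetic_config()) {
    check_grey_image(base)
    h <- cfg$crop_size[1]; w <- cfg$crop_size[2]
    H <- nrow(base); W <- ncol(base)
    head_room <- ceiling(cfg$shift_range) + 2L
    if (h + 2L * head_room > H || w + 2L * head_room > W)
        stop("base image too small for crop ", h, "x", w,
             " with shift range ", cfg$shift_range)
    top <- floor((H - h) / 2) + 1L
    left <- floor((W - w) / 2) + 1L
    rows <- top:(top + h - 1L)
    cols <- left:(left + w - 1L)
    with_seed(cfg$seed, {
        n <- cfg$n_images
        sx <- runif(n, -cfg$shift_range, cfg$shift_range)
        sy <- runif(n, -cfg$shift_range, cfg$shift_range)
        n_gamma <- round(cfg$frac_gamma * n)
        n_blur <- round(cfg$frac_blur * n)
        pick <- sample.int(n, n_gamma + n_blur)
        idx_gamma <- pick[seq_len(n_gamma)]
        idx_blur <- setdiff(pick, idx_gamma)
        gammas <- rep(NA_real_, n)
        gammas[idx_gamma] <- runif(n_gamma, cfg$gamma_range[1], cfg$gamma_range[2])
        pairs <- vector("list", n)
        for (j in seq_len(n)) {
            # sample base at +shift so the aligning translation is +shift
            shifted <- cpp_shift_bicubic(base, -sx[j], -sy[j])
            crop <- shifted[rows, cols]
            if (j %in% idx_gamma) {
                crop <- apply_gamma(crop, gammas[j])
            } else if (j %in% idx_blur) {
                crop <- gaussian_filter(crop, cfg$blur_sigma, cfg$blur_kernel)
            }
            tag <- sprintf("syn%03d", j)
            pairs[[j]] <- tag_image_pair(tag, crop, crop, index = j)
        }
        corruption <- rep("none", n)
        corruption[idx_gamma] <- "gamma"
        corruption[idx_blur] <- "blur"
        truth <- data.frame(tag = vapply(pairs, `[[`, character(1), "tag"),
                            true_dx = sx, true_dy = sy,
                            corruption = corruption, gamma = gammas,
                            stringsAsFactors = FALSE)
        reference <- base[rows, cols]
        stack <- if (n >= 2L) image_stack(pairs) else NULL
        list(stack = stack, pairs = pairs, reference = reference,
             truth = truth)
    })
}

#' Score estimated shifts against the synthetic truth
#'
#' Per-axis mean absolute difference and standard deviation of the
#' differences between true and estimated shifts (the accuracy summary of
#' the synthetic drift experiment).
#'
#' @param truth data frame with `true_dx`, `true_dy` (as returned by
#'   [generate_stack()]), or an `n x 2` matrix.
#' @param estimated `n x 2` matrix of estimated translations (columns
#'   `dx`, `dy`).
#' @return named list: `mean_abs_err_x`, `mean_abs_err_y`, `sd_x`, `sd_y`.
#' @export
score_registration <- function(truth, estimated) {
    tm <- if (is.data.frame(truth)) cbind(truth$true_dx, truth$true_dy)
          else as.matrix(truth)
    em <- as.matrix(estimated)
    if (!all(dim(tm) == dim(em)))
        stop("truth and estimated shapes differ")
    dxd <- tm[, 1] - em[, 1]
    dyd <- tm[, 2] - em[, 2]
    list(mean_abs_err_x = mean(abs(dxd)), mean_abs_err_y = mean(abs(dyd)),
         sd_x = stats::sd(dxd), sd_y = stats::sd(dyd))
}
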