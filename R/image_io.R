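#' Construct a tag image pair
#'
#' One sequential-staining cycle yields a phase-contrast image (used for
#' registration, because its content is tag-independent) and a fluorescence
#' image (the tag signal, which receives the computed translation). Both
#' must be 2-D numeric matrices of identical size with finite intensities.
#'
#' @param tag character tag label (e.g. an antibody name).
#' @param phase,fluorescence numeric matrices, identical dimensions.
#' @param index integer position of the pair in its stack (1-based).
#' @param bit_depth original integer bit depth of the source rasters, kept
#'   for round-trip writing; intensities are held as doubles in `[0, 1]`.
#' @return object of class `tag_image_pair`.
#' @export
tag_image_pair <- function(tag, phase, fluorescence, index = NA_integer_,
                           bit_depth = 8L) {
    check_grey_image(phase, paste0("phase image of tag '", tag, "'"))
    check_grey_image(fluorescence, paste0("fluorescence image of tag '", tag, "'"))
    if (!identical(dim(phase), dim(fluorescence)))
        stop("tag '", tag, "': phase and fluorescence dimensions differ")
    structure(list(tag = as.character(tag), phase = phase,
                   fluorescence = fluorescence, index = as.integer(index),
                   bit_depth = as.integer(bit_depth)),
              class = "tag_image_pair")
}

check_grey_image <- function(img, what = "image") {
    if (!is.matrix(img) || !is.numeric(img))
        stop(what, " must be a 2-D numeric matrix")
    if (nrow(img) < 1L || ncol(img) < 1L)
        stop(what, " has zero extent")
    if (any(!is.finite(img)))
        stop(what, " contains non-finite intensities")
    invisible(TRUE)
}

#' Construct an image stack
#'
#' @param pairs list of [tag_image_pair()] objects; at least two, all sharing
#'   the same dimensions, with unique tag names.
#' @return object of class `image_stack` with elements `pairs`, `h`, `w`,
#'   `tags`.
#' @export
image_stack <- function(pairs) {
    if (length(pairs) < 2L)
        stop("an image stack needs at least 2 tag image pairs")
    if (!all(vapply(pairs, inherits, logical(1), "tag_image_pair")))
        stop("all elements must be tag_image_pair objects")
    dims <- vapply(pairs, function(p) dim(p$phase), integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
        bad <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])[1]
        stop("dimension mismatch across pairs: tag '", pairs[[bad]]$tag,
             "' is ", dims[1, bad], "x", dims[2, bad], " but tag '",
             pairs[[1]]$tag, "' is ", dims[1, 1], "x", dims[2, 1])
    }
    tags <- vapply(pairs, `[[`, character(1), "tag")
    if (anyDuplicated(tags))
        stop("tag names must be unique; duplicated: ",
             paste(unique(tags[duplicated(tags)]), collapse = ", "))
    for (j in seq_along(pairs)) pairs[[j]]$index <- j
    structure(list(pairs = pairs, h = dims[1, 1], w = dims[2, 1], tags = tags),
              class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
    cat("image_stack:", length(x$pairs), "tag image pairs,",
        x$h, "x", x$w, "px\n")
    cat("  tags:", paste(x$tags, collapse = ", "), "\n")
    invisible(x)
}

#' Read a single grey raster image
#'
#' Reads an 8/16-bit single-channel TIFF or PNG as a numeric matrix with
#' intensities in `[0, 1]`. Multi-channel rasters are rejected.
#'
#' @param path file path; format chosen by extension (`.tif`/`.tiff`/`.png`).
#' @return numeric matrix with attribute `bit_depth`.
#' @export
read_grey_image <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("tif", "tiff")) {
        img <- tiff::readTIFF(path, info = TRUE)
        bits <- attr(img, "bits.per.sample")
        if (is.null(bits)) bits <- 8L
    } else if (ext == "png") {
        img <- png::readPNG(path)
        bits <- 8L
    } else {
        stop("unreadable format '", ext, "' for ", path,
             " (TIFF and PNG are supported)")
    }
    if (length(dim(img)) == 3L) {
        if (dim(img)[3] == 1L) img <- img[, , 1L]
        else stop("expected a single-channel grey image: ", path)
    }
    img <- unclass(img)
    attributes(img) <- list(dim = dim(img))
    attr(img, "bit_depth") <- as.integer(bits)
    img
}

#' Write a grey image
#'
#' Intensities are clamped to `[0, 1]` and written as 8- or 16-bit grey
#' TIFF or 8-bit grey PNG, by extension.
#'
#' @param img numeric matrix.
#' @param path output path.
#' @param bits bits per sample for TIFF output (8 or 16).
#' @return `path`, invisibly.
#' @export
write_grey_image <- function(img, path, bits = 16L) {
    check_grey_image(img)
    img <- pmin(pmax(img, 0), 1)
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("tif", "tiff")) {
        tiff::writeTIFF(img, path, bits.per.sample = as.integer(bits))
    } else if (ext == "png") {
        png::writePNG(img, path)
    } else {
        stop("unsupported output format: ", ext)
    }
    invisible(path)
}

#' Read an image stack from a manifest
#'
#' The manifest maps tag names to image paths, one row per tag with fields
#' `tag`, `phase`, `fluor`. CSV/TSV (by extension) and YAML (a list of
#' mappings) are accepted; relative image paths are resolved against the
#' manifest's directory.
#'
#' @param manifest_path path to the manifest file.
#' @return an [image_stack()].
#' @export
read_stack <- function(manifest_path) {
    man <- read_manifest(manifest_path)
    base <- dirname(manifest_path)
    pairs <- vector("list", nrow(man))
    for (i in seq_len(nrow(man))) {
        ph <- resolve_path(man$phase[i], base)
        fl <- resolve_path(man$fluor[i], base)
        pair <- tryCatch({
            p <- read_grey_image(ph)
            f <- read_grey_image(fl)
            tag_image_pair(man$tag[i], p, f, index = i,
                           bit_depth = attr(p, "bit_depth"))
        }, error = function(e) {
            stop("tag '", man$tag[i], "': ", conditionMessage(e), call. = FALSE)
        })
        pairs[[i]] <- pair
    }
    image_stack(pairs)
}

read_manifest <- function(path) {
    if (!file.exists(path)) stop("manifest not found: ", path)
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("yaml", "yml")) {
        rows <- yaml::read_yaml(path)
        man <- do.call(rbind, lapply(rows, function(r)
            data.frame(tag = r$tag, phase = r$phase, fluor = r$fluor,
                       stringsAsFactors = FALSE)))
    } else if (ext %in% c("csv", "tsv", "txt")) {
        sep <- if (ext == "csv") "," else "\t"
        man <- utils::read.table(path, header = TRUE, sep = sep,
                                 stringsAsFactors = FALSE)
    } else {
        stop("unsupported manifest format: ", ext)
    }
    need <- c("tag", "phase", "fluor")
    if (!all(need %in% names(man)))
        stop("manifest must have columns ", paste(need, collapse = ", "))
    man
}

resolve_path <- function(p, base) {
    if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
}

#' Write an image stack and its manifest
#'
#' @param stack an [image_stack()].
#' @param dir output directory (created if needed).
#' @param format `"tiff"` or `"png"`.
#' @param manifest manifest file name written inside `dir`.
#' @return path of the written manifest, invisibly.
#' @export
write_stack <- function(stack, dir, format = c("tiff", "png"),
                        manifest = "manifest.csv") {
    format <- match.arg(format)
    ext <- if (format == "tiff") "tif" else "png"
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    rows <- lapply(stack$pairs, function(p) {
        ph <- sprintf("%s_phase.%s", p$tag, ext)
        fl <- sprintf("%s_fluor.%s", p$tag, ext)
        write_grey_image(p$phase, file.path(dir, ph),
                         bits = max(p$bit_depth, 8L))
        write_grey_image(p$fluorescence, file.path(dir, fl),
                         bits = max(p$bit_depth, 8L))
        data.frame(tag = p$tag, phase = ph, fluor = fl,
                   stringsAsFactors = FALSE)
    })
    man <- do.call(rbind, rows)
    mp <- file.path(dir, manifest)
    utils::write.csv(man, mp, row.names = FALSE)
    invisible(mp)
}

#' Translate an image
#'
#' Shifts an image by a real-valued translation under the package's
#' coordinate convention: `out[r, c] = in[r - dy, c - dx]`. Sub-pixel
#' accuracy uses the Keys bicubic convolution kernel with edge replication
#' for the kernel taps; pixels whose source centre falls outside the input
#' are filled with 0 (blank rows/columns appear at the edges the content
#' moved away from). With `interpolation = "nearest"` an integer translation
#' is an exact pixel relocation.
#'
#' @param image numeric matrix with finite values.
#' @param t translation `c(dx, dy)`.
#' @param interpolation `"bicubic"` (default) or `"nearest"`.
#' @return numeric matrix, same dimensions as `image`.
#' @examples
#' m <- matrix(runif(25), 5, 5)
#' identical(apply_translation(m, c(0, 0), "nearest"), m)
#' @export
apply_translation <- function(image, t, interpolation = c("bicubic", "nearest")) {
    check_grey_image(image)
    t <- as_translation(t)
    interpolation <- match.arg(interpolation)
    if (interpolation == "nearest")
        cpp_shift_nearest(image, t[1], t[2])
    else
        cpp_shift_bicubic(image, t[1], t[2])
}

#' RGB composite of three grey images
#'
#' Stacks three equally-sized grey images as the R, G and B channels of a
#' colour image after per-channel min-max scaling to `[0, 1]`. Misalignment
#' between the channels shows up as colour fringes; a perfectly aligned
#' triple of identical images renders as pure grey.
#'
#' @param r,g,b numeric matrices of identical dimensions.
#' @return `h x w x 3` numeric array in `[0, 1]`.
#' @export
rgb_composite <- function(r, g, b) {
    check_grey_image(r); check_grey_image(g); check_grey_image(b)
    if (!identical(dim(r), dim(g)) || !identical(dim(r), dim(b)))
        stop("channel dimension mismatch")
    sc <- function(x) {
        rng <- range(x)
        if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) else x * 0
    }
    array(c(sc(r), sc(g), sc(b)), dim = c(dim(r), 3L))
}

#' RMS difference between three colour channels
#'
#' Composite mis-alignment diagnostic: the root-mean-square of the three
#' pairwise channel differences,
#' `sqrt((sum((R-G)^2) + sum((G-B)^2) + sum((R-B)^2)) / (3 B))`,
#' where `B` is the number of pixels per channel. Zero iff all three
#' channels are identical; invariant under channel permutation. Computed on
#' the intensities as given (scale it consistently before/after alignment
#' when comparing).
#'
#' @param r,g,b numeric matrices of identical dimensions.
#' @return non-negative scalar.
#' @export
rms_channel_difference <- function(r, g, b) {
    check_grey_image(r); check_grey_image(g); check_grey_image(b)
    if (!identical(dim(r), dim(g)) || !identical(dim(r), dim(b)))
        stop("channel dimension mismatch")
    B <- length(r)
    sqrt((sum((r - g)^2) + sum((g - b)^2) + sum((r - b)^2)) / (3 * B))
}

#' Frame region covered by every translated image
#'
#' The complement of [mosaic_extent()]: the rectangle of frame pixels that
#' carry data from every image after the translations are applied (aligned
#' image `j` has valid content at rows `r` with `1 <= r - dy_j <= h`). This
#' is the region on which post-alignment diagnostics such as
#' [rms_channel_difference()] are meaningful, since pixels outside it are
#' zero-filled by construction rather than misaligned.
#'
#' @param stack_dims `c(h, w)` common image dimensions in pixels.
#' @param translations list (or n x 2 matrix) of applied translations.
#' @return list with integer ranges `rows = c(first, last)` and
#'   `cols = c(first, last)`; errors if the intersection is empty.
#' @export
overlap_region <- function(stack_dims, translations) {
    h <- stack_dims[1]; w <- stack_dims[2]
    tm <- if (is.matrix(translations)) translations
          else do.call(rbind, lapply(translations, as_translation))
    r1 <- 1L + max(0L, ceiling(max(tm[, 2])))
    r2 <- h + min(0L, floor(min(tm[, 2])))
    c1 <- 1L + max(0L, ceiling(max(tm[, 1])))
    c2 <- w + min(0L, floor(min(tm[, 1])))
    if (r1 > r2 || c1 > c2) stop("translated footprints have empty overlap")
    list(rows = c(r1, r2), cols = c(c1, c2))
}

#' Bounding box of a mosaic of translated images
#'
#' The minimal axis-aligned frame containing the footprints of all images
#' after applying their alignment translations (the frame a mosaic of the
#' aligned stack would need). Footprint of image `j` is
#' `[dx_j, dx_j + w] x [dy_j, dy_j + h]` in reference coordinates.
#'
#' @param stack_dims `c(h, w)` common image dimensions in pixels.
#' @param translations list (or n x 2 matrix) of translations, one per
#'   image; the reference contributes `c(0, 0)`.
#' @return list with `xmin`, `xmax`, `ymin`, `ymax`, `width`, `height`.
#' @export
mosaic_extent <- function(stack_dims, translations) {
    h <- stack_dims[1]; w <- stack_dims[2]
    tm <- if (is.matrix(translations)) translations
          else do.call(rbind, lapply(translations, as_translation))
    xmin <- min(tm[, 1]); xmax <- max(tm[, 1]) + w
    ymin <- min(tm[, 2]); ymax <- max(tm[, 2]) + h
    list(xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax,
         width = xmax - xmin, height = ymax - ymin)
}
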