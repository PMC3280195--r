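test_that("stack constructors enforce the invariants", {
    img <- texture_image(20, 24, seed = 1)
    p1 <- tag_image_pair("a", img, img)
    p2 <- tag_image_pair("b", img, img)
    st <- image_stack(list(p1, p2))
    expect_equal(st$h, 20)
    expect_equal(st$w, 24)
    expect_error(image_stack(list(p1)), "at least 2")
    small <- tag_image_pair("c", img[1:10, ], img[1:10, ])
    expect_error(image_stack(list(p1, small)), "tag 'c'")
    expect_error(image_stack(list(p1, p1)), "unique")
    bad <- img; bad[1] <- NA
    expect_error(tag_image_pair("d", bad, img), "non-finite")
})

test_that("manifests round-trip through TIFF and PNG and report bad input", {
    img <- texture_image(16, 16, seed = 2)
    st <- image_stack(list(tag_image_pair("a", img, img),
                           tag_image_pair("b", img * 0.5, img)))
    for (fmt in c("tiff", "png")) {
        d <- withr::local_tempdir()
        man <- write_stack(st, d, format = fmt)
        back <- read_stack(man)
        expect_equal(back$tags, c("a", "b"))
        # 8-bit rasters quantize to 1/255
        expect_equal(back$pairs[[1]]$phase, img, tolerance = 1e-2,
                     ignore_attr = TRUE)
    }
    # manifest pointing at a missing file names the offending tag
    d <- withr::local_tempdir()
    man <- write_stack(st, d)
    file.remove(file.path(d, "b_phase.tif"))
    expect_error(read_stack(man), "tag 'b'")
    # single-tag manifest violates N >= 2
    d2 <- withr::local_tempdir()
    write_grey_image(img, file.path(d2, "a.tif"))
    write.csv(data.frame(tag = "a", phase = "a.tif", fluor = "a.tif"),
              file.path(d2, "m.csv"), row.names = FALSE)
    expect_error(read_stack(file.path(d2, "m.csv")), "at least 2")
    # mismatched sizes name the tag
    d3 <- withr::local_tempdir()
    write_grey_image(img, file.path(d3, "a.tif"))
    write_grey_image(img[1:8, ], file.path(d3, "b.tif"))
    write.csv(data.frame(tag = c("a", "b"),
                         phase = c("a.tif", "b.tif"),
                         fluor = c("a.tif", "b.tif")),
              file.path(d3, "m.csv"), row.names = FALSE)
    expect_error(read_stack(file.path(d3, "m.csv")), "tag 'b'")
})

test_that("yaml manifests are read", {
    img <- texture_image(12, 12, seed = 3)
    d <- withr::local_tempdir()
    write_grey_image(img, file.path(d, "a.png"))
    write_grey_image(img, file.path(d, "b.png"))
    yaml::write_yaml(list(list(tag = "a", phase = "a.png", fluor = "a.png"),
                          list(tag = "b", phase = "b.png", fluor = "b.png")),
                     file.path(d, "m.yaml"))
    st <- read_stack(file.path(d, "m.yaml"))
    expect_equal(st$tags, c("a", "b"))
})

test_that("integer translations relocate pixels exactly", {
    img <- texture_image(15, 15, seed = 4)
    expect_identical(apply_translation(img, c(0, 0), "nearest"), img)
    sh <- apply_translation(img, c(3, 0), "nearest")
    expect_equal(sh[, 4:15], img[, 1:12])
    expect_true(all(sh[, 1:3] == 0))
    sh2 <- apply_translation(img, c(-2, 5), "nearest")
    expect_equal(sh2[6:15, 1:13], img[1:10, 3:15])
    # bicubic with an integer shift is also exact relocation on the interior
    shb <- apply_translation(img, c(3, 0), "bicubic")
    expect_equal(shb[, 4:15], img[, 1:12], tolerance = 1e-12)
})

test_that("bicubic sub-pixel shift matches the direct convolution oracle", {
    img <- texture_image(18, 17, seed = 5)
    for (t in list(c(0.5, 0), c(-1.3, 2.7), c(0.25, -0.75))) {
        got <- apply_translation(img, t, "bicubic")
        want <- bicubic_shift_oracle(img, t[1], t[2])
        expect_equal(got, want, tolerance = 1e-12)
        expect_true(all(is.finite(got)))
    }
    # a linear ramp is reproduced exactly at half-pixel offsets (the Keys
    # kernel has linear precision): interior values equal the shifted ramp
    ramp <- matrix(rep(seq_len(20), each = 20), 20, 20)  # f(r, c) = c
    sh <- apply_translation(ramp, c(0.5, 0), "bicubic")
    expect_equal(sh[5:15, 5:15], ramp[5:15, 5:15] - 0.5, tolerance = 1e-9)
})

test_that("shifting forth and back restores the interior", {
    img <- texture_image(30, 30, seed = 6)
    t <- c(2, -3)
    back <- apply_translation(apply_translation(img, t, "nearest"),
                              -t, "nearest")
    expect_equal(back[4:27, 4:27], img[4:27, 4:27], tolerance = 1e-6)
    # bicubic round trip on a smooth (slowly varying) image
    rr <- matrix(seq_len(30), 30, 30)
    smooth <- sin(2 * pi * rr / 19) + cos(2 * pi * t(rr) / 23)
    ts <- c(1.6, -2.2)
    backb <- apply_translation(apply_translation(smooth, ts, "bicubic"),
                               -ts, "bicubic")
    idx <- 7:24
    expect_equal(backb[idx, idx], smooth[idx, idx], tolerance = 1e-3)
})

test_that("rgb composite scales channels and keeps constants constant", {
    img <- texture_image(10, 10, seed = 7)
    comp <- rgb_composite(img, img, img)
    expect_equal(comp[, , 1], comp[, , 2])
    expect_equal(dim(comp), c(10, 10, 3))
    const <- matrix(0.4, 10, 10)
    cc <- rgb_composite(const, const, const)
    expect_true(all(cc == cc[1]))
    expect_error(rgb_composite(img, img, img[1:5, ]), "mismatch")
    # a shifted channel produces fringes: before != after alignment
    sh <- apply_translation(img, c(2, 0), "nearest")
    expect_gt(rms_channel_difference(img, img, sh),
              rms_channel_difference(img, img, img))
})

test_that("rms channel difference matches hand evaluation", {
    img <- texture_image(8, 8, seed = 8)
    expect_equal(rms_channel_difference(img, img, img), 0)
    # r = g = b + c: pairs differ by (0, c, c) -> rms = c * sqrt(2/3)
    cst <- 0.3
    b <- img; r <- img + cst; g <- img + cst
    expect_equal(rms_channel_difference(r, g, b), cst * sqrt(2 / 3),
                 tolerance = 1e-12)
    # 2x2 toy values, brute force over the 4 pixels
    r2 <- matrix(c(1, 2, 3, 4), 2); g2 <- matrix(c(0, 2, 1, 4), 2)
    b2 <- matrix(c(1, 1, 1, 1), 2)
    want <- sqrt((sum((r2 - g2)^2) + sum((g2 - b2)^2) + sum((r2 - b2)^2)) / 12)
    expect_equal(rms_channel_difference(r2, g2, b2), want)
    # permutation invariance
    expect_equal(rms_channel_difference(b2, r2, g2),
                 rms_channel_difference(r2, g2, b2))
})

test_that("mosaic extent is the union of translated footprints", {
    e <- mosaic_extent(c(20, 30), list(c(0, 0), c(0, 0)))
    expect_equal(c(e$height, e$width), c(20, 30))
    e2 <- mosaic_extent(c(20, 30), list(c(0, 0), c(10, 0)))
    expect_equal(c(e2$height, e2$width), c(20, 40))
    # random integer shifts: compare against a rasterized union oracle
    set.seed(9)
    for (rep in 1:20) {
        sh <- matrix(sample(-6:6, 8, replace = TRUE), 4, 2)
        e3 <- mosaic_extent(c(5, 7), sh)
        canvas <- matrix(FALSE, 40, 40)  # footprints offset to stay positive
        for (j in 1:4)
            canvas[sh[j, 2] + 15 + 1:5, sh[j, 1] + 15 + 1:7] <- TRUE
        expect_equal(e3$height, diff(range(which(rowSums(canvas) > 0))) + 1)
        expect_equal(e3$width, diff(range(which(colSums(canvas) > 0))) + 1)
    }
})
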