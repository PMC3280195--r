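test_that("shift matrices complete the registration graph", {
    # N = 2: single pair
    m <- build_shift_matrices(rbind(c(3, -1)), r = 1, tags = c("a", "b"))
    expect_equal(m$dx, rbind(c(0, 3), c(-3, 0)))
    expect_equal(m$dy, rbind(c(0, -1), c(1, 0)))
    # all-zero base translations give zero matrices
    m0 <- build_shift_matrices(matrix(0, 3, 2), r = 2)
    expect_true(all(m0$dx == 0) && all(m0$dy == 0))
    # N = 4 random case: every entry equals delta_rk - delta_rj
    set.seed(21)
    base <- matrix(runif(6, -10, 10), 3, 2)
    r <- 2
    m4 <- build_shift_matrices(base, r = r)
    v <- numeric(4); v[-r] <- base[, 1]
    u <- numeric(4); u[-r] <- base[, 2]
    for (j in 1:4) for (k in 1:4) {
        expect_equal(m4$dx[j, k], v[k] - v[j], tolerance = 1e-12)
        expect_equal(m4$dy[j, k], u[k] - u[j], tolerance = 1e-12)
    }
    expect_error(build_shift_matrices(base, r = 9), "out of range")
})

test_that("skew-symmetry, zero diagonal and path independence hold exactly", {
    set.seed(22)
    for (rep in 1:50) {
        N <- sample(3:20, 1)
        m <- build_shift_matrices(matrix(runif(2 * (N - 1), -15, 15),
                                         N - 1, 2),
                                  r = sample(N, 1))
        expect_identical(m$dx, -t(m$dx))
        expect_identical(m$dy, -t(m$dy))
        expect_true(all(diag(m$dx) == 0) && all(diag(m$dy) == 0))
        # composing through any intermediate image reproduces the entry
        idx <- cbind(sample(N, 10, TRUE), sample(N, 10, TRUE), sample(N, 10, TRUE))
        for (i in seq_len(nrow(idx))) {
            j <- idx[i, 1]; k <- idx[i, 2]; mm <- idx[i, 3]
            expect_equal(m$dx[j, mm] + m$dx[mm, k], m$dx[j, k],
                         tolerance = 1e-12)
            expect_equal(m$dy[j, mm] + m$dy[mm, k], m$dy[j, k],
                         tolerance = 1e-12)
        }
    }
})

test_that("the objective picks the central image", {
    m <- build_shift_matrices(rbind(c(10, 0), c(-10, 0)), r = 1)
    # image 1 at 0, image 2 at +10, image 3 at -10: image 1 is central
    obj <- rimo_objective(m, 100, 100)
    expect_equal(which.min(obj), 1)
    # hand-evaluated closed form for each candidate
    d <- function(dx) symmetric_difference_area(c(dx, 0), 100, 100)
    expect_equal(obj, c(d(10) + d(10), d(10) + d(20), d(10) + d(20)))
    # l1 dominates exact component-wise in the overlapping regime
    expect_true(all(rimo_objective(m, 100, 100, mode = "l1") >= obj))
    # all-zero shifts: zero objective, tie broken to index 1
    mz <- build_shift_matrices(matrix(0, 2, 2), r = 1)
    rz <- select_rimo(mz, 50, 50)
    expect_equal(rz$rimo_index, 1)
    expect_true(all(rz$objective == 0))
})

test_that("select_rimo agrees with exhaustive minimization", {
    set.seed(23)
    for (rep in 1:200) {
        N <- sample(2:20, 1)
        h <- sample(30:120, 1); w <- sample(30:120, 1)
        m <- build_shift_matrices(matrix(runif(2 * (N - 1), -25, 25),
                                         N - 1, 2),
                                  r = sample(N, 1))
        res <- select_rimo(m, h, w)
        # independent brute force, scalar evaluation per candidate
        brute <- sapply(seq_len(N), function(r) {
            s <- 0
            for (j in seq_len(N)) {
                ax <- abs(m$dx[r, j]); ay <- abs(m$dy[r, j])
                s <- s + if (ax >= w || ay >= h) 2 * h * w
                         else 2 * (h * ax + w * ay - ax * ay)
            }
            s
        })
        expect_equal(res$rimo_index, which.min(brute))
        expect_equal(res$objective, brute, tolerance = 1e-9)
        expect_equal(res$per_image_shift_magnitude[res$rimo_index], 0)
        expect_equal(min(res$objective), res$objective[res$rimo_index])
    }
})

test_that("changing the arbitrary base reference leaves the RIMO unchanged", {
    set.seed(24)
    v <- c(0, runif(4, -12, 12)); u <- c(0, runif(4, -12, 12))
    m1 <- build_shift_matrices(cbind(v[-1], u[-1]), r = 1)
    # re-expressing the same geometry with image 3 as the base reference
    base3 <- cbind(v - v[3], u - u[3])[-3, ]
    m3 <- build_shift_matrices(base3, r = 3)
    expect_equal(m1$dx, m3$dx, tolerance = 1e-12)
    expect_equal(select_rimo(m1, 80, 80)$rimo_index,
                 select_rimo(m3, 80, 80)$rimo_index)
})

test_that("realigning to the RIMO restores the stack", {
    img <- texture_image(80, 80, seed = 25)
    shifts <- rbind(c(0, 0), c(4, 2), c(-3, 1))
    st <- shifted_stack(img, shifts)
    m <- build_shift_matrices(shifts[-1, , drop = FALSE], r = 1,
                              tags = st$tags)
    rimo <- select_rimo(m, 80, 80)
    expect_equal(rimo$rimo_index, 1)  # zero-shift image overlaps most
    out <- realign_stack(st, m, rimo$rimo_index)
    expect_identical(out$stack$pairs[[1]]$phase, img)  # reference untouched
    # aligned interiors match the reference (integer shifts, bicubic exact)
    for (j in 2:3) {
        al <- out$stack$pairs[[j]]$phase
        expect_equal(al[20:60, 20:60], img[20:60, 20:60], tolerance = 1e-9)
    }
    # zero-shift stack passes through unchanged
    mz <- build_shift_matrices(matrix(0, 2, 2), r = 1, tags = st$tags)
    outz <- realign_stack(st, mz, 1)
    for (j in 1:3)
        expect_identical(outz$stack$pairs[[j]]$phase, st$pairs[[j]]$phase)
})

test_that("register_stack estimates the truth on a small synthetic stack", {
    img <- texture_image(300, 300, seed = 26)
    shifts <- rbind(c(0, 0), c(5, -3), c(-2, 4))
    st <- shifted_stack(img, shifts)
    res <- register_stack(st, reference = 1, K = 4, S = 64, margin = 12)
    expect_length(res$pairs, 2)
    expect_equal(res$flagged, character(0))
    for (j in 2:3)
        expect_lt(max(abs(c(res$matrices$dx[1, j], res$matrices$dy[1, j]) -
                          shifts[j, ])), 0.1)
    rimo <- select_rimo(res$matrices, 300, 300)
    expect_equal(rimo$rimo_index, 1)
})
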