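test_that("triplet reading folds symmetric duplicates onto canonical pairs", {
    grid <- smallGrid(4)
    path <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("0\t1\t5", "1\t0\t5", "0\t1\t2", "2\t2\t3"), path)
    m <- readTriplets(path, grid)
    expect_equal(contactValue(m, 0, 1), 12)  # 5 + 5 + 2
    expect_equal(contactValue(m, 1, 0), 12)  # symmetric access
    expect_equal(contactValue(m, 2, 2), 3)
    expect_equal(contactValue(m, 0, 3), 0)   # absent pair
})

test_that("triplet write/read is an identity and errors carry line numbers", {
    grid <- smallGrid(6)
    set.seed(3)
    M <- randomCountMatrix(6)
    m <- fromDense(grid, M)
    path <- withr::local_tempfile(fileext = ".tsv")
    writeTriplets(m, path)
    back <- readTriplets(path, grid)
    expect_identical(back@i, m@i)
    expect_identical(back@j, m@j)
    expect_equal(back@x, m@x)

    writeLines(c("0\t1\t5", "0\t99\t1"), path)
    expect_error(readTriplets(path, grid), "line 2")
    writeLines(c("0\t1\t5", "0\t1\t-2"), path)
    expect_error(readTriplets(path, grid), "line 2.*non-negative")
    writeLines("0\tx\t5", path)
    expect_error(readTriplets(path, grid), "line 1")
})

test_that("total interactions counts each unordered pair once", {
    grid <- smallGrid(4)
    m <- ContactMatrix(grid, c(0, 1), c(1, 1), c(5, 2))
    expect_equal(totalInteractions(m), 7)
    expect_equal(totalInteractions(ContactMatrix(grid)), 0)
    bal <- suppressWarnings(iceBalance(m, lowCovFraction = 0)$matrix)
    sub <- subtractMatrices(scaleToMeanTotal(list(bal))[[1]],
        scaleToMeanTotal(list(bal))[[1]])
    expect_error(totalInteractions(sub), "subtraction")
})

test_that("merging replicates sums entries over the union of supports", {
    grid <- smallGrid(5)
    A <- ContactMatrix(grid, c(0, 1), c(1, 2), c(3, 4),
        sampleMeta = list(state = "s", replicate = 1))
    B <- ContactMatrix(grid, c(1, 3), c(2, 4), c(1, 7),
        sampleMeta = list(state = "s", replicate = 2))
    E <- ContactMatrix(grid)
    expect_equal(denseMatrix(mergeReplicates(list(A, E))),
        denseMatrix(A))
    expect_equal(denseMatrix(mergeReplicates(list(A, A))),
        2 * denseMatrix(A))
    M <- mergeReplicates(list(A, B))
    expect_equal(contactValue(M, 1, 2), 5)
    expect_equal(contactValue(M, 3, 4), 7)
    expect_identical(matrixStage(M), "merged")
    expect_equal(sampleMeta(M)$replicate, c(1, 2))
    otherGrid <- smallGrid(7)
    C <- ContactMatrix(otherGrid, 0, 1, 2)
    expect_error(mergeReplicates(list(A, C)), "grids")
    bal <- suppressWarnings(iceBalance(A, lowCovFraction = 0)$matrix)
    expect_error(mergeReplicates(list(A, bal)), "balanced")
})

test_that("ICE balances a rank-1 matrix to constant off-diagonals", {
    grid <- smallGrid(3)
    v <- c(1, 2, 4)
    m <- fromDense(grid, outer(v, v))
    out <- iceBalance(m, lowCovFraction = 0)
    B <- denseMatrix(out$matrix)
    off <- B[upper.tri(B)]
    expect_equal(max(off) / min(off), 1, tolerance = 1e-4)
    marg <- rowSums(B)
    expect_lt(max(abs(marg / mean(marg) - 1)), 2e-4)
    # bias proportional to the coverage vector, up to scale
    bias <- out$result@bias
    expect_equal(bias / bias[1], v / v[1], tolerance = 1e-3)
    # total preserved
    expect_equal(totalInteractions(out$matrix), totalInteractions(m),
        tolerance = 1e-9)
})

test_that("ICE leaves a uniform matrix unchanged and masks empty bins", {
    grid <- smallGrid(5)
    M <- matrix(1, 5, 5)
    out <- iceBalance(fromDense(grid, M), lowCovFraction = 0)
    expect_lte(out$result@iterations, 2L)
    expect_equal(denseMatrix(out$matrix), M)

    M2 <- randomCountMatrix(5) + 1
    M2[3, ] <- 0; M2[, 3] <- 0
    out2 <- iceBalance(fromDense(grid, M2), lowCovFraction = 0)
    expect_true(2L %in% maskedBins(out2$matrix))
    expect_true(all(denseMatrix(out2$matrix)[3, ] == 0))
    expect_true(is.na(out2$result@bias[3]))
})

test_that("re-balancing a balanced matrix is a no-op within tolerance", {
    grid <- smallGrid(12)
    set.seed(9)
    m <- fromDense(grid, randomCountMatrix(12) + 1)
    b1 <- iceBalance(m, lowCovFraction = 0, tol = 1e-8)$matrix
    again <- ContactMatrix(grid, b1@i, b1@j, b1@x)  # reset stage to raw
    b2 <- iceBalance(again, lowCovFraction = 0, tol = 1e-8)$matrix
    expect_equal(b2@x, b1@x, tolerance = 1e-6)
})

test_that("low-coverage masking removes the weakest fraction of bins", {
    grid <- smallGrid(50)
    set.seed(21)
    M <- randomCountMatrix(50) + 1
    M[7, ] <- M[, 7] <- rbinom(50, 1, 0.1)
    M[7, 7] <- 0
    out <- iceBalance(fromDense(grid, M), lowCovFraction = 0.02)
    expect_gte(length(maskedBins(out$matrix)), 1L)
    expect_true(6L %in% maskedBins(out$matrix))
})

test_that("scaling to the mean total equalises totals and preserves ratios", {
    grid <- smallGrid(4)
    mk <- function(tot) {
        m <- ContactMatrix(grid, c(0, 1), c(1, 2), c(0.25, 0.75) * tot)
        new("ContactMatrix", grid = grid, i = m@i, j = m@j, x = m@x,
            stage = "balanced", sampleMeta = list(), maskedBins = integer(0))
    }
    sc <- scaleToMeanTotal(list(mk(100), mk(300)))
    expect_equal(totalInteractions(sc[[1]]), 200)
    expect_equal(totalInteractions(sc[[2]]), 200)
    expect_equal(sc[[1]]@x / sum(sc[[1]]@x), c(0.25, 0.75))  # ratios kept
    sc3 <- scaleToMeanTotal(list(mk(10), mk(20), mk(30)))
    expect_equal(vapply(sc3, totalInteractions, numeric(1)), rep(20, 3),
        tolerance = 1e-12)
    one <- scaleToMeanTotal(list(mk(42)))
    expect_equal(one[[1]]@x, mk(42)@x)
    expect_error(scaleToMeanTotal(list(mk(10), ContactMatrix(grid))),
        "zero-total")
})

test_that("subtraction is antisymmetric over the union of supports", {
    grid <- smallGrid(5)
    mk <- function(i, j, x) {
        m <- ContactMatrix(grid, i, j, x)
        new("ContactMatrix", grid = grid, i = m@i, j = m@j, x = m@x,
            stage = "scaled", sampleMeta = list(), maskedBins = integer(0))
    }
    A <- mk(0, 1, 5)
    B <- mk(c(0, 2), c(1, 3), c(2, 1))
    D <- subtractMatrices(A, B)
    expect_equal(contactValue(D, 0, 1), 3)
    expect_equal(contactValue(D, 2, 3), -1)
    R <- subtractMatrices(B, A)
    expect_equal(denseMatrix(R), -denseMatrix(D))
    Z <- subtractMatrices(A, A)
    expect_identical(nEntries(Z), 0L)
    expect_error(subtractMatrices(A, ContactMatrix(grid, 0, 1, 1)),
        "scaled")
})

test_that("percentile capping interpolates order statistics of non-zeros", {
    grid <- smallGrid(100)
    m <- ContactMatrix(grid, rep(0, 100), 0:99, 1:100)
    capped <- percentileCap(m, 94)
    expect_equal(max(capped@x), 94.06)
    expect_equal(sum(abs(capped@x - 94.06) < 1e-9), 6)  # 95..100 capped
    expect_equal(percentileCap(m, 100)@x, m@x)

    sub <- new("ContactMatrix", grid = grid, i = rep(0L, 4), j = 1:4,
        x = c(-10, -1, 1, 10), stage = "subtraction",
        sampleMeta = list(), maskedBins = integer(0))
    cs <- percentileCap(sub, 97)
    cap <- stats::quantile(c(1, 10), 0.97, names = FALSE)
    expect_equal(sort(cs@x), sort(c(-cap, -1, 1, cap)))
    expect_error(percentileCap(ContactMatrix(grid), 94), "empty")
    expect_error(percentileCap(m, 0), "q must be")
})

test_that("balanced entries agree with the brute-force oracle", {
    set.seed(40)
    for (trial in 1:20) {
        M <- randomCountMatrix(20) + 1  # full coverage, no masking
        grid <- smallGrid(20)
        ours <- denseMatrix(
            iceBalance(fromDense(grid, M), lowCovFraction = 0,
                tol = 1e-10, maxIter = 5000)$matrix)
        oracle <- oracleIceDense(M)
        expect_equal(ours, oracle, tolerance = 1e-6)
    }
})
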