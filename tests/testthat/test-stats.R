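test_that("median-of-ratios size factors match the closed form", {
    tab <- cbind(a = c(1, 2, 4), b = c(1, 2, 4))
    expect_equal(unname(sizeFactors(tab)), c(1, 1))
    tab2 <- cbind(a = c(1, 2, 4), b = 2 * c(1, 2, 4))
    expect_equal(unname(sizeFactors(tab2)), c(1 / sqrt(2), sqrt(2)))
    # rows containing zeros are ignored
    tab3 <- rbind(tab2, c(0, 100))
    expect_equal(sizeFactors(tab3), sizeFactors(tab2))
    expect_error(sizeFactors(cbind(c(0, 1), c(1, 0))), "all-positive")
})

test_that("size factors agree with the DESeq2 reference implementation", {
    skip_if_not_installed("DESeq2")
    set.seed(14)
    tab <- matrix(rpois(500, lambda = rep(c(5, 20, 80), length.out = 500)),
        ncol = 5)
    tab <- sweep(tab, 2, c(1, 2, 0.5, 1.5, 1), "*")
    ref <- DESeq2::estimateSizeFactorsForMatrix(tab)
    expect_equal(unname(sizeFactors(tab)), unname(ref), tolerance = 1e-8)
})

test_that("log normalisation applies log2(x/f + 1)", {
    expect_equal(logNormalize(matrix(0), 1)[1], 0)
    expect_equal(logNormalize(matrix(1), 1)[1], 1)
    expect_equal(logNormalize(matrix(3), 2)[1], log2(2.5))
})

test_that("sample PCA has deterministic signs and valid variance shares", {
    set.seed(2)
    X <- matrix(rnorm(300), nrow = 50)
    pc <- pcaSamples(X)
    expect_true(all(diff(pc$varianceExplained) <= 1e-12))
    expect_equal(sum(pc$varianceExplained), 1)
    # largest-magnitude loading of each component is positive
    for (k in seq_len(ncol(pc$loadings))) {
        col <- pc$loadings[, k]
        expect_gte(col[which.max(abs(col))], 0)
    }
    # identical samples land on identical coordinates
    Y <- cbind(X[, 1], X[, 1], X[, 2])
    pcy <- pcaSamples(Y)
    expect_equal(pcy$coordinates[1, ], pcy$coordinates[2, ])
    # a single differing row makes PC1 explain everything
    Z <- matrix(1, nrow = 10, ncol = 3)
    Z[4, ] <- c(1, 5, 9)
    pcz <- pcaSamples(Z)
    expect_equal(pcz$varianceExplained[1], 1)
    expect_error(pcaSamples(matrix(1, 5, 3)), "constant")
})

test_that("PCA reconstruction reproduces the centred table", {
    set.seed(6)
    X <- matrix(rnorm(80), nrow = 16, ncol = 5)
    pc <- pcaSamples(X)
    centred <- t(scale(t(X), center = TRUE, scale = FALSE))
    recon <- pc$coordinates %*% t(pc$loadings)
    expect_equal(t(recon), centred, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("the normality gate rejects degenerate input", {
    expect_error(normalityCheck(c(1, 2)), "3 <= n")
    expect_error(normalityCheck(rep(2, 10)), "constant")
    set.seed(77)
    x <- stats::rcauchy(50)
    # frozen reference value from an independent implementation
    # (scipy.stats.shapiro on the identical sample)
    expect_lt(normalityCheck(x), 1e-6)
    expect_equal(normalityCheck(x), .shapiroReferenceP, tolerance = 1e-3)
})

test_that("Kruskal-Wallis matches the hand-evaluated rank formula", {
    kw <- kruskalWallis(list(c(1, 2, 3), c(4, 5, 6)))
    expect_equal(kw@H, 3.8571, tolerance = 1e-4)
    expect_equal(kw@p, 0.04953, tolerance = 1e-4)
    expect_identical(kw@df, 1L)
    expect_equal(kw@groupMeanRanks, c(2, 5))
    tied <- kruskalWallis(list(c(2, 2), c(2, 2, 2)))
    expect_equal(tied@H, 0)
    expect_equal(tied@p, 1)
    expect_error(kruskalWallis(list(1:3)), "2 non-empty")
})

test_that("Kruskal-Wallis agrees with stats::kruskal.test under ties", {
    set.seed(31)
    for (trial in 1:10) {
        g <- lapply(c(5, 8, 6), function(n)
            sample(1:6, n, replace = TRUE))  # heavy ties
        kw <- kruskalWallis(g)
        ref <- stats::kruskal.test(unlist(g),
            rep(seq_along(g), lengths(g)))
        expect_equal(kw@H, unname(ref$statistic), tolerance = 1e-10)
        expect_equal(kw@p, ref$p.value, tolerance = 1e-10)
    }
})

test_that("the chi-square p approximates a permutation p at small n", {
    set.seed(12)
    g <- list(rnorm(8), rnorm(8, 0.8), rnorm(8, 0.4))
    kw <- kruskalWallis(g)
    permP <- kwPermutationP(g, nPerm = 10000)
    expect_lt(abs(kw@p - permP), 0.02)
})

test_that("Dunn's z matches the formula and collapses to KW for k = 2", {
    dn <- dunnTest(list(c(1, 2, 3), c(4, 5, 6)), adjust = "none")
    expect_equal(abs(dn@pairs$z), 1.9640, tolerance = 1e-4)
    expect_equal(dn@pairs$p, 0.0495, tolerance = 1e-3)
    expect_equal(dn@pairs$p_adj, dn@pairs$p)  # none, one pair
    same <- dunnTest(list(c(1, 1), c(1, 1), c(1, 1)), adjust = "holm")
    expect_true(all(same@pairs$z == 0))
    expect_true(all(same@pairs$p == 1))
    # for two groups Dunn's unadjusted p equals the KW p (same ranks)
    set.seed(18)
    for (trial in 1:5) {
        g <- list(rnorm(6), rnorm(7, mean = trial / 4))
        kw <- kruskalWallis(g)
        dn <- dunnTest(g, adjust = "none")
        expect_lt(abs(dn@pairs$p - kw@p), 0.002)
    }
})

test_that("Dunn flags post hoc as unwarranted when the omnibus p >= 0.05", {
    set.seed(4)
    g <- list(rnorm(5), rnorm(5))
    dn <- dunnTest(g)
    expect_identical(dn@warranted, kruskalWallis(g)@p < 0.05)
})

test_that("Holm and BH adjustments follow the step procedures", {
    expect_equal(adjustPvalues(0.03, "holm"), 0.03)
    expect_equal(adjustPvalues(c(0.01, 0.02, 0.03), "bh"),
        c(0.03, 0.03, 0.03))
    expect_equal(adjustPvalues(c(0.01, 0.04), "holm"), c(0.02, 0.04))
    set.seed(25)
    ps <- runif(20)
    for (meth in c("holm", "bh")) {
        adj <- adjustPvalues(ps, meth)
        expect_true(all(adj >= ps))
        expect_true(all(adj <= 1))
    }
    adjBH <- adjustPvalues(ps, "bh")
    expect_true(all(diff(adjBH[order(ps)]) >= -1e-12))  # order preserved
    expect_error(adjustPvalues(c(0.5, 1.2), "bh"), "\\[0, 1\\]")
})

test_that("count tables align canonical pairs across samples", {
    grid <- smallGrid(5)
    A <- ContactMatrix(grid, c(0, 1), c(1, 2), c(3, 4))
    B <- ContactMatrix(grid, c(1, 0), c(2, 3), c(5, 6))
    tab <- buildCountTable(list(s1 = A, s2 = B))
    expect_identical(dim(tab), c(3L, 2L))
    expect_equal(tab["1_2", ], c(s1 = 4, s2 = 5))
    expect_equal(tab["0_3", ], c(s1 = 0, s2 = 6))
})
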