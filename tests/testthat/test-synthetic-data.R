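test_that("expected intensity follows the power-law distance decay", {
    cfg <- tinyConfig(n = 30, gamma = 1)  # no enrichment
    E <- expectedMatrix(cfg, "s1")
    expect_equal(E[1, 2] / E[1, 3], 1.5)  # (2)^-1 / (3)^-1
    expect_equal(sum(E), 1)
    expect_true(all(E[lower.tri(E)] == 0))
    # strictly decreasing in distance
    row0 <- E[1, ]
    expect_true(all(diff(row0) < 0))
    expect_error(expectedMatrix(cfg, "nope"), "unknown state")
})

test_that("domain boosts multiply intra-domain pairs only", {
    cfg <- tinyConfig(n = 60, gamma = 2, domainRange = c(20L, 40L))
    base <- tinyConfig(n = 60, gamma = 1, domainRange = c(20L, 40L))
    E2 <- expectedMatrix(cfg, "s1")
    E1 <- expectedMatrix(base, "s1")
    # same-distance pairs: inside (25,30) vs outside (45,50); the boosted
    # pair gains a factor gamma relative to the unboosted pair
    rIn <- E2[26, 31] / E1[26, 31]
    rOut <- E2[46, 51] / E1[46, 51]
    expect_equal(rIn / rOut, 2)
})

test_that("raising a domain boost raises every intra-domain intensity", {
    cfgs <- lapply(c(1, 1.5, 3), function(g)
        tinyConfig(n = 60, gamma = g, domainRange = c(20L, 40L)))
    Es <- lapply(cfgs, expectedMatrix, state = "s1")
    dom <- 21:40
    ratioFor <- function(E) {
        S <- E + t(E); diag(S) <- diag(E)
        sum(S[dom, dom]) / sum(S[dom, -dom])
    }
    ratios <- vapply(Es, ratioFor, numeric(1))
    expect_true(all(diff(ratios) > 0))
    # normalised intra-domain cells themselves increase with gamma
    expect_true(Es[[2]][26, 31] > Es[[1]][26, 31])
    expect_true(Es[[3]][26, 31] > Es[[2]][26, 31])
})

test_that("loops add localised enrichment at their anchors", {
    cfg <- tinyConfig(n = 60, gamma = 1, lambda = 3,
        anchors = c(10L, 50L))
    E <- expectedMatrix(cfg, "s1")
    base <- expectedMatrix(tinyConfig(n = 60, gamma = 1), "s1")
    enrich <- (E[11, 51] / E[11, 31]) / (base[11, 51] / base[11, 31])
    expect_equal(enrich, 4, tolerance = 1e-6)  # 1 + lambda at the anchor
})

test_that("multinomial sampling hits the requested depth reproducibly", {
    cfg <- tinyConfig(n = 30)
    E <- expectedMatrix(cfg, "s1")
    m1 <- sampleCounts(cfg@grid, E, 1000, seed = 5)
    expect_equal(totalInteractions(m1), 1000)
    m2 <- sampleCounts(cfg@grid, E, 1000, seed = 5)
    expect_identical(m1@i, m2@i)
    expect_identical(m1@x, m2@x)
    m3 <- sampleCounts(cfg@grid, E, 1000, seed = 6)
    expect_false(identical(m1@x, m3@x))
})

test_that("sampled counts match binomial expectation at a known cell", {
    grid <- smallGrid(10)
    p <- 0.01
    E <- matrix(0, 10, 10)
    E[upper.tri(E, diag = TRUE)] <- (1 - p) / 54  # 55 cells, one reserved
    E[1, 2] <- p
    depth <- 1e6
    sigma <- sqrt(depth * p * (1 - p))
    for (s in 1:5) {
        m <- sampleCounts(grid, E, depth, seed = 100 + s)
        obs <- contactValue(m, 0, 1)
        expect_lt(abs(obs - depth * p), 3.3 * sigma)
    }
})

test_that("empirical frequencies converge to the expectation with depth", {
    cfg <- tinyConfig(n = 30, gamma = 2, lambda = 2)
    E <- expectedMatrix(cfg, "s1")
    tv <- function(depth, seed) {
        m <- sampleCounts(cfg@grid, E, depth, seed)
        D <- denseMatrix(m); D[lower.tri(D)] <- 0
        sum(abs(D / depth - E)) / 2
    }
    expect_lt(tv(1e6, 7), tv(1e4, 7))
})

test_that("simulateExperiment writes reproducible per-replicate files", {
    cfg <- tinyConfig(n = 40, gamma = 2, states = c("a", "b", "c"),
        depth = 2000)
    cfg@replicatesPerState <- 2L
    outdir <- withr::local_tempdir()
    man <- simulateExperiment(cfg, outdir)
    files <- list.files(outdir)
    expect_length(grep("_rep\\d+\\.tsv$", files), 6)
    expect_true("manifest.json" %in% files)
    expect_true("grid.json" %in% files)
    expect_length(man$replicates, 6)
    # distinct derived seeds
    seeds <- vapply(man$replicates, `[[`, numeric(1), "seed")
    expect_identical(anyDuplicated(seeds), 0L)
    # manifest round-trips through serialization
    back <- jsonlite::read_json(file.path(outdir, "manifest.json"),
        simplifyVector = FALSE)
    expect_equal(length(back$replicates), 6)
    expect_equal(back$config$depth, cfg@depth)
    # deleting one output and re-running restores an identical file
    target <- file.path(outdir, "b_rep2.tsv")
    before <- readLines(target)
    unlink(target)
    simulateExperiment(cfg, outdir)
    expect_identical(readLines(target), before)
})

test_that("the tiled-region preset reproduces the locus geometry", {
    cfg <- runx1LikeConfig(depth = 1000, seed = 3)
    expect_identical(nBins(cfg@grid), 1268L)
    expect_identical(cfg@states, c("ESC", "mesoderm", "HPC"))
    main <- cfg@domains[[1]]
    expect_identical(main@name, "main_TAD")
    expect_identical(main@binRange, c(465L, 1026L))
    expect_identical(diff(main@binRange), 561L)
    # sub-domain boosts strengthen monotonically across the time course
    for (d in cfg@domains[-1]) {
        b <- d@boostByState[cfg@states]
        expect_true(all(diff(b) >= 0))
        expect_lt(b[1], b[3])
    }
    # features present for downstream quantification
    expect_gte(nFeatures(featuresOfCategory(cfg@features, "ctcf")), 8)
    expect_gte(nFeatures(featuresOfCategory(cfg@features, "enhancer")), 3)
    expect_identical(
        nFeatures(featuresOfCategory(cfg@features, "promoter")), 2L)
})

test_that("knockout variant differs only at the boundary-anchored loops", {
    wt <- runx1LikeConfig(depth = 1000, seed = 3, knockout = TRUE)
    expect_identical(wt@states[4], "HPC_KO")
    # boundary bin shared by the nested sub-domains
    bnd <- wt@domains[[2]]@binRange[2] - 1L
    for (L in wt@loops) {
        lamHPC <- L@strengthByState[["HPC"]]
        lamKO <- L@strengthByState[["HPC_KO"]]
        if (L@anchorA == bnd || L@anchorB == bnd) {
            expect_equal(lamKO, 0)
            expect_gt(lamHPC, 0)
        } else {
            expect_equal(lamKO, lamHPC)
        }
    }
    # domain boosts identical between HPC and its KO variant
    for (d in wt@domains)
        expect_equal(d@boostByState[["HPC_KO"]], d@boostByState[["HPC"]])
})
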