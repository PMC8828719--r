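# Shared fixtures and independent oracles for the test suite.

# small grids ---------------------------------------------------------------

smallGrid <- function(n = 10L, binSize = 2000) {
    BinGrid(GenomicInterval("chrT", 0, n * binSize), binSize)
}

runxGrid <- function() {
    BinGrid(GenomicInterval("chr16", 91566000, 94102000), 2000)
}

# a dense symmetric random count matrix with per-bin coverage bias
randomCountMatrix <- function(n = 20L, meanCount = 50) {
    cov <- stats::runif(n, 0.3, 3)
    lam <- meanCount * outer(cov, cov) / (1 + abs(outer(1:n, 1:n, "-")))
    M <- matrix(0, n, n)
    ut <- upper.tri(M, diag = TRUE)
    M[ut] <- stats::rpois(sum(ut), lam[ut])
    M[lower.tri(M)] <- t(M)[lower.tri(M)]
    M
}

# independent brute-force iterative-correction oracle -----------------------
# Symmetric Sinkhorn variant: divide by sqrt of the relative marginals each
# round, explicit full-matrix updates. Same fixed point as ICE, different
# implementation path. Returns the balanced dense matrix rescaled to the
# input upper-triangle total.
oracleIceDense <- function(M, tol = 1e-10, maxIter = 5000) {
    total <- sum(M[upper.tri(M, diag = TRUE)])
    for (it in seq_len(maxIter)) {
        marg <- rowSums(M)
        target <- mean(marg)
        if (max(abs(marg / target - 1)) <= tol) break
        d <- sqrt(marg / target)
        M <- M / outer(d, d)
    }
    ut <- sum(M[upper.tri(M, diag = TRUE)])
    M * (total / ut)
}

# permutation oracle for the Kruskal-Wallis p-value --------------------------
kwPermutationP <- function(groups, nPerm = 10000) {
    pooled <- unlist(groups)
    sizes <- lengths(groups)
    obs <- kruskalWallis(groups)@H
    idx <- rep(seq_along(groups), sizes)
    count <- 0L
    for (b in seq_len(nPerm)) {
        perm <- sample(pooled)
        g <- split(perm, idx)
        if (kruskalWallis(g)@H >= obs - 1e-12) count <- count + 1L
    }
    count / nPerm
}

# tiny simulation config with one domain and one loop ------------------------
tinyConfig <- function(n = 60L, gamma = 2, lambda = 0, states = "s1",
                       domainRange = c(as.integer(n %/% 3),
                           as.integer(2 * n %/% 3)),
                       anchors = c(as.integer(n %/% 6),
                           as.integer(n - n %/% 6)),
                       depth = 1e4, seed = 1L) {
    grid <- smallGrid(n)
    boosts <- stats::setNames(rep(gamma, length(states)), states)
    lams <- stats::setNames(rep(lambda, length(states)), states)
    SimulationConfig(grid, decayExponent = 1,
        domains = list(DomainSpec("dom", domainRange, boosts)),
        loops = if (any(lams > 0))
            list(LoopSpec(anchors[1], anchors[2], lams)) else list(),
        states = states, replicatesPerState = 1L, depth = depth,
        seed = seed)
}

# expected-intensity matrix wrapped as a balanced-stage ContactMatrix so
# noise-free structure can be fed to profile/insulation operations
expectedAsMatrix <- function(config, state) {
    E <- expectedMatrix(config, state)
    fromDense(config@grid, E * 1e6, stage = "balanced")
}

# Shapiro-Wilk p-value for the fixed heavy-tailed sample
# set.seed(77); rcauchy(50), computed with scipy.stats.shapiro (1.17.1)
.shapiroReferenceP <- 1.8006153278963116e-08
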