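#' Domain specification for the contact-map generator
#'
#' A self-interacting block (TAD or sub-TAD) of the simulated matrix: all
#' pairs with both bins inside \code{binRange} are enriched by a
#' state-dependent multiplicative boost \eqn{\gamma \ge 1}.
#'
#' @slot name domain label.
#' @slot binRange half-open 0-based bin range \code{c(first, lastPlusOne)}.
#' @slot boostByState named numeric vector, state -> boost.
#' @export
setClass("DomainSpec",
    representation(name = "character", binRange = "integer",
        boostByState = "numeric"))

setValidity("DomainSpec", function(object) {
    if (length(object@binRange) != 2L ||
        object@binRange[2] <= object@binRange[1])
        return("binRange must be a half-open pair c(first, lastPlusOne)")
    if (any(object@boostByState <= 0)) return("all boosts must be > 0")
    if (is.null(names(object@boostByState)))
        return("boostByState must be named by state")
    TRUE
})

#' @rdname DomainSpec-class
#' @param name,binRange,boostByState see slots.
#' @export
DomainSpec <- function(name, binRange, boostByState) {
    new("DomainSpec", name = name, binRange = as.integer(binRange),
        boostByState = boostByState)
}

#' Loop specification for the contact-map generator
#'
#' A focal interaction (enhancer-promoter or CTCF-CTCF) between two
#' anchor bins: the expected intensity around \code{(anchorA, anchorB)}
#' is multiplied by \eqn{1 + \lambda \exp(-((i-a)^2 + (j-b)^2)/(2 w^2))}
#' with state-dependent strength \eqn{\lambda \ge 0} and Gaussian width
#' \eqn{w} in bins.
#'
#' @slot anchorA,anchorB 0-based anchor bins, \code{anchorA < anchorB}.
#' @slot strengthByState named numeric vector, state -> \eqn{\lambda}.
#' @slot width Gaussian SD in bins.
#' @export
setClass("LoopSpec",
    representation(anchorA = "integer", anchorB = "integer",
        strengthByState = "numeric", width = "numeric"))

setValidity("LoopSpec", function(object) {
    if (object@anchorA >= object@anchorB)
        return("anchorA must be < anchorB")
    if (any(object@strengthByState < 0))
        return("loop strengths must be >= 0")
    if (object@width <= 0) return("width must be > 0")
    TRUE
})

#' @rdname LoopSpec-class
#' @param anchorA,anchorB,strengthByState,width see slots.
#' @export
LoopSpec <- function(anchorA, anchorB, strengthByState, width = 1) {
    new("LoopSpec", anchorA = as.integer(anchorA),
        anchorB = as.integer(anchorB), strengthByState = strengthByState,
        width = as.numeric(width))
}

#' Full configuration of a simulated tiled-contact experiment
#'
#' The generative model: expected intensity decays with genomic distance
#' as a power law with exponent \eqn{\alpha}, multiplied by domain boosts
#' and loop enrichments, then normalised over the upper triangle; observed
#' counts are a multinomial draw of \code{depth} read pairs.
#'
#' @slot grid the \linkS4class{BinGrid}.
#' @slot decayExponent distance-decay exponent \eqn{\alpha > 0}.
#' @slot domains list of \linkS4class{DomainSpec}.
#' @slot loops list of \linkS4class{LoopSpec}.
#' @slot states ordered state labels.
#' @slot replicatesPerState replicates simulated per state.
#' @slot depth read pairs per replicate.
#' @slot seed master seed; per-replicate seeds are derived from it.
#' @slot features annotated \linkS4class{FeatureSet} (promoters,
#'   enhancers, CTCF sites) used by downstream quantification.
#' @export
setClass("SimulationConfig",
    representation(grid = "BinGrid", decayExponent = "numeric",
        domains = "list", loops = "list", states = "character",
        replicatesPerState = "integer", depth = "numeric",
        seed = "integer", features = "FeatureSet"))

setValidity("SimulationConfig", function(object) {
    if (length(object@states) < 1) return("at least one state required")
    if (object@depth <= 0) return("depth must be positive")
    if (object@replicatesPerState < 1) return("need >= 1 replicate")
    if (object@decayExponent <= 0) return("decay exponent must be > 0")
    nb <- nBins(object@grid)
    for (d in object@domains)
        if (d@binRange[1] < 0 || d@binRange[2] > nb)
            return(sprintf("domain '%s' outside grid", d@name))
    for (L in object@loops)
        if (L@anchorA < 0 || L@anchorB >= nb)
            return("loop anchor outside grid")
    TRUE
})

#' @rdname SimulationConfig-class
#' @param grid,decayExponent,domains,loops,states,replicatesPerState,depth,seed,features
#'   see slots.
#' @export
SimulationConfig <- function(grid, decayExponent = 1, domains = list(),
                             loops = list(), states = "state1",
                             replicatesPerState = 1L, depth = 5e5,
                             seed = 1L,
                             features = FeatureSet(character(0), numeric(0),
                                 numeric(0))) {
    new("SimulationConfig", grid = grid,
        decayExponent = as.numeric(decayExponent), domains = domains,
        loops = loops, states = as.character(states),
        replicatesPerState = as.integer(replicatesPerState),
        depth = as.numeric(depth), seed = as.integer(seed),
        features = features)
}

setMethod("show", "SimulationConfig", function(object) {
    cat(sprintf(paste0("SimulationConfig: %d bins, alpha=%.2g, ",
        "%d domains, %d loops, states [%s], %d reps x depth %s, seed %d\n"),
        nBins(object@grid), object@decayExponent, length(object@domains),
        length(object@loops), paste(object@states, collapse = ", "),
        object@replicatesPerState,
        format(object@depth, scientific = FALSE), object@seed))
})

#' Expected contact intensity matrix for one state
#'
#' Builds the noise-free expected intensity over the upper triangle
#' (diagonal included with distance term \eqn{(1+0)^{-\alpha} = 1}):
#' \deqn{E_{ij} = (1+|i-j|)^{-\alpha} \prod_{D: i,j \in D} \gamma_D
#'   \prod_L (1 + \lambda_L e^{-((i-a)^2+(j-b)^2)/(2w^2)})}
#' then normalised so the upper-triangle sum is 1.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param state one of \code{config@states} (or a KO-variant label known
#'   to the config's domains/loops).
#' @return Dense \code{nBins x nBins} matrix, zero below the diagonal,
#'   upper triangle summing to 1.
#' @export
expectedMatrix <- function(config, state) {
    if (!(state %in% config@states))
        stop(sprintf("unknown state '%s' (states: %s)", state,
            paste(config@states, collapse = ", ")))
    nb <- nBins(config@grid)
    d <- abs(outer(seq_len(nb), seq_len(nb), "-"))
    E <- (1 + d)^(-config@decayExponent)
    for (dom in config@domains) {
        g <- dom@boostByState[[state]]
        if (is.null(g) || is.na(g)) g <- 1
        if (g != 1) {
            rng <- (dom@binRange[1] + 1L):dom@binRange[2]
            E[rng, rng] <- E[rng, rng] * g
        }
    }
    for (L in config@loops) {
        lam <- L@strengthByState[[state]]
        if (is.null(lam) || is.na(lam) || lam == 0) next
        w <- L@width
        half <- ceiling(8 * w)
        ia <- max(1L, L@anchorA + 1L - half):min(nb, L@anchorA + 1L + half)
        jb <- max(1L, L@anchorB + 1L - half):min(nb, L@anchorB + 1L + half)
        bump <- outer(exp(-(ia - (L@anchorA + 1L))^2 / (2 * w^2)),
                      exp(-(jb - (L@anchorB + 1L))^2 / (2 * w^2)))
        E[ia, jb] <- E[ia, jb] * (1 + lam * bump)
        E[jb, ia] <- E[jb, ia] * (1 + lam * t(bump))
    }
    E[lower.tri(E)] <- 0
    E / sum(E)
}

#' Sample raw counts from an expected intensity matrix
#'
#' Multinomial draw of \code{depth} read pairs over the upper-triangle
#' cells with probabilities \code{E}; the sampled total equals
#' \code{depth} exactly and the draw is reproducible for a fixed seed.
#'
#' @param grid the \linkS4class{BinGrid} of \code{E}.
#' @param E normalised expected matrix from \code{\link{expectedMatrix}}.
#' @param depth number of read pairs.
#' @param seed integer seed.
#' @param sampleMeta metadata for the resulting matrix.
#' @return A raw-stage \linkS4class{ContactMatrix} with total
#'   interactions equal to \code{depth}.
#' @export
sampleCounts <- function(grid, E, depth, seed, sampleMeta = list()) {
    nb <- nBins(grid)
    ut <- which(upper.tri(E, diag = TRUE))
    p <- E[ut]
    old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    counts <- as.vector(stats::rmultinom(1, size = depth, prob = p))
    nz <- counts > 0
    idx <- ut[nz]
    i0 <- (idx - 1L) %% nb
    j0 <- (idx - 1L) %/% nb
    ContactMatrix(grid, i = i0, j = j0, x = counts[nz], stage = "raw",
        sampleMeta = sampleMeta)
}

.replicateSeed <- function(seed, stateIndex, rep) {
    as.integer((as.numeric(seed) + 99991 * stateIndex + 101 * rep) %%
        2147483647)
}

#' Simulate a full tiled-contact experiment to disk
#'
#' Writes one triplet matrix per (state, replicate) with a per-replicate
#' seed derived from the master seed, a grid sidecar, a feature BED and a
#' JSON truth manifest (config echo, per-replicate seeds, file paths and
#' the expected qualitative domain orderings). Re-running with the same
#' config reproduces byte-identical files.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param outdir writable output directory (created if absent).
#' @return The manifest, invisibly (also written as
#'   \code{manifest.json}).
#' @export
simulateExperiment <- function(config, outdir) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    writeGridSidecar(config@grid, file.path(outdir, "grid.json"))
    if (nFeatures(config@features) > 0)
        writeBedFeatures(config@features, file.path(outdir, "features.bed"))
    entries <- list()
    for (s in seq_along(config@states)) {
        state <- config@states[s]
        E <- expectedMatrix(config, state)
        for (r in seq_len(config@replicatesPerState)) {
            rs <- .replicateSeed(config@seed, s, r)
            fname <- sprintf("%s_rep%d.tsv", state, r)
            m <- sampleCounts(config@grid, E, config@depth, rs,
                sampleMeta = list(state = state, replicate = r))
            writeTriplets(m, file.path(outdir, fname))
            entries[[length(entries) + 1L]] <- list(
                state = state, replicate = r, seed = rs, file = fname)
        }
    }
    ordering <- lapply(config@domains, function(d) {
        boosts <- d@boostByState[config@states]
        list(domain = d@name,
             strengthens = paste(config@states[order(boosts)],
                 collapse = " < "))
    })
    manifest <- list(
        config = list(
            chrom = config@grid@region@chrom,
            start = config@grid@region@start,
            end = config@grid@region@end,
            bin_size = config@grid@binSize,
            decay_exponent = config@decayExponent,
            states = config@states,
            replicates_per_state = config@replicatesPerState,
            depth = config@depth, seed = config@seed),
        replicates = entries,
        expected_orderings = ordering)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
}

#' Preset configuration emulating the Runx1 tiled region
#'
#' A 2.5 Mb tile at 2 kb resolution (1268 bins, chr16-like coordinates)
#' with: a main TAD at bins [465, 1026) (561 bins, ~1.1 Mb); two nested
#' sub-TADs sharing an internal boundary bin near the P1 promoter whose
#' boosts strengthen monotonically over the developmental states
#' ESC -> mesoderm -> HPC; CTCF-anchored loops at the main-TAD corners;
#' and enhancer-promoter loops from the P2 promoter viewpoint that gain
#' strength over differentiation. With \code{knockout = TRUE} a fourth
#' state \code{"HPC_KO"} is added in which every loop anchored at the
#' promoter-proximal sub-TAD boundary bin is removed, emulating a CTCF
#' boundary deletion.
#'
#' @param depth read pairs per replicate (default 5e5).
#' @param seed master seed.
#' @param replicatesPerState replicates per state (default 4).
#' @param knockout add the boundary-knockout state variant.
#' @return A \linkS4class{SimulationConfig}.
#' @export
runx1LikeConfig <- function(depth = 5e5, seed = 1L,
                            replicatesPerState = 4L, knockout = FALSE) {
    grid <- BinGrid(GenomicInterval("chr16", 91566000, 94102000), 2000)
    states <- c("ESC", "mesoderm", "HPC")
    if (knockout) states <- c(states, "HPC_KO")

    p2bin <- coordToBin(grid, 92695073)   # P2 promoter
    p1bin <- coordToBin(grid, 92823811)   # P1 promoter
    boundaryBin <- p1bin + 1L             # shared internal sub-TAD boundary

    mainBoost <- c(ESC = 2, mesoderm = 2, HPC = 2, HPC_KO = 2)
    subBoost <- c(ESC = 1.0, mesoderm = 1.5, HPC = 3.0, HPC_KO = 3.0)
    domains <- list(
        DomainSpec("main_TAD", c(465L, 1026L), mainBoost[states]),
        DomainSpec("P1_P2_subTAD", c(p2bin, boundaryBin + 1L),
            subBoost[states]),
        DomainSpec("P2_3prime_subTAD", c(boundaryBin, 720L),
            subBoost[states]))

    # enhancer bins: +23 at its published position, others spaced through
    # the gene body and gene desert within the main TAD
    enhStarts <- c(92717000, 92761000, 92585000, 92545000, 93035000)
    enhNames <- c("+23", "+110", "-59", "-181", "desertCTCFprox")
    enhBins <- coordToBin(grid, enhStarts)

    epStrength <- function(lam) c(ESC = lam * 0.2, mesoderm = lam * 0.6,
        HPC = lam, HPC_KO = lam)[states]
    loops <- list()
    for (k in seq_along(enhBins)) {
        a <- min(p2bin, enhBins[k]); b <- max(p2bin, enhBins[k])
        loops[[length(loops) + 1L]] <-
            LoopSpec(a, b, epStrength(4), width = 1)
    }
    # convergent CTCF loops at the main-TAD corners
    corner <- c(ESC = 2, mesoderm = 3, HPC = 3, HPC_KO = 3)[states]
    loops[[length(loops) + 1L]] <- LoopSpec(465L, 1025L, corner, width = 1)
    # loops anchored at the promoter-proximal sub-TAD boundary: present in
    # all wild-type states, removed in the KO variant
    bnd <- c(ESC = 1, mesoderm = 2, HPC = 3, HPC_KO = 0)[states]
    loops[[length(loops) + 1L]] <-
        LoopSpec(465L, boundaryBin, bnd, width = 1)
    loops[[length(loops) + 1L]] <-
        LoopSpec(boundaryBin, 1025L, bnd, width = 1)

    ctcfStarts <- c(92496000, 92520000, 92540000, 92560000,   # centromeric
        93540000, 93570000, 93590000, 93616000)                # telomeric
    ctcfOrient <- c(rep("forward", 4), rep("reverse", 4))
    fs <- FeatureSet(
        chrom = "chr16",
        start = c(enhStarts, ctcfStarts, 92695073, 92823811),
        end = c(enhStarts + 2000, ctcfStarts + 1000,
            92695073 + 1000, 92823811 + 1000),
        name = c(enhNames, paste0("CTCF_", seq_along(ctcfStarts)),
            "P2", "P1"),
        category = c(rep("enhancer", length(enhStarts)),
            rep("ctcf", length(ctcfStarts)), "promoter", "promoter"),
        orientation = c(rep("none", length(enhStarts)), ctcfOrient,
            "none", "none"),
        provenance = "runx1-like preset")

    SimulationConfig(grid, decayExponent = 1, domains = domains,
        loops = loops, states = states,
        replicatesPerState = as.integer(replicatesPerState),
        depth = depth, seed = as.integer(seed), features = fs)
}
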