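#' Named domain (TAD / sub-TAD) bin ranges on a grid
#'
#' Domains are analysis inputs (in this assay they are typically defined
#' by visual inspection of the contact map), stored as named half-open
#' 0-based bin ranges.
#'
#' @slot names domain names (unique).
#' @slot first,lastPlusOne parallel vectors of half-open bin ranges.
#' @slot nBinsGrid number of bins of the grid the ranges refer to.
#' @export
setClass("DomainSet",
    representation(names = "character", first = "integer",
        lastPlusOne = "integer", nBinsGrid = "integer"))

setValidity("DomainSet", function(object) {
    if (anyDuplicated(object@names)) return("domain names must be unique")
    if (any(object@lastPlusOne <= object@first))
        return("each domain range must be non-empty")
    if (any(object@first < 0L) || any(object@lastPlusOne > object@nBinsGrid))
        return("domain range outside grid")
    TRUE
})

#' Construct a DomainSet
#'
#' @param grid the \linkS4class{BinGrid}.
#' @param ranges named list of half-open bin-range pairs
#'   \code{c(first, lastPlusOne)}.
#' @return A \linkS4class{DomainSet}.
#' @examples
#' grid <- BinGrid(GenomicInterval("chr16", 91566000, 94102000), 2000)
#' DomainSet(grid, list(main_TAD = c(465, 1026)))
#' @export
DomainSet <- function(grid, ranges) {
    new("DomainSet", names = names(ranges),
        first = vapply(ranges, function(r) as.integer(r[1]), integer(1)),
        lastPlusOne = vapply(ranges, function(r) as.integer(r[2]),
            integer(1)),
        nBinsGrid = nBins(grid))
}

#' Bins of a named domain
#' @param ds a \linkS4class{DomainSet}.
#' @param name domain name.
#' @return Integer vector of 0-based bin indices.
#' @export
domainBins <- function(ds, name) {
    k <- match(name, ds@names)
    if (is.na(k)) stop(sprintf("unknown domain '%s'", name))
    ds@first[k]:(ds@lastPlusOne[k] - 1L)
}

setMethod("show", "DomainSet", function(object) {
    cat(sprintf("DomainSet with %d domains:\n", length(object@names)))
    for (k in seq_along(object@names))
        cat(sprintf("  %s: bins [%d, %d) (%d bins)\n", object@names[k],
            object@first[k], object@lastPlusOne[k],
            object@lastPlusOne[k] - object@first[k]))
})

#' Intra-TAD interaction ratio (insulation score)
#'
#' For each unmasked bin \code{b} inside the domain:
#' \code{intra(b)} = sum of contacts between \code{b} and every other
#' domain bin (the self-bin diagonal is excluded), \code{extra(b)} = sum
#' of contacts between \code{b} and all bins outside the domain; the
#' score is \code{intra/extra}. Bins that are masked or have zero
#' extra-domain contact are dropped and counted.
#'
#' @param m a balanced or scaled \linkS4class{ContactMatrix}.
#' @param domainBins 0-based bin indices of the domain.
#' @param allowRaw also accept raw/merged matrices (count mode).
#' @return List with \code{ratios} (named by bin), \code{bins} (the bins
#'   retained) and \code{dropped} (number of domain bins dropped).
#' @export
intraTadRatio <- function(m, domainBins, allowRaw = FALSE) {
    okStages <- c("balanced", "scaled", if (allowRaw) c("raw", "merged"))
    if (!(m@stage %in% okStages))
        stop(sprintf("insulation expects a balanced or scaled matrix, got '%s'",
            m@stage))
    if (length(domainBins) == 0) stop("empty domain")
    M <- denseMatrix(m)
    dom <- as.integer(domainBins) + 1L
    out <- setdiff(seq_len(nBins(m@grid)), dom)
    subM <- M[dom, dom, drop = FALSE]
    intra <- rowSums(subM) - diag(subM)
    extra <- rowSums(M[dom, out, drop = FALSE])
    keep <- !(dom %in% (m@maskedBins + 1L)) & extra > 0
    ratios <- intra[keep] / extra[keep]
    bins <- dom[keep] - 1L
    names(ratios) <- bins
    list(ratios = ratios, bins = bins, dropped = sum(!keep))
}

#' Bin sets of the outermost CTCF sites at both domain ends
#'
#' Selects the \code{k} CTCF features with smallest start coordinate
#' inside the domain (centromeric end) and the \code{k} with largest
#' start (telomeric end), and returns the de-duplicated sets of bins they
#' overlap. A feature spanning two bins contributes both.
#'
#' @param features a \linkS4class{FeatureSet} (only its CTCF features are
#'   used).
#' @param domainRange half-open bin range \code{c(first, lastPlusOne)} of
#'   the domain.
#' @param grid the \linkS4class{BinGrid}.
#' @param k number of outermost sites per end (default 4).
#' @return List with bin vectors \code{A} (centromeric) and \code{B}
#'   (telomeric).
#' @export
boundaryBinSets <- function(features, domainRange, grid, k = 4L) {
    ctcf <- featuresOfCategory(features, "ctcf")
    n <- nFeatures(ctcf)
    inDom <- logical(n)
    for (f in seq_len(n)) {
        rng <- tryCatch(binsForInterval(grid, featureInterval(ctcf, f)),
            error = function(e) NULL)
        inDom[f] <- !is.null(rng) && rng[1] >= domainRange[1] &&
            rng[2] <= domainRange[2]
    }
    idx <- which(inDom)
    if (length(idx) < k)
        stop(sprintf("need >= %d CTCF sites inside the domain, found %d",
            k, length(idx)))
    ord <- idx[order(ctcf@start[idx])]
    if (length(ord) < 2 * k)
        warning("fewer than 2k CTCF sites in domain; ends overlap")
    takeBins <- function(which) {
        bins <- integer(0)
        for (f in which) {
            rng <- binsForInterval(grid, featureInterval(ctcf, f))
            bins <- c(bins, rng[1]:(rng[2] - 1L))
        }
        sort(unique(bins))
    }
    list(A = takeBins(ord[seq_len(k)]),
         B = takeBins(ord[seq(length(ord) - k + 1L, length(ord))]))
}

#' Contacts between two boundary bin sets
#'
#' Returns the matrix value (0 if absent) for every pair in \code{A x B}
#' as a flat vector — the per-sample distribution used for boundary
#' CTCF-CTCF contact testing.
#'
#' @param m a \linkS4class{ContactMatrix}.
#' @param A,B disjoint non-empty 0-based bin sets.
#' @return Numeric vector of length \code{length(A) * length(B)}.
#' @export
boundaryContacts <- function(m, A, B) {
    if (length(A) == 0 || length(B) == 0) stop("empty bin set")
    if (length(intersect(A, B)) > 0)
        stop("boundary bin sets must be disjoint")
    pairs <- expand.grid(a = A, b = B)
    contactValue(m, pairs$a, pairs$b)
}

#' Enhancer-promoter contact quantification
#'
#' From the viewpoint of the promoter-containing bin, sums the contact
#' values to the bins overlapping each enhancer. The per-enhancer value
#' is the sum over that enhancer's bins; the total is the sum over the
#' de-duplicated union of all enhancer bins (bins shared by several
#' enhancers counted once). The promoter's own bin is excluded even if an
#' enhancer overlaps it.
#'
#' @param m a \linkS4class{ContactMatrix}.
#' @param promoterBin 0-based promoter bin.
#' @param enhancers a \linkS4class{FeatureSet} (only enhancer-category
#'   features are used).
#' @param grid the \linkS4class{BinGrid}.
#' @return List with \code{promoterBin}, \code{perEnhancer} (named
#'   numeric) and \code{total}.
#' @export
epContacts <- function(m, promoterBin, enhancers, grid) {
    promoterBin <- as.integer(promoterBin)
    if (promoterBin %in% m@maskedBins)
        stop(sprintf("promoter bin %d is masked", promoterBin))
    enh <- featuresOfCategory(enhancers, "enhancer")
    if (nFeatures(enh) == 0) stop("no enhancer features supplied")
    perEnh <- numeric(nFeatures(enh))
    allBins <- integer(0)
    for (f in seq_len(nFeatures(enh))) {
        rng <- binsForInterval(grid, featureInterval(enh, f))
        bins <- setdiff(rng[1]:(rng[2] - 1L), promoterBin)
        perEnh[f] <- sum(contactValue(m, rep(promoterBin, length(bins)),
            bins))
        allBins <- c(allBins, bins)
    }
    names(perEnh) <- featureName(enh)
    u <- unique(allBins)
    total <- sum(contactValue(m, rep(promoterBin, length(u)), u))
    list(promoterBin = promoterBin, perEnhancer = perEnh, total = total)
}
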