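#' Virtual Capture-C viewpoint profile
#'
#' One-dimensional contact profile obtained by extracting a single
#' viewpoint row/column from a contact matrix. Values are per bin;
#' excluded bins (the viewpoint itself, its exclusion window and any
#' balancing-masked bins) are \code{NA}.
#'
#' @slot viewpointBin 0-based viewpoint bin.
#' @slot values numeric vector of length \code{nBins}; \code{NA} where
#'   missing.
#' @slot normalization \code{"raw"} or \code{"per-million-cis"}.
#' @slot sourceStage processing stage of the matrix the profile was
#'   extracted from.
#' @slot sampleMeta as in \linkS4class{ContactMatrix}.
#' @export
setClass("ViewpointProfile",
    representation(viewpointBin = "integer", values = "numeric",
        normalization = "character", sourceStage = "character",
        sampleMeta = "list"))

setValidity("ViewpointProfile", function(object) {
    if (!(object@normalization %in% c("raw", "per-million-cis")))
        return("normalization must be 'raw' or 'per-million-cis'")
    if (!is.na(object@values[object@viewpointBin + 1L]))
        return("viewpoint bin must be flagged missing")
    v <- object@values
    if (any(v[!is.na(v)] < 0)) return("profile values must be >= 0")
    TRUE
})

setMethod("show", "ViewpointProfile", function(object) {
    cat(sprintf(
        "ViewpointProfile: viewpoint bin %d, %d/%d bins, %s (%s matrix)\n",
        object@viewpointBin, sum(!is.na(object@values)),
        length(object@values), object@normalization, object@sourceStage))
})

#' Mean/SD aggregate of replicate viewpoint profiles
#'
#' @slot mean,sd per-bin mean and sample standard deviation.
#' @slot nReplicates number of replicates aggregated.
#' @slot cellState state label.
#' @slot viewpointBin 0-based viewpoint bin.
#' @slot normalization normalization tag of the inputs.
#' @export
setClass("ProfileAggregate",
    representation(mean = "numeric", sd = "numeric",
        nReplicates = "integer", cellState = "character",
        viewpointBin = "integer", normalization = "character"))

#' Extract a virtual Capture-C profile from a contact matrix
#'
#' The profile value at bin \code{k} is the matrix entry for the pair
#' (viewpoint, k). The viewpoint bin itself (dominated by self-ligation)
#' and bins within \code{exclusionRadius} of it are flagged missing, as
#' are balancing-masked bins.
#'
#' @param m a \linkS4class{ContactMatrix} (raw, balanced or scaled).
#' @param viewpointBin 0-based viewpoint bin.
#' @param exclusionRadius extra bins around the viewpoint to exclude
#'   (default 0: only the viewpoint bin).
#' @return A raw-normalization \linkS4class{ViewpointProfile}.
#' @export
virtualCapture <- function(m, viewpointBin, exclusionRadius = 0L) {
    nb <- nBins(m@grid)
    viewpointBin <- as.integer(viewpointBin)
    if (viewpointBin < 0L || viewpointBin >= nb)
        stop("viewpoint bin outside grid")
    if (viewpointBin %in% m@maskedBins)
        stop(sprintf("viewpoint bin %d is masked (low coverage)",
            viewpointBin))
    if (m@stage == "subtraction")
        stop("profiles are extracted from raw, balanced or scaled matrices")
    vals <- contactValue(m, rep(viewpointBin, nb), 0:(nb - 1L))
    excl <- abs(0:(nb - 1L) - viewpointBin) <= exclusionRadius
    vals[excl] <- NA_real_
    if (length(m@maskedBins)) vals[m@maskedBins + 1L] <- NA_real_
    new("ViewpointProfile", viewpointBin = viewpointBin, values = vals,
        normalization = "raw", sourceStage = m@stage,
        sampleMeta = m@sampleMeta)
}

#' Normalise a profile to per-million cis contacts
#'
#' Multiplies each value by \eqn{10^6 / } total interactions of the
#' matrix the profile came from, making tracks comparable across samples
#' of different depth.
#'
#' @param p a raw \linkS4class{ViewpointProfile}.
#' @param m the \linkS4class{ContactMatrix} \code{p} was extracted from.
#' @return A per-million-cis \linkS4class{ViewpointProfile}.
#' @export
normalizeProfile <- function(p, m) {
    if (p@normalization != "raw")
        stop("profile is already normalized")
    total <- totalInteractions(m)
    if (total == 0) stop("cannot normalize against a zero-total matrix")
    new("ViewpointProfile", viewpointBin = p@viewpointBin,
        values = p@values * (1e6 / total),
        normalization = "per-million-cis", sourceStage = p@sourceStage,
        sampleMeta = p@sampleMeta)
}

#' Aggregate replicate profiles into a mean/SD track
#'
#' @param profiles list of \linkS4class{ViewpointProfile} objects with
#'   identical viewpoint, normalization and length.
#' @param cellState state label recorded on the aggregate.
#' @return A \linkS4class{ProfileAggregate}: per-bin mean and sample SD
#'   (denominator \code{n - 1}; 0 when \code{n = 1}); bins missing in any
#'   replicate are missing in the aggregate.
#' @export
aggregateReplicates <- function(profiles, cellState = "") {
    stopifnot(length(profiles) >= 1)
    vp <- profiles[[1]]@viewpointBin
    norm <- profiles[[1]]@normalization
    len <- length(profiles[[1]]@values)
    for (p in profiles) {
        if (p@viewpointBin != vp) stop("viewpoint mismatch")
        if (p@normalization != norm) stop("normalization mismatch")
        if (length(p@values) != len) stop("grid mismatch")
    }
    V <- do.call(rbind, lapply(profiles, slot, "values"))
    anyNA <- apply(V, 2, function(col) any(is.na(col)))
    mu <- colMeans(V)
    s <- if (nrow(V) == 1) rep(0, len) else apply(V, 2, stats::sd)
    mu[anyNA] <- NA_real_
    s[anyNA] <- NA_real_
    new("ProfileAggregate", mean = mu, sd = s,
        nReplicates = length(profiles), cellState = cellState,
        viewpointBin = vp, normalization = norm)
}

#' Difference track between two aggregated profiles
#'
#' @param aggA,aggB \linkS4class{ProfileAggregate} objects with the same
#'   viewpoint, grid length and normalization.
#' @return Numeric vector \code{meanA - meanB}; \code{NA} where either is
#'   missing.
#' @export
subtractProfiles <- function(aggA, aggB) {
    if (aggA@viewpointBin != aggB@viewpointBin)
        stop("viewpoint mismatch")
    if (length(aggA@mean) != length(aggB@mean)) stop("grid mismatch")
    if (aggA@normalization != aggB@normalization)
        stop("normalization mismatch")
    aggA@mean - aggB@mean
}

#' Write a per-bin track as bedGraph
#'
#' One line per non-missing bin: chrom, bin start, bin end (0-based
#' half-open), value — ordered by bin.
#'
#' @param track numeric vector of length \code{nBins(grid)} (\code{NA} =
#'   missing).
#' @param grid the \linkS4class{BinGrid}.
#' @param path output path.
#' @export
writeBedGraph <- function(track, grid, path) {
    if (length(track) != nBins(grid))
        stop("track length must equal the number of bins")
    keep <- !is.na(track)
    lines <- sprintf("%s\t%s\t%s\t%s", grid@region@chrom,
        format(binStarts(grid)[keep], scientific = FALSE, trim = TRUE),
        format(binEnds(grid)[keep], scientific = FALSE, trim = TRUE),
        sprintf("%.15g", track[keep]))
    writeLines(lines, path)
    invisible(path)
}
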