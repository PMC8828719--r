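#' @import methods
NULL

#' Genomic interval on a single chromosome
#'
#' A half-open interval \code{[start, end)} in 0-based coordinates, the
#' convention used throughout the package (BED-compatible). Intervals
#' published with inclusive ends must be converted by adding 1 to the end
#' on ingest.
#'
#' @slot chrom chromosome name.
#' @slot start 0-based inclusive start.
#' @slot end exclusive end.
#' @export
setClass("GenomicInterval",
    representation(chrom = "character", start = "numeric", end = "numeric"))

setValidity("GenomicInterval", function(object) {
    if (length(object@chrom) != 1L || !nzchar(object@chrom))
        return("'chrom' must be a single non-empty string")
    if (object@start < 0) return("'start' must be >= 0")
    if (object@end <= object@start) return("'end' must be > 'start'")
    TRUE
})

#' Construct a GenomicInterval
#'
#' @param chrom chromosome name.
#' @param start 0-based inclusive start position.
#' @param end exclusive end position (\code{end > start}).
#' @return A \linkS4class{GenomicInterval}.
#' @examples
#' GenomicInterval("chr16", 92496000, 93618000)
#' @export
GenomicInterval <- function(chrom, start, end) {
    new("GenomicInterval", chrom = as.character(chrom),
        start = as.numeric(start), end = as.numeric(end))
}

#' @rdname GenomicInterval
#' @param x a \code{GenomicInterval}.
#' @export
intervalWidth <- function(x) x@end - x@start

setMethod("show", "GenomicInterval", function(object) {
    cat(sprintf("GenomicInterval %s:%s-%s (%s bp, 0-based half-open)\n",
        object@chrom, format(object@start, scientific = FALSE),
        format(object@end, scientific = FALSE),
        format(intervalWidth(object), scientific = FALSE)))
})

#' Fixed-width bin grid over a tiled region
#'
#' Partition of a single genomic region into consecutive fixed-width bins.
#' The grid is the coordinate authority for every matrix, profile and
#' domain in the package. The last bin may be short when the region length
#' is not a multiple of the bin size; it is still a full member of the grid.
#'
#' @slot region the tiled \linkS4class{GenomicInterval}.
#' @slot binSize bin width in base pairs.
#' @export
setClass("BinGrid",
    representation(region = "GenomicInterval", binSize = "numeric"))

setValidity("BinGrid", function(object) {
    if (length(object@binSize) != 1L || object@binSize <= 0)
        return("'binSize' must be a single positive number")
    TRUE
})

#' Construct a BinGrid
#'
#' @param region a \linkS4class{GenomicInterval} covering the tiled region.
#' @param binSize bin width in base pairs.
#' @return A \linkS4class{BinGrid}.
#' @examples
#' grid <- BinGrid(GenomicInterval("chr16", 91566000, 94102000), 2000)
#' nBins(grid)
#' @export
BinGrid <- function(region, binSize) {
    new("BinGrid", region = region, binSize = as.numeric(binSize))
}

#' Number of bins of a grid
#' @param grid a \linkS4class{BinGrid}.
#' @export
nBins <- function(grid) {
    as.integer(ceiling(intervalWidth(grid@region) / grid@binSize))
}

#' @rdname nBins
#' @export
binSize <- function(grid) grid@binSize

#' @rdname nBins
#' @export
gridRegion <- function(grid) grid@region

setMethod("show", "BinGrid", function(object) {
    cat(sprintf("BinGrid: %s:%s-%s, %d bins of %s bp\n",
        object@region@chrom,
        format(object@region@start, scientific = FALSE),
        format(object@region@end, scientific = FALSE),
        nBins(object), format(object@binSize, scientific = FALSE)))
})

#' Map a base position to its bin index
#'
#' @param grid a \linkS4class{BinGrid}.
#' @param pos base position(s), 0-based; must satisfy
#'   \code{region start <= pos < region end}.
#' @return Integer 0-based bin index (vectorised over \code{pos}).
#' @examples
#' grid <- BinGrid(GenomicInterval("chr16", 91566000, 94102000), 2000)
#' coordToBin(grid, 91566000)  # 0
#' coordToBin(grid, 93617999)  # 1025
#' @export
coordToBin <- function(grid, pos) {
    r <- grid@region
    if (any(pos < r@start | pos >= r@end))
        stop(sprintf("position outside tile %s:%s-%s", r@chrom,
            format(r@start, scientific = FALSE),
            format(r@end, scientific = FALSE)))
    as.integer(floor((pos - r@start) / grid@binSize))
}

#' Start coordinates of every bin
#' @param grid a \linkS4class{BinGrid}.
#' @return Numeric vector of 0-based bin starts, length \code{nBins(grid)}.
#' @export
binStarts <- function(grid) {
    grid@region@start + grid@binSize * (seq_len(nBins(grid)) - 1)
}

#' End coordinates (exclusive) of every bin
#' @param grid a \linkS4class{BinGrid}.
#' @export
binEnds <- function(grid) {
    pmin(binStarts(grid) + grid@binSize, grid@region@end)
}

#' Bins overlapping an interval
#'
#' Returns the half-open bin range \code{[first, last + 1)} covering every
#' bin that overlaps the query interval.
#'
#' @param grid a \linkS4class{BinGrid}.
#' @param iv a \linkS4class{GenomicInterval}; must overlap the grid region
#'   on the same chromosome.
#' @return Integer vector \code{c(first, lastPlusOne)} of 0-based bin
#'   indices.
#' @examples
#' grid <- BinGrid(GenomicInterval("chr16", 91566000, 94102000), 2000)
#' binsForInterval(grid, GenomicInterval("chr16", 92496000, 93618000))
#' # [465, 1026) -> 561 bins
#' @export
binsForInterval <- function(grid, iv) {
    r <- grid@region
    if (iv@chrom != r@chrom || iv@end <= r@start || iv@start >= r@end)
        stop(sprintf("interval %s:%s-%s does not overlap tile %s:%s-%s",
            iv@chrom, format(iv@start, scientific = FALSE),
            format(iv@end, scientific = FALSE), r@chrom,
            format(r@start, scientific = FALSE),
            format(r@end, scientific = FALSE)))
    first <- coordToBin(grid, max(iv@start, r@start))
    last <- coordToBin(grid, min(iv@end, r@end) - 1)
    c(first, last + 1L)
}

#' Write / read the grid sidecar
#'
#' A small JSON file describing the grid (chrom, start, end, bin size),
#' written next to every matrix file so that matrices are self-describing.
#'
#' @param grid a \linkS4class{BinGrid}.
#' @param path file path of the JSON sidecar.
#' @return \code{readGridSidecar} returns the \linkS4class{BinGrid}.
#' @export
writeGridSidecar <- function(grid, path) {
    r <- grid@region
    jsonlite::write_json(
        list(chrom = r@chrom, start = r@start, end = r@end,
             bin_size = grid@binSize),
        path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeGridSidecar
#' @export
readGridSidecar <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    BinGrid(GenomicInterval(x$chrom, x$start, x$end), x$bin_size)
}
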