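#' Sparse symmetric contact matrix on a bin grid
#'
#' Contact values are stored once per unordered bin pair in canonical
#' upper-triangle form (\code{i <= j}); querying \code{(j, i)} returns the
#' \code{(i, j)} value. The processing stage is tracked so that operations
#' can enforce their preconditions (e.g. ICE balancing acts on raw or
#' merged counts, subtraction on scaled matrices).
#'
#' @slot grid the \linkS4class{BinGrid} indexing the matrix.
#' @slot i,j 0-based bin indices with \code{i <= j}, sorted by
#'   \code{(i, j)}.
#' @slot x contact values (non-negative except at the subtraction stage).
#' @slot stage one of \code{"raw"}, \code{"merged"}, \code{"balanced"},
#'   \code{"scaled"}, \code{"subtraction"}.
#' @slot sampleMeta list with elements such as \code{state},
#'   \code{replicate}, \code{genotype}.
#' @slot maskedBins 0-based indices of bins masked during balancing
#'   (empty before balancing).
#' @export
setClass("ContactMatrix",
    representation(grid = "BinGrid", i = "integer", j = "integer",
        x = "numeric", stage = "character", sampleMeta = "list",
        maskedBins = "integer"))

.STAGES <- c("raw", "merged", "balanced", "scaled", "subtraction")

setValidity("ContactMatrix", function(object) {
    n <- length(object@i)
    if (length(object@j) != n || length(object@x) != n)
        return("i, j, x must have equal length")
    if (!(object@stage %in% .STAGES))
        return(paste("stage must be one of", paste(.STAGES, collapse = ", ")))
    if (n > 0) {
        nb <- nBins(object@grid)
        if (any(object@i < 0L) || any(object@j >= nb))
            return("bin indices out of grid range")
        if (any(object@i > object@j))
            return("entries must be canonical (i <= j)")
        if (!all(is.finite(object@x)))
            return("values must be finite")
        if (object@stage != "subtraction" && any(object@x < 0))
            return("negative values only allowed at subtraction stage")
    }
    TRUE
})

#' Construct a ContactMatrix from triplet vectors
#'
#' Entries are folded to canonical upper-triangle pairs (duplicates
#' summed) and sorted by \code{(i, j)}.
#'
#' @param grid a \linkS4class{BinGrid}.
#' @param i,j 0-based bin indices (either order).
#' @param x contact values.
#' @param stage processing stage tag.
#' @param sampleMeta named list of sample metadata.
#' @param maskedBins 0-based indices of masked bins.
#' @return A \linkS4class{ContactMatrix}.
#' @export
ContactMatrix <- function(grid, i = integer(0), j = integer(0),
                          x = numeric(0), stage = "raw",
                          sampleMeta = list(), maskedBins = integer(0)) {
    ii <- pmin(as.integer(i), as.integer(j))
    jj <- pmax(as.integer(i), as.integer(j))
    if (length(ii) > 0) {
        key <- ii * as.numeric(nBins(grid)) + jj
        agg <- rowsum(as.numeric(x), group = key, reorder = TRUE)
        ukey <- as.numeric(rownames(agg))
        ii <- as.integer(ukey %/% nBins(grid))
        jj <- as.integer(ukey %% nBins(grid))
        x <- as.numeric(agg[, 1])
        keep <- x != 0
        ii <- ii[keep]; jj <- jj[keep]; x <- x[keep]
    }
    new("ContactMatrix", grid = grid, i = ii, j = jj, x = as.numeric(x),
        stage = stage, sampleMeta = sampleMeta,
        maskedBins = as.integer(maskedBins))
}

#' @rdname ContactMatrix
#' @param m a \code{ContactMatrix}.
#' @export
matrixStage <- function(m) m@stage

#' @rdname ContactMatrix
#' @export
matrixGrid <- function(m) m@grid

#' @rdname ContactMatrix
#' @export
sampleMeta <- function(m) m@sampleMeta

#' @rdname ContactMatrix
#' @export
maskedBins <- function(m) m@maskedBins

#' @rdname ContactMatrix
#' @export
nEntries <- function(m) length(m@x)

setMethod("show", "ContactMatrix", function(object) {
    meta <- object@sampleMeta
    tag <- if (length(meta)) paste0(" [",
        paste(names(meta), unlist(lapply(meta, paste, collapse = "+")),
            sep = "=", collapse = ", "), "]") else ""
    cat(sprintf(
        "ContactMatrix (%s stage)%s: %d stored pairs on %d bins, %d masked\n",
        object@stage, tag, nEntries(object), nBins(object@grid),
        length(object@maskedBins)))
})

#' Query contact values by bin pair
#'
#' Symmetric access: \code{contactValue(m, i, j) == contactValue(m, j, i)}.
#' Absent pairs return 0.
#'
#' @param m a \linkS4class{ContactMatrix}.
#' @param i,j 0-based bin indices (vectorised).
#' @return Numeric vector of contact values.
#' @export
contactValue <- function(m, i, j) {
    ii <- pmin(i, j); jj <- pmax(i, j)
    key <- ii * as.numeric(nBins(m@grid)) + jj
    skey <- m@i * as.numeric(nBins(m@grid)) + m@j
    idx <- match(key, skey)
    out <- m@x[idx]
    out[is.na(out)] <- 0
    out
}

#' Dense symmetric matrix view
#'
#' @param m a \linkS4class{ContactMatrix}.
#' @return An \code{nBins x nBins} dense symmetric matrix with the diagonal
#'   stored once.
#' @export
denseMatrix <- function(m) {
    nb <- nBins(m@grid)
    M <- matrix(0, nb, nb)
    M[cbind(m@i + 1L, m@j + 1L)] <- m@x
    M[cbind(m@j + 1L, m@i + 1L)] <- m@x
    M
}

#' Build a ContactMatrix from a dense symmetric matrix
#' @param grid a \linkS4class{BinGrid}.
#' @param M dense symmetric matrix.
#' @param stage,sampleMeta,maskedBins as in \code{\link{ContactMatrix}}.
#' @export
fromDense <- function(grid, M, stage = "raw", sampleMeta = list(),
                      maskedBins = integer(0)) {
    idx <- which(upper.tri(M, diag = TRUE) & M != 0, arr.ind = TRUE)
    ContactMatrix(grid, i = idx[, 1] - 1L, j = idx[, 2] - 1L,
        x = M[idx], stage = stage, sampleMeta = sampleMeta,
        maskedBins = maskedBins)
}

#' Read a sparse triplet contact matrix
#'
#' The interchange format is a tab-separated file with lines
#' \code{i<TAB>j<TAB>value}, 0-based bin indices on the given grid.
#' \code{(i, j)} and \code{(j, i)} lines fold onto the canonical pair;
#' duplicate pairs are summed.
#'
#' @param path triplet file path.
#' @param grid the \linkS4class{BinGrid} the indices refer to.
#' @param stage stage tag for the result (default \code{"raw"}).
#' @param sampleMeta sample metadata list.
#' @return A \linkS4class{ContactMatrix}.
#' @export
readTriplets <- function(path, grid, stage = "raw", sampleMeta = list()) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    n <- length(lines)
    i <- integer(n); j <- integer(n); x <- numeric(n)
    nb <- nBins(grid)
    for (k in seq_len(n)) {
        f <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
        if (length(f) < 3)
            stop(sprintf("%s: unparsable triplet line %d", path, k))
        ik <- suppressWarnings(as.integer(f[1]))
        jk <- suppressWarnings(as.integer(f[2]))
        xk <- suppressWarnings(as.numeric(f[3]))
        if (is.na(ik) || is.na(jk) || is.na(xk))
            stop(sprintf("%s: unparsable triplet line %d", path, k))
        if (ik < 0L || jk < 0L || ik >= nb || jk >= nb)
            stop(sprintf("%s: line %d: bin index outside grid (0..%d)",
                path, k, nb - 1L))
        if (stage == "raw" && (xk < 0 || abs(xk - round(xk)) > 1e-9))
            stop(sprintf(
                "%s: line %d: raw-stage values must be non-negative integers",
                path, k))
        i[k] <- ik; j[k] <- jk; x[k] <- xk
    }
    ContactMatrix(grid, i, j, x, stage = stage, sampleMeta = sampleMeta)
}

#' Write a contact matrix as sorted canonical triplets
#'
#' @param m a \linkS4class{ContactMatrix}.
#' @param path output file path.
#' @export
writeTriplets <- function(m, path) {
    writeLines(sprintf("%d\t%d\t%.15g", m@i, m@j, m@x), path)
    invisible(path)
}

#' Total interactions of a matrix
#'
#' Sum over canonical entries: each unordered pair counted once, the
#' diagonal included once. Undefined for subtraction matrices.
#'
#' @param m a \linkS4class{ContactMatrix}.
#' @return A single number.
#' @export
totalInteractions <- function(m) {
    if (m@stage == "subtraction")
        stop("total interactions undefined for a subtraction matrix")
    sum(m@x)
}

#' Merge biological replicates
#'
#' Element-wise sum of raw count matrices over the union of their
#' supports. All matrices must share the grid and be at the raw stage.
#'
#' @param matrices list of raw-stage \linkS4class{ContactMatrix} objects.
#' @return A merged \linkS4class{ContactMatrix} (stage \code{"merged"})
#'   whose metadata records the contributing replicates.
#' @export
mergeReplicates <- function(matrices) {
    stopifnot(length(matrices) >= 1)
    g <- matrices[[1]]@grid
    for (m in matrices) {
        if (!identical(nBins(m@grid), nBins(g)) ||
            !identical(m@grid@region@chrom, g@region@chrom))
            stop("cannot merge matrices on different grids")
        if (m@stage != "raw")
            stop(sprintf("cannot merge a '%s'-stage matrix", m@stage))
    }
    i <- unlist(lapply(matrices, slot, "i"))
    j <- unlist(lapply(matrices, slot, "j"))
    x <- unlist(lapply(matrices, slot, "x"))
    reps <- unlist(lapply(matrices, function(m)
        if (!is.null(m@sampleMeta$replicate)) m@sampleMeta$replicate else NA))
    meta <- matrices[[1]]@sampleMeta
    meta$replicate <- reps[!is.na(reps)]
    ContactMatrix(g, i, j, x, stage = "merged", sampleMeta = meta)
}
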