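#' Result of ICE matrix balancing
#'
#' @slot bias per-bin multiplicative bias factor (NA for masked bins).
#' @slot maskedBins 0-based indices of masked bins.
#' @slot iterations number of correction rounds performed.
#' @slot converged whether the marginal spread reached tolerance.
#' @slot finalMarginalSpread max relative deviation of unmasked marginals
#'   from their mean at the last iteration.
#' @export
setClass("BalancingResult",
    representation(bias = "numeric", maskedBins = "integer",
        iterations = "integer", converged = "logical",
        finalMarginalSpread = "numeric"))

setMethod("show", "BalancingResult", function(object) {
    cat(sprintf(
        "BalancingResult: %s in %d iterations, %d bins masked, spread %.3g\n",
        if (object@converged) "converged" else "NOT converged",
        object@iterations, length(object@maskedBins),
        object@finalMarginalSpread))
})

#' Iterative correction (ICE) balancing of a contact matrix
#'
#' Removes per-bin coverage bias by iteratively equalising marginals
#' (row sums with the diagonal counted once). Bins with zero marginal,
#' plus the lowest \code{lowCovFraction} of positive marginals, are masked
#' and their entries removed before correction. Each round divides every
#' entry by \eqn{b_i b_j}, where \eqn{b_i \gets b_i \cdot m_i / \bar m}
#' and \eqn{m_i} is the current unmasked marginal. Iteration stops when
#' \eqn{\max_i |m_i/\bar m - 1| \le} \code{tol} or at \code{maxIter}.
#' The balanced matrix is finally rescaled to the input total so that
#' total interactions remain comparable across samples.
#'
#' @param m a \linkS4class{ContactMatrix} at the raw or merged stage.
#' @param lowCovFraction fraction of lowest positive-coverage bins to mask
#'   (default 0.02).
#' @param tol convergence tolerance on the relative marginal spread.
#' @param maxIter maximum number of correction rounds.
#' @return A list with elements \code{matrix} (the balanced
#'   \linkS4class{ContactMatrix}, stage \code{"balanced"}) and
#'   \code{result} (a \linkS4class{BalancingResult}).
#' @examples
#' grid <- BinGrid(GenomicInterval("chr1", 0, 6000), 2000)
#' m <- ContactMatrix(grid, c(0, 0, 1), c(1, 2, 2), c(4, 2, 8))
#' iceBalance(m)$result
#' @export
iceBalance <- function(m, lowCovFraction = 0.02, tol = 1e-4,
                       maxIter = 300L) {
    if (!(m@stage %in% c("raw", "merged")))
        stop(sprintf("ICE balancing expects a raw or merged matrix, got '%s'",
            m@stage))
    nb <- nBins(m@grid)
    M <- denseMatrix(m)
    total <- sum(m@x)

    marg <- rowSums(M)
    masked <- marg == 0
    nLow <- floor(lowCovFraction * sum(!masked))
    if (nLow > 0) {
        ord <- order(marg)
        posIdx <- ord[marg[ord] > 0]
        masked[posIdx[seq_len(nLow)]] <- TRUE
    }
    keep <- which(!masked)
    if (length(keep) == 0) stop("all bins masked; nothing to balance")
    W0 <- M[keep, keep, drop = FALSE]

    # track only the bias vector: the current corrected matrix is
    # W0_ij / (b_i b_j), so its marginal is (W0 %*% (1/b))_i / b_i
    bias <- rep(1, length(keep))
    iter <- 0L
    spread <- Inf
    repeat {
        mi <- as.vector(W0 %*% (1 / bias)) / bias
        mbar <- mean(mi)
        spread <- max(abs(mi / mbar - 1))
        if (spread <= tol || iter >= maxIter) break
        iter <- iter + 1L
        bias <- bias * (mi / mbar)
    }
    W <- W0 / outer(bias, bias)
    converged <- spread <= tol
    if (!converged)
        warning(sprintf(
            "ICE did not converge in %d iterations (spread %.3g > tol %.3g)",
            maxIter, spread, tol))

    # rescale to original total (canonical upper-triangle sum)
    ut <- sum(W[upper.tri(W, diag = TRUE)])
    if (ut > 0) W <- W * (total / ut)

    full <- matrix(0, nb, nb)
    full[keep, keep] <- W
    biasFull <- rep(NA_real_, nb)
    biasFull[keep] <- bias
    bm <- fromDense(m@grid, full, stage = "balanced",
        sampleMeta = m@sampleMeta, maskedBins = which(masked) - 1L)
    res <- new("BalancingResult", bias = biasFull,
        maskedBins = which(masked) - 1L, iterations = iter,
        converged = converged, finalMarginalSpread = spread)
    list(matrix = bm, result = res)
}

#' Scale matrices to their mean total interactions
#'
#' Each matrix is multiplied by \code{mean(totals) / own total}, after
#' which all totals are equal (to the mean of the input totals) and
#' within-matrix ratios are unchanged.
#'
#' @param matrices list of balanced \linkS4class{ContactMatrix} objects.
#' @return List of scaled matrices (stage \code{"scaled"}).
#' @export
scaleToMeanTotal <- function(matrices) {
    stopifnot(length(matrices) >= 1)
    totals <- vapply(matrices, totalInteractions, numeric(1))
    if (any(totals == 0)) stop("cannot scale a zero-total matrix")
    target <- mean(totals)
    lapply(seq_along(matrices), function(k) {
        m <- matrices[[k]]
        new("ContactMatrix", grid = m@grid, i = m@i, j = m@j,
            x = m@x * (target / totals[k]), stage = "scaled",
            sampleMeta = m@sampleMeta, maskedBins = m@maskedBins)
    })
}

#' Subtraction matrix between two scaled samples
#'
#' Entry-wise \code{a - b} over the union of supports; exact zeros are
#' dropped from storage. The result is tagged \code{"subtraction"} and may
#' hold negative values.
#'
#' @param a,b scaled \linkS4class{ContactMatrix} objects on the same grid.
#' @return A subtraction-stage \linkS4class{ContactMatrix}.
#' @export
subtractMatrices <- function(a, b) {
    if (!identical(nBins(a@grid), nBins(b@grid)))
        stop("subtraction requires matrices on the same grid")
    if (a@stage != "scaled" || b@stage != "scaled")
        stop("subtraction requires scaled matrices")
    ContactMatrix(a@grid, i = c(a@i, b@i), j = c(a@j, b@j),
        x = c(a@x, -b@x), stage = "subtraction",
        sampleMeta = list(minuend = a@sampleMeta, subtrahend = b@sampleMeta),
        maskedBins = sort(unique(c(a@maskedBins, b@maskedBins))))
}

#' Cap matrix values at a percentile for display
#'
#' For non-subtraction matrices, values above the q-th percentile of the
#' non-zero stored values are set to that percentile (the convention used
#' for displaying heavy-tailed contact maps). For subtraction matrices the
#' cap is applied symmetrically: positives are capped at the q-th
#' percentile of the positives and negatives floored at minus the q-th
#' percentile of the absolute negatives. Percentiles use linear
#' interpolation between order statistics.
#'
#' @param m a \linkS4class{ContactMatrix}.
#' @param q percentile in (0, 100].
#' @return A capped copy of \code{m} (same stage).
#' @export
percentileCap <- function(m, q) {
    if (q <= 0 || q > 100) stop("q must be in (0, 100]")
    if (nEntries(m) == 0) stop("cannot cap an empty matrix")
    x <- m@x
    if (m@stage == "subtraction") {
        pos <- x[x > 0]; neg <- -x[x < 0]
        if (length(pos) > 0) {
            cap <- stats::quantile(pos, q / 100, names = FALSE, type = 7)
            x[x > cap] <- cap
        }
        if (length(neg) > 0) {
            cap <- stats::quantile(neg, q / 100, names = FALSE, type = 7)
            x[x < -cap] <- -cap
        }
    } else {
        nz <- x[x != 0]
        cap <- stats::quantile(nz, q / 100, names = FALSE, type = 7)
        x[x > cap] <- cap
    }
    new("ContactMatrix", grid = m@grid, i = m@i, j = m@j, x = x,
        stage = m@stage, sampleMeta = m@sampleMeta,
        maskedBins = m@maskedBins)
}
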