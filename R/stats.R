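#' Kruskal-Wallis result
#'
#' Tie-corrected rank statistic over k groups, with the quantities the
#' post hoc test reuses (group mean ranks, pooled N and the tie term).
#'
#' @slot H tie-corrected statistic.
#' @slot df degrees of freedom (groups - 1).
#' @slot p upper-tail chi-square probability.
#' @slot groupMeanRanks named per-group mean ranks.
#' @slot N pooled sample size.
#' @slot tieTerm \eqn{\sum_t (t^3 - t)} over tied value groups.
#' @export
setClass("KWResult",
    representation(H = "numeric", df = "integer", p = "numeric",
        groupMeanRanks = "numeric", N = "integer", tieTerm = "numeric"))

setMethod("show", "KWResult", function(object) {
    cat(sprintf("Kruskal-Wallis: H = %.4f, df = %d, p = %.4g (N = %d)\n",
        object@H, object@df, object@p, object@N))
})

#' Dunn's post hoc result
#'
#' @slot pairs data.frame with columns \code{group1}, \code{group2},
#'   \code{z}, \code{p}, \code{p_adj}.
#' @slot adjustment adjustment method used.
#' @slot warranted whether the omnibus Kruskal-Wallis p was < 0.05.
#' @export
setClass("DunnResult",
    representation(pairs = "data.frame", adjustment = "character",
        warranted = "logical"))

setMethod("show", "DunnResult", function(object) {
    cat(sprintf("Dunn's post hoc (%s adjustment%s):\n", object@adjustment,
        if (object@warranted) "" else "; omnibus test not significant"))
    print(object@pairs, row.names = FALSE)
})

#' Median-of-ratios size factors
#'
#' Per-sample normalisation factors: for every row of the count table
#' with all-positive values, compute its geometric mean; each sample's
#' factor is the median over those rows of \code{value / geometric mean}.
#'
#' @param table numeric matrix, rows = matrix cells, columns = samples.
#' @return Numeric vector of per-sample factors.
#' @examples
#' sizeFactors(cbind(a = c(1, 2, 4), b = c(2, 4, 8)))
#' @export
sizeFactors <- function(table) {
    table <- as.matrix(table)
    allPos <- rowSums(table > 0) == ncol(table)
    if (!any(allPos))
        stop("no row with all-positive values; cannot estimate size factors")
    logGeo <- rowMeans(log(table[allPos, , drop = FALSE]))
    apply(table[allPos, , drop = FALSE], 2, function(col)
        exp(stats::median(log(col) - logGeo)))
}

#' Log-normalise a count table
#'
#' \code{log2(value / factor + 1)} per cell.
#'
#' @param table numeric count matrix (cells x samples).
#' @param factors per-sample size factors (positive).
#' @return Transformed matrix of the same shape.
#' @export
logNormalize <- function(table, factors) {
    if (any(factors <= 0)) stop("size factors must be positive")
    log2(sweep(as.matrix(table), 2, factors, "/") + 1)
}

#' PCA of samples from a (log-normalised) count table
#'
#' Rows are centred internally; optionally only the \code{topN} rows by
#' variance are used. Components follow a deterministic sign convention:
#' each is flipped so that its largest-magnitude loading is positive.
#'
#' @param table numeric matrix, rows = features/cells, columns = samples.
#' @param topN number of most-variable rows to keep (default: all rows
#'   with non-zero variance).
#' @return List with \code{coordinates} (samples x components),
#'   \code{varianceExplained} and \code{loadings}.
#' @export
pcaSamples <- function(table, topN = NULL) {
    X <- as.matrix(table)
    if (ncol(X) < 2) stop("ordination needs >= 2 samples")
    v <- apply(X, 1, stats::var)
    keep <- v > 0
    if (!any(keep)) stop("constant table; no variance to ordinate")
    X <- X[keep, , drop = FALSE]
    v <- v[keep]
    if (!is.null(topN) && topN < nrow(X))
        X <- X[order(v, decreasing = TRUE)[seq_len(topN)], , drop = FALSE]
    pc <- stats::prcomp(t(X), center = TRUE, scale. = FALSE)
    flip <- apply(pc$rotation, 2, function(col)
        sign(col[which.max(abs(col))]))
    flip[flip == 0] <- 1
    coords <- sweep(pc$x, 2, flip, "*")
    loadings <- sweep(pc$rotation, 2, flip, "*")
    list(coordinates = coords,
         varianceExplained = pc$sdev^2 / sum(pc$sdev^2),
         loadings = loadings)
}

#' Shapiro-Wilk normality gate
#'
#' Contact-level quantifications are heavy-tailed; this gate (the
#' standard Royston approximation) documents the non-normality that
#' motivates the rank-based tests downstream.
#'
#' @param values numeric vector, \code{3 <= n <= 5000}, non-constant.
#' @return The Shapiro-Wilk p-value.
#' @export
normalityCheck <- function(values) {
    values <- values[!is.na(values)]
    n <- length(values)
    if (n < 3 || n > 5000)
        stop("Shapiro-Wilk requires 3 <= n <= 5000")
    if (length(unique(values)) == 1)
        stop("constant input; normality test undefined")
    stats::shapiro.test(values)$p.value
}

.rankStats <- function(groups) {
    groups <- groups[lengths(groups) > 0]
    if (length(groups) < 2) stop("need >= 2 non-empty groups")
    pooled <- unlist(groups, use.names = FALSE)
    N <- length(pooled)
    if (N < 3) stop("need pooled N >= 3")
    r <- rank(pooled)  # midranks for ties
    idx <- rep(seq_along(groups), lengths(groups))
    meanRanks <- tapply(r, idx, mean)
    names(meanRanks) <- if (!is.null(names(groups))) names(groups)
        else paste0("group", seq_along(groups))
    tie <- table(pooled)
    tieTerm <- sum(tie^3 - tie)
    list(groups = groups, N = N, meanRanks = meanRanks, tieTerm = tieTerm,
        n = lengths(groups))
}

#' Kruskal-Wallis rank test with tie correction
#'
#' \deqn{H = \frac{\frac{12}{N(N+1)} \sum_i n_i (\bar r_i - (N+1)/2)^2}
#'   {1 - \sum_t (t^3 - t) / (N^3 - N)}}
#' with midranks for ties; p is the upper tail of the chi-square
#' distribution with k-1 degrees of freedom. The fully-tied degenerate
#' case (all pooled values equal) is defined as H = 0, p = 1.
#'
#' @param groups list of numeric vectors, one per group.
#' @return A \linkS4class{KWResult}.
#' @examples
#' kruskalWallis(list(c(1, 2, 3), c(4, 5, 6)))
#' @export
kruskalWallis <- function(groups) {
    rs <- .rankStats(groups)
    k <- length(rs$groups)
    N <- rs$N
    denom <- 1 - rs$tieTerm / (N^3 - N)
    num <- 12 / (N * (N + 1)) *
        sum(rs$n * (rs$meanRanks - (N + 1) / 2)^2)
    if (denom <= 0) {  # all pooled values tied
        H <- 0; p <- 1
    } else {
        H <- num / denom
        p <- stats::pchisq(H, df = k - 1, lower.tail = FALSE)
    }
    new("KWResult", H = H, df = as.integer(k - 1), p = p,
        groupMeanRanks = as.numeric(rs$meanRanks), N = as.integer(N),
        tieTerm = rs$tieTerm)
}

#' Dunn's post hoc pairwise comparisons
#'
#' For each pair of groups,
#' \deqn{z_{ij} = \frac{\bar r_i - \bar r_j}
#'   {\sqrt{\left(\frac{N(N+1)}{12} - \frac{\sum_t (t^3-t)}{12(N-1)}\right)
#'    \left(\frac{1}{n_i} + \frac{1}{n_j}\right)}}}
#' on the ranks of the pooled data, with two-sided p from the standard
#' normal, adjusted across all pairs. The test is run unconditionally but
#' flagged as not warranted when the omnibus Kruskal-Wallis p is >= 0.05.
#'
#' @param groups list of numeric vectors, one per group.
#' @param adjust \code{"holm"}, \code{"bh"} or \code{"none"}.
#' @return A \linkS4class{DunnResult}.
#' @examples
#' dunnTest(list(c(1, 2, 3), c(4, 5, 6)), adjust = "holm")
#' @export
dunnTest <- function(groups, adjust = c("holm", "bh", "none")) {
    adjust <- match.arg(adjust)
    rs <- .rankStats(groups)
    kw <- kruskalWallis(groups)
    N <- rs$N
    varTerm <- N * (N + 1) / 12 - rs$tieTerm / (12 * (N - 1))
    gnames <- names(rs$meanRanks)
    cmb <- utils::combn(length(rs$groups), 2)
    z <- p <- numeric(ncol(cmb))
    for (c_ in seq_len(ncol(cmb))) {
        a <- cmb[1, c_]; b <- cmb[2, c_]
        se2 <- varTerm * (1 / rs$n[a] + 1 / rs$n[b])
        if (se2 <= 0) { z[c_] <- 0; p[c_] <- 1; next }
        z[c_] <- (rs$meanRanks[a] - rs$meanRanks[b]) / sqrt(se2)
        p[c_] <- 2 * stats::pnorm(abs(z[c_]), lower.tail = FALSE)
    }
    padj <- adjustPvalues(p, method = adjust)
    new("DunnResult",
        pairs = data.frame(group1 = gnames[cmb[1, ]],
            group2 = gnames[cmb[2, ]], z = z, p = p, p_adj = padj,
            stringsAsFactors = FALSE),
        adjustment = adjust, warranted = kw@p < 0.05)
}

#' Multiple-testing adjustment
#'
#' Holm step-down or Benjamini-Hochberg step-up adjustment (with
#' monotonicity enforcement and capping at 1); input order preserved.
#' \code{"none"} returns the raw p-values.
#'
#' @param ps numeric p-values in [0, 1].
#' @param method \code{"holm"}, \code{"bh"} or \code{"none"}.
#' @return Adjusted p-values in the input order.
#' @export
adjustPvalues <- function(ps, method = c("holm", "bh", "none")) {
    method <- match.arg(method)
    if (any(ps < 0 | ps > 1, na.rm = TRUE))
        stop("p-values must be in [0, 1]")
    switch(method,
        holm = stats::p.adjust(ps, method = "holm"),
        bh = stats::p.adjust(ps, method = "BH"),
        none = ps)
}

#' Build a cell-by-sample count table from raw contact matrices
#'
#' Rows are canonical bin pairs present in at least one sample; columns
#' are samples. The table feeds \code{\link{sizeFactors}},
#' \code{\link{logNormalize}} and \code{\link{pcaSamples}}.
#'
#' @param matrices named list of raw-stage \linkS4class{ContactMatrix}
#'   objects on one grid.
#' @return Numeric matrix with rownames \code{"i_j"}.
#' @export
buildCountTable <- function(matrices) {
    stopifnot(length(matrices) >= 2)
    nb <- nBins(matrices[[1]]@grid)
    keys <- lapply(matrices, function(m) m@i * as.numeric(nb) + m@j)
    allKeys <- sort(unique(unlist(keys)))
    tab <- matrix(0, nrow = length(allKeys), ncol = length(matrices))
    for (k in seq_along(matrices)) {
        idx <- match(keys[[k]], allKeys)
        tab[idx, k] <- matrices[[k]]@x
    }
    rownames(tab) <- sprintf("%d_%d", as.integer(allKeys %/% nb),
        as.integer(allKeys %% nb))
    colnames(tab) <- if (!is.null(names(matrices))) names(matrices)
        else paste0("sample", seq_along(matrices))
    tab
}
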