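#' Configuration of a full analysis run
#'
#' A plain list validated by \code{pipelineConfig()}:
#' \describe{
#'   \item{grid}{a \linkS4class{BinGrid} or path to a grid sidecar JSON.}
#'   \item{samples}{data.frame with columns \code{path}, \code{state},
#'     \code{replicate} and optionally \code{genotype}.}
#'   \item{domains}{named list of half-open bin ranges.}
#'   \item{features}{a \linkS4class{FeatureSet}, or path to a BED plus
#'     per-line categories.}
#'   \item{viewpoints}{named integer vector of viewpoint bins (e.g.
#'     promoters).}
#'   \item{analyses}{character subset of \code{c("insulation",
#'     "boundary", "ep", "pca", "tests")}.}
#'   \item{adjust}{p-value adjustment for Dunn's test.}
#'   \item{outdir}{output directory.}
#' }
#'
#' @param grid,samples,domains,features,viewpoints,analyses,adjust,outdir
#'   see description.
#' @param lowCovFraction,tol,maxIter ICE balancing parameters.
#' @return Validated config list of class \code{"tiledPipelineConfig"}.
#' @export
pipelineConfig <- function(grid, samples, domains = list(),
        features = NULL, viewpoints = integer(0),
        analyses = c("insulation", "boundary", "ep", "pca", "tests"),
        adjust = "holm", outdir,
        lowCovFraction = 0.02, tol = 1e-4, maxIter = 300L) {
    if (is.character(grid)) grid <- readGridSidecar(grid)
    stopifnot(is(grid, "BinGrid"))
    samples <- as.data.frame(samples)
    if (!all(c("path", "state", "replicate") %in% names(samples)))
        stop("sample sheet needs columns path, state, replicate")
    missing <- !file.exists(samples$path)
    if (any(missing))
        stop(sprintf("sample file(s) not found: %s",
            paste(samples$path[missing], collapse = ", ")))
    structure(list(grid = grid, samples = samples, domains = domains,
        features = features, viewpoints = viewpoints,
        analyses = analyses, adjust = adjust, outdir = outdir,
        lowCovFraction = lowCovFraction, tol = tol, maxIter = maxIter),
        class = "tiledPipelineConfig")
}

.logmsg <- function(...) message(sprintf(...))

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop(sprintf("pipeline stage '%s' failed: %s", name,
            conditionMessage(e)), call. = FALSE))
}

#' Run the full contact-map analysis pipeline
#'
#' Per replicate: read triplets, ICE-balance; across replicates: scale to
#' the mean total. Per state: merge raw replicates, balance and scale the
#' merged matrices for display and subtraction. Then, as requested in
#' \code{config$analyses}: virtual Capture-C profile aggregates per
#' viewpoint and state (bedGraph tracks), intra-TAD insulation ratios per
#' domain, boundary CTCF contacts, enhancer-promoter totals, PCA of
#' log-normalised counts, and Kruskal-Wallis + Dunn comparisons across
#' states for every quantification. All tables are written as TSV, and a
#' JSON summary records every output file with the parameters used.
#' Identical config and inputs give identical outputs.
#'
#' @param config a config from \code{\link{pipelineConfig}}.
#' @return The summary list, invisibly (written as
#'   \code{summary.json} in \code{outdir}).
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "tiledPipelineConfig"))
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    grid <- config$grid
    outputs <- character(0)
    emit <- function(path) { outputs <<- c(outputs, path); path }

    sam <- config$samples
    .logmsg("reading %d sample matrices", nrow(sam))
    raws <- .stage("read_triplets", lapply(seq_len(nrow(sam)), function(k)
        readTriplets(sam$path[k], grid, sampleMeta = list(
            state = sam$state[k], replicate = sam$replicate[k],
            genotype = if ("genotype" %in% names(sam)) sam$genotype[k]
                else "WT"))))
    names(raws) <- sprintf("%s_rep%s", sam$state, sam$replicate)

    .logmsg("balancing per-replicate matrices")
    balanced <- .stage("ice_balance", lapply(raws, function(m)
        iceBalance(m, config$lowCovFraction, config$tol,
            config$maxIter)$matrix))
    scaled <- .stage("scale_to_mean_total", scaleToMeanTotal(balanced))
    names(scaled) <- names(raws)

    states <- unique(sam$state)
    .logmsg("merging and balancing per-state matrices")
    mergedScaled <- .stage("merge", {
        merged <- lapply(states, function(s)
            mergeReplicates(raws[sam$state == s]))
        mb <- lapply(merged, function(m)
            iceBalance(m, config$lowCovFraction, config$tol,
                config$maxIter)$matrix)
        ms <- scaleToMeanTotal(mb)
        names(ms) <- states
        ms
    })
    for (s in states)
        writeTriplets(mergedScaled[[s]],
            emit(file.path(config$outdir, sprintf("%s_merged_scaled.tsv", s))))
    if (length(states) >= 2) {
        for (k in seq_len(length(states) - 1)) {
            sub <- subtractMatrices(mergedScaled[[states[k + 1]]],
                mergedScaled[[states[k]]])
            writeTriplets(percentileCap(sub, 97),
                emit(file.path(config$outdir, sprintf(
                    "subtraction_%s_minus_%s_cap97.tsv",
                    states[k + 1], states[k]))))
        }
    }

    summaryTables <- list()
    groupTest <- function(values, label) {
        if (!("tests" %in% config$analyses) || length(values) < 2)
            return(NULL)
        kw <- kruskalWallis(values)
        dn <- dunnTest(values, adjust = config$adjust)
        df <- dn@pairs
        df$statistic <- label
        df$kw_H <- kw@H; df$kw_p <- kw@p
        df
    }

    if (length(config$viewpoints) > 0) {
        .logmsg("virtual Capture-C profiles")
        for (v in seq_along(config$viewpoints)) {
            vp <- config$viewpoints[v]
            vpName <- names(config$viewpoints)[v]
            for (s in states) {
                reps <- which(sam$state == s)
                profs <- lapply(reps, function(k) {
                    m <- scaled[[k]]
                    normalizeProfile(virtualCapture(m, vp), m)
                })
                agg <- aggregateReplicates(profs, cellState = s)
                writeBedGraph(agg@mean, grid, emit(file.path(config$outdir,
                    sprintf("vcc_%s_%s_mean.bedgraph", vpName, s))))
                writeBedGraph(agg@sd, grid, emit(file.path(config$outdir,
                    sprintf("vcc_%s_%s_sd.bedgraph", vpName, s))))
            }
        }
    }

    if ("insulation" %in% config$analyses && length(config$domains) > 0) {
        .logmsg("intra-TAD insulation ratios")
        rows <- list()
        tests <- list()
        for (d in names(config$domains)) {
            rng <- config$domains[[d]]
            bins <- rng[1]:(rng[2] - 1L)
            byState <- lapply(states, function(s) {
                unlist(lapply(which(sam$state == s), function(k)
                    intraTadRatio(scaled[[k]], bins)$ratios))
            })
            names(byState) <- states
            for (s in states)
                rows[[length(rows) + 1L]] <- data.frame(domain = d,
                    state = s, value = byState[[s]])
            tests[[d]] <- groupTest(byState, paste0("insulation_", d))
        }
        tab <- do.call(rbind, rows)
        utils::write.table(tab, emit(file.path(config$outdir,
            "insulation.tsv")), sep = "\t", quote = FALSE,
            row.names = FALSE)
        summaryTables$insulation <- do.call(rbind, tests)
    }

    if ("boundary" %in% config$analyses && !is.null(config$features) &&
        length(config$domains) > 0) {
        .logmsg("boundary CTCF contacts")
        d <- names(config$domains)[1]
        sets <- boundaryBinSets(config$features, config$domains[[d]], grid)
        byState <- lapply(states, function(s)
            unlist(lapply(which(sam$state == s), function(k)
                boundaryContacts(scaled[[k]], sets$A, sets$B))))
        names(byState) <- states
        tab <- do.call(rbind, lapply(states, function(s)
            data.frame(state = s, value = byState[[s]])))
        utils::write.table(tab, emit(file.path(config$outdir,
            "boundary_contacts.tsv")), sep = "\t", quote = FALSE,
            row.names = FALSE)
        summaryTables$boundary <- groupTest(byState, "boundary_contacts")
    }

    if ("ep" %in% config$analyses && !is.null(config$features) &&
        length(config$viewpoints) > 0) {
        .logmsg("enhancer-promoter quantification")
        rows <- list()
        tests <- list()
        for (v in seq_along(config$viewpoints)) {
            vp <- config$viewpoints[v]
            vpName <- names(config$viewpoints)[v]
            byState <- lapply(states, function(s)
                vapply(which(sam$state == s), function(k)
                    epContacts(scaled[[k]], vp, config$features,
                        grid)$total, numeric(1)))
            names(byState) <- states
            for (s in states)
                rows[[length(rows) + 1L]] <- data.frame(
                    promoter = vpName, state = s, value = byState[[s]])
            tests[[vpName]] <- groupTest(byState, paste0("ep_", vpName))
        }
        utils::write.table(do.call(rbind, rows), emit(file.path(
            config$outdir, "ep_contacts.tsv")), sep = "\t",
            quote = FALSE, row.names = FALSE)
        summaryTables$ep <- do.call(rbind, tests)
    }

    pcaOut <- NULL
    if ("pca" %in% config$analyses && nrow(sam) >= 2) {
        .logmsg("PCA of log-normalised counts")
        tab <- buildCountTable(raws)
        sf <- sizeFactors(tab)
        # ordination on the 500 most-variable cells, the convention of the
        # count-based PCA tooling this step mirrors
        pc <- pcaSamples(logNormalize(tab, sf), topN = 500)
        coords <- data.frame(sample = rownames(pc$coordinates),
            state = sam$state, pc$coordinates[, seq_len(
                min(4, ncol(pc$coordinates))), drop = FALSE])
        utils::write.table(coords, emit(file.path(config$outdir,
            "pca_coordinates.tsv")), sep = "\t", quote = FALSE,
            row.names = FALSE)
        pcaOut <- list(varianceExplained = pc$varianceExplained)
    }

    statTab <- do.call(rbind, summaryTables)
    if (!is.null(statTab))
        utils::write.table(statTab, emit(file.path(config$outdir,
            "group_tests.tsv")), sep = "\t", quote = FALSE,
            row.names = FALSE)

    summary <- list(
        parameters = list(
            bin_size = grid@binSize, n_bins = nBins(grid),
            low_cov_fraction = config$lowCovFraction, tol = config$tol,
            max_iter = config$maxIter, adjust = config$adjust,
            analyses = config$analyses),
        samples = sam[, c("path", "state", "replicate")],
        n_balanced = length(balanced),
        n_merged = length(mergedScaled),
        pca = pcaOut,
        outputs = basename(outputs))
    jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(summary)
}
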