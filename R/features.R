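#' Annotated genomic features on a tile
#'
#' An ordered collection of named features (enhancers, CTCF sites,
#' promoters) stored as parallel vectors. Coordinates are 0-based
#' half-open, matching \linkS4class{GenomicInterval}. Orientation encodes
#' CTCF motif direction and is \code{"none"} for non-CTCF features.
#'
#' @slot chrom chromosome (one per feature, all equal on a single tile).
#' @slot start,end 0-based half-open coordinates.
#' @slot name feature label (e.g. the enhancer distance label "+23").
#' @slot category one of \code{"enhancer"}, \code{"ctcf"},
#'   \code{"promoter"}.
#' @slot orientation one of \code{"forward"}, \code{"reverse"},
#'   \code{"none"}.
#' @slot provenance free-text source tag.
#' @export
setClass("FeatureSet",
    representation(chrom = "character", start = "numeric", end = "numeric",
        name = "character", category = "character",
        orientation = "character", provenance = "character"))

.FEATURE_CATEGORIES <- c("enhancer", "ctcf", "promoter")
.ORIENTATIONS <- c("forward", "reverse", "none")

setValidity("FeatureSet", function(object) {
    n <- length(object@start)
    lens <- c(length(object@chrom), length(object@end), length(object@name),
        length(object@category), length(object@orientation))
    if (any(lens != n)) return("all feature columns must have equal length")
    if (n > 0) {
        if (any(object@end <= object@start))
            return("feature end must exceed start")
        if (!all(object@category %in% .FEATURE_CATEGORIES))
            return("category must be enhancer, ctcf or promoter")
        if (!all(object@orientation %in% .ORIENTATIONS))
            return("orientation must be forward, reverse or none")
        bad <- object@category != "ctcf" & object@orientation != "none"
        if (any(bad))
            return("orientation must be 'none' for non-CTCF features")
    }
    TRUE
})

#' Construct a FeatureSet
#'
#' @param chrom chromosome name(s), recycled to the number of features.
#' @param start,end 0-based half-open coordinates.
#' @param name feature labels.
#' @param category per-feature category (\code{"enhancer"}, \code{"ctcf"}
#'   or \code{"promoter"}), recycled.
#' @param orientation CTCF motif orientation (\code{"forward"},
#'   \code{"reverse"}); defaults to \code{"none"} for non-CTCF features.
#' @param provenance free-text source tag.
#' @return A \linkS4class{FeatureSet}.
#' @export
FeatureSet <- function(chrom, start, end, name = NULL,
                       category = "enhancer", orientation = NULL,
                       provenance = "unspecified") {
    n <- length(start)
    if (is.null(name)) name <- sprintf("feature_%d", seq_len(n))
    category <- rep_len(category, n)
    if (is.null(orientation))
        orientation <- ifelse(category == "ctcf", "forward", "none")
    new("FeatureSet", chrom = rep_len(as.character(chrom), n),
        start = as.numeric(start), end = as.numeric(end),
        name = as.character(name), category = as.character(category),
        orientation = rep_len(as.character(orientation), n),
        provenance = provenance)
}

#' @rdname FeatureSet
#' @param x a \code{FeatureSet}.
#' @export
nFeatures <- function(x) length(x@start)

#' @rdname FeatureSet
#' @export
featureCategory <- function(x) x@category

#' @rdname FeatureSet
#' @export
featureName <- function(x) x@name

#' @rdname FeatureSet
#' @export
featureOrientation <- function(x) x@orientation

#' Subset a FeatureSet by category
#' @param x a \linkS4class{FeatureSet}.
#' @param category category to keep.
#' @export
featuresOfCategory <- function(x, category) {
    keep <- x@category == category
    new("FeatureSet", chrom = x@chrom[keep], start = x@start[keep],
        end = x@end[keep], name = x@name[keep],
        category = x@category[keep], orientation = x@orientation[keep],
        provenance = x@provenance)
}

#' Interval of the i-th feature
#' @param x a \linkS4class{FeatureSet}.
#' @param i feature index (1-based).
#' @export
featureInterval <- function(x, i) {
    GenomicInterval(x@chrom[i], x@start[i], x@end[i])
}

setMethod("show", "FeatureSet", function(object) {
    cat(sprintf("FeatureSet with %d features (%s)\n", nFeatures(object),
        paste(sprintf("%d %s", table(factor(object@category,
            .FEATURE_CATEGORIES)), .FEATURE_CATEGORIES), collapse = ", ")))
})

#' Read features from a BED file
#'
#' Parses a 3-6 column tab-separated BED file into a
#' \linkS4class{FeatureSet}. Column 4 supplies the feature name, column 6
#' the strand, mapped to motif orientation (\code{+} forward, \code{-}
#' reverse). Coordinates are kept 0-based half-open as in the file.
#'
#' BED carries no category column; the category is supplied by the caller
#' (commonly one BED file per category: enhancers, CTCF sites, promoters).
#'
#' @param path BED file path.
#' @param category category assigned to the features (scalar or one per
#'   line).
#' @param provenance source tag recorded on the set.
#' @return A \linkS4class{FeatureSet}.
#' @export
readBedFeatures <- function(path, category = "enhancer",
                            provenance = basename(path)) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    lines <- lines[!grepl("^(track|browser|#)", lines)]
    n <- length(lines)
    chrom <- character(n); start <- numeric(n); end <- numeric(n)
    name <- character(n); strand <- character(n)
    for (k in seq_len(n)) {
        f <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
        if (length(f) < 3)
            stop(sprintf("malformed BED line %d: fewer than 3 columns", k))
        s <- suppressWarnings(as.numeric(f[2]))
        e <- suppressWarnings(as.numeric(f[3]))
        if (is.na(s) || is.na(e) || e <= s)
            stop(sprintf("malformed BED line %d: bad coordinates '%s' '%s'",
                k, f[2], f[3]))
        chrom[k] <- f[1]; start[k] <- s; end[k] <- e
        name[k] <- if (length(f) >= 4) f[4] else paste0("feature_", k)
        strand[k] <- if (length(f) >= 6) f[6] else "."
    }
    category <- rep_len(category, n)
    orientation <- ifelse(category == "ctcf",
        ifelse(strand == "-", "reverse", "forward"), "none")
    FeatureSet(chrom, start, end, name, category, orientation, provenance)
}

#' Write features to a BED file
#'
#' Emits 6-column BED (chrom, start, end, name, score 0, strand).
#' CTCF orientation maps to strand (\code{forward -> +},
#' \code{reverse -> -}); other features get strand \code{.}.
#' \code{readBedFeatures(writeBedFeatures(fs), category)} round-trips
#' name, interval, category and orientation.
#'
#' @param fs a \linkS4class{FeatureSet}.
#' @param path output file path.
#' @export
writeBedFeatures <- function(fs, path) {
    strand <- ifelse(fs@orientation == "reverse", "-",
        ifelse(fs@orientation == "forward", "+", "."))
    lines <- sprintf("%s\t%s\t%s\t%s\t0\t%s", fs@chrom,
        format(fs@start, scientific = FALSE, trim = TRUE),
        format(fs@end, scientific = FALSE, trim = TRUE), fs@name, strand)
    writeLines(lines, path)
    invisible(path)
}
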