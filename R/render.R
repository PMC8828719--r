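#' Render a contact matrix as a rotated triangular heatmap
#'
#' Caps the matrix at the given percentile (the convention for displaying
#' heavy-tailed contact data) and draws the upper triangle rotated 45
#' degrees, the standard orientation for tiled contact maps. Subtraction
#' matrices use a diverging blue-white-red palette with symmetric colour
#' limits; all other stages a white-to-red ramp.
#'
#' @param m a \linkS4class{ContactMatrix}.
#' @param q display percentile in (0, 100].
#' @param path output file; extension selects the device (\code{.pdf} or
#'   \code{.png}).
#' @param maxDistance largest bin separation drawn (default: all).
#' @return \code{path}, invisibly.
#' @export
renderMatrix <- function(m, q = 94, path, maxDistance = NULL) {
    capped <- percentileCap(m, q)
    nb <- nBins(m@grid)
    if (is.null(maxDistance)) maxDistance <- nb - 1L
    ext <- tolower(tools::file_ext(path))
    if (ext == "png") {
        grDevices::png(path, width = 1200, height = 500)
    } else {
        grDevices::pdf(path, width = 10, height = 4)
    }
    on.exit(grDevices::dev.off())

    div <- m@stage == "subtraction"
    x <- capped@x
    lim <- max(abs(x))
    if (lim == 0) lim <- 1
    if (div) {
        pal <- grDevices::colorRampPalette(
            c("#2166AC", "white", "#B2182B"))(256)
        colIdx <- pmax(1L, pmin(256L,
            as.integer(round((x / lim + 1) / 2 * 255)) + 1L))
    } else {
        pal <- grDevices::colorRampPalette(c("white", "#B2182B"))(256)
        colIdx <- pmax(1L, pmin(256L,
            as.integer(round(x / lim * 255)) + 1L))
    }
    keep <- (capped@j - capped@i) <= maxDistance
    graphics::plot(NA, xlim = c(0, nb), ylim = c(0, maxDistance + 1),
        xlab = sprintf("%s bin", m@grid@region@chrom), ylab = "",
        yaxt = "n", bty = "n", main = sprintf("%s (capped at %gth pct)",
            m@stage, q))
    # rotated coordinates: pair (i, j) plots at x = (i+j)/2, y = j - i
    ii <- capped@i[keep]; jj <- capped@j[keep]
    cx <- (ii + jj) / 2; cy <- jj - ii
    graphics::symbols(cx, cy + 0.5, squares = rep(1, length(cx)),
        inches = FALSE, add = TRUE, fg = NA, bg = pal[colIdx[keep]])
    invisible(path)
}
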