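#' Plot individual and windowed z-score tracks for one chromosome
#'
#' Diagnostic profile plot: individual per-bin z-scores in blue, windowed
#' z-scores in red, call-threshold guides dashed, and called segments as
#' purple bars under the axis. Non-normative; intended for eyeballing a
#' sample's profile.
#'
#' @param zprofile a windowed [ZProfile-class].
#' @param chrom chromosome to plot.
#' @param segments optional `GRanges` of called segments to draw as bars.
#' @param callThreshold threshold guide lines (default 3.5).
#' @return invisibly, `NULL`.
#' @importFrom graphics abline legend lines rect
#' @export
plotZProfile <- function(zprofile, chrom, segments = NULL,
                         callThreshold = 3.5) {
  stopifnot(is(zprofile, "ZProfile"))
  ch <- .gridChrom(zprofile@grid)[zprofile@usableIdx]
  sel <- ch == chrom
  if (!any(sel)) stop("no scored bins on chromosome ", chrom)
  pos <- (.gridStart0(zprofile@grid)[zprofile@usableIdx][sel] +
          .gridEnd0(zprofile@grid)[zprofile@usableIdx][sel]) / 2 / 1e6
  zi <- zprofile@z[sel]
  zw <- zprofile@zWindowed[sel]
  ylim <- range(c(zi, zw, -5, 5), na.rm = TRUE)
  plot(pos, zi, type = "l", col = "steelblue", xlab = sprintf("chr%s (Mb)", chrom),
       ylab = "z-score", ylim = ylim, main = sampleId(zprofile))
  if (!all(is.na(zw))) lines(pos, zw, col = "firebrick")
  abline(h = c(-callThreshold, callThreshold), lty = 2, col = "grey50")
  abline(h = 0, col = "grey80")
  if (!is.null(segments) && length(segments)) {
    segSel <- as.character(GenomicRanges::seqnames(segments)) == chrom
    if (any(segSel)) {
      s0 <- (GenomicRanges::start(segments)[segSel] - 1) / 1e6
      e0 <- GenomicRanges::end(segments)[segSel] / 1e6
      rect(s0, ylim[1], e0, ylim[1] + 0.4, col = "purple", border = NA)
    }
  }
  legend("topright", legend = c("individual", "windowed"),
         col = c("steelblue", "firebrick"), lty = 1, bty = "n", cex = 0.8)
  invisible(NULL)
}
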