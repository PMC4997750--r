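## The prespecified cancer screen rule and catalog annotation.

#' Apply the prespecified segment-size screen rule
#'
#' A subject screens positive iff at least one called segment is at least
#' `minSizeMb` in size (inclusive; default 15 Mb, the prespecified
#' screen-positive threshold).
#'
#' @param segments `GRanges` of one sample's called segments.
#' @param sampleId subject identifier.
#' @param minSizeMb inclusive size threshold in Mb (default 15).
#' @return a [ScreenCall-class].
#' @export
applySizeRule <- function(segments, sampleId = "sample", minSizeMb = 15) {
  sz <- if (length(segments)) S4Vectors::mcols(segments)$sizeMb else numeric()
  qual <- segments[sz >= minSizeMb]
  new("ScreenCall",
    sampleId = as.character(sampleId),
    status = if (length(qual)) "positive" else "negative",
    segments = segments, qualifying = qual, minSizeMb = minSizeMb
  )
}

#' Classify an (arm, direction) pair against the catalog
#'
#' The recurrence-specificity rule: `q < 0.25` and frequency `> 0.5` is
#' `highly_specific`; `q < 0.25` and frequency `<= 0.5` is
#' `moderately_specific`; anything else — including arms absent from the
#' catalog — is `non_specific`. A total, deterministic function of
#' `(arm, direction, catalog)`; catalog row order is irrelevant.
#'
#' @param arm character vector of arm ids (e.g. `"3q"`).
#' @param direction parallel vector of `"gain"`/`"loss"`.
#' @param catalog a [CNVCatalog-class].
#' @return character vector of classes.
#' @export
classifyCNV <- function(arm, direction, catalog) {
  tab <- catalogTable(catalog)
  key <- paste(tab$arm, tab$direction)
  m <- match(paste(arm, direction), key)
  out <- rep("non_specific", length(arm))
  hit <- !is.na(m)
  q <- tab$q_value[m[hit]]
  f <- tab$frequency[m[hit]]
  out[hit] <- ifelse(q < 0.25 & f > 0.5, "highly_specific",
                     ifelse(q < 0.25, "moderately_specific", "non_specific"))
  out
}

.CLASS_ORDER <- c("highly_specific", "moderately_specific", "non_specific")

#' Annotate segments with chromosome arms and catalog specificity
#'
#' Each segment is assigned every arm it overlaps by at least
#' `minOverlapFrac` of the segment's own length (default 25 %; a
#' whole-chromosome segment is assigned to both arms). Each assigned
#' `(arm, direction)` is classified with [classifyCNV()], and the segment's
#' overall class is the most specific among its arms.
#'
#' @param segments `GRanges` of called segments.
#' @param genome a [GenomeSpec-class] providing arm boundaries.
#' @param catalog a [CNVCatalog-class].
#' @param minOverlapFrac minimum overlap as a fraction of segment length
#'   (default 0.25).
#' @return the segments with added metadata columns `arms` (comma-joined),
#'   `armFractions` (comma-joined overlap fractions) and `class`.
#' @export
annotateSegments <- function(segments, genome, catalog,
                             minOverlapFrac = 0.25) {
  stopifnot(is(genome, "GenomeSpec"), is(catalog, "CNVCatalog"))
  n <- length(segments)
  arms <- character(n); fracs <- character(n); cls <- character(n)
  if (n) {
    sn <- as.character(GenomicRanges::seqnames(segments))
    lens <- chromLengths(genome)
    if (any(!sn %in% names(lens)))
      stop("segment chromosome not in genome: ",
           paste(unique(sn[!sn %in% names(lens)]), collapse = ", "))
    if (any(GenomicRanges::end(segments) > lens[sn]))
      stop("segment extends beyond its chromosome")
    armGr <- .armRanges(genome)
    hits <- GenomicRanges::findOverlaps(segments, armGr)
    ov <- GenomicRanges::pintersect(
      segments[S4Vectors::queryHits(hits)], armGr[S4Vectors::subjectHits(hits)]
    )
    frac <- GenomicRanges::width(ov) / GenomicRanges::width(segments[S4Vectors::queryHits(hits)])
    keep <- frac >= minOverlapFrac
    qh <- S4Vectors::queryHits(hits)[keep]
    armHit <- S4Vectors::mcols(armGr)$arm[S4Vectors::subjectHits(hits)[keep]]
    fracHit <- frac[keep]
    dir <- S4Vectors::mcols(segments)$direction
    for (i in seq_len(n)) {
      sel <- qh == i
      if (!any(sel)) { arms[i] <- ""; fracs[i] <- ""; cls[i] <- "non_specific"; next }
      a <- armHit[sel]
      arms[i] <- paste(a, collapse = ",")
      fracs[i] <- paste(sprintf("%.3f", fracHit[sel]), collapse = ",")
      armCls <- classifyCNV(a, rep(dir[i], length(a)), catalog)
      cls[i] <- .CLASS_ORDER[min(match(armCls, .CLASS_ORDER))]
    }
  }
  S4Vectors::mcols(segments)$arms <- arms
  S4Vectors::mcols(segments)$armFractions <- fracs
  S4Vectors::mcols(segments)$class <- cls
  segments
}

#' Count focal aberrations among called segments
#'
#' Focal changes are called segments below the screen-size threshold
#' (default < 15 Mb). In recurrent-CNV-rich tumors most cases carry several
#' focal changes while benign controls rarely carry more than one, so the
#' count is a useful secondary feature.
#'
#' @param segments `GRanges` of one sample's called segments.
#' @param focalMaxMb exclusive upper size bound in Mb (default 15).
#' @return integer count.
#' @export
countFocalAberrations <- function(segments, focalMaxMb = 15) {
  if (!length(segments)) return(0L)
  sum(S4Vectors::mcols(segments)$sizeMb < focalMaxMb)
}
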