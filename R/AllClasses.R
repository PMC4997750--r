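#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps pintersect
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits DataFrame
NULL

#' Genome specification: chromosome names, lengths and centromere positions
#'
#' A `GenomeSpec` fixes the coordinate system every other object in the
#' package lives on: an ordered set of chromosomes (22 autosomes plus X by
#' default), their lengths in bp, and a centromere position per chromosome
#' that splits each into a p arm (`[0, centromere)`) and a q arm
#' (`[centromere, length)`). All coordinates in the package are 0-based
#' half-open.
#'
#' @slot chroms ordered chromosome names (unique).
#' @slot lengths numeric chromosome lengths in bp, parallel to `chroms`.
#' @slot centromeres numeric centromere positions in bp, strictly inside
#'   each chromosome.
#'
#' @seealso [defaultGenome()], [armBounds()]
#' @export
setClass("GenomeSpec",
  representation(
    chroms = "character",
    lengths = "numeric",
    centromeres = "numeric"
  )
)

setValidity("GenomeSpec", function(object) {
  msg <- character()
  n <- length(object@chroms)
  if (length(object@lengths) != n || length(object@centromeres) != n)
    msg <- c(msg, "chroms, lengths and centromeres must have equal length")
  if (anyDuplicated(object@chroms))
    msg <- c(msg, "chromosome names must be unique")
  if (length(object@lengths) == n && any(object@lengths <= 0))
    msg <- c(msg, "chromosome lengths must be > 0")
  if (length(object@centromeres) == n && length(object@lengths) == n &&
      any(object@centromeres <= 0 | object@centromeres >= object@lengths))
    msg <- c(msg, "centromeres must lie strictly inside their chromosome")
  if (length(msg)) msg else TRUE
})

#' Fixed genomic binning shared by all samples
#'
#' A `BinGrid` wraps a sorted, non-overlapping [GenomicRanges::GRanges] of
#' constant-size bins with per-bin GC fraction and a usability flag. Every
#' count profile, reference index and z-score track is aligned to one grid.
#' Unusable bins (trailing partial bins, user-masked regions) are carried in
#' the grid but excluded from every statistic.
#'
#' @slot bins `GRanges` with metadata columns `gc` (fraction in `[0,1]`) and
#'   `usable` (logical).
#' @slot binSize nominal bin width in bp.
#'
#' @seealso [makeDefaultGrid()], [loadBinGrid()]
#' @export
setClass("BinGrid",
  representation(
    bins = "GRanges",
    binSize = "numeric"
  )
)

setValidity("BinGrid", function(object) {
  msg <- character()
  b <- object@bins
  mc <- S4Vectors::mcols(b)
  if (!all(c("gc", "usable") %in% colnames(mc)))
    return("bins must carry 'gc' and 'usable' metadata columns")
  if (any(mc$gc < 0 | mc$gc > 1, na.rm = TRUE))
    msg <- c(msg, "gc fractions must lie in [0, 1]")
  if (length(object@binSize) != 1L || object@binSize <= 0)
    msg <- c(msg, "binSize must be a single positive number")
  # sorted and non-overlapping within chromosome
  sn <- as.character(GenomicRanges::seqnames(b))
  st <- GenomicRanges::start(b)
  en <- GenomicRanges::end(b)
  if (length(b) > 1L) {
    same <- sn[-1L] == sn[-length(b)]
    if (is.unsorted(match(sn, unique(sn))))
      msg <- c(msg, "bins must be grouped by chromosome in grid order")
    if (any(same & st[-1L] <= st[-length(b)]))
      msg <- c(msg, "bins must be sorted by start within chromosome")
    if (any(same & st[-1L] <= en[-length(b)]))
      msg <- c(msg, "bins must not overlap")
  }
  if (length(msg)) msg else TRUE
})

#' Per-sample bin counts and normalized values
#'
#' A `SampleProfile` holds one plasma sample's raw read counts per grid bin
#' together with (once computed) normalized values: each usable bin's share
#' of the total autosomal usable count, optionally GC-corrected. X-chromosome
#' bins are normalized against the same autosomal total so that female
#' X-dosage variation cannot perturb autosomal statistics.
#'
#' @slot sampleId sample identifier.
#' @slot grid the [BinGrid-class] the counts are aligned to.
#' @slot counts non-negative integer read counts, one per grid bin.
#' @slot values normalized per-bin values (NA until [normalizeCounts()] is
#'   run; NA on unusable bins).
#' @slot totalReads total read count over usable bins.
#' @slot normalized logical, `TRUE` once values are populated.
#' @slot gcCorrected logical, `TRUE` once [gcCorrect()] has been applied.
#'
#' @export
setClass("SampleProfile",
  representation(
    sampleId = "character",
    grid = "BinGrid",
    counts = "numeric",
    values = "numeric",
    totalReads = "numeric",
    normalized = "logical",
    gcCorrected = "logical"
  )
)

setValidity("SampleProfile", function(object) {
  msg <- character()
  nb <- length(object@grid@bins)
  if (length(object@counts) != nb)
    msg <- c(msg, "counts length must equal number of grid bins")
  if (length(object@values) != nb)
    msg <- c(msg, "values length must equal number of grid bins")
  if (any(object@counts < 0, na.rm = TRUE))
    msg <- c(msg, "raw counts must be non-negative")
  if (isTRUE(object@normalized)) {
    ua <- autosomalUsable(object@grid)
    s <- sum(object@values[ua])
    if (is.na(s) || abs(s - 1) > 1e-9)
      msg <- c(msg, "normalized values of usable autosomal bins must sum to 1")
  }
  if (length(msg)) msg else TRUE
})

#' Within-sample reference index built from a panel of unaffected samples
#'
#' For every usable bin `i` the index stores the `k` other bins whose
#' normalized values behave most like bin `i` across a reference panel
#' (smallest sum of squared differences), together with the panel mean and
#' standard deviation of the ratio `r_i = v_i / mean(v over ref(i))`. Scoring
#' a new sample against these within-sample references cancels sample-wide
#' biases that survive normalization. By default a bin's own chromosome is
#' excluded from its reference set so whole-chromosome events are not
#' self-normalized away.
#'
#' @slot grid the [BinGrid-class] the index is aligned to.
#' @slot usableIdx integer indices (into the grid) of the scored bins.
#' @slot refIdx integer matrix, `k` rows, one column per scored bin; entries
#'   index into `usableIdx` space.
#' @slot mu,sigma panel mean and sd of the reference ratio per scored bin
#'   (`sigma` floored at `1e-4 * mu`).
#' @slot k number of reference bins per bin.
#' @slot panelSize number of panel samples used.
#' @slot excludeSameChrom whether same-chromosome bins were excluded.
#'
#' @seealso [buildReferenceIndex()], [scoreBins()]
#' @export
setClass("ReferenceIndex",
  representation(
    grid = "BinGrid",
    usableIdx = "integer",
    refIdx = "matrix",
    mu = "numeric",
    sigma = "numeric",
    k = "integer",
    panelSize = "integer",
    excludeSameChrom = "logical"
  )
)

setValidity("ReferenceIndex", function(object) {
  msg <- character()
  nb <- length(object@usableIdx)
  if (ncol(object@refIdx) != nb)
    msg <- c(msg, "refIdx must have one column per scored bin")
  if (nrow(object@refIdx) != object@k)
    msg <- c(msg, "refIdx must have k rows")
  if (length(object@mu) != nb || length(object@sigma) != nb)
    msg <- c(msg, "mu and sigma must have one entry per scored bin")
  if (any(object@sigma <= 0))
    msg <- c(msg, "sigma must be positive (floored)")
  if (nb > 0 && any(object@refIdx == rep(seq_len(nb), each = nrow(object@refIdx))))
    msg <- c(msg, "a bin must not reference itself")
  if (length(msg)) msg else TRUE
})

#' Individual and windowed z-score tracks for one sample
#'
#' Per usable bin, the individual z-score of the sample's reference ratio
#' against the panel, and the Stouffer combination of those z-scores over a
#' centered window truncated at chromosome ends (windows never span
#' chromosomes).
#'
#' @slot sampleId sample identifier.
#' @slot grid the [BinGrid-class].
#' @slot usableIdx integer indices (into the grid) of scored bins.
#' @slot z individual per-bin z-scores.
#' @slot zWindowed Stouffer-windowed z-scores (NA until [windowedScores()]).
#' @slot window window width in bins (odd; `NA_integer_` until windowed).
#'
#' @seealso [scoreBins()], [windowedScores()], [callSegments()]
#' @export
setClass("ZProfile",
  representation(
    sampleId = "character",
    grid = "BinGrid",
    usableIdx = "integer",
    z = "numeric",
    zWindowed = "numeric",
    window = "integer"
  )
)

setValidity("ZProfile", function(object) {
  msg <- character()
  n <- length(object@usableIdx)
  if (length(object@z) != n || length(object@zWindowed) != n)
    msg <- c(msg, "z tracks must have one entry per scored bin")
  if (any(!is.finite(object@z)))
    msg <- c(msg, "individual z-scores must be finite")
  if (length(msg)) msg else TRUE
})

#' Recurrent arm-level CNV catalog
#'
#' Records of (chromosome arm, direction, q-value, population frequency)
#' describing recurrent arm-level copy-number changes in a tumor type. Used
#' to classify called segments as highly specific (q < 0.25 and frequency
#' > 0.5), moderately specific (q < 0.25, frequency <= 0.5) or non-specific.
#'
#' @slot table data.frame with columns `arm`, `direction` (`gain`/`loss`),
#'   `q_value` (>= 0) and `frequency` (in `[0,1]`); `(arm, direction)` pairs
#'   unique.
#'
#' @seealso [loadCatalog()], [defaultCatalog()], [annotateSegments()]
#' @export
setClass("CNVCatalog", representation(table = "data.frame"))

setValidity("CNVCatalog", function(object) {
  tab <- object@table
  msg <- character()
  need <- c("arm", "direction", "q_value", "frequency")
  if (!all(need %in% colnames(tab)))
    return(paste("catalog must have columns", paste(need, collapse = ", ")))
  if (nrow(tab)) {
    if (!all(tab$direction %in% c("gain", "loss")))
      msg <- c(msg, "direction must be 'gain' or 'loss'")
    if (any(tab$q_value < 0))
      msg <- c(msg, "q_value must be >= 0")
    if (any(tab$frequency < 0 | tab$frequency > 1))
      msg <- c(msg, "frequency must lie in [0, 1]")
    if (anyDuplicated(tab[, c("arm", "direction")]))
      msg <- c(msg, "(arm, direction) pairs must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Simulation parameters for synthetic cfDNA cohorts
#'
#' Defines the count model the synthetic-cohort generator draws from: total
#' reads per sample uniform on `[readsMin, readsMax]`; a per-sample linear GC
#' bias factor `1 + slope * (gc - gcRef)` with `slope ~ Normal(0, gcSlopeSd^2)`,
#' floored at `gcFloor`; fixed per-grid log-normal bin baseline weights
#' (`sd = baselineSd` on the log scale); and negative-binomial counts with
#' dispersion `dispersion` (variance `mu + mu^2/dispersion`).
#'
#' @slot readsMin,readsMax bounds of the uniform total-read draw.
#' @slot gcSlopeSd sd of the per-sample GC bias slope.
#' @slot gcRef GC fraction at which the bias factor is 1.
#' @slot gcFloor lower floor for the GC bias factor.
#' @slot baselineSd sd of the per-bin log baseline weight.
#' @slot dispersion negative-binomial size parameter.
#' @slot baselineSeed seed fixing the per-grid baseline weights.
#'
#' @seealso [simParams()], [simulatePanel()], [simulateCase()]
#' @export
setClass("SimParams",
  representation(
    readsMin = "numeric",
    readsMax = "numeric",
    gcSlopeSd = "numeric",
    gcRef = "numeric",
    gcFloor = "numeric",
    baselineSd = "numeric",
    dispersion = "numeric",
    baselineSeed = "integer"
  )
)

setValidity("SimParams", function(object) {
  msg <- character()
  if (object@readsMin <= 0 || object@readsMax < object@readsMin)
    msg <- c(msg, "need 0 < readsMin <= readsMax")
  if (object@dispersion <= 0)
    msg <- c(msg, "dispersion must be > 0")
  if (object@gcFloor <= 0)
    msg <- c(msg, "gcFloor must be > 0 (expected counts must stay positive)")
  if (length(msg)) msg else TRUE
})

#' Ground-truth copy-number profile for one simulated case
#'
#' A tumor fraction plus a list of non-overlapping copy-number events
#' (arm-level events spanning a full p or q arm, or focal events of a few
#' Mb), each with an integer copy number in `{0, 1, 3, 4}` and a provenance
#' tag (`catalog` or `focal`).
#'
#' @slot tumorFraction fraction of plasma DNA of tumor origin, in `[0,1]`.
#' @slot events data.frame with columns `chrom`, `start`, `end`, `copy`,
#'   `origin`.
#'
#' @seealso [drawTumorProfile()], [simulateCase()]
#' @export
setClass("TruthProfile",
  representation(
    tumorFraction = "numeric",
    events = "data.frame"
  )
)

setValidity("TruthProfile", function(object) {
  msg <- character()
  if (object@tumorFraction < 0 || object@tumorFraction > 1)
    msg <- c(msg, "tumorFraction must lie in [0, 1]")
  ev <- object@events
  need <- c("chrom", "start", "end", "copy", "origin")
  if (!all(need %in% colnames(ev)))
    return(paste("events must have columns", paste(need, collapse = ", ")))
  if (nrow(ev)) {
    if (!all(ev$copy %in% c(0, 1, 3, 4)))
      msg <- c(msg, "event copy numbers must be in {0, 1, 3, 4}")
    if (any(ev$end <= ev$start))
      msg <- c(msg, "events must have end > start")
    sp <- split(ev, ev$chrom)
    for (d in sp) {
      d <- d[order(d$start), ]
      if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)]))
        msg <- c(msg, "events must not overlap")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Per-subject cancer screen decision
#'
#' The prespecified screen rule: a subject is screen positive iff at least
#' one called segment is at least `minSizeMb` (default 15 Mb) in size.
#'
#' @slot sampleId subject identifier.
#' @slot status `"positive"` or `"negative"`.
#' @slot segments all called segments (`GRanges`).
#' @slot qualifying the subset meeting the size rule.
#' @slot minSizeMb the size threshold applied, in Mb.
#'
#' @seealso [applySizeRule()]
#' @export
setClass("ScreenCall",
  representation(
    sampleId = "character",
    status = "character",
    segments = "GRanges",
    qualifying = "GRanges",
    minSizeMb = "numeric"
  )
)

setValidity("ScreenCall", function(object) {
  msg <- character()
  if (!object@status %in% c("positive", "negative"))
    msg <- c(msg, "status must be 'positive' or 'negative'")
  if ((length(object@qualifying) > 0) != (object@status == "positive"))
    msg <- c(msg, "status must be positive iff at least one qualifying segment")
  if (length(msg)) msg else TRUE
})

#' NIPT-style whole-chromosome aneuploidy screen result
#'
#' Per-target (13, 18, 21, X) chromosome read fraction and z-score against a
#' reference panel, plus the sample-level status. A sample is `no_call` when
#' any non-target autosome deviates beyond the QC threshold — the situation
#' the routine prenatal pipeline reports as a normalizing-chromosome failure;
#' calls are only present when the status is `reported`.
#'
#' @slot sampleId sample identifier.
#' @slot status `"reported"` or `"no_call"`.
#' @slot reason human-readable no-call reason (empty when reported).
#' @slot fractions named per-chromosome read fractions.
#' @slot z named per-chromosome z-scores.
#' @slot calls named per-target calls (`low_risk`, `high_risk_gain`,
#'   `high_risk_loss`); empty when `no_call`.
#' @slot labels named per-target labels (e.g. `"monosomy 18"`) for
#'   high-risk calls.
#'
#' @seealso [ncvScores()], [classifyAneuploidy()]
#' @export
setClass("AneuploidyResult",
  representation(
    sampleId = "character",
    status = "character",
    reason = "character",
    fractions = "numeric",
    z = "numeric",
    calls = "character",
    labels = "character"
  )
)

setValidity("AneuploidyResult", function(object) {
  msg <- character()
  if (!object@status %in% c("reported", "no_call"))
    msg <- c(msg, "status must be 'reported' or 'no_call'")
  if (object@status == "no_call" && length(object@calls) > 0)
    msg <- c(msg, "calls must be absent when status is no_call")
  if (length(msg)) msg else TRUE
})
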