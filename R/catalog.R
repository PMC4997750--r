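#' Construct a CNV catalog
#'
#' @param arm chromosome arm identifiers (e.g. `"8q"`).
#' @param direction `"gain"` or `"loss"` per record.
#' @param q_value statistical significance (FDR q-value) per record.
#' @param frequency fraction of tumors carrying the event, in `[0,1]`.
#' @return a [CNVCatalog-class].
#' @export
CNVCatalog <- function(arm = character(), direction = character(),
                       q_value = numeric(), frequency = numeric()) {
  new("CNVCatalog", table = data.frame(
    arm = as.character(arm), direction = as.character(direction),
    q_value = as.numeric(q_value), frequency = as.numeric(frequency),
    stringsAsFactors = FALSE
  ))
}

#' Load a recurrent-CNV catalog from a TSV file
#'
#' Expects tab-separated columns `arm`, `direction`, `q_value`, `frequency`.
#' Duplicate `(arm, direction)` pairs and frequencies outside `[0,1]` are
#' rejected; an empty file yields an empty catalog (annotation then labels
#' every segment non-specific).
#'
#' @param path file path.
#' @return a validated [CNVCatalog-class].
#' @seealso [defaultCatalog()], [annotateSegments()]
#' @export
loadCatalog <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = c(arm = "character"))
  need <- c("arm", "direction", "q_value", "frequency")
  if (!all(need %in% colnames(tab)))
    stop("catalog file must have columns: ", paste(need, collapse = ", "))
  cat <- CNVCatalog(tab$arm, tab$direction, tab$q_value, tab$frequency)
  methods::validObject(cat)
  cat
}

#' The bundled recurrent HGSOC CNV catalog (synthetic q/frequency values)
#'
#' Arm-level gains and losses recurrent in high-grade serous ovarian
#' carcinoma: 8 gained arms (5 at > 50 % tumor frequency) and 22 lost arms
#' (18 at > 50 %), matching the summary counts of the tumor-genome-atlas
#' arm analysis this screen annotates against. The q-values and frequencies
#' are synthetic placeholders consistent with those summary counts — the
#' source study's exact per-arm numbers are not redistributed here — and the
#' file (`inst/extdata/hgsoc_cnv_catalog_synthetic.tsv`) is user-editable.
#'
#' @return a [CNVCatalog-class] with 30 records.
#' @examples
#' defaultCatalog()
#' @export
defaultCatalog <- function() {
  loadCatalog(system.file("extdata", "hgsoc_cnv_catalog_synthetic.tsv",
                          package = "cfScreen", mustWork = TRUE))
}
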