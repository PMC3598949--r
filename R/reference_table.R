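#' Packaged reference compression table for a child mandible model
#'
#' The 64 published relative compression percentages for the eight
#' unerupted teeth (canines, first and second premolars, second molars,
#' both sides) of a CT-derived child-mandible finite element model: one
#' value per (side, load mode, basis, cap, tooth). The `percent` column is
#' the relative percentage of cap volume (basis `volume`) or of summated
#' |BRU| (basis `bru`) under compression; `mark` preserves the printed
#' exception annotations. The underlying anatomical mesh is not
#' redistributable, so these percentages are packaged as data: the
#' exception classifier runs on this table exactly as it runs on
#' pipeline-computed summaries.
#'
#' @return Data frame with columns `side`, `load`, `basis`, `cap`, `tooth`,
#'   `percent`, `mark` (64 rows).
#' @examples
#' tab <- reference_compression_table()
#' classify_exceptions(tab, basis = "volume")
#' @export
reference_compression_table <- function() {
  path <- system.file("extdata", "reference_mandible_compression.csv",
                      package = "eruptsim", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(percent = "numeric"))
  tab$mark[is.na(tab$mark)] <- ""
  tab
}
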