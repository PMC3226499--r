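#' Paths to packaged example data
#'
#' Small curated plain-text tables shipped with the package:
#' \describe{
#'   \item{`vascular_targets_ac50.csv`}{AC50 activity (uM) of 14 screening
#'     chemicals against seven biochemical targets critical to vascular
#'     development (VEGFR1/2/3, TIE2, EphB2, PI3Ka, PTEN); blanks are
#'     inactive.}
#'   \item{`vascular_targets_vbs.csv`}{The curated vascular bioactivity
#'     score of those chemicals and whether they were classified pVDC.}
#'   \item{`vascular_targets_annotations.csv`}{Assay annotations for the
#'     seven biochemical targets.}
#'   \item{`reference_compounds_activity.csv`}{LEC/AC50 activity of the
#'     antiangiogenic reference compounds thalidomide and 5HPP-33 across the
#'     six vascular target features.}
#'   \item{`reference_compounds_annotations.csv`}{Annotations mapping those
#'     assays to the default VBS target features.}
#'   \item{`reference_compounds_vbs.csv`}{Curated VBS of the reference
#'     compounds.}
#'   \item{`rabbit_specific_endpoints.csv`, `rat_specific_endpoints.csv`}{
#'     Prenatal developmental endpoint categories recorded for pVDCs with
#'     rabbit-only (22 chemicals) or rat-only (21) effects.}
#' }
#'
#' @param file File name, or `NULL` to list the available files.
#' @return A file path (or a character vector of file names).
#' @export
#' @examples
#' m <- read_potency_matrix(pvdc_extdata("vascular_targets_ac50.csv"))
#' filter_hits(m, threshold = 20)
pvdc_extdata <- function(file = NULL) {
  if (is.null(file))
    return(list.files(system.file("extdata", package = "pvdc")))
  path <- system.file("extdata", file, package = "pvdc")
  if (!nzchar(path)) stop("no packaged file called ", file, call. = FALSE)
  path
}
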