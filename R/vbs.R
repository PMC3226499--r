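#' Configuration for the vascular bioactivity score
#'
#' The VBS is a weighted sum of per-target unit scores, with targets listed
#' in order of descending influence on embryonic vascular development. The
#' default panel is down-regulation of VEGFR2, inhibition of TIE2,
#' down-regulation of the proangiogenic chemokine CCL2, perturbation of
#' PAI-1 (plasminogen-activating system), up-regulation of the antiangiogenic
#' chemokine CXCL10, and perturbation of uPAR, with weights 6..1.
#'
#' @param targets Ordered character vector of target feature ids.
#' @param weights Strictly positive weights, non-increasing in list order
#'   (descending influence).
#' @param c_inactive Inactive sentinel concentration, uM (default 1e6).
#' @param c_floor Saturating floor concentration, uM (default 1e-3): any
#'   potency at or below the floor scores 1.
#' @param aggregation How to combine multiple assays mapped to one target
#'   feature: `"max"` (default; most potent assay wins) or `"mean"`.
#' @return A `vbs_config` list.
#' @export
vbs_config <- function(targets = c("VEGFR2_down", "TIE2_inhib", "CCL2_down",
                                   "PAI1_updown", "CXCL10_up", "uPAR_updown"),
                       weights = c(6, 5, 4, 3, 2, 1),
                       c_inactive = 1e6, c_floor = 1e-3,
                       aggregation = c("max", "mean")) {
  aggregation <- match.arg(aggregation)
  if (length(targets) < 1 || length(weights) != length(targets))
    stop("`weights` must match `targets` in length", call. = FALSE)
  if (any(weights <= 0)) stop("weights must be strictly positive", call. = FALSE)
  if (is.unsorted(rev(weights)))
    stop("weights must be non-increasing (descending influence)", call. = FALSE)
  if (!(c_floor > 0 && c_floor < c_inactive))
    stop("c_floor must lie in (0, c_inactive)", call. = FALSE)
  structure(list(targets = targets, weights = setNames(weights, targets),
                 c_inactive = c_inactive, c_floor = c_floor,
                 aggregation = aggregation),
            class = "vbs_config")
}

#' Unit score of a single potency value
#'
#' Log-transformed, floor-normalized potency on the unit interval:
#' `clip(log10(c_inactive / potency) / log10(c_inactive / c_floor), 0, 1)`.
#' The inactive sentinel maps to 0 and the floor concentration to 1; more
#' potent (lower) concentrations score higher.
#'
#' @param potency Micromolar potency (vectorized); must be > 0.
#' @param config A [vbs_config()].
#' @return Scores in \[0, 1\].
#' @export
#' @examples
#' assay_unit_score(1)      # 6/9
#' assay_unit_score(1e6)    # inactive -> 0
assay_unit_score <- function(potency, config = vbs_config()) {
  if (any(!is.finite(potency) | potency <= 0))
    stop("potency must be strictly positive", call. = FALSE)
  s <- log10(config$c_inactive / potency) /
    log10(config$c_inactive / config$c_floor)
  pmin(pmax(s, 0), 1)
}

# Map each configured target feature to its assay columns; errors when a
# target has no mapped assay in the annotations/matrix intersection.
target_assay_map <- function(m, annotations, config) {
  ann_idx <- match(norm_id(colnames(m)), norm_id(annotations$assay_id))
  feat <- annotations$target_feature[ann_idx]
  lapply(setNames(config$targets, config$targets), function(tg) {
    cols <- which(!is.na(feat) & norm_id(feat) == norm_id(tg))
    if (length(cols) == 0)
      stop("no assay mapped to target feature '", tg, "'", call. = FALSE)
    cols
  })
}

#' Vascular bioactivity scores for all chemicals
#'
#' For each chemical, every configured target feature gets a unit score by
#' aggregating (max or mean) the [assay_unit_score()] of its mapped assays;
#' the VBS is the weighted sum of target scores. Chemicals are ranked by
#' VBS descending with alphabetical tie-breaking, and classified as pVDC
#' against the mean-VBS cutoff (see [classify_pvdc()]).
#'
#' @param m A [potency_matrix()].
#' @param annotations Annotation data.frame (see [read_annotations()]) whose
#'   `target_feature` column maps assays to the configured targets.
#' @param config A [vbs_config()].
#' @param cutoff Optional explicit pVDC cutoff; default is the mean VBS.
#' @return A `vbs_result` data.frame with columns `chemical`, one unit-score
#'   column per target, `vbs`, `is_pvdc` and `rank`.
#' @export
vbs_scores <- function(m, annotations, config = vbs_config(), cutoff = NULL) {
  stopifnot(inherits(m, "potency_matrix"))
  amap <- target_assay_map(m, annotations, config)
  scores <- sapply(config$targets, function(tg) {
    sub <- unclass(m)[, amap[[tg]], drop = FALSE]
    u <- matrix(assay_unit_score(sub, config), nrow = nrow(sub))
    if (config$aggregation == "max") apply(u, 1, max) else rowMeans(u)
  })
  scores <- matrix(scores, nrow = nrow(m),
                   dimnames = list(rownames(m), config$targets))
  vbs <- as.numeric(scores %*% config$weights)
  ord <- order(-vbs, rownames(m))
  rank <- integer(nrow(m))
  rank[ord] <- seq_len(nrow(m))
  out <- data.frame(chemical = rownames(m), scores, vbs = vbs,
                    is_pvdc = classify_pvdc(vbs, cutoff = cutoff),
                    rank = rank,
                    check.names = FALSE, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "config") <- config
  class(out) <- c("vbs_result", "data.frame")
  out
}

#' Classify chemicals as putative vascular disruptors
#'
#' The default cutoff is the arithmetic mean VBS over all chemicals scored;
#' classification is inclusive (`vbs >= cutoff`), so a chemical sitting
#' exactly at the mean is a pVDC.
#'
#' @param vbs Numeric vector of VBS values, or a `vbs_result` data.frame.
#' @param cutoff Optional explicit cutoff; when `NULL`, the mean of `vbs`.
#' @return Logical vector, `TRUE` for pVDC.
#' @export
classify_pvdc <- function(vbs, cutoff = NULL) {
  if (is.data.frame(vbs)) vbs <- vbs$vbs
  if (length(vbs) == 0 && is.null(cutoff))
    stop("no scores and no explicit cutoff", call. = FALSE)
  if (is.null(cutoff)) cutoff <- mean(vbs)
  vbs >= cutoff
}
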