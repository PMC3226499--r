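#' Inactive-chemical sentinel concentration
#'
#' Inactive chemical-assay pairs are encoded as 1 M = 1e6 uM, the
#' conventional default for HTS potency tables where no AC50/LEC could be
#' derived. The sentinel is excluded from all hit counts and potency means.
#'
#' @return The sentinel concentration in micromolar (1e6).
#' @export
inactive_sentinel <- function() 1e6

#' Construct a chemical-by-assay potency matrix
#'
#' Wraps a numeric matrix of micromolar potencies (AC50 or LEC) with
#' validation: all values must be strictly positive and no larger than the
#' inactive sentinel of 1e6 uM. Rows are chemicals, columns assays.
#'
#' @param values Numeric matrix; rownames are chemical ids, colnames assay ids.
#' @param provenance Optional free-text description of the data source.
#' @return A `potency_matrix` object (a classed numeric matrix).
#' @export
#' @examples
#' m <- potency_matrix(matrix(c(5, 1e6, 0.5, 1e6), 2, 2,
#'   dimnames = list(c("chemA", "chemB"), c("assay1", "assay2"))))
#' filter_hits(m, threshold = 1)
potency_matrix <- function(values, provenance = "") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) && nrow(values) > 0)
    stop("rownames (chemical ids) are required", call. = FALSE)
  if (is.null(colnames(values)))
    stop("colnames (assay ids) are required", call. = FALSE)
  if (anyDuplicated(norm_id(rownames(values))))
    stop("duplicate chemical id: ",
         rownames(values)[duplicated(norm_id(rownames(values)))][1],
         call. = FALSE)
  if (anyDuplicated(norm_id(colnames(values))))
    stop("duplicate assay id", call. = FALSE)
  bad <- which(!is.finite(values) | values <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("nonpositive or nonnumeric potency at chemical '%s', assay '%s'",
                 rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]),
         call. = FALSE)
  if (any(values > inactive_sentinel()))
    stop("potency values above the 1e6 uM inactive sentinel", call. = FALSE)
  structure(values, class = c("potency_matrix", class(values)),
            provenance = provenance)
}

#' @export
print.potency_matrix <- function(x, ...) {
  cat(sprintf("<potency_matrix> %d chemicals x %d assays, %d active values\n",
              nrow(x), ncol(x), sum(x < inactive_sentinel())))
  invisible(x)
}

#' Read an assay annotation table
#'
#' The annotation table maps each assay to its platform, cell system, gene
#' symbol, target feature (the unit scored in the vascular bioactivity
#' score, e.g. `"CCL2_down"`), regulation direction and potency measure.
#'
#' @param path Delimited text file (comma for `.csv`, tab otherwise) with
#'   columns `assay_id`, `platform`, `cell_system`, `gene_symbol`,
#'   `target_feature`, `direction` (up/down/updown/na), `measure` (AC50/LEC).
#' @return A data.frame of annotations, one row per assay.
#' @export
read_annotations <- function(path) {
  df <- read_table_auto(path, colClasses = "character")
  need <- c("assay_id", "platform", "cell_system", "gene_symbol",
            "target_feature", "direction", "measure")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("annotation table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- df[, need]
  if (anyDuplicated(norm_id(df$assay_id)))
    stop("duplicate assay_id in annotations", call. = FALSE)
  if (!all(norm_id(df$direction) %in% c("up", "down", "updown", "na")))
    stop("direction must be one of up/down/updown/na", call. = FALSE)
  if (!all(toupper(trimws(df$measure)) %in% c("AC50", "LEC")))
    stop("measure must be AC50 or LEC", call. = FALSE)
  df$direction <- norm_id(df$direction)
  df$measure <- toupper(trimws(df$measure))
  df
}

#' Read a chemical-by-assay potency matrix from delimited text
#'
#' The file has a header row of assay ids, a first column of chemical ids,
#' and micromolar potencies in the body; blank cells mean "inactive" and are
#' mapped to the 1e6 uM sentinel.
#'
#' @param path Delimited text file (comma for `.csv`, tab otherwise).
#' @param annotations Optional annotation data.frame from
#'   [read_annotations()]; assays absent from it trigger a warning.
#' @param units Units of the stored values: `"uM"` (default) or `"M"`
#'   (converted to micromolar on read).
#' @return A [potency_matrix()].
#' @export
read_potency_matrix <- function(path, annotations = NULL,
                                units = c("uM", "M")) {
  units <- match.arg(units)
  df <- read_table_auto(path, colClasses = "character")
  if (ncol(df) < 1) stop("no columns in ", path, call. = FALSE)
  chems <- trimws(df[[1]])
  dup <- duplicated(norm_id(chems))
  if (any(dup))
    stop("duplicate chemical id: ", chems[dup][1], call. = FALSE)
  assays <- names(df)[-1]
  vals <- matrix(inactive_sentinel(), nrow = nrow(df), ncol = length(assays),
                 dimnames = list(chems, assays))
  for (j in seq_along(assays)) {
    raw <- trimws(df[[j + 1]])
    filled <- !is.na(raw) & raw != ""
    num <- suppressWarnings(as.numeric(raw[filled]))
    bad <- which(is.na(num) | num <= 0)
    if (length(bad) > 0)
      stop(sprintf("nonpositive or nonnumeric potency '%s' at chemical '%s', assay '%s'",
                   raw[filled][bad[1]], chems[filled][bad[1]], assays[j]),
           call. = FALSE)
    vals[filled, j] <- if (units == "M") num * 1e6 else num
  }
  if (!is.null(annotations)) {
    unknown <- setdiff(norm_id(assays), norm_id(annotations$assay_id))
    if (length(unknown) > 0)
      warning("assays not present in annotations: ",
              paste(unknown, collapse = ", "), call. = FALSE)
  }
  potency_matrix(vals, provenance = path)
}

#' Write a potency matrix to delimited text
#'
#' Sentinel (inactive) cells are written as blanks; active potencies are
#' written with 17 significant digits so a write/read round trip reproduces
#' the matrix bit-exactly.
#'
#' @param m A [potency_matrix()].
#' @param path Output file; `.csv` writes comma-separated, otherwise tabs.
#' @return `path`, invisibly.
#' @export
write_potency_matrix <- function(m, path) {
  stopifnot(inherits(m, "potency_matrix"))
  cells <- matrix("", nrow(m), ncol(m))
  active <- m < inactive_sentinel()
  cells[active] <- sprintf("%.17g", m[active])
  out <- data.frame(chemical = rownames(m), cells, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(out) <- c("chemical", colnames(m))
  write.table(out, path, sep = table_sep(path), row.names = FALSE,
              quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Subset a potency matrix by chemical id
#'
#' Matching is case-insensitive after whitespace trimming; the returned rows
#' follow the order of `chemicals`.
#'
#' @param m A [potency_matrix()].
#' @param chemicals Character vector of chemical ids.
#' @return A [potency_matrix()] restricted to the requested chemicals.
#' @export
subset_chemicals <- function(m, chemicals) {
  stopifnot(inherits(m, "potency_matrix"))
  idx <- match(norm_id(chemicals), norm_id(rownames(m)))
  if (anyNA(idx))
    stop("chemical not found: ", chemicals[is.na(idx)][1], call. = FALSE)
  potency_matrix(unclass(m)[idx, , drop = FALSE],
                 provenance = attr(m, "provenance"))
}

#' Summarize hits in a potency matrix
#'
#' A (chemical, assay) pair is a hit iff its value is below the 1e6 uM
#' inactive sentinel. The mean potency is the arithmetic mean over hit
#' values only; `n_at_or_below` counts hits at or below `threshold`
#' (inclusive).
#'
#' @param m A [potency_matrix()].
#' @param threshold Cutoff in micromolar, in (0, 1e6].
#' @return A `hit_summary` list with `n_hits`, `mean_potency` (NA when there
#'   are no hits), `n_at_or_below`, `threshold` and `per_chemical_hits`.
#' @export
filter_hits <- function(m, threshold = 20) {
  stopifnot(inherits(m, "potency_matrix"))
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > inactive_sentinel())
    stop("threshold must be in (0, 1e6] uM", call. = FALSE)
  hits <- unclass(m) < inactive_sentinel()
  hit_vals <- unclass(m)[hits]
  structure(list(
    n_hits = sum(hits),
    mean_potency = if (length(hit_vals) > 0) mean(hit_vals) else NA_real_,
    n_at_or_below = sum(hit_vals <= threshold),
    threshold = threshold,
    per_chemical_hits = setNames(as.integer(rowSums(hits)), rownames(m))
  ), class = "hit_summary")
}

#' @export
print.hit_summary <- function(x, ...) {
  cat(sprintf("<hit_summary> %d hits, mean potency %s uM, %d at or below %g uM\n",
              x$n_hits,
              if (is.na(x$mean_potency)) "NA" else format(x$mean_potency),
              x$n_at_or_below, x$threshold))
  invisible(x)
}

#' Chemicals with a minimum number of hits
#'
#' @param m A [potency_matrix()].
#' @param k Minimum number of non-sentinel values required (>= 1).
#' @return Chemical ids with at least `k` hits, in matrix row order.
#' @export
chemicals_with_min_hits <- function(m, k = 1) {
  stopifnot(inherits(m, "potency_matrix"))
  if (!is.numeric(k) || length(k) != 1 || k < 1)
    stop("k must be >= 1", call. = FALSE)
  rownames(m)[rowSums(unclass(m) < inactive_sentinel()) >= k]
}
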