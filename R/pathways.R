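#' Construct a pathway gene-set collection
#'
#' @param ids Character vector of pathway ids (unique).
#' @param genes List of character vectors of gene symbols, one per pathway;
#'   nonempty, no duplicates within a pathway.
#' @param source Character vector of source tags (e.g. "GO:Process", "KEGG",
#'   "IPA"); recycled if length 1.
#' @return A `pathway_set` object.
#' @export
pathway_set <- function(ids, genes, source = "") {
  if (length(ids) != length(genes))
    stop("`ids` and `genes` must have equal length", call. = FALSE)
  if (anyDuplicated(ids)) stop("duplicate pathway id", call. = FALSE)
  source <- rep_len(as.character(source), length(ids))
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    if (length(g) == 0) stop("empty gene set in pathway ", ids[i], call. = FALSE)
    if (anyDuplicated(norm_id(g)))
      stop("duplicate gene within pathway ", ids[i], call. = FALSE)
  }
  structure(list(ids = as.character(ids), source = source,
                 genes = setNames(genes, ids)),
            class = "pathway_set")
}

#' @export
print.pathway_set <- function(x, ...) {
  cat(sprintf("<pathway_set> %d pathways, %d-%d genes each\n",
              length(x$ids),
              min(lengths(x$genes)), max(lengths(x$genes))))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT: pathway id, description (kept as the source
#' tag, e.g. a GO/KEGG/IPA label), then gene symbols.
#'
#' @param path GMT file.
#' @return A [pathway_set()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(parts) < 3
  if (any(short))
    stop("GMT line ", which(short)[1], " has fewer than 3 fields", call. = FALSE)
  pathway_set(ids = vapply(parts, `[[`, "", 1),
              genes = lapply(parts, function(p) unique(trimws(p[-(1:2)]))),
              source = vapply(parts, `[[`, "", 2))
}

#' Write gene sets to a GMT file
#'
#' @param pathways A [pathway_set()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(pathways, path) {
  stopifnot(inherits(pathways, "pathway_set"))
  lines <- vapply(seq_along(pathways$ids), function(i) {
    paste(c(pathways$ids[i], pathways$source[i], pathways$genes[[i]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Chemical-pathway perturbation score
#'
#' A chemical perturbs a pathway when it is active (AC50 or LEC below the
#' sentinel) against at least `min_targets` distinct gene symbols whose
#' assays map into the pathway; the score is then the minimum potency over
#' all hits on pathway-mapped assays, otherwise undefined (NA).
#'
#' @param m A [potency_matrix()].
#' @param chemical Chemical id (matched case-insensitively).
#' @param annotations Annotation data.frame mapping assays to gene symbols.
#' @param genes Character vector of the pathway's gene symbols.
#' @param min_targets Minimum distinct active genes required (default 5).
#' @return List with `n_active_targets` and `score` (uM or NA).
#' @export
perturbation_score <- function(m, chemical, annotations, genes,
                               min_targets = 5) {
  stopifnot(inherits(m, "potency_matrix"))
  if (!is.numeric(min_targets) || min_targets < 1)
    stop("min_targets must be >= 1", call. = FALSE)
  row <- match(norm_id(chemical), norm_id(rownames(m)))
  if (is.na(row)) stop("chemical not found: ", chemical, call. = FALSE)
  ann_idx <- match(norm_id(colnames(m)), norm_id(annotations$assay_id))
  gene_of_assay <- norm_id(annotations$gene_symbol[ann_idx])
  in_path <- !is.na(gene_of_assay) & gene_of_assay %in% norm_id(genes)
  vals <- unclass(m)[row, in_path]
  hit <- vals < inactive_sentinel()
  n_active <- length(unique(gene_of_assay[in_path][hit]))
  list(n_active_targets = n_active,
       score = if (n_active >= min_targets) min(vals[hit]) else NA_real_)
}

#' Score all chemicals against all pathways
#'
#' @param m A [potency_matrix()].
#' @param annotations Annotation data.frame (see [read_annotations()]).
#' @param pathways A [pathway_set()].
#' @param min_targets Minimum distinct active genes required (default 5).
#' @return Data.frame with one row per (chemical, pathway): `chemical`,
#'   `pathway`, `source`, `n_active_targets`, `score` (NA when undefined).
#'   Annotation gene symbols absent from every pathway are reported via
#'   `message()`, not an error.
#' @export
score_pathways <- function(m, annotations, pathways, min_targets = 5) {
  stopifnot(inherits(m, "potency_matrix"), inherits(pathways, "pathway_set"))
  all_genes <- norm_id(unique(unlist(pathways$genes)))
  orphan <- setdiff(norm_id(unique(annotations$gene_symbol)), all_genes)
  orphan <- orphan[nzchar(orphan)]
  if (length(orphan) > 0)
    message("gene symbols absent from all pathways: ",
            paste(orphan, collapse = ", "))
  grid <- expand.grid(chemical = rownames(m), p = seq_along(pathways$ids),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    ps <- perturbation_score(m, grid$chemical[i], annotations,
                             pathways$genes[[grid$p[i]]], min_targets)
    data.frame(chemical = grid$chemical[i],
               pathway = pathways$ids[grid$p[i]],
               source = pathways$source[grid$p[i]],
               n_active_targets = ps$n_active_targets,
               score = ps$score, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
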