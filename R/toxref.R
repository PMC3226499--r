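#' Controlled vocabulary of prenatal developmental endpoint categories
#'
#' Categories follow the aggregated endpoint style of regulatory prenatal
#' guideline studies in rat and rabbit: direct embryo/fetal outcomes,
#' pregnancy-related maternal loss, and defect categories qualified by
#' subtype after a colon (e.g. `"skeletal: axial"`).
#'
#' @return Character vector of valid category strings.
#' @export
endpoint_vocabulary <- function() {
  c("embryo fetal loss",
    "maternal pregnancy loss",
    "fetal weight reduction",
    "general fetal pathology",
    "skeletal: axial",
    "skeletal: appendicular",
    "skeletal: cranial",
    "urogenital: renal",
    "urogenital: ureteric",
    "neurosensory: eye",
    "trunk: body wall")
}

# Validate a raw endpoint data.frame into one record per (row, category).
# `line` carries the source line number for error messages.
validate_endpoints <- function(df, vocabulary, lines = NULL) {
  need <- c("chemical", "species", "category", "lel")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("endpoint table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  lines <- lines %||% seq_len(nrow(df)) + 1L
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    sp <- norm_id(df$species[i])
    if (!sp %in% c("rat", "rabbit"))
      stop(sprintf("line %d: unknown species '%s'", lines[i], df$species[i]),
           call. = FALSE)
    cats <- trimws(strsplit(as.character(df$category[i]), ";", fixed = TRUE)[[1]])
    cats <- cats[nzchar(cats)]
    idx <- match(norm_id(cats), norm_id(vocabulary))
    if (anyNA(idx))
      stop(sprintf("line %d: unknown category '%s'", lines[i],
                   cats[is.na(idx)][1]), call. = FALSE)
    lel <- suppressWarnings(as.numeric(df$lel[i]))
    if (!is.na(df$lel[i]) && nzchar(trimws(as.character(df$lel[i]))) &&
        (is.na(lel) || lel <= 0))
      stop(sprintf("line %d: lel must be a positive dose (mg/kg/day)", lines[i]),
           call. = FALSE)
    if (length(cats) > 0)
      out[[i]] <- data.frame(chemical = trimws(df$chemical[i]), species = sp,
                             category = vocabulary[idx], lel = lel,
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chemical = character(0), species = character(0),
                      category = character(0), lel = numeric(0),
                      stringsAsFactors = FALSE)
  res
}

#' Load prenatal developmental endpoint records
#'
#' Reads a delimited table with header `chemical,species,category,lel`.
#' Multiple categories per row are separated by `";"`. Species must be
#' `rat` or `rabbit`; categories must match the controlled vocabulary
#' exactly (punctuation included, case and whitespace normalized); `lel`
#' (lowest effect level, mg/kg/day) may be blank.
#'
#' @param path Delimited text file (comma for `.csv`, tab otherwise).
#' @param vocabulary Allowed category strings; extend beyond
#'   [endpoint_vocabulary()] to accept additional aggregated endpoints.
#' @return Data.frame of endpoint records, one row per (chemical-row,
#'   category).
#' @export
load_endpoints <- function(path, vocabulary = endpoint_vocabulary()) {
  df <- read_table_auto(path, colClasses = "character")
  validate_endpoints(df, vocabulary)
}

#' Species-specific positive and negative chemical sets
#'
#' A chemical is developmental-toxicity positive in a species iff it has at
#' least one endpoint record for that species in the counted categories.
#' Species-only positives are positive in one species and negative in the
#' other; the negatives for each contrast are the remainder of the tested
#' universe.
#'
#' @param records Endpoint record data.frame (see [load_endpoints()]).
#' @param universe Chemicals tested in both species; records for chemicals
#'   outside the universe are excluded with a `message()`.
#' @param include_maternal Count `"maternal pregnancy loss"` (pregnancy-
#'   related fetal wastage, possibly maternally mediated) as developmental
#'   toxicity (default `TRUE`); `FALSE` restricts to direct embryo/fetal
#'   categories.
#' @return A `species_label_set` list: `tested_both`, `rabbit_only_pos`,
#'   `rat_only_pos`, `rabbit_negatives`, `rat_negatives`.
#' @export
species_specific_sets <- function(records, universe, include_maternal = TRUE) {
  if (length(universe) == 0) stop("universe must be nonempty", call. = FALSE)
  universe <- universe[!duplicated(norm_id(universe))]
  cats <- endpoint_vocabulary()
  extra <- setdiff(unique(records$category), cats)
  cats <- c(cats, extra)
  if (!include_maternal) cats <- setdiff(cats, "maternal pregnancy loss")
  keep <- match(norm_id(records$chemical), norm_id(universe))
  if (anyNA(keep))
    message("excluding records for chemicals outside the universe: ",
            paste(unique(records$chemical[is.na(keep)]), collapse = ", "))
  rec <- records[!is.na(keep) & records$category %in% cats, , drop = FALSE]
  chem <- universe[keep[!is.na(keep) & records$category %in% cats]]
  pos_in <- function(sp) unique(chem[rec$species == sp])
  pos_rabbit <- pos_in("rabbit")
  pos_rat <- pos_in("rat")
  rabbit_only <- setdiff(pos_rabbit, pos_rat)
  rat_only <- setdiff(pos_rat, pos_rabbit)
  structure(list(tested_both = universe,
                 rabbit_only_pos = rabbit_only,
                 rat_only_pos = rat_only,
                 rabbit_negatives = setdiff(universe, rabbit_only),
                 rat_negatives = setdiff(universe, rat_only)),
            class = "species_label_set")
}

#' @export
print.species_label_set <- function(x, ...) {
  cat(sprintf("<species_label_set> %d tested in both species: %d rabbit-only, %d rat-only positives\n",
              length(x$tested_both), length(x$rabbit_only_pos),
              length(x$rat_only_pos)))
  invisible(x)
}

#' Prevalence of a phenotype category group
#'
#' Counts chemicals (not records) having at least one endpoint record whose
#' category falls in `categories`; repeated categories for one chemical
#' count once.
#'
#' @param records Endpoint record data.frame.
#' @param categories Nonempty character vector of category strings.
#' @param chemicals The chemical set over which prevalence is computed;
#'   default: all chemicals appearing in `records`.
#' @return List with `count`, `n` (set size), `fraction` and `percent`
#'   (rounded to whole percent).
#' @export
phenotype_prevalence <- function(records, categories, chemicals = NULL) {
  if (length(categories) == 0)
    stop("category list must be nonempty", call. = FALSE)
  chemicals <- chemicals %||% unique(records$chemical)
  chemicals <- chemicals[!duplicated(norm_id(chemicals))]
  if (length(chemicals) == 0) stop("chemical set is empty", call. = FALSE)
  hit <- records$category %in% categories &
    norm_id(records$chemical) %in% norm_id(chemicals)
  count <- length(unique(norm_id(records$chemical[hit])))
  list(count = count, n = length(chemicals),
       fraction = count / length(chemicals),
       percent = round(100 * count / length(chemicals)))
}
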