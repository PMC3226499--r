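#' Read an abstract corpus
#'
#' Either a one-record-per-line tab-separated file (`doc_id TAB text`) or a
#' directory of `.txt` files (file name without extension as the doc id).
#'
#' @param path File or directory.
#' @return Data.frame with columns `doc_id` and `text`; ids are unique.
#' @export
read_corpus <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    df <- data.frame(
      doc_id = sub("\\.txt$", "", basename(files)),
      text = vapply(files, function(f)
        paste(readLines(f, encoding = "UTF-8", warn = FALSE),
              collapse = " "), ""),
      stringsAsFactors = FALSE, row.names = NULL)
  } else {
    if (!file.exists(path)) stop("corpus not found: ", path, call. = FALSE)
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    tab <- regexpr("\t", lines, fixed = TRUE)
    if (any(tab < 0))
      stop("corpus line without a tab separator: line ",
           which(tab < 0)[1], call. = FALSE)
    df <- data.frame(doc_id = substr(lines, 1, tab - 1),
                     text = substring(lines, tab + 1),
                     stringsAsFactors = FALSE)
  }
  if (anyDuplicated(df$doc_id)) stop("duplicate doc id", call. = FALSE)
  df
}

# Normalize text for matching: case-fold and collapse hyphens/whitespace
# runs to single spaces, so "PAI-1", "PAI 1" and "pai-1" coincide.
norm_text <- function(x) tolower(gsub("[-\\s]+", " ", x, perl = TRUE))

# Does each document mention any of `terms` (literal, word-boundary)?
# \b is only anchored against word characters, so terms that start or end
# with punctuation are matched without a boundary on that side.
docs_matching <- function(texts, terms) {
  terms <- norm_text(terms)
  pats <- paste0(ifelse(grepl("^\\w", terms), "\\b", ""),
                 regex_escape(terms),
                 ifelse(grepl("\\w$", terms), "\\b", ""))
  pat <- paste0("(", paste(pats, collapse = ")|("), ")")
  grepl(pat, norm_text(texts), perl = TRUE)
}

#' Filter a corpus to documents mentioning any keyword
#'
#' Matching is case-insensitive with word boundaries; keywords are treated
#' literally (regex metacharacters escaped), and hyphen/whitespace runs are
#' normalized to single spaces on both sides.
#'
#' @param corpus Data.frame from [read_corpus()].
#' @param keywords Nonempty character vector.
#' @return The matching subset of `corpus`.
#' @export
filter_corpus <- function(corpus, keywords) {
  if (length(keywords) == 0) stop("keyword list must be nonempty",
                                  call. = FALSE)
  corpus[docs_matching(corpus$text, keywords), , drop = FALSE]
}

#' Read a target synonym table
#'
#' Tab-separated lines `target TAB synonym TAB synonym ...`; multiple lines
#' for one target accumulate. No synonym may map to two targets.
#'
#' @param path Synonym file.
#' @return Named list mapping target id to its synonym vector.
#' @export
read_synonyms <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tab <- list()
  for (p in parts) {
    if (length(p) < 2)
      stop("synonym line needs a target and at least one synonym",
           call. = FALSE)
    tab[[p[1]]] <- c(tab[[p[1]]], trimws(p[-1]))
  }
  syn_table(tab)
}

#' Validate a synonym table
#'
#' @param synonyms Named list mapping target id to a nonempty character
#'   vector of synonyms; after normalization no synonym may belong to two
#'   targets.
#' @return The validated list.
#' @export
syn_table <- function(synonyms) {
  if (is.null(names(synonyms)) || any(!nzchar(names(synonyms))))
    stop("synonym table must be a named list", call. = FALSE)
  if (any(lengths(synonyms) == 0))
    stop("every target needs at least one synonym", call. = FALSE)
  all_syn <- norm_text(unlist(synonyms, use.names = FALSE))
  if (anyDuplicated(all_syn)) {
    dup <- all_syn[duplicated(all_syn)][1]
    stop("synonym '", dup, "' maps to more than one target", call. = FALSE)
  }
  synonyms
}

#' Rank targets by document co-occurrence
#'
#' For each target, counts the documents mentioning at least one of its
#' synonyms (document-level counting: several synonyms or repeats within
#' one abstract count once). Targets are ordered by descending count, ties
#' broken alphabetically.
#'
#' @param corpus Data.frame from [read_corpus()] (typically pre-filtered to
#'   the topic of interest with [filter_corpus()]).
#' @param synonyms Named list from [read_synonyms()]/[syn_table()].
#' @return Data.frame with columns `target` and `n_docs`, ranked.
#' @export
rank_targets <- function(corpus, synonyms) {
  synonyms <- syn_table(synonyms)
  counts <- vapply(synonyms, function(s)
    sum(docs_matching(corpus$text, s)), integer(1))
  ord <- order(-counts, names(counts))
  data.frame(target = names(counts)[ord], n_docs = unname(counts[ord]),
             stringsAsFactors = FALSE, row.names = NULL)
}
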