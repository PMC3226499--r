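# Internal helpers shared across modules.

# Identifiers are matched case-insensitively after collapsing internal
# whitespace; the original spelling is preserved everywhere it is shown.
norm_id <- function(x) tolower(gsub("\\s+", " ", trimws(as.character(x))))

# Run code with a fixed RNG state, restoring the caller's stream afterwards
# so library functions never perturb user-level reproducibility.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Delimiter by extension: .csv -> comma, anything else (.tsv, .txt) -> tab.
table_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

read_table_auto <- function(path, colClasses = NA) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  read.csv(path, sep = table_sep(path), check.names = FALSE,
           stringsAsFactors = FALSE, colClasses = colClasses,
           fileEncoding = "UTF-8")
}

# Escape regex metacharacters so user-supplied keywords match literally.
regex_escape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

`%||%` <- function(a, b) if (is.null(a)) b else a
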