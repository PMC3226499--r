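#' ToxPi-style radial profiles from VBS results
#'
#' Each target feature becomes a slice whose angular width is proportional
#' to its weight and whose radial value is the chemical's unit score
#' normalized by the maximum score any chemical attains on that target
#' (0 when the slice is all-zero). Profiles are ordered by VBS descending,
#' ties broken alphabetically by chemical id.
#'
#' @param results A `vbs_result` data.frame from [vbs_scores()].
#' @param config The [vbs_config()] used; defaults to the one attached to
#'   `results`.
#' @return A `toxpi_profiles` object: list with `chemicals` (ordered),
#'   `vbs`, `slices` (chemicals x targets matrix of normalized values in
#'   \[0,1\]) and `fractions` (angular weight fractions summing to 1).
#' @export
toxpi_profiles <- function(results, config = NULL) {
  config <- config %||% attr(results, "config")
  if (is.null(config)) stop("a vbs_config is required", call. = FALSE)
  if (nrow(results) < 1) stop("at least one chemical is required", call. = FALSE)
  ord <- order(-results$vbs, results$chemical)
  scores <- as.matrix(results[ord, config$targets, drop = FALSE])
  rownames(scores) <- results$chemical[ord]
  mx <- apply(scores, 2, max)
  slices <- sweep(scores, 2, ifelse(mx > 0, mx, 1), "/")
  structure(list(chemicals = results$chemical[ord],
                 vbs = results$vbs[ord],
                 slices = slices,
                 fractions = config$weights / sum(config$weights)),
            class = "toxpi_profiles")
}

#' @export
print.toxpi_profiles <- function(x, ...) {
  cat(sprintf("<toxpi_profiles> %d chemicals x %d slices\n",
              length(x$chemicals), length(x$fractions)))
  invisible(x)
}

# Draw one radial profile on the current device. Slices start at 12 o'clock
# and run clockwise in target order; wedge radius is the slice value.
draw_toxpi <- function(values, fractions, label = "", cols = NULL) {
  k <- length(fractions)
  cols <- cols %||% grDevices::hcl.colors(k, "Dark 3")
  plot.new()
  plot.window(c(-1.1, 1.1), c(-1.25, 1.1), asp = 1)
  bounds <- pi / 2 - 2 * pi * cumsum(c(0, fractions))
  for (i in seq_len(k)) {
    th <- seq(bounds[i], bounds[i + 1], length.out = 64)
    r <- values[i]
    polygon(c(0, r * cos(th)), c(0, r * sin(th)), col = cols[i],
            border = "grey30", lwd = 0.5)
    th_out <- seq(bounds[i], bounds[i + 1], length.out = 64)
    lines(cos(th_out), sin(th_out), col = "grey70", lwd = 0.5)
  }
  if (nzchar(label)) text(0, -1.2, label, cex = 0.8)
  invisible(NULL)
}

#' Render ToxPi profiles to image files
#'
#' Writes one radial chart per chemical plus a grid sheet of the top-ranked
#' profiles. Layout is deterministic given the profile ordering.
#'
#' @param profiles A [toxpi_profiles()] object.
#' @param out_dir Output directory (created if needed); must be writable.
#' @param top Number of profiles on the grid sheet (default: all, capped at
#'   the number of chemicals).
#' @param width,height Size of each single-chemical chart in pixels.
#' @return Character vector of the files written, invisibly.
#' @export
render_toxpi <- function(profiles, out_dir, top = NULL,
                         width = 480, height = 480) {
  stopifnot(inherits(profiles, "toxpi_profiles"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2) != 0)
    stop("output directory is not writable: ", out_dir, call. = FALSE)
  files <- character(0)
  for (i in seq_along(profiles$chemicals)) {
    chem <- profiles$chemicals[i]
    f <- file.path(out_dir, paste0(gsub("[^A-Za-z0-9._-]+", "_", chem), ".png"))
    png(f, width = width, height = height)
    par(mar = c(0, 0, 2, 0))
    draw_toxpi(profiles$slices[i, ], profiles$fractions, label = chem)
    title(sprintf("%s (VBS %.2f)", chem, profiles$vbs[i]), cex.main = 0.9)
    dev.off()
    files <- c(files, f)
  }
  top <- min(top %||% length(profiles$chemicals), length(profiles$chemicals))
  ncolg <- ceiling(sqrt(top))
  nrowg <- ceiling(top / ncolg)
  grid_file <- file.path(out_dir, "toxpi_grid.png")
  png(grid_file, width = 180 * ncolg, height = 200 * nrowg)
  par(mfrow = c(nrowg, ncolg), mar = c(0, 0, 1, 0))
  for (i in seq_len(top)) {
    draw_toxpi(profiles$slices[i, ], profiles$fractions,
               label = profiles$chemicals[i])
  }
  dev.off()
  invisible(c(files, grid_file))
}
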