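#' Bin sequence lengths for a histogram
#'
#' Builds the binned specification for one of the four length-distribution
#' plots (above/below cutoff, linear/log count axis). Bins cover
#' `[min(lengths), max(lengths)]` and conserve the total count. The bin rule:
#' width-1 bins centred on each integer when the length range spans at most
#' 100 distinct values (readable at peptide scale), otherwise 50 equal-width
#' bins (transcript scale). An empty input yields a spec flagged as not
#' renderable.
#'
#' @param lengths integer vector of sequence lengths (may be empty).
#' @param scale `"linear"` or `"log"`; for `"log"` the count axis is drawn
#'   logarithmic (base 10). Zero-count bins are kept in the spec either way.
#' @param side `"above"` or `"below"`; selects the title wording
#'   ("above {cutoff-1} {unit}" / "below {cutoff} {unit}").
#' @param unit length unit label, `"bp"` or `"aa"`.
#' @param cutoff the partition cutoff, used only for labelling.
#' @return an object of class `hist_spec`: list with `bin_edges`
#'   (ascending, one more than the number of bins), `bin_counts`, `scale`,
#'   `side`, `unit`, `cutoff`, `title`, `xlab`, `ylab`, and `renderable`.
#' @export
build_histogram <- function(lengths, scale = c("linear", "log"),
                            side = c("above", "below"),
                            unit = c("bp", "aa"), cutoff = 200L) {
  scale <- match.arg(scale)
  side <- match.arg(side)
  unit <- match.arg(unit)
  cutoff <- as.integer(cutoff)
  side_label <- if (side == "above") {
    sprintf("above %d %s", cutoff - 1L, unit)
  } else {
    sprintf("below %d %s", cutoff, unit)
  }
  title <- sprintf("Sequence length distribution %s%s", side_label,
                   if (scale == "log") " (log scale)" else "")
  spec <- list(
    bin_edges = numeric(0), bin_counts = integer(0),
    scale = scale, side = side, unit = unit, cutoff = cutoff,
    title = title,
    xlab = sprintf("Sequence length (%s)", unit),
    ylab = if (scale == "log") "Count (log10 scale)" else "Count",
    renderable = FALSE
  )
  if (length(lengths) == 0L) {
    class(spec) <- "hist_spec"
    return(spec)
  }
  lo <- min(lengths)
  hi <- max(lengths)
  if (hi - lo + 1L <= 100L) {
    edges <- seq(lo - 0.5, hi + 0.5, by = 1)
  } else {
    edges <- seq(lo, hi, length.out = 51L)
  }
  # bins are [e_i, e_{i+1}) with the last bin closed on the right
  idx <- findInterval(lengths, edges, rightmost.closed = TRUE)
  spec$bin_edges <- edges
  spec$bin_counts <- tabulate(idx, nbins = length(edges) - 1L)
  spec$renderable <- TRUE
  class(spec) <- "hist_spec"
  spec
}

#' @export
print.hist_spec <- function(x, ...) {
  cat(sprintf("<hist_spec> %s: %d bin(s), %d sequence(s)%s\n",
              x$title, length(x$bin_counts), sum(x$bin_counts),
              if (x$renderable) "" else " [not renderable]"))
  invisible(x)
}

# Known display backends, matching the CLI contract. All off-screen
# rendering uses the png device regardless; the backend only selects how an
# interactive window is attempted when show = TRUE.
slp_backends <- c("TkAgg", "MacOSX", "Agg")

draw_hist <- function(spec) {
  edges <- spec$bin_edges
  counts <- spec$bin_counts
  nb <- length(counts)
  xlim <- range(edges)
  if (spec$scale == "log") {
    top <- max(counts)
    # floor just below 1 so single-count bars remain visible on a log axis
    base <- 0.8
    graphics::plot(NA, xlim = xlim, ylim = c(base, top * 1.1), log = "y",
                   xlab = spec$xlab, ylab = spec$ylab, main = spec$title)
    pos <- counts > 0L
    graphics::rect(edges[-(nb + 1L)][pos], base, edges[-1L][pos],
                   counts[pos], col = "steelblue", border = "grey30")
  } else {
    graphics::plot(NA, xlim = xlim, ylim = c(0, max(counts) * 1.05),
                   xlab = spec$xlab, ylab = spec$ylab, main = spec$title)
    graphics::rect(edges[-(nb + 1L)], 0, edges[-1L], counts,
                   col = "steelblue", border = "grey30")
  }
  invisible(NULL)
}

#' Render a histogram specification to a PNG file
#'
#' Writes the plot described by a [build_histogram()] spec to `out_path`
#' using an off-screen PNG device, so no display is required (safe inside
#' pipelines). A not-renderable spec (empty partition side) is skipped with
#' a warning and no file is produced. When `show = TRUE` the plot is
#' additionally displayed on an interactive device selected by `backend`;
#' failure to open a display degrades to a warning.
#'
#' @param spec a `hist_spec` object.
#' @param out_path destination PNG path; the directory must exist.
#' @param show logical; also display the plot interactively.
#' @param backend display backend identifier; one of `"TkAgg"` (default,
#'   Linux/Windows), `"MacOSX"` (macOS) or `"Agg"` (never interactive).
#'   Unknown identifiers raise a configuration error.
#' @return (invisibly) `out_path`, or `NULL` when the spec was skipped.
#' @export
render_plot <- function(spec, out_path, show = FALSE, backend = "TkAgg") {
  if (!backend %in% slp_backends) {
    stop_config(sprintf(
      "unknown plotting backend '%s' (available: %s)",
      backend, paste(slp_backends, collapse = ", ")))
  }
  if (!isTRUE(spec$renderable)) {
    warning(sprintf("no sequences %s %d %s: skipping plot '%s'",
                    spec$side, if (spec$side == "above") spec$cutoff - 1L
                    else spec$cutoff,
                    spec$unit, basename(out_path)),
            call. = FALSE)
    return(invisible(NULL))
  }
  grDevices::png(out_path, width = 900, height = 650, res = 100)
  ok <- tryCatch({ draw_hist(spec); TRUE },
                 finally = grDevices::dev.off())
  if (isTRUE(show) && backend != "Agg") {
    tryCatch({
      grDevices::dev.new()
      draw_hist(spec)
    }, error = function(e) {
      warning(sprintf("could not open an interactive display (%s): %s",
                      backend, conditionMessage(e)), call. = FALSE)
    })
  }
  invisible(out_path)
}
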