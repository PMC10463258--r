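#' Four-channel chromatogram trace
#'
#' Container for a (possibly mixed) capillary sequencing trace: per-scan
#' amplitudes for the four dye channels plus the called peak positions.
#' Scan coordinates are 0-based.
#'
#' @param channel_data Numeric matrix, one row per scan, columns named
#'   `A`, `C`, `G`, `T`; all amplitudes non-negative.
#' @param peak_positions 0-based scan indices of the called peaks, one per
#'   base, strictly increasing. May be `NULL` if peaks are to be detected
#'   with [detect_peaks()].
#' @param base_calls Optional called-base string with one character per
#'   peak.
#'
#' @return An object of class `"chromatogram"`.
#' @seealso [simulate_trace()], [read_trace()], [fit_trace_mixture()]
#' @export
chromatogram <- function(channel_data, peak_positions = NULL,
                         base_calls = NULL) {
  channel_data <- as.matrix(channel_data)
  if (is.null(colnames(channel_data)) && ncol(channel_data) == 4)
    colnames(channel_data) <- c("A", "C", "G", "T")
  stopifnot(identical(colnames(channel_data), c("A", "C", "G", "T")),
            all(channel_data >= 0))
  if (!is.null(peak_positions)) {
    stopifnot(is.numeric(peak_positions))
    if (length(peak_positions) > 1 && any(diff(peak_positions) <= 0))
      stop("peak_positions must be strictly increasing")
    if (any(peak_positions < 0 | peak_positions > nrow(channel_data) - 1))
      stop("peak_positions out of scan range")
  }
  if (!is.null(base_calls)) {
    stopifnot(is.character(base_calls), length(base_calls) == 1)
    if (nchar(base_calls) != length(peak_positions))
      stop("base_calls length must match the number of peaks")
  }
  structure(list(channel_data = channel_data,
                 peak_positions = peak_positions,
                 base_calls = base_calls),
            class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat("Chromatogram:", nrow(x$channel_data), "scans,",
      if (is.null(x$peak_positions)) "no called peaks"
      else paste(length(x$peak_positions), "called peaks"), "\n")
  if (!is.null(x$base_calls)) cat("  calls:", x$base_calls, "\n")
  invisible(x)
}

#' Plot a chromatogram trace
#'
#' Draws the four channel signals with conventional colours (A green,
#' C blue, G black, T red) and tick marks at called peak positions.
#'
#' @param x A [chromatogram()].
#' @param scans Optional range of scan indices to display.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.chromatogram <- function(x, scans = NULL, ...) {
  cols <- c(A = "forestgreen", C = "blue", G = "black", T = "red")
  m <- x$channel_data
  sc <- 0:(nrow(m) - 1)
  if (!is.null(scans)) {
    keep <- sc >= min(scans) & sc <= max(scans)
    m <- m[keep, , drop = FALSE]
    sc <- sc[keep]
  }
  graphics::matplot(sc, m, type = "l", lty = 1, col = cols,
                    xlab = "scan", ylab = "amplitude", ...)
  if (!is.null(x$peak_positions)) {
    pp <- x$peak_positions
    if (!is.null(scans)) pp <- pp[pp >= min(scans) & pp <= max(scans)]
    graphics::axis(3, at = pp, labels = FALSE, tcl = -0.25)
  }
  graphics::legend("topright", legend = names(cols), col = cols,
                   lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}

#' 1-D gel lane intensity profile
#'
#' @param positions Strictly increasing pixel indices.
#' @param intensities Non-negative intensities, same length.
#' @return An object of class `"lane_profile"`.
#' @seealso [simulate_lane()], [quantify_bands()]
#' @export
lane_profile <- function(positions, intensities) {
  stopifnot(is.numeric(positions), is.numeric(intensities),
            length(positions) == length(intensities))
  if (length(positions) > 1 && any(diff(positions) <= 0))
    stop("positions must be strictly increasing")
  if (any(intensities < 0))
    stop("intensities must be non-negative")
  structure(list(positions = as.numeric(positions),
                 intensities = as.numeric(intensities)),
            class = "lane_profile")
}

#' @export
print.lane_profile <- function(x, ...) {
  cat("Lane profile:", length(x$positions), "pixels, intensity range [",
      signif(min(x$intensities), 4), ",", signif(max(x$intensities), 4),
      "]\n")
  invisible(x)
}

#' @export
plot.lane_profile <- function(x, ...) {
  graphics::plot(x$positions, x$intensities, type = "l",
                 xlab = "lane position (px)", ylab = "intensity", ...)
  invisible(x)
}
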