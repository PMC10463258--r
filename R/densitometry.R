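#' Subtract background from a lane profile
#'
#' `method = "linear"` subtracts the straight line through the mean of the
#' first and last 5% of positions (a flat or tilted baseline, as drawn by
#' hand in interactive densitometry). `method = "rolling_min"` subtracts a
#' running minimum over a sliding window, following the profile's local
#' baseline. Negative values after subtraction are clipped to zero.
#'
#' @param profile A [lane_profile()].
#' @param method `"linear"` or `"rolling_min"`.
#' @param window Window width in pixels for `"rolling_min"`; must be
#'   positive and smaller than the profile length.
#' @return A background-subtracted [lane_profile()].
#' @export
subtract_background <- function(profile, method = c("linear", "rolling_min"),
                                window = 50L) {
  method <- match.arg(method)
  stopifnot(inherits(profile, "lane_profile"))
  y <- profile$intensities
  x <- profile$positions
  n <- length(y)
  if (method == "linear") {
    k <- max(1L, floor(0.05 * n))
    head_idx <- seq_len(k)
    tail_idx <- (n - k + 1L):n
    x1 <- mean(x[head_idx]); y1 <- mean(y[head_idx])
    x2 <- mean(x[tail_idx]); y2 <- mean(y[tail_idx])
    base <- if (x2 == x1) rep(y1, n) else y1 + (y2 - y1) * (x - x1) / (x2 - x1)
  } else {
    if (window <= 0) stop("window must be positive")
    if (window >= n) stop("window must be smaller than the profile length")
    half <- floor(window / 2)
    base <- vapply(seq_len(n), function(i)
      min(y[max(1L, i - half):min(n, i + half)]), numeric(1))
  }
  lane_profile(x, pmax(y - base, 0))
}

#' Locate and integrate gel bands
#'
#' For each labelled band, finds the local maximum of the profile nearest
#' its expected centre within `tolerance` pixels, estimates the band
#' half-width from the half-maximum crossings (linear interpolation on both
#' flanks), and integrates the intensity by the trapezoidal rule over
#' centre plus/minus three half-widths. A label with no local maximum in
#' tolerance gets volume 0 (band absent). Two labels resolving to the same
#' maximum are assigned to the nearer expected centre; an exact tie is an
#' error.
#'
#' @param profile A background-subtracted [lane_profile()].
#' @param expected_centers Named numeric vector of expected band centres in
#'   pixels (e.g. `c(long = 213, short = 241)`), inside the profile range.
#' @param tolerance Maximum distance (pixels) between expected centre and
#'   the matched local maximum.
#' @return A data frame of class `"band_table"` with columns `label`,
#'   `center` (pixel of the matched maximum, `NA` if absent), `sigma`
#'   (half-width / sqrt(2 log 2), `NA` if absent), and `volume`.
#' @export
#' @examples
#' lp <- simulate_lane(c(long = 312, short = 688), c(long = 542, short = 500),
#'                     gel_params(noise_sd = 0, background_level = 0))
#' ctr <- default_migration(c(long = 542, short = 500))
#' quantify_bands(lp, ctr)
quantify_bands <- function(profile, expected_centers, tolerance = 10) {
  stopifnot(inherits(profile, "lane_profile"),
            is.numeric(expected_centers), !is.null(names(expected_centers)))
  x <- profile$positions
  y <- profile$intensities
  n <- length(y)
  if (any(expected_centers < min(x) | expected_centers > max(x)))
    stop("expected band centre outside the profile range")
  i <- 2:(n - 1)
  maxima <- i[y[i] > y[i - 1] & y[i] >= y[i + 1]]

  assigned <- rep(NA_integer_, length(expected_centers))
  for (b in seq_along(expected_centers)) {
    if (length(maxima) == 0) next
    d <- abs(x[maxima] - expected_centers[b])
    if (min(d) <= tolerance) assigned[b] <- maxima[which.min(d)]
  }
  # resolve two labels claiming the same maximum
  dup <- which(!is.na(assigned) & duplicated(assigned))
  for (m in unique(assigned[dup])) {
    claim <- which(assigned == m)
    d <- abs(expected_centers[claim] - x[m])
    if (sum(d == min(d)) > 1)
      stop("bands ", paste(names(expected_centers)[claim], collapse = ", "),
           " are equidistant from the same maximum")
    assigned[claim[-which.min(d)]] <- NA_integer_
  }

  res <- data.frame(label = names(expected_centers),
                    center = NA_real_, sigma = NA_real_, volume = 0,
                    stringsAsFactors = FALSE)
  for (b in seq_along(expected_centers)) {
    m <- assigned[b]
    if (is.na(m)) next
    half <- y[m] / 2
    # half-maximum crossings, linearly interpolated
    li <- m
    while (li > 1 && y[li - 1] > half) li <- li - 1
    left <- if (li == 1) x[1] else
      x[li - 1] + (x[li] - x[li - 1]) * (half - y[li - 1]) / (y[li] - y[li - 1])
    ri <- m
    while (ri < n && y[ri + 1] > half) ri <- ri + 1
    right <- if (ri == n) x[n] else
      x[ri] + (x[ri + 1] - x[ri]) * (half - y[ri]) / (y[ri + 1] - y[ri])
    hw <- (right - left) / 2
    lo <- x[m] - 3 * hw
    hi <- x[m] + 3 * hw
    keep <- which(x >= lo & x <= hi)
    vol <- if (length(keep) > 1)
      sum(diff(x[keep]) * (y[keep][-1] + y[keep][-length(keep)]) / 2) else 0
    res$center[b] <- x[m]
    res$sigma[b] <- hw / sqrt(2 * log(2))
    res$volume[b] <- vol
  }
  class(res) <- c("band_table", "data.frame")
  res
}

#' Fraction of the long fragment from band volumes
#'
#' `f_long = V(long) / (V(long) + V(short))`, the quantity densitometry of
#' the two RT-PCR bands reports. By default the ratio is taken on raw band
#' intensities, as standard gel quantification produces. With
#' `length_correction`, volumes are first divided by fragment length,
#' converting a mass-responsive stain signal to molar abundance (an
#' intercalating stain makes a 42-nt-longer fragment about 8% brighter per
#' molecule at these lengths; the correction removes that bias).
#'
#' @param bands A band table from [quantify_bands()] containing labels
#'   `long` and `short`.
#' @param length_correction Optional named numeric vector of fragment
#'   lengths (nt) for `long` and `short`.
#' @return The long-fragment fraction in `[0, 1]`.
#' @export
#' @examples
#' b <- data.frame(label = c("long", "short"), volume = c(312, 688))
#' long_fraction(b)                                    # 0.312
#' long_fraction(data.frame(label = c("long", "short"), volume = c(100, 100)),
#'               length_correction = c(long = 542, short = 500))
long_fraction <- function(bands, length_correction = NULL) {
  stopifnot(is.data.frame(bands), all(c("label", "volume") %in% names(bands)))
  if (!all(c("long", "short") %in% bands$label))
    stop("band table must contain labels 'long' and 'short'")
  v_long <- bands$volume[bands$label == "long"][1]
  v_short <- bands$volume[bands$label == "short"][1]
  if (!is.null(length_correction)) {
    stopifnot(all(c("long", "short") %in% names(length_correction)))
    v_long <- v_long / length_correction[["long"]]
    v_short <- v_short / length_correction[["short"]]
  }
  if (v_long + v_short == 0)
    stop("both band volumes are zero; fraction undefined")
  v_long / (v_long + v_short)
}

#' Reference-normalised expression
#'
#' Ratio of a target band volume to a loading-control band volume (e.g. a
#' GAPDH band in the same or a parallel lane), the standard readout for
#' relative total expression.
#'
#' @param target_volume Non-negative target band volume.
#' @param reference_volume Positive reference band volume.
#' @return `target_volume / reference_volume`.
#' @export
normalize_to_reference <- function(target_volume, reference_volume) {
  stopifnot(is.numeric(target_volume), is.numeric(reference_volume))
  if (any(reference_volume <= 0))
    stop("reference volume must be positive")
  target_volume / reference_volume
}
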