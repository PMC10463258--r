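#' Detect peaks in a four-channel trace
#'
#' Finds local maxima of the summed channel signal and greedily thins them,
#' in order of increasing scan position, so that consecutive peaks are at
#' least `0.6 * expected_spacing` apart (when two candidates are closer,
#' the lower scan index wins). Used when a trace file carries no peak
#' locations.
#'
#' @param channel_data Numeric scan-by-channel matrix (columns A, C, G, T).
#' @param expected_spacing Expected scan points per base.
#' @return 0-based peak scan positions, strictly increasing; empty for a
#'   flat signal.
#' @export
detect_peaks <- function(channel_data, expected_spacing) {
  channel_data <- as.matrix(channel_data)
  stopifnot(is.numeric(expected_spacing), expected_spacing > 0)
  if (nrow(channel_data) < 2 * expected_spacing)
    stop("trace too short for the expected peak spacing")
  s <- rowSums(channel_data)
  n <- length(s)
  i <- 2:(n - 1)
  # strict rise on the left, fall-or-plateau on the right: plateaus keep
  # their first scan, flat signal yields no maxima; boundary scans count
  # when the signal falls away from them
  is_max <- s[i] > s[i - 1] & s[i] >= s[i + 1]
  cand <- i[is_max] - 1L            # 0-based
  if (s[1] > s[2]) cand <- c(0L, cand)
  if (s[n] > s[n - 1]) cand <- c(cand, n - 1L)
  if (length(cand) == 0) return(numeric(0))
  keep <- cand[1]
  for (p in cand[-1])
    if (p - keep[length(keep)] >= 0.6 * expected_spacing) keep <- c(keep, p)
  as.numeric(keep)
}

#' Per-peak channel amplitude table
#'
#' Reads one amplitude per called peak and channel, over a window of half a
#' peak spacing on either side of the peak position. Where windows of
#' adjacent peaks overlap, each scan is assigned to its nearest peak (ties
#' to the lower peak index).
#'
#' Two readings are available. `method = "max"` is the classical visual
#' one: the maximum channel value in the window. Under per-scan noise this
#' is an order statistic and biases weak channels upward, so the default,
#' `method = "height"`, estimates the peak height by linear projection of
#' the windowed signal onto the trace's peak shape (a Gaussian of width
#' [estimate_peak_width()]): the two coincide on clean traces, but the
#' projection is unbiased under additive noise, and any error in the
#' assumed width cancels in between-channel ratios at the same peak
#' because all channels share one peak shape.
#'
#' @param trace A [chromatogram()] with `peak_positions` set.
#' @param spacing Scan points per base; inferred from the median
#'   peak-position difference when `NULL`.
#' @param method `"height"` (shape-fit peak height, default) or `"max"`
#'   (window maximum).
#' @param peak_width Peak shape SD in scans for `method = "height"`;
#'   estimated from the trace when `NULL`.
#' @return Numeric `n_peaks x 4` matrix with columns A, C, G, T
#'   (non-negative).
#' @export
extract_peak_amplitudes <- function(trace, spacing = NULL,
                                    method = c("height", "max"),
                                    peak_width = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(trace, "chromatogram"))
  pp <- trace$peak_positions
  if (is.null(pp) || length(pp) == 0)
    stop("trace has no peak positions; run detect_peaks() first")
  if (is.null(spacing))
    spacing <- if (length(pp) > 1) stats::median(diff(pp)) else
      nrow(trace$channel_data)
  if (method == "height" && is.null(peak_width))
    peak_width <- estimate_peak_width(trace, spacing)
  half <- spacing / 2
  n_scan <- nrow(trace$channel_data)
  out <- matrix(0, length(pp), 4,
                dimnames = list(NULL, c("A", "C", "G", "T")))
  for (k in seq_along(pp)) {
    lo <- ceiling(pp[k] - half)
    hi <- floor(pp[k] + half)
    if (k > 1) lo <- max(lo, floor((pp[k - 1] + pp[k]) / 2) + 1)
    if (k < length(pp)) hi <- min(hi, floor((pp[k] + pp[k + 1]) / 2))
    lo <- max(lo, 0); hi <- min(hi, n_scan - 1)
    if (lo > hi) next
    rows <- (lo:hi) + 1L
    y <- trace$channel_data[rows, , drop = FALSE]
    if (method == "max") {
      out[k, ] <- apply(y, 2, max)
    } else {
      w <- exp(-((lo:hi) - pp[k])^2 / (2 * peak_width^2))
      out[k, ] <- pmax(colSums(w * y) / sum(w * w), 0)
    }
  }
  out
}

#' Estimate the peak width of a trace
#'
#' Median, across called peaks, of the Gaussian SD obtained by fitting a
#' parabola to the log of the summed channel signal at the apex and its
#' two neighbouring scans (log-parabola interpolation, exact for a
#' Gaussian sampled on the scan grid); robust to per-scan noise through
#' the median.
#'
#' @param trace A [chromatogram()] with peak positions.
#' @param spacing Scan points per base (unused; kept for interface
#'   stability).
#' @return Peak SD in scan points.
#' @export
estimate_peak_width <- function(trace, spacing = NULL) {
  pp <- trace$peak_positions
  if (is.null(pp) || length(pp) == 0)
    stop("trace has no peak positions")
  s <- rowSums(trace$channel_data)
  n <- length(s)
  sd_est <- vapply(pp, function(p) {
    m <- round(p) + 1L
    if (m < 2 || m > n - 1) return(NA_real_)
    y <- s[(m - 1):(m + 1)]
    if (any(y <= 0)) return(NA_real_)
    curv <- log(y[1]) + log(y[3]) - 2 * log(y[2])  # = -1/sigma^2 for a Gaussian
    if (curv >= 0) return(NA_real_)
    sqrt(-1 / curv)
  }, numeric(1))
  sd_est <- sd_est[is.finite(sd_est)]
  if (length(sd_est) == 0) stop("could not estimate peak width")
  stats::median(sd_est)
}

#' Estimate the insertion-bearing fraction from a mixed chromatogram
#'
#' Fits a two-species mixture to a mixed Sanger trace of co-amplified
#' products that differ by a short insertion, returning the estimated
#' fraction of the insertion-bearing species.
#'
#' Two estimators are available. `method = "amplitude"` is the classical
#' peak-height reading: at each informative site (a read position where the
#' two species predict different bases, see [find_informative_sites()]),
#' the site fraction is `a(+) / (a(+) + a(-))`, the amplitude of the
#' insertion base's channel over the sum of the two predicted channels;
#' the reported fraction is the mean over sites (default three) with the
#' sample SD across sites. Because both channels at a site share the same
#' positional decay, the ratio cancels signal decay exactly. Sites where
#' both predicted channels read zero are dropped with a warning.
#'
#' `method = "lsq"` generalises this: per-peak channel amplitudes over a
#' window starting at the junction are normalised by their channel sum
#' (removing the per-peak scale) and the fraction minimising the summed
#' squared difference from `f * E(+) + (1 - f) * E(-)` is computed in
#' closed form and projected onto `[0, 1]`, where `E(+)`/`E(-)` are the
#' indicator templates of the two species' expected base channels.
#'
#' @param trace A [chromatogram()] with peak positions.
#' @param refs A [reference_pair()]; for reverse-primer reads pass
#'   `reverse_complement(refs)`.
#' @param method `"amplitude"` (peak-height ratio, the default) or `"lsq"`.
#' @param n_sites Number of informative sites for the amplitude method.
#' @param window Read positions scanned downstream of the junction.
#'
#' @return An object of class `"mixture_fit"` with components `fraction`
#'   (clamped to `[0, 1]`), `per_site_fractions`, `sd` (0 when a single
#'   site is used), `n_sites`, `method` (`"amplitude_ratio"` or
#'   `"least_squares"`), `sites`, and for the least-squares fit the
#'   normalised `observed`, `fitted` and `residuals` matrices. Supports
#'   [print()], [summary()], [coef()], [fitted()], [residuals()],
#'   [simulate()] and [plot()].
#' @export
#' @examples
#' rp <- default_serine_reference()
#' tr <- simulate_trace(0.25, rp, trace_params(noise_sd = 0, crosstalk = 0))
#' fit <- fit_trace_mixture(tr, rp)
#' coef(fit)
#' summary(fit_trace_mixture(tr, rp, method = "lsq"))
fit_trace_mixture <- function(trace, refs,
                              method = c("amplitude", "lsq"),
                              n_sites = 3L, window = 12L) {
  method <- match.arg(method)
  stopifnot(inherits(trace, "chromatogram"),
            inherits(refs, "reference_pair"))
  amps <- extract_peak_amplitudes(trace)
  if (method == "amplitude") {
    sites <- find_informative_sites(refs, n_sites = n_sites, window = window)
    if (nrow(sites) == 0)
      stop("no informative sites: species are indistinguishable in the window")
    fit <- amplitude_ratio_estimate(amps, sites)
    fit$refs <- refs
  } else {
    fit <- lsq_fraction(amps, refs, window)
    fit$refs <- refs
  }
  class(fit) <- "mixture_fit"
  fit
}

#' Amplitude-ratio mixture estimate from a peak table
#'
#' The classical three-nucleotide reading: at each informative site the
#' site fraction is `a(base_plus) / (a(base_plus) + a(base_minus))`, the
#' ratio using only the two predicted channels (insensitive to baseline in
#' the unrelated channels); the overall fraction is the mean across sites
#' with the sample SD. Because both channels at a site carry the same
#' positional signal decay, the ratio cancels decay exactly. Sites where
#' both predicted channels read zero are dropped with a warning; if all
#' sites are dropped this is an error.
#'
#' @param peak_table `n_peaks x 4` amplitude matrix from
#'   [extract_peak_amplitudes()] (columns A, C, G, T).
#' @param sites Data frame from [find_informative_sites()].
#' @return An object of class `"mixture_fit"` (without trace provenance);
#'   usually reached through [fit_trace_mixture()].
#' @export
#' @examples
#' tab <- matrix(c(0, 70, 30, 0), 1, dimnames = list(NULL, c("A","C","G","T")))
#' sites <- data.frame(peak_index = 0, base_plus = "G", base_minus = "C")
#' amplitude_ratio_estimate(tab, sites)$fraction  # 0.3
amplitude_ratio_estimate <- function(peak_table, sites) {
  stopifnot(is.matrix(peak_table), ncol(peak_table) == 4,
            is.data.frame(sites), nrow(sites) >= 1)
  if (any(sites$peak_index + 1L > nrow(peak_table)))
    stop("informative site beyond the last called peak")
  f_i <- numeric(0)
  kept <- logical(nrow(sites))
  for (j in seq_len(nrow(sites))) {
    row <- peak_table[sites$peak_index[j] + 1L, ]
    ap <- row[[sites$base_plus[j]]]
    am <- row[[sites$base_minus[j]]]
    if (ap + am == 0) {
      warning("informative site with zero amplitude in both channels dropped")
      next
    }
    kept[j] <- TRUE
    f_i <- c(f_i, ap / (ap + am))
  }
  if (length(f_i) == 0)
    stop("all informative sites had zero amplitude")
  f_i <- pmin(pmax(f_i, 0), 1)
  structure(list(fraction = min(max(mean(f_i), 0), 1),
                 per_site_fractions = f_i,
                 sd = if (length(f_i) > 1) stats::sd(f_i) else 0,
                 n_sites = length(f_i),
                 method = "amplitude_ratio",
                 sites = sites[kept, , drop = FALSE]),
            class = "mixture_fit")
}

# Closed-form projected least squares on per-peak normalised amplitudes.
lsq_fraction <- function(amps, refs, window) {
  long <- strsplit(long_sequence(refs), "")[[1]]
  short <- strsplit(refs$short_seq, "")[[1]]
  from <- refs$insert_offset
  to <- min(from + window - 1L, length(short) - 1L, nrow(amps) - 1L)
  if (to < from) stop("window covers no read positions")
  idx <- from:to
  bases <- c("A", "C", "G", "T")
  P <- t(vapply(long[idx + 1L], function(b) as.numeric(bases == b),
                numeric(4)))
  M <- t(vapply(short[idx + 1L], function(b) as.numeric(bases == b),
                numeric(4)))
  colnames(P) <- colnames(M) <- bases
  if (all(P == M))
    stop("unidentifiable: species templates are identical over the window")
  Y <- amps[idx + 1L, , drop = FALSE]
  sums <- rowSums(Y)
  ok <- sums > 0
  if (!any(ok)) stop("no usable peaks in the window (all amplitudes zero)")
  Yn <- Y[ok, , drop = FALSE] / sums[ok]
  D <- (P - M)[ok, , drop = FALSE]
  R <- Yn - M[ok, , drop = FALSE]
  denom <- sum(D * D)
  f <- min(max(sum(D * R) / denom, 0), 1)
  # per informative peak: the same projection restricted to that row
  inf_rows <- which(rowSums(D != 0) > 0)
  per_site <- vapply(inf_rows, function(r) {
    min(max(sum(D[r, ] * R[r, ]) / sum(D[r, ]^2), 0), 1)
  }, numeric(1))
  fitted <- f * P[ok, , drop = FALSE] + (1 - f) * M[ok, , drop = FALSE]
  site_idx <- idx[ok][inf_rows]
  list(fraction = f,
       per_site_fractions = per_site,
       sd = if (length(per_site) > 1) stats::sd(per_site) else 0,
       n_sites = length(per_site),
       method = "least_squares",
       sites = data.frame(peak_index = site_idx,
                          base_plus = long[site_idx + 1L],
                          base_minus = short[site_idx + 1L],
                          stringsAsFactors = FALSE),
       observed = Yn, fitted = fitted, residuals = Yn - fitted)
}

#' Brute-force grid search for the mixture fraction
#'
#' Independent reference estimator for [fit_trace_mixture()]'s least-squares
#' method: evaluates the same normalised-amplitude objective on an explicit
#' grid over `[0, 1]` and returns the minimising fraction. Self-contained
#' (recomputes peak amplitudes directly from the trace), so it serves as a
#' slow oracle against which the closed-form solution can be checked.
#'
#' @param trace A [chromatogram()] with peak positions.
#' @param refs A [reference_pair()].
#' @param window Read positions scanned downstream of the junction.
#' @param step Grid step (default `1e-3`).
#' @return The grid fraction with the smallest sum of squared residuals.
#' @export
grid_search_fraction <- function(trace, refs, window = 12L, step = 1e-3) {
  pp <- trace$peak_positions
  spacing <- if (length(pp) > 1) stats::median(diff(pp)) else
    nrow(trace$channel_data)
  sig <- estimate_peak_width(trace, spacing)
  long <- strsplit(long_sequence(refs), "")[[1]]
  short <- strsplit(refs$short_seq, "")[[1]]
  from <- refs$insert_offset
  to <- min(from + window - 1L, length(short) - 1L, length(pp) - 1L)
  bases <- c("A", "C", "G", "T")
  n_scan <- nrow(trace$channel_data)
  rows <- list()
  for (i in from:to) {
    lo <- max(ceiling(pp[i + 1L] - spacing / 2), 0)
    hi <- min(floor(pp[i + 1L] + spacing / 2), n_scan - 1)
    if (i > 0) lo <- max(lo, floor((pp[i] + pp[i + 1L]) / 2) + 1)
    if (i + 2L <= length(pp))
      hi <- min(hi, floor((pp[i + 1L] + pp[i + 2L]) / 2))
    w <- exp(-((lo:hi) - pp[i + 1L])^2 / (2 * sig^2))
    a <- pmax(colSums(w * trace$channel_data[(lo:hi) + 1L, , drop = FALSE]) /
                sum(w * w), 0)
    if (sum(a) == 0) next
    rows[[length(rows) + 1L]] <-
      list(y = a / sum(a),
           p = as.numeric(bases == long[i + 1L]),
           m = as.numeric(bases == short[i + 1L]))
  }
  grid <- seq(0, 1, by = step)
  sse <- vapply(grid, function(f) {
    sum(vapply(rows, function(r)
      sum((r$y - f * r$p - (1 - f) * r$m)^2), numeric(1)))
  }, numeric(1))
  grid[which.min(sse)]
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("Mixture fit (%s): insertion-bearing fraction = %.4f (sd %.4f, %d sites)\n",
              x$method, x$fraction, x$sd, x$n_sites))
  invisible(x)
}

#' @export
summary.mixture_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.mixture_fit")
}

#' @export
print.summary.mixture_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  tab <- cbind(f$sites, fraction = round(f$per_site_fractions, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.mixture_fit <- function(object, ...) c(fraction = object$fraction)

#' @export
fitted.mixture_fit <- function(object, ...) {
  if (!is.null(object$fitted)) object$fitted
  else rep(object$fraction, object$n_sites)
}

#' @export
residuals.mixture_fit <- function(object, ...) {
  if (!is.null(object$residuals)) object$residuals
  else object$per_site_fractions - object$fraction
}

#' Simulate traces from a fitted mixture
#'
#' Draws new synthetic chromatograms at the fitted insertion-bearing
#' fraction, using the fit's reference pair — a parametric-bootstrap-style
#' forward simulation.
#'
#' @param object A `mixture_fit`.
#' @param nsim Number of traces.
#' @param seed Integer seed for the first trace; subsequent traces use
#'   consecutive seeds.
#' @param params A [trace_params()] supplying the measurement model.
#' @param ... Unused.
#' @return A list of `nsim` [chromatogram()] objects.
#' @export
simulate.mixture_fit <- function(object, nsim = 1, seed = 1L,
                                 params = trace_params(), ...) {
  lapply(seq_len(nsim), function(k) {
    p <- params
    p$seed <- as.integer(seed) + k - 1L
    simulate_trace(object$fraction, object$refs, p)
  })
}

#' Plot per-site fraction estimates of a mixture fit
#'
#' @param x A `mixture_fit`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.mixture_fit <- function(x, ...) {
  bp <- graphics::barplot(x$per_site_fractions,
                          names.arg = x$sites$peak_index,
                          xlab = "read position (0-based)",
                          ylab = "insertion-bearing fraction",
                          ylim = c(0, 1), ...)
  graphics::abline(h = x$fraction, lty = 2)
  invisible(bp)
}
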