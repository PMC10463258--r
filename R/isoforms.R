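#' Four-isoform relative abundance profile
#'
#' Fractions of the four splice variants: A (neither insert), B (long,
#' acidic-cluster insert), C (short, serine insert), D (both inserts),
#' summing to 1, with per-isoform SDs across technical replicates.
#'
#' @param fractions Numeric vector of four fractions in `[0, 1]` summing to
#'   1 within `1e-9`, named or ordered A, B, C, D.
#' @param sds Non-negative per-isoform SDs (0 for a single measurement).
#' @param n_replicates Number of replicates the profile summarises.
#' @return An object of class `"isoform_profile"`.
#' @export
isoform_profile <- function(fractions, sds = rep(0, 4), n_replicates = 1L) {
  stopifnot(is.numeric(fractions), length(fractions) == 4,
            all(fractions >= 0), all(fractions <= 1),
            is.numeric(sds), length(sds) == 4, all(sds >= 0))
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("isoform fractions must sum to 1")
  names(fractions) <- names(sds) <- c("A", "B", "C", "D")
  structure(list(fractions = fractions, sds = sds,
                 n_replicates = as.integer(n_replicates)),
            class = "isoform_profile")
}

#' @export
print.isoform_profile <- function(x, ...) {
  cat("Isoform profile (", x$n_replicates, " replicate",
      if (x$n_replicates != 1) "s", "):\n", sep = "")
  tab <- rbind(fraction = round(x$fractions, 4), sd = round(x$sds, 4))
  print(tab)
  invisible(x)
}

#' Combine band and trace fractions into a four-isoform profile
#'
#' The two-step measurement determines the four-way split: the gel gives
#' the fraction `f_long` of long (acidic-cluster) transcripts, and
#' sequencing each excised band gives the serine-insert fraction within
#' that band (`s_short` for the short band, `s_long` for the long band).
#' Since each band is sequenced separately, the product of band fraction
#' and within-band serine fraction is the isoform fraction:
#' `A = (1 - f_long) (1 - s_short)`, `C = (1 - f_long) s_short`,
#' `B = f_long (1 - s_long)`, `D = f_long s_long`. The result sums to 1
#' exactly. When `f_long` is 0 or 1, the serine fraction of the absent band
#' is ignored.
#'
#' @param f_long Fraction of long-fragment transcripts, in `[0, 1]`.
#' @param s_short Serine-insert fraction within the short band.
#' @param s_long Serine-insert fraction within the long band.
#' @return A single-replicate [isoform_profile()].
#' @seealso [splice_fractions()] for the inverse map.
#' @export
#' @examples
#' combine_isoform_fractions(0.312, 0, 0)       # A = 0.688, B = 0.312
#' combine_isoform_fractions(0.5, 0.2, 0.4)     # A 0.4, B 0.3, C 0.1, D 0.2
combine_isoform_fractions <- function(f_long, s_short, s_long) {
  for (v in c(f_long, s_short, s_long))
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1)
      stop("all inputs must be single numbers in [0, 1]")
  fr <- c(A = (1 - f_long) * (1 - s_short),
          B = f_long * (1 - s_long),
          C = (1 - f_long) * s_short,
          D = f_long * s_long)
  isoform_profile(fr)
}

#' Band and serine fractions implied by an isoform profile
#'
#' Inverse of [combine_isoform_fractions()] on interior profiles:
#' `f_long = B + D`, `s_short = C / (A + C)`, `s_long = D / (B + D)`.
#' When a band is absent its serine fraction is returned as `NA`.
#'
#' @param profile An [isoform_profile()].
#' @return A list with `f_long`, `s_short`, `s_long`.
#' @export
splice_fractions <- function(profile) {
  stopifnot(inherits(profile, "isoform_profile"))
  fr <- profile$fractions
  f_long <- fr[["B"]] + fr[["D"]]
  list(f_long = f_long,
       s_short = if (fr[["A"]] + fr[["C"]] > 0)
         fr[["C"]] / (fr[["A"]] + fr[["C"]]) else NA_real_,
       s_long = if (f_long > 0) fr[["D"]] / f_long else NA_real_)
}

#' Aggregate technical replicates of an isoform profile
#'
#' Per-isoform mean and sample SD across replicate profiles, as figure
#' legends report ("mean +/- SD of three technical replicates"); means are
#' renormalised to sum to 1.
#'
#' @param profiles Non-empty list of single-replicate [isoform_profile()]s.
#' @return An [isoform_profile()] with `n_replicates = length(profiles)`.
#' @export
aggregate_replicates <- function(profiles) {
  stopifnot(is.list(profiles), length(profiles) >= 1)
  for (p in profiles) {
    stopifnot(inherits(p, "isoform_profile"))
    if (p$n_replicates != 1)
      stop("aggregate_replicates expects single-replicate profiles")
  }
  m <- do.call(rbind, lapply(profiles, function(p) p$fractions))
  means <- colMeans(m)
  sds <- if (nrow(m) > 1) apply(m, 2, stats::sd) else rep(0, 4)
  isoform_profile(means / sum(means), sds, n_replicates = nrow(m))
}

#' Two-isoform profile for species with a single splice event
#'
#' In mouse only the two variants without the acidic cluster are expressed,
#' so the profile reduces to `A = 1 - s`, `C = s` — equivalent to
#' `combine_isoform_fractions(0, s_fraction, 0)`.
#'
#' @param s_fraction Serine-insert fraction in `[0, 1]`.
#' @return An [isoform_profile()] with `B = D = 0`.
#' @export
#' @examples
#' mouse_two_isoform_profile(0.25) # A = 0.75, C = 0.25
mouse_two_isoform_profile <- function(s_fraction) {
  combine_isoform_fractions(0, s_fraction, 0)
}

#' Quantify a synthetic (or assembled) replicate dataset
#'
#' Runs the full inference on a [generate_dataset()] bundle: for every
#' replicate, the lane is background-subtracted and its long/short bands
#' integrated to give `f_long`; the two band traces are decomposed with
#' [fit_trace_mixture()] to give `s_long` and `s_short`; the three
#' fractions are combined into a four-isoform profile; finally the
#' replicate profiles are aggregated to mean and SD.
#'
#' @param dataset A `splice_dataset` from [generate_dataset()].
#' @param method Trace estimator, `"amplitude"` or `"lsq"`.
#' @param n_sites Informative sites per trace.
#' @param window Read positions scanned downstream of the junction.
#' @param background Background-subtraction method for the lanes.
#' @param tolerance Band-matching tolerance in pixels.
#' @param length_correction If `TRUE`, divide band volumes by fragment
#'   length before forming `f_long` (appropriate for mass-responsive
#'   stains); default `FALSE`, the plain intensity ratio.
#' @return An aggregated [isoform_profile()] with the per-replicate
#'   profiles attached as attribute `"replicates"`.
#' @export
quantify_dataset <- function(dataset, method = c("amplitude", "lsq"),
                             n_sites = 3L, window = 12L,
                             background = c("linear", "rolling_min"),
                             tolerance = 10,
                             length_correction = FALSE) {
  method <- match.arg(method)
  background <- match.arg(background)
  stopifnot(inherits(dataset, "splice_dataset"))
  fl <- dataset$fragment_lengths
  centers <- c(long = dataset$gel_params$migration_model(fl[["long"]]),
               short = dataset$gel_params$migration_model(fl[["short"]]))
  lc <- if (length_correction) c(long = fl[["long"]], short = fl[["short"]])
  profiles <- lapply(dataset$replicates, function(rep) {
    lane <- subtract_background(rep$lane, method = background)
    bands <- quantify_bands(lane, centers, tolerance = tolerance)
    f_long <- long_fraction(bands, length_correction = lc)
    s_long <- if (f_long > 0)
      fit_trace_mixture(rep$trace_long, dataset$refs, method = method,
                        n_sites = n_sites, window = window)$fraction else 0
    s_short <- if (f_long < 1)
      fit_trace_mixture(rep$trace_short, dataset$refs, method = method,
                        n_sites = n_sites, window = window)$fraction else 0
    combine_isoform_fractions(f_long, s_short, s_long)
  })
  out <- aggregate_replicates(profiles)
  attr(out, "replicates") <- profiles
  out
}
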