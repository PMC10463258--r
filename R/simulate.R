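#' Simulate a mixed Sanger chromatogram
#'
#' Forward model for the mixed electropherogram of two co-amplified species
#' that are identical up to a short insertion. The trace is the
#' superposition `f_insert * T(long) + (1 - f_insert) * T(short)`, where
#' `T(s)` places, for base `i` (0-based) of sequence `s`, a Gaussian peak of
#' width `peak_sigma` at scan `i * peak_spacing` in that base's channel,
#' scaled by `base_amplitude * exp(-decay_rate * i)`, with a `crosstalk`
#' fraction leaking equally into the other three channels. I.i.d. Gaussian
#' noise is added per scan and channel, and the signal is truncated at zero.
#' Both species run on the same scan grid (co-amplified fragments migrate in
#' one reaction, so there is no mobility shift); past the end of the short
#' read only the insertion-bearing species contributes.
#'
#' @param f_insert Fraction of the insertion-bearing species, in `[0, 1]`.
#' @param refs A [reference_pair()].
#' @param params A [trace_params()].
#'
#' @return A [chromatogram()] with one recorded peak position per base of
#'   the long read and majority base calls. The simulation truth
#'   (`f_insert`, per-peak noiseless channel amplitudes) is attached as
#'   attribute `"truth"`. Identical inputs and seed reproduce the identical
#'   trace.
#' @export
#' @examples
#' rp <- default_serine_reference()
#' tr <- simulate_trace(0.3, rp, trace_params(noise_sd = 0, crosstalk = 0))
#' coef(fit_trace_mixture(tr, rp))  # recovers 0.3
simulate_trace <- function(f_insert, refs, params = trace_params()) {
  stopifnot(inherits(refs, "reference_pair"), inherits(params, "trace_params"),
            is.numeric(f_insert), length(f_insert) == 1,
            f_insert >= 0, f_insert <= 1)
  long <- long_sequence(refs)
  n_long <- nchar(long)
  spacing <- params$peak_spacing
  sigma <- params$peak_sigma
  n_scan <- as.integer(ceiling((n_long - 1) * spacing + 6 * sigma + 1))
  scan <- 0:(n_scan - 1)

  species_signal <- function(seq_str, weight) {
    mat <- matrix(0, n_scan, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
    if (weight == 0) return(mat)
    bases <- strsplit(seq_str, "")[[1]]
    for (i in seq_along(bases)) {
      amp <- weight * params$base_amplitude *
        exp(-params$decay_rate * (i - 1))
      g <- amp * exp(-((scan - (i - 1) * spacing)^2) / (2 * sigma^2))
      ch <- bases[i]
      mat[, ch] <- mat[, ch] + (1 - params$crosstalk) * g
      for (o in setdiff(c("A", "C", "G", "T"), ch))
        mat[, o] <- mat[, o] + (params$crosstalk / 3) * g
    }
    mat
  }

  sig <- species_signal(long, f_insert) +
    species_signal(refs$short_seq, 1 - f_insert)
  clean <- sig
  if (params$noise_sd > 0) {
    noise <- with_seed(params$seed,
                       matrix(stats::rnorm(length(sig), 0, params$noise_sd),
                              nrow = n_scan))
    sig <- sig + noise
  }
  sig <- pmax(sig, 0)

  peaks <- (0:(n_long - 1)) * spacing
  peak_rows <- round(peaks) + 1L
  calls <- colnames(clean)[max.col(clean[peak_rows, , drop = FALSE],
                                   ties.method = "first")]
  out <- chromatogram(sig, peak_positions = peaks,
                      base_calls = paste(calls, collapse = ""))
  attr(out, "truth") <- list(f_insert = f_insert,
                             clean_peak_amplitudes =
                               clean[peak_rows, , drop = FALSE])
  out
}

#' Simulate a gel lane profile
#'
#' Forward model for a 1-D densitometry profile: each species contributes a
#' Gaussian band centred at `migration_model(length)` whose total volume is
#' its abundance (`stain_mode = "molar"`) or abundance times length
#' (`stain_mode = "mass"`), on a constant background with additive Gaussian
#' noise truncated at zero.
#'
#' @param abundances Named non-negative numeric vector of species molar
#'   abundances; at least one must be positive.
#' @param lengths Named numeric vector of fragment lengths (nt) covering the
#'   same species names.
#' @param params A [gel_params()].
#' @param n_pixels Number of pixels in the lane profile.
#'
#' @return A [lane_profile()] with the simulation truth attached as
#'   attribute `"truth"`: a data frame of species, band centre, and true
#'   band volume, plus a `coincident` flag set when two distinct species
#'   migrate to the same position (their bands are unresolvable).
#' @export
#' @examples
#' lp <- simulate_lane(c(long = 312, short = 688),
#'                     c(long = 542, short = 500),
#'                     gel_params(noise_sd = 0, background_level = 0))
#' attr(lp, "truth")
simulate_lane <- function(abundances, lengths, params = gel_params(),
                          n_pixels = 700L) {
  stopifnot(inherits(params, "gel_params"),
            is.numeric(abundances), is.numeric(lengths),
            !is.null(names(abundances)), !is.null(names(lengths)),
            all(names(abundances) %in% names(lengths)),
            all(abundances >= 0))
  if (!any(abundances > 0))
    stop("at least one species must have positive abundance")
  pos <- 0:(n_pixels - 1L)
  prof <- rep(params$background_level, n_pixels)
  centers <- vapply(names(abundances),
                    function(s) params$migration_model(lengths[[s]]),
                    numeric(1))
  volumes <- vapply(names(abundances), function(s) {
    if (params$stain_mode == "mass") abundances[[s]] * lengths[[s]]
    else abundances[[s]]
  }, numeric(1))
  for (s in names(abundances)) {
    if (abundances[[s]] == 0) next
    prof <- prof + volumes[[s]] *
      stats::dnorm(pos, centers[[s]], params$band_sigma)
  }
  if (params$noise_sd > 0) {
    prof <- prof + with_seed(params$seed,
                             stats::rnorm(n_pixels, 0, params$noise_sd))
  }
  prof <- pmax(prof, 0)
  dup <- duplicated(round(centers, 6)) | duplicated(round(centers, 6),
                                                    fromLast = TRUE)
  out <- lane_profile(pos, prof)
  attr(out, "truth") <- list(
    bands = data.frame(species = names(abundances), center = unname(centers),
                       volume = unname(volumes), stringsAsFactors = FALSE),
    coincident = any(dup & length(unique(names(abundances))) > 1))
  out
}

#' Generate a complete synthetic replicate dataset
#'
#' Emulates the study design end to end: for each technical replicate, a
#' gel lane separating the long (insertion-bearing) and short RT-PCR
#' fragments at the true long fraction `f_long`, plus one mixed chromatogram
#' per excised band sequencing the short-insert junction — the long-band
#' trace is a mixture at `s_long`, the short-band trace at `s_short`.
#' Each replicate uses seeds derived deterministically from the truth's
#' master seed, so identical inputs reproduce byte-identical bundles.
#'
#' @param truth A [synthetic_truth()].
#' @param refs A [reference_pair()] for the short-insert (serine) junction
#'   shared by both bands.
#' @param trace_params A [trace_params()]; its seed field is overridden by
#'   the derived per-replicate seeds.
#' @param gel_params A [gel_params()]; seed handled likewise.
#' @param fragment_lengths Named numeric vector with elements `short` and
#'   `long` giving the RT-PCR fragment lengths in nt (default 500 and 542,
#'   differing by the 42-nt insertion).
#' @param lane_scale Total molar abundance loaded per lane (arbitrary
#'   units).
#'
#' @return An object of class `"splice_dataset"`: a list with `truth`,
#'   `refs`, `trace_params`, `gel_params`, `fragment_lengths`, and
#'   `replicates`, a list of `replicate_count` elements each holding
#'   `trace_long`, `trace_short`, and `lane`.
#' @seealso [quantify_dataset()]
#' @export
generate_dataset <- function(truth, refs = default_serine_reference(),
                             trace_params = splicefrac::trace_params(),
                             gel_params = splicefrac::gel_params(),
                             fragment_lengths = c(short = 500, long = 542),
                             lane_scale = 1000) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(refs, "reference_pair"),
            all(c("short", "long") %in% names(fragment_lengths)))
  reps <- vector("list", truth$replicate_count)
  for (r in seq_len(truth$replicate_count)) {
    base <- truth$seed + (r - 1L) * 3L
    tp_long <- trace_params; tp_long$seed <- base + 1L
    tp_short <- trace_params; tp_short$seed <- base + 2L
    gp <- gel_params; gp$seed <- base + 3L
    reps[[r]] <- list(
      trace_long = simulate_trace(truth$s_long, refs, tp_long),
      trace_short = simulate_trace(truth$s_short, refs, tp_short),
      lane = simulate_lane(
        c(long = lane_scale * truth$f_long,
          short = lane_scale * (1 - truth$f_long)),
        fragment_lengths[c("long", "short")], gp))
  }
  structure(list(truth = truth, refs = refs, trace_params = trace_params,
                 gel_params = gel_params,
                 fragment_lengths = fragment_lengths,
                 replicates = reps),
            class = "splice_dataset")
}

#' @export
print.splice_dataset <- function(x, ...) {
  cat("Synthetic splice dataset:", length(x$replicates),
      "technical replicates\n")
  print(x$truth)
  invisible(x)
}

#' Default reference pair for the serine-codon junction
#'
#' A synthetic stand-in junction sequence for the 3-nt serine-codon
#' insertion event (the study does not print the nucleotide sequence around
#' the junction, only amino acids), with the insert placed mid-read so that
#' several informative sites fall inside both reads. Always configurable;
#' estimators never assume it.
#'
#' @return A [reference_pair()] with a 40-nt short read, insert `"AGC"`,
#'   0-based offset 18.
#' @export
default_serine_reference <- function() {
  reference_pair("ACGTTGCAGGTCCTGATAACGATTACCGGTTGCACGTAAT",
                 insert_seq = "AGC", insert_offset = 18L)
}
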