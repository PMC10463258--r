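#' Electropherogram simulation parameters
#'
#' Parameters of the forward measurement model used by [simulate_trace()]:
#' a capillary trace is a train of Gaussian peaks on a uniform scan grid,
#' one peak per base, with exponential signal decay along the read, optional
#' spectral crosstalk between dye channels, and additive Gaussian noise
#' truncated at zero.
#'
#' @param peak_spacing Scan points per base (positive).
#' @param peak_sigma Gaussian peak width in scan points; must be smaller than
#'   `peak_spacing` so that adjacent peaks are resolvable. The default keeps
#'   a peak's tail below `2e-8` of its height at the edge of the adjacent
#'   peak's read-out window, so neighbouring bases do not bleed into each
#'   other's peak-height readings.
#' @param base_amplitude Peak amplitude of the first base, arbitrary units.
#' @param decay_rate Per-base exponential signal decay (non-negative); base
#'   `i` (0-based) has amplitude `base_amplitude * exp(-decay_rate * i)`.
#' @param noise_sd Standard deviation of per-scan additive Gaussian noise,
#'   arbitrary units (non-negative). The default is 5% of `base_amplitude`.
#' @param crosstalk Fraction of each peak's amplitude leaking equally into
#'   the three other channels, in `[0, 0.2]`. Leakage conserves the channel
#'   sum: a peak contributes `1 - crosstalk` to its own channel and
#'   `crosstalk / 3` to each other channel.
#' @param seed Integer seed controlling the noise draw.
#'
#' @return An object of class `"trace_params"`.
#' @seealso [simulate_trace()], [gel_params()]
#' @export
#' @examples
#' trace_params(noise_sd = 0, crosstalk = 0) # noiseless ideal trace
trace_params <- function(peak_spacing = 12, peak_sigma = 1,
                         base_amplitude = 1000, decay_rate = 0.002,
                         noise_sd = 50, crosstalk = 0.02, seed = 1L) {
  stopifnot(is.numeric(peak_spacing), peak_spacing > 0,
            is.numeric(peak_sigma), peak_sigma > 0,
            is.numeric(base_amplitude), base_amplitude > 0,
            is.numeric(decay_rate), decay_rate >= 0,
            is.numeric(noise_sd), noise_sd >= 0,
            is.numeric(crosstalk), crosstalk >= 0, crosstalk <= 0.2)
  if (peak_sigma >= peak_spacing)
    stop("peak_sigma must be smaller than peak_spacing (peaks unresolvable)")
  structure(list(peak_spacing = peak_spacing, peak_sigma = peak_sigma,
                 base_amplitude = base_amplitude, decay_rate = decay_rate,
                 noise_sd = noise_sd, crosstalk = crosstalk,
                 seed = as.integer(seed)),
            class = "trace_params")
}

#' Default gel migration model
#'
#' Maps fragment length (nt) to lane position (pixels from the well),
#' linear in log10 length as for agarose electrophoresis in the usual
#' separation range. Strictly decreasing in length: longer fragments
#' migrate less far.
#'
#' @param length_nt Fragment length(s) in nucleotides.
#' @return Lane position(s) in pixels.
#' @export
#' @examples
#' default_migration(c(500, 542)) # ~28 px apart
default_migration <- function(length_nt) 2400 - 800 * log10(length_nt)

#' Gel lane simulation parameters
#'
#' Parameters of the lane forward model used by [simulate_lane()]: each
#' fragment produces a Gaussian band centred at `migration_model(length)`,
#' with band volume proportional to molar abundance (`stain_mode = "molar"`)
#' or to abundance times length (`stain_mode = "mass"`, emulating
#' intercalating stains whose signal scales with the mass of DNA), on a
#' constant background with additive Gaussian noise truncated at zero.
#'
#' @param migration_model Function mapping fragment length (nt) to lane
#'   position (pixels), strictly decreasing in length.
#' @param band_sigma Gaussian band width in pixels (positive).
#' @param stain_mode `"molar"` or `"mass"`.
#' @param background_level Constant background intensity, arbitrary units.
#' @param noise_sd Per-pixel Gaussian noise SD, arbitrary units.
#' @param seed Integer seed controlling the noise draw.
#'
#' @return An object of class `"gel_params"`.
#' @seealso [simulate_lane()], [default_migration()]
#' @export
gel_params <- function(migration_model = default_migration, band_sigma = 3,
                       stain_mode = c("molar", "mass"), background_level = 5,
                       noise_sd = 2, seed = 1L) {
  stain_mode <- match.arg(stain_mode)
  stopifnot(is.function(migration_model),
            is.numeric(band_sigma), band_sigma > 0,
            is.numeric(background_level), background_level >= 0,
            is.numeric(noise_sd), noise_sd >= 0)
  structure(list(migration_model = migration_model, band_sigma = band_sigma,
                 stain_mode = stain_mode, background_level = background_level,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "gel_params")
}

#' Ground-truth isoform composition for a synthetic dataset
#'
#' Defines the true four-isoform composition used by [generate_dataset()].
#' The four variants arise from two independent splice events: a short
#' (e.g. 3 nt, serine-codon) insertion and a long (e.g. 42 nt, acidic
#' cluster) insertion. Isoform A carries neither insert, B the long insert,
#' C the short insert, D both. Three measurable quantities follow:
#' `f_long = B + D` (fraction of long-insert transcripts, read from the gel),
#' `s_short = C / (A + C)` and `s_long = D / (B + D)` (short-insert fraction
#' within each gel band, read from the mixed traces).
#'
#' @param fractions Numeric vector of four non-negative isoform fractions,
#'   named or in order A, B, C, D; must sum to 1 within `1e-9`.
#' @param replicate_count Number of technical replicates (positive integer).
#' @param seed Integer master seed; per-replicate seeds are derived
#'   deterministically from it.
#'
#' @return An object of class `"synthetic_truth"` with fields `fractions`,
#'   `f_long`, `s_short`, `s_long`, `replicate_count`, `seed`.
#' @export
#' @examples
#' tr <- synthetic_truth(c(A = 0.4, B = 0.3, C = 0.1, D = 0.2))
#' tr$f_long   # 0.5
#' tr$s_short  # 0.2
#' tr$s_long   # 0.4
synthetic_truth <- function(fractions, replicate_count = 3L, seed = 1L) {
  stopifnot(is.numeric(fractions), length(fractions) == 4,
            all(fractions >= 0), replicate_count >= 1)
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("isoform fractions must sum to 1")
  names(fractions) <- c("A", "B", "C", "D")
  f_long <- fractions[["B"]] + fractions[["D"]]
  s_short <- if (fractions[["A"]] + fractions[["C"]] > 0)
    fractions[["C"]] / (fractions[["A"]] + fractions[["C"]]) else 0
  s_long <- if (f_long > 0) fractions[["D"]] / f_long else 0
  structure(list(fractions = fractions, f_long = f_long,
                 s_short = s_short, s_long = s_long,
                 replicate_count = as.integer(replicate_count),
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic isoform truth (", x$replicate_count, " replicates, seed ",
      x$seed, ")\n", sep = "")
  print(round(x$fractions, 4))
  cat(sprintf("f_long = %.4f, s_short = %.4f, s_long = %.4f\n",
              x$f_long, x$s_short, x$s_long))
  invisible(x)
}

# Evaluate code with a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    } else assign(".Random.seed", old, envir = genv)
  })
  set.seed(seed)
  force(code)
}
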