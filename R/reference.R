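#' Reference junction pair for an insertion splice event
#'
#' Describes the two co-amplified species that a mixed chromatogram
#' superimposes: a reference read without the insertion and the same read
#' with `insert_seq` inserted before base `insert_offset` (0-based,
#' half-open convention). Downstream of the junction the two reads are
#' frame-shifted relative to each other, so individual read positions can
#' predict different bases under the two species.
#'
#' @param short_seq Nucleotide string of the read without the insertion
#'   (alphabet A, C, G, T).
#' @param insert_seq Inserted nucleotides (length >= 1); defaults to the
#'   serine codon `"AGC"` used for 3-nt alternative 3' splice-site events.
#' @param insert_offset 0-based base index in `short_seq` before which the
#'   insert is placed; `0 <= insert_offset <= nchar(short_seq)`.
#'
#' @return An object of class `"reference_pair"`.
#' @seealso [long_sequence()], [find_informative_sites()]
#' @export
#' @examples
#' rp <- reference_pair("AAACCC", "GGG", 3)
#' long_sequence(rp) # "AAAGGGCCC"
reference_pair <- function(short_seq, insert_seq = "AGC", insert_offset) {
  short_seq <- toupper(short_seq)
  insert_seq <- toupper(insert_seq)
  stopifnot(is.character(short_seq), length(short_seq) == 1,
            is.character(insert_seq), length(insert_seq) == 1,
            nchar(insert_seq) >= 1)
  if (grepl("[^ACGT]", short_seq) || grepl("[^ACGT]", insert_seq))
    stop("sequences must use the A/C/G/T alphabet")
  insert_offset <- as.integer(insert_offset)
  if (insert_offset < 0 || insert_offset > nchar(short_seq))
    stop("insert_offset must lie within [0, nchar(short_seq)]")
  structure(list(short_seq = short_seq, insert_seq = insert_seq,
                 insert_offset = insert_offset),
            class = "reference_pair")
}

#' Insertion-bearing sequence of a reference pair
#'
#' @param refs A [reference_pair()].
#' @return The long (insertion-bearing) nucleotide string:
#'   `short_seq[0:offset] + insert_seq + short_seq[offset:]`.
#' @export
long_sequence <- function(refs) {
  stopifnot(inherits(refs, "reference_pair"))
  paste0(substr(refs$short_seq, 1, refs$insert_offset),
         refs$insert_seq,
         substr(refs$short_seq, refs$insert_offset + 1,
                nchar(refs$short_seq)))
}

#' Reverse-complement a reference pair
#'
#' Produces the reference pair seen by a read from the reverse primer.
#' Strand handling is explicit: traces sequenced with the reverse primer are
#' quantified against `reverse_complement(refs)`, never guessed.
#'
#' @param refs A [reference_pair()].
#' @return A [reference_pair()] describing the reverse-complement strand;
#'   the insertion offset is re-expressed from the new read start.
#' @export
reverse_complement <- function(refs) {
  stopifnot(inherits(refs, "reference_pair"))
  rc <- function(s) {
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  n <- nchar(refs$short_seq)
  # insert placed before offset base -> on the rc strand it sits before
  # base (n - offset) of the rc short read
  reference_pair(rc(refs$short_seq), rc(refs$insert_seq),
                 n - refs$insert_offset)
}

#' @export
print.reference_pair <- function(x, ...) {
  cat("Reference pair (insert of", nchar(x$insert_seq),
      "nt before 0-based offset", x$insert_offset, ")\n")
  cat("  short:", x$short_seq, "\n")
  cat("  long: ", long_sequence(x), "\n")
  invisible(x)
}

#' Find informative sites downstream of an insertion junction
#'
#' Compares, position by position, the insertion-bearing (long) read with
#' the reference (short) read over a window starting at the junction, and
#' returns the first `n_sites` read positions at which the two species
#' predict different bases. At such a site the fraction of insertion-bearing
#' template can be read directly off the two channel amplitudes. The default
#' of three sites reflects standard practice of averaging three nucleotide
#' positions from the mixed profile; the earliest differing positions are
#' used because signal decays along the read.
#'
#' @param refs A [reference_pair()].
#' @param n_sites Number of informative sites requested (>= 1).
#' @param window Number of read positions to scan, starting at the junction
#'   (`window >= n_sites`). Truncated with a warning if it extends past the
#'   end of the short read.
#'
#' @return A data frame with columns `peak_index` (0-based read position),
#'   `base_plus` (base under the insertion-bearing species) and `base_minus`
#'   (base under the reference species); fewer than `n_sites` rows if the
#'   window is exhausted, zero rows if the species are indistinguishable
#'   (e.g. homopolymer insertions).
#' @export
#' @examples
#' find_informative_sites(reference_pair("AAACCC", "GGG", 3), n_sites = 3)
find_informative_sites <- function(refs, n_sites = 3L, window = 12L) {
  stopifnot(inherits(refs, "reference_pair"), n_sites >= 1,
            window >= n_sites)
  long <- strsplit(long_sequence(refs), "")[[1]]
  short <- strsplit(refs$short_seq, "")[[1]]
  from <- refs$insert_offset           # 0-based first shifted position
  to <- from + window - 1L
  last_short <- length(short) - 1L     # 0-based last comparable position
  if (to > last_short) {
    warning("window extends past the end of the short read; truncated")
    to <- last_short
  }
  if (from > to)
    return(data.frame(peak_index = integer(), base_plus = character(),
                      base_minus = character(), stringsAsFactors = FALSE))
  idx <- from:to
  differ <- long[idx + 1L] != short[idx + 1L]
  idx <- idx[differ]
  if (length(idx) > n_sites) idx <- idx[seq_len(n_sites)]
  data.frame(peak_index = idx,
             base_plus = long[idx + 1L],
             base_minus = short[idx + 1L],
             stringsAsFactors = FALSE)
}
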