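#' Read a chromatogram from ABIF/AB1 or TSV
#'
#' Sniffs the format by magic bytes: files starting with `ABIF` are parsed
#' as ABIF containers (analyzed channel tags DATA9-DATA12, channel order
#' from FWO_, peak locations from PLOC, called bases from PBAS); anything
#' else is read as the package's plain-text trace format written by
#' [write_trace()]. When a file carries no peak locations, peaks are
#' detected with [detect_peaks()] at `expected_spacing`.
#'
#' @param path File path.
#' @param expected_spacing Scan points per base used only when peak
#'   locations are missing from the file.
#' @return A [chromatogram()].
#' @export
read_trace <- function(path, expected_spacing = 12) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("empty file: ", path)
  magic <- readBin(path, "raw", n = 4)
  tr <- if (length(magic) == 4 && rawToChar(magic) == "ABIF")
    read_abif(path) else read_trace_tsv(path)
  if (is.null(tr$peak_positions)) {
    pk <- detect_peaks(tr$channel_data, expected_spacing)
    tr <- chromatogram(tr$channel_data, pk, NULL)
  }
  tr
}

#' Write a chromatogram as plain-text TSV
#'
#' Format: comment header lines (`# peak_positions=` comma-separated
#' 0-based scan indices, `# base_calls=` optional), then a tab-separated
#' table with columns `scan`, `A`, `C`, `G`, `T`. Round-trips through
#' [read_trace()].
#'
#' @param trace A [chromatogram()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "chromatogram"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# splicefrac trace v1; scan coordinates 0-based", con)
  if (!is.null(trace$peak_positions))
    writeLines(paste0("# peak_positions=",
                      paste(format(trace$peak_positions, digits = 15,
                                   trim = TRUE, scientific = FALSE),
                            collapse = ",")), con)
  if (!is.null(trace$base_calls))
    writeLines(paste0("# base_calls=", trace$base_calls), con)
  m <- trace$channel_data
  writeLines("scan\tA\tC\tG\tT", con)
  lines <- paste(0:(nrow(m) - 1),
                 formatC(m[, "A"], format = "g", digits = 15),
                 formatC(m[, "C"], format = "g", digits = 15),
                 formatC(m[, "G"], format = "g", digits = 15),
                 formatC(m[, "T"], format = "g", digits = 15),
                 sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

read_trace_tsv <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty trace file: ", path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  if (length(body) < 2)
    stop("unknown trace format (no data rows): ", path)
  dat <- utils::read.delim(text = body, check.names = FALSE)
  need <- c("A", "C", "G", "T")
  if (!all(need %in% names(dat)))
    stop("trace TSV must have columns A, C, G, T")
  peaks <- NULL
  pk_line <- grep("^# ?peak_positions=", hdr, value = TRUE)
  if (length(pk_line))
    peaks <- as.numeric(strsplit(sub("^# ?peak_positions=", "", pk_line[1]),
                                 ",")[[1]])
  calls <- NULL
  bc_line <- grep("^# ?base_calls=", hdr, value = TRUE)
  if (length(bc_line))
    calls <- sub("^# ?base_calls=", "", bc_line[1])
  chromatogram(as.matrix(dat[, need]), peaks, calls)
}

# Minimal ABIF container reader (big-endian). Directory entries are 28
# bytes: name[4], int32 tag number, int16 element type, int16 element
# size, int32 element count, int32 data size, int32 data offset (holding
# the data bytes themselves when data size <= 4), int32 handle.
read_abif <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 128 || rawToChar(raw[1:4]) != "ABIF")
    stop("not an ABIF file: ", path)
  int32 <- function(off) readBin(raw[(off + 1):(off + 4)], "integer",
                                 size = 4, endian = "big")
  int16v <- function(off, n) readBin(raw[(off + 1):(off + 2 * n)], "integer",
                                     n = n, size = 2, endian = "big")
  entry <- function(off) {
    list(name = rawToChar(raw[(off + 1):(off + 4)]),
         number = int32(off + 4),
         type = int16v(off + 8, 1),
         n = int32(off + 12),
         datasize = int32(off + 16),
         dataoffset = int32(off + 20),
         off = off)
  }
  tdir <- entry(6L)
  if (tdir$name != "tdir") stop("truncated or corrupt ABIF header: ", path)
  if (tdir$dataoffset + 28 * tdir$n > length(raw))
    stop("truncated ABIF file: ", path)
  entries <- lapply(seq_len(tdir$n) - 1L,
                    function(i) entry(tdir$dataoffset + 28L * i))
  payload <- function(e) {
    if (e$datasize <= 4) raw[(e$off + 21):(e$off + 20 + e$datasize)]
    else raw[(e$dataoffset + 1):(e$dataoffset + e$datasize)]
  }
  get <- function(name, number) {
    for (e in entries)
      if (e$name == name && e$number == number) return(e)
    NULL
  }
  decode <- function(e) {
    p <- payload(e)
    switch(as.character(e$type),
           "1" = as.integer(p),
           "2" = rawToChar(p),
           "4" = readBin(p, "integer", n = e$n, size = 2, endian = "big"),
           "5" = readBin(p, "integer", n = e$n, size = 4, endian = "big"),
           "18" = rawToChar(p[-1]),
           "19" = rawToChar(p[p != as.raw(0)]),
           stop("unsupported ABIF element type ", e$type))
  }
  if (is.null(get("DATA", 9))) {
    if (!is.null(get("DATA", 1)))
      stop("only raw channel data (DATA1-4) present; ",
           "analyzed channels DATA9-12 are required for amplitude ratios")
    stop("missing analyzed channel data (DATA9-12): ", path)
  }
  fwo <- get("FWO_", 1)
  if (is.null(fwo)) stop("missing channel order record FWO_: ", path)
  order <- strsplit(decode(fwo), "")[[1]]
  if (!setequal(order, c("A", "C", "G", "T")))
    stop("invalid FWO_ channel order: ", decode(fwo))
  chans <- lapply(9:12, function(k) {
    e <- get("DATA", k)
    if (is.null(e)) stop("missing channel DATA", k, ": ", path)
    decode(e)
  })
  names(chans) <- order
  m <- cbind(A = chans$A, C = chans$C, G = chans$G, T = chans$T)
  m <- pmax(m, 0)
  ploc <- get("PLOC", 2)
  if (is.null(ploc)) ploc <- get("PLOC", 1)
  peaks <- if (!is.null(ploc)) as.numeric(decode(ploc)) else NULL
  pbas <- get("PBAS", 2)
  if (is.null(pbas)) pbas <- get("PBAS", 1)
  calls <- if (!is.null(pbas) && !is.null(peaks)) decode(pbas) else NULL
  if (!is.null(calls) && nchar(calls) != length(peaks)) calls <- NULL
  chromatogram(m, peaks, calls)
}

#' Read and write gel lane profiles
#'
#' Lane profiles are two-column tab-separated files (`position`,
#' `intensity`) with optional `#` comment lines.
#'
#' @param path File path.
#' @return `read_lane()` returns a [lane_profile()].
#' @export
read_lane <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) < 2) stop("malformed lane profile: ", path)
  dat <- utils::read.delim(text = body)
  if (ncol(dat) < 2) stop("lane profile needs two columns: ", path)
  lane_profile(dat[[1]], pmax(dat[[2]], 0))
}

#' @rdname read_lane
#' @param profile A [lane_profile()].
#' @export
write_lane <- function(profile, path) {
  stopifnot(inherits(profile, "lane_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# splicefrac lane profile v1; positions 0-based pixels", con)
  writeLines("position\tintensity", con)
  writeLines(paste(formatC(profile$positions, format = "g", digits = 15),
                   formatC(profile$intensities, format = "g", digits = 15),
                   sep = "\t"), con)
  invisible(path)
}

#' Read reference sequences from FASTA
#'
#' Standard multi-record, line-wrapped FASTA; sequences are upper-cased and
#' validated against the A/C/G/T/N alphabet. Record ids are the first
#' whitespace-delimited word of each header and must be unique.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readDNAStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  if (anyDuplicated(ids))
    stop("duplicate FASTA record id: ", ids[duplicated(ids)][1])
  seqs <- toupper(as.character(set))
  if (any(grepl("[^ACGTN]", seqs)))
    stop("FASTA contains characters outside A/C/G/T/N")
  names(seqs) <- ids
  seqs
}

#' Write an isoform report
#'
#' Tab-separated report with one row per sample and isoform (fraction,
#' SD, replicate count), samples and isoforms in deterministic sorted
#' order; optional test results and the seed are recorded in the comment
#' header. Re-running on the same inputs reproduces the file byte for
#' byte.
#'
#' @param profiles Named list of [isoform_profile()]s (names are sample
#'   labels).
#' @param path Output path.
#' @param stats Optional list of `splice_test` results to record.
#' @param seed Optional integer seed to record.
#' @return `path`, invisibly.
#' @export
write_report <- function(profiles, path, stats = NULL, seed = NULL) {
  stopifnot(is.list(profiles), length(profiles) >= 1,
            !is.null(names(profiles)), all(nzchar(names(profiles))))
  for (p in profiles) stopifnot(inherits(p, "isoform_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# splicefrac report v1",
               "# coordinates 0-based, half-open; fractions sum to 1 per sample"),
             con)
  if (!is.null(seed)) writeLines(paste0("# seed=", as.integer(seed)), con)
  for (s in stats) {
    stopifnot(inherits(s, "splice_test"))
    writeLines(sprintf("# test %s%s: statistic=%.6g df=%s p=%.6g",
                       s$test_name,
                       if (is.null(s$effect)) "" else paste0("/", s$effect),
                       s$statistic, paste(signif(s$df, 6), collapse = ","),
                       s$p_value), con)
  }
  writeLines("sample\tisoform\tfraction\tsd\tn_replicates", con)
  for (nm in sort(names(profiles))) {
    p <- profiles[[nm]]
    for (iso in c("A", "B", "C", "D"))
      writeLines(paste(nm, iso,
                       formatC(p$fractions[[iso]], format = "g", digits = 10),
                       formatC(p$sds[[iso]], format = "g", digits = 10),
                       p$n_replicates, sep = "\t"), con)
  }
  invisible(path)
}

#' Write a mixture estimate as JSON
#'
#' @param fit A `mixture_fit` from [fit_trace_mixture()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mixture_json <- function(fit, path) {
  stopifnot(inherits(fit, "mixture_fit"))
  jsonlite::write_json(
    list(fraction = fit$fraction,
         per_site_fractions = fit$per_site_fractions,
         sd = fit$sd, n_sites = fit$n_sites, method = fit$method),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
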