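# Build a minimal valid ABIF container in memory (big-endian), used to test
# the AB1 reader without binary fixture files. Supports int16 arrays (type
# 4) and character data (type 2).

write_minimal_abif <- function(path, channels, fwo = "GATC",
                               ploc = NULL, pbas = NULL,
                               data_numbers = 9:12) {
  stopifnot(length(channels) == 4, nchar(fwo) == 4)
  be_int32 <- function(x) writeBin(as.integer(x), raw(), size = 4,
                                   endian = "big")
  be_int16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                   endian = "big")
  entries <- list()
  payloads <- list()
  add <- function(name, number, type, elsize, n, data_raw) {
    entries[[length(entries) + 1]] <<- list(
      name = name, number = number, type = type, elsize = elsize,
      n = n, data = data_raw)
  }
  for (k in 1:4)
    add("DATA", data_numbers[k], 4L, 2L, length(channels[[k]]),
        be_int16(channels[[k]]))
  add("FWO_", 1L, 2L, 1L, 4L, charToRaw(fwo))
  if (!is.null(ploc))
    add("PLOC", 2L, 4L, 2L, length(ploc), be_int16(ploc))
  if (!is.null(pbas))
    add("PBAS", 2L, 2L, 1L, nchar(pbas), charToRaw(pbas))

  # layout: 128-byte header, then payloads (> 4 bytes), then directory
  offset <- 128L
  dir_raw <- raw(0)
  body <- raw(0)
  for (e in entries) {
    size <- length(e$data)
    if (size > 4) {
      data_field <- be_int32(offset)
      body <- c(body, e$data)
      offset <- offset + size
    } else {
      data_field <- c(e$data, raw(4 - size))
    }
    dir_raw <- c(dir_raw, charToRaw(e$name), be_int32(e$number),
                 be_int16(e$type), be_int16(e$elsize), be_int32(e$n),
                 be_int32(size), data_field, be_int32(0L))
  }
  dir_offset <- offset
  header <- c(charToRaw("ABIF"), be_int16(101L),
              charToRaw("tdir"), be_int32(1L), be_int16(1023L),
              be_int16(28L), be_int32(length(entries)),
              be_int32(28L * length(entries)), be_int32(dir_offset),
              be_int32(0L))
  header <- c(header, raw(128 - length(header)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(header, body, dir_raw), con)
  invisible(path)
}
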