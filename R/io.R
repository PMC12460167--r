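# Plain-format I/O: mono WAV with a JSON sidecar for stimuli, TSV + JSON for
# binned responses. Small, dependency-free containers that round-trip every
# field of the in-memory objects.

#' Write a stimulus as WAV plus JSON sidecar
#'
#' Samples are written as 32-bit IEEE float mono WAV; the sidecar
#' (`<path>.json`) carries the rate, calibration level and annotations.
#'
#' @param x a `sound_stimulus`
#' @param path output WAV path
#' @return `path`, invisibly
#' @export
write_stimulus <- function(x, path) {
  stopifnot(inherits(x, "sound_stimulus"))
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(x$samples)
  data_bytes <- n * 4L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")   # IEEE float
  writeBin(1L, con, size = 2, endian = "little")   # mono
  sr <- as.integer(round(x$rate))
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(as.integer(sr * 4L), con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(x$samples, con, size = 4, endian = "little")
  jsonlite::write_json(
    list(rate = x$rate, level_db_spl = x$level_db_spl,
         annotations = x$annotations),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a stimulus written by [write_stimulus()]
#'
#' @param path WAV path; the `<path>.json` sidecar restores exact rate,
#'   level and annotations when present.
#' @return a `sound_stimulus`
#' @export
read_stimulus <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4); stopifnot(identical(hdr, "RIFF"))
  invisible(readBin(con, "integer", size = 4, endian = "little"))
  stopifnot(identical(readChar(con, 4), "WAVE"))
  rate <- NA_real_; fmt <- NA_integer_; samples <- NULL
  repeat {
    tag <- readChar(con, 4)
    if (length(tag) == 0 || nchar(tag) < 4) break
    sz <- readBin(con, "integer", size = 4, endian = "little")
    if (identical(tag, "fmt ")) {
      fmt <- readBin(con, "integer", size = 2, endian = "little")
      invisible(readBin(con, "integer", size = 2, endian = "little"))
      rate <- readBin(con, "integer", size = 4, endian = "little")
      invisible(readBin(con, "raw", n = sz - 8))
    } else if (identical(tag, "data")) {
      if (fmt == 3L) {
        samples <- readBin(con, "numeric", n = sz / 4, size = 4, endian = "little")
      } else {
        samples <- readBin(con, "integer", n = sz / 2, size = 2,
                           endian = "little", signed = TRUE) / 32768
      }
      break
    } else {
      invisible(readBin(con, "raw", n = sz))
    }
  }
  level <- NA_real_; ann <- empty_annotations()
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(meta$rate)) rate <- meta$rate
    if (!is.null(meta$level_db_spl)) level <- as.numeric(meta$level_db_spl)
    if (!is.null(meta$annotations) && length(meta$annotations)) {
      ann <- tibble::as_tibble(meta$annotations)
    }
  }
  sound_stimulus(samples, rate = rate, level_db_spl = level, annotations = ann)
}

#' Write a binned multi-unit response as TSV plus JSON sidecar
#'
#' Counts go to a units x bins TSV matrix; bin rate, trial start time and the
#' unit metadata tibble go to `<path>.json`.
#'
#' @param x a `mua_response`
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_response <- function(x, path) {
  stopifnot(inherits(x, "mua_response"))
  utils::write.table(x$counts, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(bin_rate_hz = x$bin_rate_hz, t0_s = x$t0_s, units = x$units),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a response written by [write_response()]
#' @param path TSV path
#' @return a `mua_response`
#' @export
read_response <- function(path) {
  counts <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(counts) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  mua_response(counts, bin_rate_hz = meta$bin_rate_hz, t0_s = meta$t0_s,
               units = if (!is.null(meta$units)) tibble::as_tibble(meta$units) else NULL)
}
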