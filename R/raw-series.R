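## Raw series files are headerless little-endian sequences of 64-bit IEEE 754
## doubles, one value per sample, 0-based sample positions.

#' Describe a raw series file
#'
#' A raw series is a flat binary file of 64-bit IEEE 754 little-endian floats,
#' one per sample. This constructor checks the file and returns a light
#' handle; no sample data is loaded.
#'
#' @param path path to the `.f64` file.
#' @return An object of class `tslod_raw` with fields `path` and `n_samples`.
#' @export
raw_series <- function(path) {
  sz <- file.size(path)
  if (is.na(sz)) stop("raw series file not found: ", path, call. = FALSE)
  if (sz %% 8 != 0) {
    stop("raw series file size is not a multiple of 8 bytes: ", path,
         call. = FALSE)
  }
  structure(
    list(path = normalizePath(path), n_samples = sz / 8),
    class = "tslod_raw"
  )
}

#' @export
print.tslod_raw <- function(x, ...) {
  cat(sprintf("<tslod_raw> %s samples: %s\n",
              format(x$n_samples, big.mark = ","), x$path))
  invisible(x)
}

#' Write samples to a raw series file
#'
#' @param values numeric vector of samples.
#' @param path output file path.
#' @param append append to an existing file instead of truncating.
#' @return A [raw_series()] handle for `path`, invisibly.
#' @export
write_raw_series <- function(values, path, append = FALSE) {
  con <- file(path, if (append) "ab" else "wb")
  writeBin(as.numeric(values), con, size = 8L, endian = "little")
  close(con)
  invisible(raw_series(path))
}

#' Read a slice of samples from a raw series
#'
#' @param raw a [raw_series()] handle (or a path).
#' @param start,end half-open 0-based sample range `[start, end)`; defaults to
#'   the whole file.
#' @return Numeric vector of `end - start` samples.
#' @export
read_samples <- function(raw, start = 0, end = NULL) {
  if (is.character(raw)) raw <- raw_series(raw)
  if (is.null(end)) end <- raw$n_samples
  stopifnot(start >= 0, end <= raw$n_samples, start <= end)
  if (end == start) return(numeric(0))
  con <- file(raw$path, "rb")
  on.exit(close(con))
  seek(con, where = 8 * start)
  readBin(con, "numeric", n = end - start, size = 8L, endian = "little")
}
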