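#' @keywords internal
"_PACKAGE"

## Sample positions are unsigned 64-bit quantities on disk but are held as R
## doubles in memory, which are exact integers on [0, 2^53).  All bit
## operations below are therefore implemented with exact double arithmetic
## (integer division / modulo by powers of two) rather than 32-bit bitwOps.

#' Largest representable sample position
#'
#' Positions are stored on disk as 64-bit unsigned integers but handled in R
#' as doubles, which represent integers exactly up to 2^53. All position
#' arguments in the package must lie in `[0, max_position()]`.
#'
#' @return The largest exactly-representable sample position, `2^53 - 1`.
#' @export
max_position <- function() 2^53 - 1

assert_position <- function(pos, what = "position") {
  if (!is.numeric(pos) || any(!is.finite(pos)) || any(pos < 0) ||
      any(pos > max_position()) || any(pos != floor(pos))) {
    stop(sprintf("%s must be an integer-valued number in [0, 2^53)", what),
         call. = FALSE)
  }
  invisible(as.numeric(pos))
}

is_power_of_two <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 &&
    x == floor(x) && abs(log2(x) - round(log2(x))) < 1e-9 &&
    2^round(log2(x)) == x
}

#' Zero the low bits of sample positions
#'
#' The elementary data-reduction step for annotation data: all positions that
#' agree above `zero_bits` collapse onto one representative on a grid of
#' spacing `2^zero_bits`.
#'
#' @param pos numeric vector of sample positions.
#' @param zero_bits number of low-order bits to clear (`>= 0`).
#' @return Numeric vector of the same length with the low bits cleared.
#' @export
mask_low_bits <- function(pos, zero_bits) {
  stopifnot(length(zero_bits) == 1L, zero_bits >= 0)
  if (zero_bits == 0) return(pos)
  if (zero_bits >= 64) return(rep(0, length(pos)))
  g <- 2^zero_bits
  pos - (pos %% g)
}

## r-bit path chunk i (1-based, most significant first) of a 64-bit position
pos_chunk <- function(pos, i, branchfactor) {
  shift <- 64 - i * branchfactor
  floor(pos / 2^shift) %% 2^branchfactor
}

chunk_hex <- function(chunk, branchfactor) {
  digits <- ceiling(branchfactor / 4)
  sprintf(paste0("%0", digits, "x"), as.integer(chunk))
}

## ---- 64-bit little-endian unsigned binary files -------------------------

write_u64 <- function(values, path) {
  n <- length(values)
  if (n == 0L) {
    writeBin(raw(0), path)
    return(invisible(path))
  }
  m <- matrix(0, nrow = 8L, ncol = n)
  for (k in 0:7) m[k + 1L, ] <- floor(values / 2^(8 * k)) %% 256
  writeBin(as.raw(m), path)
  invisible(path)
}

read_u64 <- function(path) {
  sz <- file.size(path)
  if (is.na(sz) || sz == 0) return(numeric(0))
  if (sz %% 8 != 0) stop("corrupt 64-bit record file: ", path, call. = FALSE)
  b <- readBin(path, "raw", n = sz)
  m <- matrix(as.integer(b), nrow = 8L)
  as.numeric(colSums(m * 2^(8 * (0:7))))
}
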