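# Encoding lookup tables. All k-mer arithmetic in this package reduces
# to byte-wise table lookups over these three arrays.

.pkgenv <- new.env(parent = emptyenv())

#' Build the nucleotide encoding lookup tables
#'
#' Constructs the three tables that drive all 2-bit k-mer arithmetic:
#'
#' * `rc4`: a 256-entry table indexed by an encoded 4-mer byte, giving
#'   the encoded reverse complement of that 4-mer. Reverse
#'   complementation of an arbitrary k-mer is performed by slicing it
#'   into 4-mer bytes, mapping each through `rc4`, and concatenating
#'   the results in reverse order.
#' * `base2bit`: a 256-entry table mapping an ASCII byte to its 2-bit
#'   code (`A`/`a` = 0, `C`/`c` = 1, `G`/`g` = 2, `T`/`t` = 3); every
#'   other byte maps to the invalid sentinel `NA`.
#' * `bit2base`: the length-4 inverse map from 2-bit codes back to
#'   ASCII bases.
#'
#' The base map is chosen so that the 2-bit code of each base is the
#' bitwise complement of the code of its Watson-Crick partner
#' (`A` = 00 vs `T` = 11, `C` = 01 vs `G` = 10). This makes plain
#' sequence reversal available as a bit inversion of the reverse
#' complement, and makes integer order on codes coincide with
#' lexicographic order on k-mer strings.
#'
#' @return A list with integer vector `rc4` (length 256, values
#'   0..255), integer vector `base2bit` (length 256, values 0..3 or
#'   `NA`), and character vector `bit2base` (length 4). Tables are
#'   indexed 1-based in R: entry for byte/code `i` is at `[i + 1]`.
#' @examples
#' tb <- build_tables()
#' tb$bit2base                       # "A" "C" "G" "T"
#' tb$rc4[27 + 1]                    # 27: ACGT is its own revcomp
#' @export
build_tables <- function() {
  bit2base <- c("A", "C", "G", "T")
  base2bit <- rep(NA_integer_, 256L)
  base2bit[utf8ToInt("A") + 1L] <- 0L
  base2bit[utf8ToInt("C") + 1L] <- 1L
  base2bit[utf8ToInt("G") + 1L] <- 2L
  base2bit[utf8ToInt("T") + 1L] <- 3L
  base2bit[utf8ToInt("a") + 1L] <- 0L
  base2bit[utf8ToInt("c") + 1L] <- 1L
  base2bit[utf8ToInt("g") + 1L] <- 2L
  base2bit[utf8ToInt("t") + 1L] <- 3L

  # byte i encodes the 4-mer b1 b2 b3 b4 with b1 in the high bit pair;
  # its reverse complement is ~b4 ~b3 ~b2 ~b1 (2-bit complement = 3 - b)
  i <- 0:255
  b1 <- i %/% 64L
  b2 <- (i %/% 16L) %% 4L
  b3 <- (i %/% 4L) %% 4L
  b4 <- i %% 4L
  rc4 <- (3L - b4) * 64L + (3L - b3) * 16L + (3L - b2) * 4L + (3L - b1)

  list(rc4 = as.integer(rc4), base2bit = base2bit, bit2base = bit2base)
}

# cached copy used by the hot paths
tables <- function() {
  if (is.null(.pkgenv$tables)) .pkgenv$tables <- build_tables()
  .pkgenv$tables
}
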