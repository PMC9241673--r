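# Bit-packed k-mer values. A k-mer is stored as a 2k-bit unsigned
# integer: base i (0-based) occupies bit pair 2(k-1-i), i.e. the first
# base sits in the most significant pair. The integer is held as a
# big-endian raw vector of ceil(k/4) bytes with zero padding in the
# high bits of the first byte, so each byte below the pad is a 4-mer
# slice -- the unit on which the rc4 lookup table operates.

new_kmer <- function(k, code) {
  structure(list(k = as.integer(k), code = code), class = "kmer")
}

n_bytes <- function(k) (k + 3L) %/% 4L

#' Encode a DNA window as a bit-packed k-mer
#'
#' Packs a length-`k` window of unambiguous bases into a 2k-bit
#' unsigned integer, two bits per base (`A`=00, `C`=01, `G`=10,
#' `T`=11), first base in the most significant bit pair. Under this
#' layout integer order on codes equals lexicographic order on k-mer
#' strings. Each base is translated through the `base2bit` lookup
#' table (see [build_tables()]).
#'
#' @param window A DNA string of exactly `k` unambiguous bases
#'   (lowercase accepted; `N` is rejected because the 2-bit code has
#'   no room for ambiguity).
#' @param k K-mer length, between 1 and 1024. Defaults to the window
#'   length.
#' @return An object of class `"kmer"` with fields `k` and `code`
#'   (big-endian raw vector holding the 2k-bit integer).
#' @examples
#' encode_kmer("ACGT")             # code 27
#' kmer_code(encode_kmer("A"))     # 0
#' @seealso [decode_kmer()], [revcomp_kmer()], [kmer_code()]
#' @export
encode_kmer <- function(window, k = nchar(window)) {
  if (!is.character(window) || length(window) != 1L) {
    seqops_error("window must be a single string", "seqops_invalid_sequence")
  }
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > 1024L) {
    seqops_error("k must be between 1 and 1024", "seqops_bad_k")
  }
  if (nchar(window) != k) {
    seqops_error(sprintf("window length %d does not match k = %d",
                         nchar(window), k),
                 "seqops_length_mismatch")
  }
  codes <- tables()$base2bit[as.integer(charToRaw(window)) + 1L]
  if (anyNA(codes)) {
    seqops_error("window contains a base that is not A/C/G/T",
                 "seqops_ambiguous_base")
  }
  pad <- (-k) %% 4L
  if (pad > 0L) codes <- c(integer(pad), codes)
  m <- matrix(codes, nrow = 4L)
  new_kmer(k, as.raw(m[1L, ] * 64L + m[2L, ] * 16L + m[3L, ] * 4L + m[4L, ]))
}

#' Decode a bit-packed k-mer back to a DNA string
#'
#' Inverse of [encode_kmer()]: unpacks each 2-bit code through the
#' `bit2base` table.
#'
#' @param km A `"kmer"` object.
#' @return The k-mer as an upper-case DNA string.
#' @examples
#' decode_kmer(encode_kmer("GATTACA"))  # "GATTACA"
#' @export
decode_kmer <- function(km) {
  stopifnot(inherits(km, "kmer"))
  v <- as.integer(km$code)
  c4 <- rbind(v %/% 64L, (v %/% 16L) %% 4L, (v %/% 4L) %% 4L, v %% 4L)
  codes <- as.vector(c4)
  codes <- codes[(length(codes) - km$k + 1L):length(codes)]
  # bit2base as ASCII bytes: A=65 C=67 G=71 T=84
  rawToChar(as.raw(c(65L, 67L, 71L, 84L)[codes + 1L]))
}

#' Reverse complement of a bit-packed k-mer
#'
#' Computed entirely by table lookup: the code is sliced into 4-mer
#' bytes, each byte is mapped through the 256-entry `rc4` table, and
#' the mapped bytes are concatenated in reverse order. When `k` is not
#' a multiple of 4 the k-mer is first padded with `A` bases (code 00)
#' to a 4-mer boundary; the corresponding `T` bases appearing at the
#' front of the reverse complement are then dropped by masking to the
#' low 2k bits.
#'
#' @param km A `"kmer"` object.
#' @return The reverse-complemented `"kmer"` (same `k`).
#' @examples
#' decode_kmer(revcomp_kmer(encode_kmer("AACC")))   # "GGTT"
#' decode_kmer(revcomp_kmer(encode_kmer("ACGTA")))  # "TACGT"
#' @export
revcomp_kmer <- function(km) {
  stopifnot(inherits(km, "kmer"))
  k <- km$k
  v <- as.integer(km$code)
  nb <- length(v)
  pad <- (-k) %% 4L
  if (pad > 0L) {
    # append pad A-bases: shift the whole code left by 2*pad bits so
    # every byte becomes a full 4-mer slice (the top pad bits are zero)
    sft <- 2L * pad
    hi <- bitwAnd(bitwShiftL(v, sft), 255L)
    lo <- bitwShiftR(c(v[-1L], 0L), 8L - sft)
    v <- bitwOr(hi, lo)
  }
  r <- rev(tables()$rc4[v + 1L])
  # drop the pad T-bases: keep only the low 2k bits
  topbits <- 2L * k - 8L * (nb - 1L)
  if (topbits < 8L) r[1L] <- bitwAnd(r[1L], bitwShiftL(1L, topbits) - 1L)
  new_kmer(k, as.raw(r))
}

#' Reverse (without complementing) a bit-packed k-mer
#'
#' Because the base map satisfies `code(A) = ~code(T)` and
#' `code(C) = ~code(G)` over two bits, complementation is exactly bit
#' inversion, so plain reversal is the bitwise NOT of the reverse
#' complement restricted to the low 2k bits.
#'
#' @param km A `"kmer"` object.
#' @return The reversed `"kmer"` (same `k`).
#' @examples
#' decode_kmer(reverse_kmer(encode_kmer("ACGT")))  # "TGCA"
#' @export
reverse_kmer <- function(km) {
  rc <- revcomp_kmer(km)
  k <- rc$k
  v <- 255L - as.integer(rc$code)
  nb <- length(v)
  topbits <- 2L * k - 8L * (nb - 1L)
  if (topbits < 8L) v[1L] <- bitwAnd(v[1L], bitwShiftL(1L, topbits) - 1L)
  new_kmer(k, as.raw(v))
}

#' Numeric value of a k-mer code
#'
#' Returns the 2k-bit code as a double. Exact only while 2k fits in
#' the 53-bit mantissa, i.e. k <= 26; wider k-mers keep their exact
#' value in the raw-byte representation and cannot be flattened to a
#' single double.
#'
#' @param km A `"kmer"` object.
#' @return A double in `[0, 4^k)`.
#' @export
kmer_code <- function(km) {
  stopifnot(inherits(km, "kmer"))
  if (km$k > 26L) {
    seqops_error("code exceeds exact double range for k > 26; use km$code",
                 "seqops_bad_k")
  }
  v <- as.integer(km$code)
  sum(v * 256^((length(v) - 1L):0))
}

#' Construct a k-mer from its numeric code
#'
#' @param code Non-negative integer code, `0 <= code < 4^k`.
#' @param k K-mer length (at most 26 so the double is exact).
#' @return A `"kmer"` object.
#' @examples
#' decode_kmer(kmer_from_code(27, 4))  # "ACGT"
#' @export
kmer_from_code <- function(code, k) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > 26L) {
    seqops_error("k must be between 1 and 26 for numeric codes",
                 "seqops_bad_k")
  }
  code <- as.numeric(code)
  if (is.na(code) || code < 0 || code >= 4^k || code != floor(code)) {
    seqops_error("code must be an integer in [0, 4^k)", "seqops_bad_code")
  }
  nb <- n_bytes(k)
  v <- integer(nb)
  for (i in nb:1L) {
    v[i] <- as.integer(code %% 256)
    code <- code %/% 256
  }
  new_kmer(k, as.raw(v))
}

#' @export
print.kmer <- function(x, ...) {
  code <- if (x$k <= 26L) format(kmer_code(x), scientific = FALSE) else
    paste0("0x", paste(format(x$code), collapse = ""))
  cat(sprintf("<%d-mer %s (code %s)>\n", x$k, decode_kmer(x), code))
  invisible(x)
}

#' @export
Ops.kmer <- function(e1, e2) {
  if (!.Generic %in% c("==", "!=", "<", "<=", ">", ">=")) {
    stop(sprintf("operation '%s' is not defined for kmer objects", .Generic))
  }
  if (!inherits(e1, "kmer") || !inherits(e2, "kmer") || e1$k != e2$k) {
    seqops_error("kmer comparison requires two kmers of equal k",
                 "seqops_k_mismatch")
  }
  # big-endian bytes with zeroed pad bits: byte order = integer order
  cmp <- 0L
  a <- as.integer(e1$code)
  b <- as.integer(e2$code)
  d <- which(a != b)
  if (length(d)) cmp <- if (a[d[1L]] < b[d[1L]]) -1L else 1L
  switch(.Generic,
         "==" = cmp == 0L, "!=" = cmp != 0L,
         "<" = cmp < 0L, "<=" = cmp <= 0L,
         ">" = cmp > 0L, ">=" = cmp >= 0L)
}
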