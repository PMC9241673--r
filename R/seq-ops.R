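# Sequence-level operators: k-merization, splitting, base counting,
# self-reverse-complement tests and CpG region extraction.

#' K-merize a sequence
#'
#' Yields `(position, kmer)` pairs for windows starting at 0, `stride`,
#' `2*stride`, ... with `start + k <= length`. Windows containing any
#' non-ACGT base are skipped (the position still advances), because a
#' 2-bit packed k-mer cannot represent ambiguity codes. The result is
#' lazy: consuming `m` items touches only the first `m` valid windows.
#'
#' @param s A DNA sequence.
#' @param k Window length (>= 1).
#' @param stride Step between window starts (>= 1).
#' @return A [stream][new_stream] of lists with elements `pos`
#'   (0-based start) and `kmer` (a `"kmer"` object).
#' @examples
#' ks <- stream_collect(kmers("ACGTA", 3))
#' sapply(ks, function(x) decode_kmer(x$kmer))  # "ACG" "CGT" "GTA"
#' @export
kmers <- function(s, k, stride = 1L) {
  s <- dna(s)
  k <- as.integer(k); stride <- as.integer(stride)
  stopifnot(k >= 1L, stride >= 1L)
  L <- nchar(s)
  start <- 0L
  new_stream(function() {
    while (start + k <= L) {
      w <- substr(s, start + 1L, start + k)
      p <- start
      start <<- start + stride
      if (!grepl("[^ACGT]", w)) {
        return(list(pos = p, kmer = encode_kmer(w, k)))
      }
    }
    stream_done()
  })
}

#' Split a sequence into subsequences
#'
#' Yields raw subsequences (ambiguous bases allowed) of length `width`
#' at starts 0, `stride`, `2*stride`, ... with `start + width <=
#' length`. Lazy.
#'
#' @param s A DNA sequence.
#' @param width Subsequence length (>= 1).
#' @param stride Step between starts (>= 1).
#' @return A stream of DNA strings.
#' @examples
#' unlist(stream_collect(split_seq("ACGTACG", 3, 2)))  # "ACG" "GTA" "ACG"
#' @export
split_seq <- function(s, width, stride = 1L) {
  s <- dna(s)
  width <- as.integer(width); stride <- as.integer(stride)
  stopifnot(width >= 1L, stride >= 1L)
  L <- nchar(s)
  start <- 0L
  new_stream(function() {
    if (start + width > L) return(stream_done())
    w <- substr(s, start + 1L, start + width)
    start <<- start + stride
    w
  })
}

#' Count each base in a sequence
#'
#' @param s A DNA sequence.
#' @return A named integer vector of counts over `A`, `C`, `G`, `T`,
#'   `N`; the counts sum to `nchar(s)`.
#' @examples
#' base_counts("GGCC")  # G and C each 2
#' @export
base_counts <- function(s) {
  s <- dna(s)
  out <- c(A = 0L, C = 0L, G = 0L, T = 0L, N = 0L)
  if (nchar(s) == 0L) return(out)
  tab <- tabulate(as.integer(charToRaw(s)) + 1L, nbins = 256L)
  out["A"] <- tab[utf8ToInt("A") + 1L]
  out["C"] <- tab[utf8ToInt("C") + 1L]
  out["G"] <- tab[utf8ToInt("G") + 1L]
  out["T"] <- tab[utf8ToInt("T") + 1L]
  out["N"] <- tab[utf8ToInt("N") + 1L]
  out
}

#' Is a sequence its own reverse complement?
#'
#' True iff `s == revcomp_seq(s)` and `s` is free of ambiguity codes.
#' A sequence containing `N` never counts (its strand identity is
#' undetermined), and an odd-length sequence never can be (the middle
#' base would have to complement itself).
#'
#' @param s A DNA sequence.
#' @return Logical scalar. The empty sequence is trivially `TRUE`.
#' @examples
#' is_self_revcomp("ACGT")  # TRUE
#' is_self_revcomp("AAAA")  # FALSE
#' @export
is_self_revcomp <- function(s) {
  s <- dna(s)
  if (grepl("N", s, fixed = TRUE)) return(FALSE)
  s == revcomp_seq(s)
}

#' Is an even-length k-mer symmetric?
#'
#' A k-mer is symmetric when its first half equals the reverse
#' complement of its second half -- equivalently, when it is its own
#' reverse complement.
#'
#' @param km A `"kmer"` object with even `k`.
#' @return Logical scalar.
#' @examples
#' is_symmetric_kmer(encode_kmer("ACGTACGTACGTACGT"))  # TRUE
#' @export
is_symmetric_kmer <- function(km) {
  stopifnot(inherits(km, "kmer"))
  if (km$k %% 2L != 0L) {
    seqops_error("symmetry is defined only for even k", "seqops_odd_k")
  }
  identical(km$code, revcomp_kmer(km)$code)
}

# Vectorized symmetric-window counter used by the benchmark commands:
# counts windows of length k (even) at the given stride whose first
# half equals the revcomp of the second half. N-containing windows
# never count.
count_symmetric <- function(s, k = 16L, stride = 1L) {
  s <- dna(s)
  k <- as.integer(k); stride <- as.integer(stride)
  stopifnot(k >= 2L, k %% 2L == 0L, stride >= 1L)
  L <- nchar(s)
  if (L < k) return(0L)
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")[ch]
  comp[is.na(comp)] <- "#"  # N complements to nothing
  starts <- seq.int(1L, L - k + 1L, by = stride)
  ok <- rep(TRUE, length(starts))
  for (j in seq_len(k %/% 2L)) {
    ok <- ok & (ch[starts + j - 1L] == comp[starts + k - j])
  }
  sum(ok)
}

#' Extract CpG regions
#'
#' Finds the maximal runs of `C`/`G` characters that contain at least
#' one `C` and at least one `G` (so `CGC` is a region but `CCC` and
#' `GGG` are not; the shortest possible region has length 2). Note this
#' is a run-based definition, not the biological CpG-island criterion.
#'
#' @param s A DNA sequence.
#' @return A list with `regions` (data frame of 0-based half-open
#'   `start`/`end` columns), `count`, and `min_len`/`max_len` of the
#'   regions (`0` when `count` is zero).
#' @examples
#' cpg_regions("CGC")$count        # 1
#' cpg_regions("CCC")$count        # 0
#' cpg_regions("ACGTGGCAC")$count  # 2: "CG" and "GGC"
#' @export
cpg_regions <- function(s) {
  s <- dna(s)
  empty <- list(regions = data.frame(start = integer(), end = integer()),
                count = 0L, min_len = 0L, max_len = 0L)
  L <- nchar(s)
  if (L == 0L) return(empty)
  b <- charToRaw(s)
  isC <- b == as.raw(utf8ToInt("C"))
  isG <- b == as.raw(utf8ToInt("G"))
  r <- rle(isC | isG)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  csC <- cumsum(isC)
  csG <- cumsum(isG)
  nC <- csC[ends] - c(0L, csC)[starts]
  nG <- csG[ends] - c(0L, csG)[starts]
  keep <- r$values & r$lengths >= 2L & nC > 0L & nG > 0L
  if (!any(keep)) return(empty)
  st <- starts[keep] - 1L  # to 0-based
  en <- ends[keep]
  list(regions = data.frame(start = st, end = en),
       count = length(st),
       min_len = min(en - st),
       max_len = max(en - st))
}
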