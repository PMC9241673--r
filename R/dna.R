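# DNA sequences are plain character scalars over {A,C,G,T,N},
# validated and uppercased on entry.

seqops_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "seqops_error")))
}

#' Validate and normalize a DNA sequence
#'
#' Uppercases the input and checks that every character is one of
#' `A`, `C`, `G`, `T`, `N`. The ambiguity code `N` is allowed in
#' sequences but can never enter a 2-bit packed [kmer][encode_kmer].
#'
#' @param x A character scalar.
#' @return The normalized sequence (plain character scalar).
#' @examples
#' dna("acgtN")  # "ACGTN"
#' @export
dna <- function(x) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    seqops_error("a DNA sequence must be a single character string",
                 "seqops_invalid_sequence")
  }
  x <- toupper(x)
  if (grepl("[^ACGTN]", x)) {
    seqops_error(
      sprintf("invalid character in DNA sequence (allowed: A,C,G,T,N): %s",
              substr(gsub("[ACGTN]", "", x), 1L, 5L)),
      "seqops_invalid_sequence")
  }
  x
}

#' Reverse complement of a sequence
#'
#' Swaps `A` with `T` and `C` with `G`, leaves `N` fixed, and reverses
#' the sequence, modelling the opposite strand of the DNA duplex.
#'
#' @param s A DNA sequence (string over A,C,G,T,N; lowercase accepted).
#' @return The reverse-complemented sequence.
#' @examples
#' revcomp_seq("ACGT")  # "ACGT" (self reverse-complementary)
#' revcomp_seq("AAC")   # "GTT"
#' @export
revcomp_seq <- function(s) {
  s <- dna(s)
  if (nchar(s) == 0L) return(s)
  rawToChar(rev(charToRaw(chartr("ACGTN", "TGCAN", s))))
}
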