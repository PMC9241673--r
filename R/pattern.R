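# The sequence pattern mini-language: literal bases, single-base
# wildcards (_) and zero-or-more gaps (...), with anchored whole-
# sequence match semantics and ordered first-match dispatch.

GAP <- "*"  # internal token for a zero-or-more gap

#' Parse a sequence pattern
#'
#' Pattern syntax: `A`/`C`/`G`/`T` are literal bases (lowercase
#' accepted), `_` matches exactly one base of any kind, and `...`
#' (three dots) matches zero or more bases. A run of dots must have a
#' length divisible by 3; consecutive gaps are collapsed since they
#' are semantically redundant.
#'
#' @param text Pattern string (a parsed pattern passes through).
#' @return An object of class `"seq_pattern"` holding the token list.
#' @examples
#' parse_pattern("...A_C_G_T...")
#' @export
parse_pattern <- function(text) {
  if (inherits(text, "seq_pattern")) return(text)
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    seqops_error("pattern must be a single string", "seqops_pattern_syntax")
  }
  up <- toupper(text)
  chars <- strsplit(up, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), c("A", "C", "G", "T", "_", "."))
  if (length(bad)) {
    seqops_error(sprintf("invalid pattern character(s): %s",
                         paste(bad, collapse = " ")),
                 "seqops_pattern_syntax")
  }
  tokens <- character(0)
  dots <- 0L
  flush_dots <- function() {
    if (dots == 0L) return(invisible())
    if (dots %% 3L != 0L) {
      seqops_error(sprintf(
        "a gap must be written as '...' (got a run of %d dots)", dots),
        "seqops_pattern_syntax")
    }
    # any number of consecutive gaps collapses to one
    if (!length(tokens) || tokens[length(tokens)] != GAP) {
      tokens <<- c(tokens, GAP)
    }
    dots <<- 0L
  }
  for (ch in chars) {
    if (ch == ".") {
      dots <- dots + 1L
    } else {
      flush_dots()
      tokens <- c(tokens, ch)
    }
  }
  flush_dots()
  structure(list(tokens = tokens, text = text), class = "seq_pattern")
}

#' @export
print.seq_pattern <- function(x, ...) {
  shown <- vapply(x$tokens, function(t) if (t == GAP) "..." else t, "")
  cat(sprintf("<seq_pattern %s (%d tokens)>\n",
              paste(shown, collapse = ""), length(x$tokens)))
  invisible(x)
}

# does the gap-free token segment match s at 1-based position st?
seg_at <- function(seg, sch, st) {
  len <- length(seg)
  if (len == 0L) return(TRUE)
  if (st < 1L || st + len - 1L > length(sch)) return(FALSE)
  piece <- sch[st:(st + len - 1L)]
  all(seg == "_" | seg == piece)
}

seg_find <- function(seg, sch, from) {
  len <- length(seg)
  if (len == 0L) return(from)
  last <- length(sch) - len + 1L
  st <- from
  while (st <= last) {
    if (seg_at(seg, sch, st)) return(st)
    st <- st + 1L
  }
  NA_integer_
}

#' Match a pattern against a whole sequence
#'
#' Anchored at both ends: the match succeeds iff each gap can absorb a
#' (possibly empty) substring and each single-base wildcard exactly
#' one character so the concatenation reproduces `s` exactly. A
#' literal matches only its own base; `_` matches any of A, C, G, T or
#' N. Wrap a pattern in leading/trailing `...` to test containment.
#'
#' The matcher splits the pattern at its gaps and places the gap-free
#' segments left to right, each at its leftmost feasible position
#' (segments flanking the pattern ends are anchored); this greedy
#' placement is exact for zero-or-more wildcards and runs in
#' O(|s| * |pattern|).
#'
#' @param p Pattern string or parsed [seq_pattern][parse_pattern].
#' @param s A DNA sequence.
#' @return Logical scalar.
#' @examples
#' pattern_matches("...A_C_G_T...", "TTAACAGATTT")  # TRUE
#' pattern_matches("ACGT", "ACGA")                  # FALSE
#' @export
pattern_matches <- function(p, s) {
  p <- parse_pattern(p)
  s <- dna(s)
  tok <- p$tokens
  n <- nchar(s)
  sch <- if (n > 0L) strsplit(s, "", fixed = TRUE)[[1L]] else character(0)
  gaps <- tok == GAP
  if (!any(gaps)) {
    return(length(tok) == n && seg_at(tok, sch, 1L))
  }
  if (n < sum(!gaps)) return(FALSE)
  grp <- cumsum(gaps)[!gaps]
  segs <- if (any(!gaps)) unname(split(tok[!gaps], grp)) else list()
  lead_gap <- gaps[1L]
  trail_gap <- gaps[length(tok)]
  pos <- 1L
  if (!lead_gap && length(segs)) {
    head_seg <- segs[[1L]]
    if (!seg_at(head_seg, sch, 1L)) return(FALSE)
    pos <- 1L + length(head_seg)
    segs <- segs[-1L]
  }
  tail_seg <- NULL
  if (!trail_gap && length(segs)) {
    tail_seg <- segs[[length(segs)]]
    segs <- segs[-length(segs)]
  }
  for (sg in segs) {
    found <- seg_find(sg, sch, pos)
    if (is.na(found)) return(FALSE)
    pos <- found + length(sg)
  }
  if (!is.null(tail_seg)) {
    st <- n - length(tail_seg) + 1L
    if (st < pos) return(FALSE)
    if (!seg_at(tail_seg, sch, st)) return(FALSE)
  }
  TRUE
}

#' Ordered first-match dispatch
#'
#' Tries each case in order and returns the tag of the first whose
#' pattern matches the sequence; a trailing all-gap pattern (`"..."`)
#' therefore acts as a default case.
#'
#' @param s A DNA sequence.
#' @param cases A list of two-element lists (or pairs) `list(pattern,
#'   tag)`; patterns may be strings or parsed patterns.
#' @return The matching tag, or `NULL` if no case matches.
#' @examples
#' match_dispatch("ACGT", list(list("AAAA", 1), list("A...", 2),
#'                             list("...", 3)))  # 2
#' @export
match_dispatch <- function(s, cases) {
  s <- dna(s)
  for (cs in cases) {
    if (length(cs) != 2L) {
      seqops_error("each case must be list(pattern, tag)",
                   "seqops_pattern_syntax")
    }
    if (pattern_matches(cs[[1L]], s)) return(cs[[2L]])
  }
  NULL
}
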