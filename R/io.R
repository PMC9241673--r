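# Streaming FASTA/FASTQ input and output (gzip-transparent reading)
# and the seeded synthetic read/reference generator.

# Line source over a connection, with one-line pushback and line
# numbers for error reporting. The connection is closed on exhaustion
# and by finalizer if the stream is dropped early.
line_source <- function(path) {
  con <- gzfile(path, open = "rt")
  st <- new.env(parent = emptyenv())
  st$line_no <- 0L
  st$pushed <- NULL
  st$closed <- FALSE
  st$con <- con
  reg.finalizer(st, function(e) {
    if (!e$closed) try(close(e$con), silent = TRUE)
  })
  st$close <- function() {
    if (!st$closed) {
      st$closed <- TRUE
      close(con)
    }
  }
  st$get <- function() {
    if (!is.null(st$pushed)) {
      ln <- st$pushed
      st$pushed <- NULL
      return(ln)
    }
    if (st$closed) return(NULL)
    ln <- readLines(con, n = 1L, warn = FALSE)
    if (!length(ln)) {
      st$close()
      return(NULL)
    }
    st$line_no <- st$line_no + 1L
    ln
  }
  st$unget <- function(ln) st$pushed <- ln
  st
}

format_error <- function(path, line_no, msg) {
  seqops_error(sprintf("%s:%d: %s", path, line_no, msg), "seqops_format")
}

#' Read a FASTA file lazily
#'
#' Multi-line records are joined, lowercase is normalized to
#' uppercase, and the record name is the header text after `>` up to
#' the first whitespace. Reading is gzip transparent and streaming:
#' records are parsed on demand.
#'
#' @param path Path to a FASTA file (optionally gzip compressed).
#' @return A stream of lists with `name` and `seq`.
#' @export
read_fasta <- function(path) {
  ls_ <- line_source(path)
  new_stream(function() {
    repeat {
      ln <- ls_$get()
      if (is.null(ln)) return(stream_done())
      if (nchar(trimws(ln)) == 0L) next
      if (!startsWith(ln, ">")) {
        format_error(path, ls_$line_no, "sequence data before any '>' header")
      }
      name <- strsplit(sub("^>\\s*", "", ln), "\\s+")[[1L]][1L]
      if (is.na(name) || !nchar(name)) {
        format_error(path, ls_$line_no, "empty FASTA header")
      }
      chunks <- character(0)
      repeat {
        ln2 <- ls_$get()
        if (is.null(ln2)) break
        if (startsWith(ln2, ">")) {
          ls_$unget(ln2)
          break
        }
        if (nchar(trimws(ln2))) chunks <- c(chunks, trimws(ln2))
      }
      if (!length(chunks)) {
        format_error(path, ls_$line_no, sprintf("record '%s' has no sequence",
                                                name))
      }
      return(list(name = name, seq = dna(paste(chunks, collapse = ""))))
    }
  })
}

#' Write records to a FASTA file
#'
#' @param records Stream/list of lists with `name` and `seq`, or a
#'   named character vector.
#' @param path Output path.
#' @param wrap Line width for sequence wrapping; `0` disables
#'   wrapping. Default 60.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, wrap = 60L) {
  wrap <- as.integer(wrap)
  stopifnot(wrap >= 0L)
  if (is.character(records)) {
    nms <- names(records)
    records <- Map(function(n, s) list(name = n, seq = s), nms, records)
  }
  src <- as_stream(records)
  con <- file(path, open = "wt")
  on.exit(close(con))
  repeat {
    rec <- stream_next(src)
    if (is_stream_done(rec)) break
    s <- dna(rec$seq)
    writeLines(paste0(">", rec$name), con)
    if (wrap > 0L && nchar(s) > wrap) {
      starts <- seq.int(1L, nchar(s), by = wrap)
      writeLines(substring(s, starts, pmin(starts + wrap - 1L, nchar(s))),
                 con)
    } else {
      writeLines(s, con)
    }
  }
  invisible(path)
}

#' Construct a FASTQ record
#'
#' @param name Read identifier.
#' @param seq DNA sequence.
#' @param qual Phred+33 quality string of the same length, characters
#'   in ASCII 33..126.
#' @return A list with class `"fastq_record"`.
#' @export
fastq_record <- function(name, seq, qual) {
  seq <- dna(seq)
  if (!is.character(qual) || length(qual) != 1L ||
      nchar(qual) != nchar(seq)) {
    seqops_error("quality string length must equal sequence length",
                 "seqops_format")
  }
  if (nchar(qual)) {
    qv <- as.integer(charToRaw(qual))
    if (any(qv < 33L | qv > 126L)) {
      seqops_error("quality characters must be in ASCII 33..126",
                   "seqops_format")
    }
  }
  structure(list(name = name, seq = seq, qual = qual),
            class = "fastq_record")
}

#' Read a FASTQ file lazily
#'
#' Expects 4-line records (`@name`, sequence, `+` separator with any
#' trailing text ignored, quality). Record invariants (equal
#' sequence/quality length, printable Phred+33 qualities) are
#' enforced; errors carry the offending line number.
#'
#' @param path Path to a FASTQ file (optionally gzip compressed).
#' @return A stream of [fastq_record()] objects.
#' @export
read_fastq <- function(path) {
  ls_ <- line_source(path)
  new_stream(function() {
    h <- ls_$get()
    if (is.null(h)) return(stream_done())
    if (!startsWith(h, "@")) {
      format_error(path, ls_$line_no, "expected '@' record header")
    }
    name <- strsplit(sub("^@", "", h), "\\s+")[[1L]][1L]
    s <- ls_$get()
    p <- ls_$get()
    q <- ls_$get()
    if (is.null(s) || is.null(p) || is.null(q)) {
      format_error(path, ls_$line_no, "truncated FASTQ record")
    }
    if (!startsWith(p, "+")) {
      format_error(path, ls_$line_no - 1L, "expected '+' separator line")
    }
    tryCatch(fastq_record(name, s, q),
             seqops_error = function(e) {
               format_error(path, ls_$line_no, conditionMessage(e))
             })
  })
}

#' Write FASTQ records
#'
#' @param records Stream/list of [fastq_record()]-shaped lists.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path) {
  src <- as_stream(records)
  con <- file(path, open = "wt")
  on.exit(close(con))
  repeat {
    rec <- stream_next(src)
    if (is_stream_done(rec)) break
    writeLines(c(paste0("@", rec$name), rec$seq, "+", rec$qual), con)
  }
  invisible(path)
}

# evaluate expr under a private RNG state seeded with `seed`,
# restoring the caller's stream afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate synthetic reads
#'
#' Draws bases i.i.d. from `base_weights`, independently replaces each
#' base by `N` with probability `n_rate`, and assigns the constant
#' quality `I` (Phred 40) to every base. Deterministic given `seed`;
#' the caller's RNG state is untouched. The defaults emulate the
#' short-read regime of 75 bp Illumina-style reads.
#'
#' @param n_reads Number of reads.
#' @param read_length Bases per read (default 75).
#' @param base_weights Probability 4-vector over A, C, G, T (must sum
#'   to 1; default uniform).
#' @param n_rate Per-base probability of an `N` call (default 0).
#' @param seed Integer seed.
#' @return A stream of [fastq_record()] objects named
#'   `read1..read<n>`.
#' @export
generate_reads <- function(n_reads, read_length = 75L,
                           base_weights = c(0.25, 0.25, 0.25, 0.25),
                           n_rate = 0, seed = 1L) {
  n_reads <- as.integer(n_reads)
  read_length <- as.integer(read_length)
  stopifnot(n_reads >= 0L, read_length >= 1L,
            length(base_weights) == 4L, all(base_weights >= 0),
            abs(sum(base_weights) - 1) < 1e-6, n_rate >= 0, n_rate <= 1)
  if (n_reads == 0L) return(as_stream(list()))
  seqs <- with_seed(seed, {
    bases <- sample(c("A", "C", "G", "T"), n_reads * read_length,
                    replace = TRUE, prob = base_weights)
    if (n_rate > 0) {
      bases[stats::runif(length(bases)) < n_rate] <- "N"
    }
    m <- matrix(bases, nrow = read_length)
    do.call(paste0, as.data.frame(t(m), stringsAsFactors = FALSE))
  })
  qual <- strrep("I", read_length)
  i <- 0L
  new_stream(function() {
    if (i >= n_reads) return(stream_done())
    i <<- i + 1L
    structure(list(name = paste0("read", i), seq = seqs[[i]], qual = qual),
              class = "fastq_record")
  })
}

#' Generate a synthetic reference sequence
#'
#' Uniform i.i.d. ACGT string, deterministic given `seed`.
#'
#' @param length Reference length in bases.
#' @param seed Integer seed.
#' @return A DNA string.
#' @export
generate_reference <- function(length, seed = 1L) {
  length <- as.integer(length)
  stopifnot(length >= 0L)
  if (length == 0L) return("")
  with_seed(seed, paste(sample(c("A", "C", "G", "T"), length,
                               replace = TRUE), collapse = ""))
}
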