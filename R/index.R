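# Hash index from k-mers to reference positions, with an advisory
# prefetch protocol and read seeding. Keys are the k-mer strings
# themselves (the decoded form of the 2-bit code, with which they are
# in bijection); values are sorted 0-based positions in the
# concatenated reference.

#' Build a k-mer hash index over a reference
#'
#' Records every ambiguity-free window of length `k` at stride 1,
#' mapping the k-mer to the sorted list of its 0-based positions.
#' Multi-contig references (a named character vector) are laid out in
#' a single coordinate space using per-contig offsets, recorded in the
#' index so hits can be mapped back; windows never span a contig
#' boundary.
#'
#' @param reference A DNA string or named character vector of contigs
#'   (lowercase accepted; `N` allowed but indexed around).
#' @param k K-mer length (default 20).
#' @return An object of class `"kmer_index"` with fields `k`,
#'   `ref_length`, `contigs` (data frame `name`/`offset`/`length`),
#'   the hash `table`, and instrumentation counters
#'   (`access_count()`/`prefetch_count()` report them).
#' @examples
#' ix <- build_index("ACGTACGTAC", k = 4)
#' kmer_lookup(ix, "ACGT")  # 0 4
#' @export
build_index <- function(reference, k = 20L) {
  k <- as.integer(k)
  stopifnot(k >= 1L, k <= 1024L)
  seqs <- vapply(reference, dna, "", USE.NAMES = FALSE)
  nms <- names(reference)
  if (is.null(nms)) nms <- paste0("contig", seq_along(seqs))
  lens <- nchar(seqs)
  if (!length(seqs) || max(lens) < k) {
    seqops_error(sprintf("reference too short: no contig reaches k = %d", k),
                 "seqops_reference_too_short")
  }
  offsets <- c(0L, cumsum(lens))[seq_along(seqs)]

  all_wins <- character(0)
  all_pos <- integer(0)
  for (ci in seq_along(seqs)) {
    L <- lens[ci]
    if (L < k) next
    starts <- 0:(L - k)
    wins <- substring(seqs[ci], starts + 1L, starts + k)
    ok <- !grepl("[^ACGT]", wins)
    all_wins <- c(all_wins, wins[ok])
    all_pos <- c(all_pos, starts[ok] + offsets[ci])
  }
  tab <- split(all_pos, all_wins)  # per key ascending: insertion order

  counters <- new.env(parent = emptyenv())
  counters$access <- 0L
  counters$prefetch <- 0L
  structure(list(
    k = k,
    ref_length = sum(lens),
    contigs = data.frame(name = nms, offset = offsets, length = lens,
                         stringsAsFactors = FALSE),
    table = list2env(tab, hash = TRUE, size = max(length(tab), 29L)),
    counters = counters
  ), class = "kmer_index")
}

index_key <- function(ix, km) {
  if (inherits(km, "kmer")) {
    if (km$k != ix$k) {
      seqops_error(sprintf("k mismatch: index has k = %d, query has k = %d",
                           ix$k, km$k), "seqops_k_mismatch")
    }
    return(decode_kmer(km))
  }
  km <- dna(km)
  if (nchar(km) != ix$k) {
    seqops_error(sprintf("k mismatch: index has k = %d, query has %d bases",
                         ix$k, nchar(km)), "seqops_k_mismatch")
  }
  km
}

#' Query the index for a k-mer
#'
#' @param ix A `"kmer_index"`.
#' @param km A `"kmer"` object or a k-mer string of the index's `k`.
#' @return Sorted integer vector of 0-based positions (empty when the
#'   k-mer is absent). Each call increments the access counter.
#' @export
kmer_lookup <- function(ix, km) {
  stopifnot(inherits(ix, "kmer_index"))
  key <- index_key(ix, km)
  ix$counters$access <- ix$counters$access + 1L
  hits <- get0(key, envir = ix$table, inherits = FALSE)
  if (is.null(hits)) integer(0) else hits
}

#' Issue an advisory prefetch for a k-mer
#'
#' Semantically inert: a subsequent [kmer_lookup()] returns exactly
#' what it would have without the hint. The prefetch counter is
#' incremented so schedulers can be instrumented.
#'
#' @inheritParams kmer_lookup
#' @return `NULL`, invisibly.
#' @export
kmer_prefetch <- function(ix, km) {
  stopifnot(inherits(ix, "kmer_index"))
  index_key(ix, km)  # same validation as a real access
  ix$counters$prefetch <- ix$counters$prefetch + 1L
  invisible(NULL)
}

#' @rdname kmer_lookup
#' @export
access_count <- function(ix) ix$counters$access

#' @rdname kmer_prefetch
#' @export
prefetch_count <- function(ix) ix$counters$prefetch

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("<kmer_index k=%d, %d contig(s), reference %d bp, %d distinct k-mers>\n",
              x$k, nrow(x$contigs), x$ref_length, length(x$table)))
  invisible(x)
}

# k-mer window strings of a read at the given step; N windows dropped
read_windows <- function(s, k, step) {
  L <- nchar(s)
  if (L < k) return(character(0))
  starts <- seq.int(0L, L - k, by = step)
  wins <- substring(s, starts + 1L, starts + k)
  wins[!grepl("[^ACGT]", wins)]
}

#' Seed reads against a k-mer index
#'
#' For each read, k-merizes at the given `step` and accumulates the
#' number of candidate reference loci of each k-mer (`hits_forward`)
#' and of its reverse complement (`hits_reverse`) -- the standard
#' seeding step preceding alignment, counting both strands because
#' roughly half of all reads originate from the reverse strand. With
#' `prefetch = TRUE` the per-k-mer queries are routed through the
#' M-slot [run_prefetch()] scheduler; results are identical either
#' way.
#'
#' @param ix A `"kmer_index"`.
#' @param reads Stream/list of FASTQ records (see [read_fastq()]), or
#'   a character vector of sequences.
#' @param step Stride between k-mer starts; defaults to `k`
#'   (non-overlapping seeds).
#' @param prefetch Route queries through the prefetch scheduler?
#' @param M Scheduler slot count (default 16).
#' @return A lazy stream of seed reports: lists with `name`,
#'   `hits_forward`, `hits_reverse`.
#' @examples
#' ix <- build_index("ACGTACGTAC", k = 4)
#' rep1 <- stream_collect(seed_reads(ix, "ACGTACGT", step = 1))[[1]]
#' rep1$hits_forward  # 9
#' @export
seed_reads <- function(ix, reads, step = ix$k, prefetch = FALSE, M = 16L) {
  stopifnot(inherits(ix, "kmer_index"))
  step <- as.integer(step)
  stopifnot(step >= 1L)
  src <- as_stream(reads)
  query_stage <- prefetch_stage(
    prefetch = function(q) kmer_prefetch(ix, q),
    load = function(q) length(kmer_lookup(ix, q)),
    label = "index query")

  seed_one <- function(rec) {
    if (is.character(rec)) rec <- list(name = NA_character_, seq = rec)
    wins <- read_windows(dna(rec$seq), ix$k, step)
    queries <- c(wins, vapply(wins, revcomp_seq, "", USE.NAMES = FALSE))
    counts <- if (prefetch) {
      unlist(stream_collect(run_prefetch(query_stage, queries, M)))
    } else {
      vapply(queries, function(q) length(kmer_lookup(ix, q)), 0L,
             USE.NAMES = FALSE)
    }
    nf <- length(wins)
    list(name = rec$name,
         hits_forward = if (nf) sum(counts[seq_len(nf)]) else 0L,
         hits_reverse = if (nf) sum(counts[-seq_len(nf)]) else 0L)
  }
  run_pipeline(pipeline(stage_map(seed_one, label = "seed")), src)
}

#' Save / load a k-mer index as a versioned text table
#'
#' The format is line oriented: a header line
#' `#seqops-kmer-index<TAB>v1<TAB>k<TAB>ref_length`, one
#' `@<TAB>name<TAB>offset<TAB>length` line per contig, then one
#' `kmer<TAB>pos1,pos2,...` line per distinct k-mer, sorted.
#'
#' @param ix A `"kmer_index"`.
#' @param path File path.
#' @return `write_index` returns `path` invisibly; `read_index`
#'   returns the reconstructed index (counters reset to zero).
#' @export
write_index <- function(ix, path) {
  stopifnot(inherits(ix, "kmer_index"))
  keys <- sort(ls(ix$table))
  lines <- c(
    sprintf("#seqops-kmer-index\tv1\t%d\t%d", ix$k, ix$ref_length),
    sprintf("@\t%s\t%d\t%d", ix$contigs$name, ix$contigs$offset,
            ix$contigs$length),
    vapply(keys, function(kk) {
      paste0(kk, "\t", paste(get(kk, envir = ix$table), collapse = ","))
    }, "", USE.NAMES = FALSE)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_index
#' @export
read_index <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1L], "#seqops-kmer-index\tv1\t")) {
    seqops_error("not a v1 seqops k-mer index file", "seqops_format")
  }
  hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  k <- as.integer(hdr[3L])
  ref_length <- as.integer(hdr[4L])
  is_contig <- startsWith(lines, "@\t")
  cparts <- strsplit(lines[is_contig], "\t", fixed = TRUE)
  contigs <- data.frame(
    name = vapply(cparts, `[`, "", 2L),
    offset = as.integer(vapply(cparts, `[`, "", 3L)),
    length = as.integer(vapply(cparts, `[`, "", 4L)),
    stringsAsFactors = FALSE)
  body <- lines[!is_contig][-1L]
  tab <- new.env(hash = TRUE, parent = emptyenv(),
                 size = max(length(body), 29L))
  for (ln in body) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    assign(parts[1L],
           as.integer(strsplit(parts[2L], ",", fixed = TRUE)[[1L]]),
           envir = tab)
  }
  counters <- new.env(parent = emptyenv())
  counters$access <- 0L
  counters$prefetch <- 0L
  structure(list(k = k, ref_length = ref_length, contigs = contigs,
                 table = tab, counters = counters),
            class = "kmer_index")
}
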