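# Independent brute-force oracles and random-input generators used
# across the suite. These deliberately avoid the package's own code
# paths (no lookup tables, no bit arithmetic, no glob matcher).

# character-by-character reverse complement
oracle_revcomp <- function(s) {
  if (nchar(s) == 0L) return(s)
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

# byte-wise lexicographic string comparison (locale independent)
str_lt <- function(a, b) {
  x <- utf8ToInt(a)
  y <- utf8ToInt(b)
  n <- min(length(x), length(y))
  if (n > 0L) {
    d <- which(x[seq_len(n)] != y[seq_len(n)])
    if (length(d)) return(x[d[1L]] < y[d[1L]])
  }
  length(x) < length(y)
}

# translate a pattern string to an anchored ERE: each '...' -> '.*',
# '_' -> '.', literals stand for themselves
pattern_to_regex <- function(text) {
  r <- gsub("...", "\001", toupper(text), fixed = TRUE)
  r <- gsub("_", ".", r, fixed = TRUE)
  r <- gsub("\001", ".*", r, fixed = TRUE)
  paste0("^", r, "$")
}

# brute-force CpG segmentation by linear scan
oracle_cpg <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  regions <- list()
  i <- 1L
  while (i <= n) {
    if (ch[i] %in% c("C", "G")) {
      j <- i
      while (j < n && ch[j + 1L] %in% c("C", "G")) j <- j + 1L
      seg <- ch[i:j]
      if (length(seg) >= 2L && "C" %in% seg && "G" %in% seg) {
        regions[[length(regions) + 1L]] <- c(start = i - 1L, end = j)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  regions
}

# naive window scan of a reference for one k-mer (0-based positions)
oracle_scan <- function(ref, km) {
  L <- nchar(ref)
  k <- nchar(km)
  if (L < k) return(integer(0))
  which(substring(ref, 1:(L - k + 1L), k:L) == km) - 1L
}

rand_dna <- function(n, n_rate = 0) {
  if (n == 0L) return("")
  b <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  if (n_rate > 0) b[runif(n) < n_rate] <- "N"
  paste(b, collapse = "")
}

rand_pattern <- function(max_len = 8L) {
  n <- sample(0:max_len, 1L)
  if (n == 0L) return("")
  toks <- sample(c("A", "C", "G", "T", "_", "..."), n, replace = TRUE,
                 prob = c(rep(0.15, 4), 0.2, 0.2))
  paste(toks, collapse = "")
}

# every k-mer string of length k, in code order (A<C<G<T)
all_kmer_strings <- function(k) {
  g <- do.call(expand.grid,
               c(rep(list(c("A", "C", "G", "T")), k),
                 stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE))
  # expand.grid varies the first factor fastest; code order needs the
  # last position fastest, so feed columns reversed
  do.call(paste0, rev(as.list(g)))
}

toy_fastq <- function(seqs, path = tempfile(fileext = ".fastq")) {
  write_fastq(Map(function(i, s) fastq_record(paste0("r", i), s,
                                              strrep("I", nchar(s))),
                  seq_along(seqs), seqs), path)
  path
}
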