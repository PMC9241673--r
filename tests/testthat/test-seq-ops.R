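# K-merization, splitting, base counting, symmetry tests and CpG
# region extraction.

test_that("kmers enumerates stride windows and skips ambiguous ones", {
  got <- stream_collect(kmers("ACGTA", 3, 1))
  expect_equal(vapply(got, function(x) x$pos, 0L), c(0L, 1L, 2L))
  expect_equal(vapply(got, function(x) decode_kmer(x$kmer), ""),
               c("ACG", "CGT", "GTA"))

  # every length-3 window of ACNTA contains the N
  expect_length(stream_collect(kmers("ACNTA", 3, 1)), 0L)
  # sequence shorter than k
  expect_length(stream_collect(kmers("AC", 3, 1)), 0L)

  # position advances over a skipped window
  got <- stream_collect(kmers("ANACG", 2, 1))
  expect_equal(vapply(got, function(x) x$pos, 0L), c(2L, 3L))

  # stride-1 window count on N-free input is L - k + 1
  set.seed(21)
  for (i in 1:10) {
    L <- sample(5:60, 1L)
    k <- sample(1:5, 1L)
    s <- rand_dna(L)
    expect_length(stream_collect(kmers(s, k, 1)), max(0L, L - k + 1L))
  }
})

test_that("kmers is lazy: a prefix pulls only the windows it needs", {
  # a multi-megabase input would be prohibitive if k-merized eagerly
  s <- strrep("ACGT", 500000L)
  t0 <- proc.time()[["elapsed"]]
  first <- stream_collect(kmers(s, 4, 1), 3)
  expect_equal(vapply(first, function(x) decode_kmer(x$kmer), ""),
               c("ACGT", "CGTA", "GTAC"))
  expect_lt(proc.time()[["elapsed"]] - t0, 5)
})

test_that("split_seq yields raw windows, ambiguity included", {
  expect_equal(unlist(stream_collect(split_seq("ACGTACG", 3, 2))),
               c("ACG", "GTA", "ACG"))
  expect_equal(unlist(stream_collect(split_seq("ACGT", 4, 1))), "ACGT")
  expect_length(stream_collect(split_seq("ACGT", 5, 1)), 0L)
  expect_equal(unlist(stream_collect(split_seq("ANGT", 2, 2))),
               c("AN", "GT"))

  # on N-free input the decoded kmers equal the split windows
  set.seed(8)
  s <- rand_dna(50)
  expect_equal(vapply(stream_collect(kmers(s, 5, 1)),
                      function(x) decode_kmer(x$kmer), ""),
               unlist(stream_collect(split_seq(s, 5, 1))))
})

test_that("base_counts tallies the five-letter alphabet", {
  expect_equal(unname(base_counts("")), rep(0L, 5))
  bc <- base_counts("GGCC")
  expect_equal(bc[["G"]], 2L)
  expect_equal(bc[["C"]], 2L)
  expect_equal(sum(bc), 4L)
  # gc fraction of GGCC is 1
  expect_equal((bc[["G"]] + bc[["C"]]) / sum(bc), 1)

  set.seed(13)
  s <- rand_dna(500, n_rate = 0.1)
  expect_equal(sum(base_counts(s)), 500L)
  expect_equal(base_counts(s)[["N"]],
               sum(strsplit(s, "", fixed = TRUE)[[1L]] == "N"))
})

test_that("self-reverse-complement test excludes odd lengths and N", {
  expect_true(is_self_revcomp("ACGT"))
  expect_false(is_self_revcomp("AAAA"))
  expect_true(is_self_revcomp(""))
  expect_false(is_self_revcomp("ACG"))   # odd
  expect_false(is_self_revcomp("ANT"))   # string-equal to its revcomp,
                                         # but N has no strand identity
})

test_that("k-mer symmetry equals self-reverse-complement of the decoding", {
  expect_true(is_symmetric_kmer(encode_kmer("ACGTACGTACGTACGT")))
  expect_false(is_symmetric_kmer(encode_kmer("AAAAAAAAAAAAAAAA")))
  expect_error(is_symmetric_kmer(encode_kmer("ACG")), class = "seqops_odd_k")

  # exhaustive for k in {2, 4, 6}; sampled at k = 8
  for (k in c(2L, 4L, 6L)) {
    for (code in 0:(4^k - 1)) {
      km <- kmer_from_code(code, k)
      expect_equal(is_symmetric_kmer(km), is_self_revcomp(decode_kmer(km)))
    }
  }
  set.seed(4)
  for (i in 1:500) {
    km <- kmer_from_code(sample(0:(4^8 - 1), 1L), 8L)
    expect_equal(is_symmetric_kmer(km), is_self_revcomp(decode_kmer(km)))
  }
})

test_that("vectorized symmetric-window counter matches the per-kmer test", {
  set.seed(17)
  for (i in 1:20) {
    s <- rand_dna(sample(16:80, 1L), n_rate = 0.03)
    want <- sum(vapply(stream_collect(kmers(s, 16, 1)),
                       function(x) is_symmetric_kmer(x$kmer), TRUE))
    expect_equal(seqops:::count_symmetric(s, 16, 1), want)
  }
})

test_that("CpG regions are maximal C/G runs containing both letters", {
  r <- cpg_regions("CGC")
  expect_equal(r$count, 1L)
  expect_equal(r$regions$start, 0L)
  expect_equal(r$regions$end, 3L)
  expect_equal(cpg_regions("CCC")$count, 0L)
  expect_equal(cpg_regions("GGG")$count, 0L)

  r <- cpg_regions("ACGTGGCAC")
  expect_equal(r$count, 2L)
  expect_equal(r$regions$start, c(1L, 4L))
  expect_equal(r$regions$end, c(3L, 7L))
  expect_equal(r$min_len, 2L)
  expect_equal(r$max_len, 3L)

  empty <- cpg_regions("ATATAT")
  expect_equal(empty$count, 0L)
  expect_equal(empty$min_len, 0L)
  expect_equal(empty$max_len, 0L)
})

test_that("reported CpG regions are valid, maximal and match the scan oracle", {
  set.seed(29)
  for (i in 1:500) {
    s <- rand_dna(sample(1:120, 1L), n_rate = 0.02)
    r <- cpg_regions(s)
    want <- oracle_cpg(s)
    expect_equal(r$count, length(want))
    if (r$count > 0L) {
      expect_equal(r$regions$start, vapply(want, `[[`, 0L, "start"))
      expect_equal(r$regions$end, vapply(want, `[[`, 0L, "end"))
      ch <- strsplit(s, "", fixed = TRUE)[[1L]]
      for (j in seq_len(r$count)) {
        st <- r$regions$start[j]
        en <- r$regions$end[j]
        seg <- ch[(st + 1L):en]
        expect_true(all(seg %in% c("C", "G")))
        expect_true("C" %in% seg && "G" %in% seg)
        # maximality: flanks (if any) are not C/G
        if (st > 0L) expect_false(ch[st] %in% c("C", "G"))
        if (en < nchar(s)) expect_false(ch[en + 1L] %in% c("C", "G"))
      }
    }
  }
})
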