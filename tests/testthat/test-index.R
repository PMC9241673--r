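# The k-mer hash index: construction, lookup/prefetch protocol,
# seeding, and the text save/load format.

test_that("index records every unambiguous stride-1 window", {
  ix <- build_index("ACGTACGTAC", k = 4)
  expect_identical(kmer_lookup(ix, "ACGT"), c(0L, 4L))
  expect_identical(kmer_lookup(ix, encode_kmer("CGTA")), c(1L, 5L))
  expect_identical(kmer_lookup(ix, "AAAA"), integer(0))

  expect_identical(kmer_lookup(build_index("AAAA", k = 4), "AAAA"), 0L)

  # N-containing windows are absent, flanking ones present
  ixn <- build_index("ACGTNACGT", k = 4)
  expect_identical(kmer_lookup(ixn, "ACGT"), c(0L, 5L))
  expect_identical(kmer_lookup(ixn, "CGTN"), integer(0))

  expect_error(build_index("ACG", k = 4),
               class = "seqops_reference_too_short")
  expect_error(kmer_lookup(ix, "ACGTA"), class = "seqops_k_mismatch")
  expect_error(kmer_lookup(ix, encode_kmer("ACGTA")),
               class = "seqops_k_mismatch")
  expect_error(kmer_prefetch(ix, "ACGTA"), class = "seqops_k_mismatch")
})

test_that("lookups agree with a naive scan oracle on random references", {
  set.seed(31)
  for (i in 1:10) {
    L <- sample(50:2000, 1L)
    k <- sample(3:8, 1L)
    ref <- rand_dna(L, n_rate = 0.01)
    ix <- build_index(ref, k = k)
    for (j in 1:20) {
      probe <- rand_dna(k)
      expect_identical(kmer_lookup(ix, probe), oracle_scan(ref, probe))
    }
    # self-consistency: every stored position re-reads as its key
    keys <- sample(ls(ix$table), min(25L, length(ix$table)))
    for (kk in keys) {
      for (p in kmer_lookup(ix, kk)) {
        expect_equal(substr(ref, p + 1L, p + k), kk)
      }
    }
  }
})

test_that("multi-contig references index in concatenated coordinates", {
  ix <- build_index(c(chrA = "ACGTAC", chrB = "TTACGT"), k = 4)
  expect_equal(ix$ref_length, 12L)
  expect_equal(ix$contigs$offset, c(0L, 6L))
  # ACGT occurs at 0 (chrA) and 8 (chrB offset 6 + local 2)
  expect_identical(kmer_lookup(ix, "ACGT"), c(0L, 8L))
  # windows never span the contig boundary: TACT would otherwise exist
  expect_identical(kmer_lookup(ix, "TACT"), integer(0))
})

test_that("prefetch is semantically inert and instrumented", {
  ix <- build_index("ACGTACGTAC", k = 4)
  before <- kmer_lookup(ix, "ACGT")
  expect_equal(access_count(ix), 1L)
  kmer_prefetch(ix, "ACGT")
  expect_equal(prefetch_count(ix), 1L)
  expect_identical(kmer_lookup(ix, "ACGT"), before)
  expect_equal(access_count(ix), 2L)
})

test_that("seeding accumulates forward and reverse candidate loci", {
  ix <- build_index("ACGTACGTAC", k = 4)
  rep1 <- stream_collect(seed_reads(ix, "ACGTACGT", step = 1))[[1L]]
  # |ACGT|+|CGTA|+|GTAC|+|TACG|+|ACGT| = 2+2+2+1+2
  expect_equal(rep1$hits_forward, 9L)

  # an all-N read has no seedable window
  repN <- stream_collect(seed_reads(ix, strrep("N", 8), step = 1))[[1L]]
  expect_equal(repN$hits_forward, 0L)
  expect_equal(repN$hits_reverse, 0L)

  # reverse symmetry at step 1 on N-free reads
  set.seed(37)
  ref <- rand_dna(500)
  ix2 <- build_index(ref, k = 5)
  for (i in 1:20) {
    r <- rand_dna(30)
    a <- stream_collect(seed_reads(ix2, r, step = 1))[[1L]]
    b <- stream_collect(seed_reads(ix2, revcomp_seq(r), step = 1))[[1L]]
    expect_equal(a$hits_reverse, b$hits_forward)
    expect_equal(a$hits_forward, b$hits_reverse)
  }
})

test_that("prefetch-scheduled seeding reproduces serial reports", {
  set.seed(43)
  ref <- rand_dna(2000)
  ix <- build_index(ref, k = 6)
  reads <- replicate(200, rand_dna(40, n_rate = 0.02))
  serial <- stream_collect(seed_reads(ix, reads, step = 3))
  pf <- stream_collect(seed_reads(ix, reads, step = 3, prefetch = TRUE,
                                  M = 16))
  expect_equal(pf, serial)
  # one advisory hint per query task (forward + reverse per window)
  n_queries <- sum(vapply(reads, function(r) {
    2L * length(seqops:::read_windows(r, 6L, 3L))
  }, 0L))
  expect_equal(prefetch_count(ix), n_queries)
})

test_that("the text index format round-trips", {
  set.seed(47)
  ref <- c(c1 = rand_dna(300, n_rate = 0.01), c2 = rand_dna(200))
  ix <- build_index(ref, k = 5)
  path <- tempfile(fileext = ".tsv")
  write_index(ix, path)
  expect_true(startsWith(readLines(path, n = 1L), "#seqops-kmer-index\tv1"))

  ix2 <- read_index(path)
  expect_equal(ix2$k, ix$k)
  expect_equal(ix2$ref_length, ix$ref_length)
  expect_equal(ix2$contigs, ix$contigs)
  expect_setequal(ls(ix2$table), ls(ix$table))
  for (kk in sample(ls(ix$table), min(30L, length(ix$table)))) {
    expect_identical(kmer_lookup(ix2, kk), kmer_lookup(ix, kk))
  }
  expect_error(read_index(toy_fastq("ACGT")), class = "seqops_format")
})
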