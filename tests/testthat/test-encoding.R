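# 2-bit k-mer encoding, lookup tables, and table-driven reverse
# complementation / reversal.

test_that("lookup tables satisfy their defining relations", {
  tb <- build_tables()

  # bit2base is a bijection onto the four bases
  expect_setequal(tb$bit2base, c("A", "C", "G", "T"))
  # base2bit inverts bit2base
  for (code in 0:3) {
    expect_equal(tb$base2bit[utf8ToInt(tb$bit2base[code + 1L]) + 1L], code)
  }
  # lowercase maps like uppercase; everything else is the NA sentinel
  expect_equal(tb$base2bit[utf8ToInt("g") + 1L],
               tb$base2bit[utf8ToInt("G") + 1L])
  expect_true(is.na(tb$base2bit[utf8ToInt("X") + 1L]))
  expect_true(is.na(tb$base2bit[utf8ToInt("N") + 1L]))
  expect_equal(sum(!is.na(tb$base2bit)), 8L)

  # complement constraint: f(A) = ~f(T), f(C) = ~f(G) over 2 bits
  f <- function(b) tb$base2bit[utf8ToInt(b) + 1L]
  expect_equal(f("A"), bitwAnd(bitwNot(f("T")), 3L))
  expect_equal(f("C"), bitwAnd(bitwNot(f("G")), 3L))

  # rc4 is an involution on all 256 encoded 4-mers
  expect_identical(tb$rc4[tb$rc4 + 1L], 0:255)
  # ACGT is its own reverse complement
  acgt <- kmer_code(encode_kmer("ACGT"))
  expect_equal(tb$rc4[acgt + 1L], acgt)
})

test_that("encoding packs bases most-significant-first and rejects bad input", {
  expect_equal(kmer_code(encode_kmer("A")), 0)
  expect_equal(kmer_code(encode_kmer("ACGT")), 27)  # 00 01 10 11

  # independent per-base arithmetic: code = sum f(b_i) * 4^(k-1-i)
  fmap <- c(A = 0, C = 1, G = 2, T = 3)
  set.seed(11)
  for (k in c(1:9, 13, 21, 26)) {
    s <- rand_dna(k)
    expected <- sum(fmap[strsplit(s, "", fixed = TRUE)[[1L]]] *
                      4^((k - 1):0))
    expect_equal(kmer_code(encode_kmer(s)), expected)
  }

  expect_error(encode_kmer("ACGN"), class = "seqops_ambiguous_base")
  expect_error(encode_kmer("ACG", k = 4), class = "seqops_length_mismatch")
  expect_error(encode_kmer("A", k = 0), class = "seqops_bad_k")
  expect_error(encode_kmer(strrep("A", 1025)), class = "seqops_bad_k")
  # lowercase accepted and normalized
  expect_equal(decode_kmer(encode_kmer("acgt")), "ACGT")
})

test_that("decode inverts encode across the full k range", {
  expect_equal(decode_kmer(encode_kmer("GATTACA")), "GATTACA")
  expect_equal(decode_kmer(kmer_from_code(0, 1)), "A")
  expect_equal(decode_kmer(kmer_from_code(27, 4)), "ACGT")

  # exhaustive on small k: encode(decode(code)) recovers the code
  for (k in 1:4) {
    for (code in 0:(4^k - 1)) {
      expect_equal(kmer_code(encode_kmer(decode_kmer(
        kmer_from_code(code, k)), k)), code)
    }
  }
  # sampled on wide k-mers whose code exceeds a machine word
  set.seed(7)
  for (k in c(27, 31, 64, 257, 1023, 1024)) {
    s <- rand_dna(k)
    expect_equal(decode_kmer(encode_kmer(s)), s)
  }
})

test_that("table-driven revcomp and reversal agree with string oracles", {
  # paper's padding rule exercised at every k mod 4 residue
  expect_equal(decode_kmer(revcomp_kmer(encode_kmer("AACC"))), "GGTT")
  expect_equal(decode_kmer(revcomp_kmer(encode_kmer("ACGTA"))), "TACGT")
  expect_equal(decode_kmer(reverse_kmer(encode_kmer("ACGT"))), "TGCA")
  expect_equal(decode_kmer(reverse_kmer(encode_kmer("AA"))), "AA")

  set.seed(5)
  for (k in c(1:9, 16, 20, 33, 127, 1024)) {
    for (rep in 1:3) {
      s <- rand_dna(k)
      km <- encode_kmer(s)
      rc <- revcomp_kmer(km)
      expect_equal(decode_kmer(rc), oracle_revcomp(s))
      expect_true(revcomp_kmer(rc) == km)            # involution
      rv <- reverse_kmer(km)
      expect_equal(decode_kmer(rv),
                   paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]),
                         collapse = ""))
      expect_true(reverse_kmer(rv) == km)            # involution
    }
  }
})

test_that("reversal is the bit inversion of the reverse complement", {
  for (k in 1:4) {
    codes <- 0:(4^k - 1)
    got <- vapply(codes, function(code) {
      kmer_code(reverse_kmer(kmer_from_code(code, k)))
    }, 0)
    want <- (4^k - 1) - vapply(codes, function(code) {
      kmer_code(revcomp_kmer(kmer_from_code(code, k)))
    }, 0)
    expect_equal(got, want)
  }
})

test_that("integer order on codes is lexicographic order on strings", {
  set.seed(3)
  for (i in 1:300) {
    k <- sample(1:24, 1L)
    u <- rand_dna(k)
    v <- rand_dna(k)
    expect_equal(kmer_code(encode_kmer(u)) < kmer_code(encode_kmer(v)),
                 str_lt(u, v))
    expect_equal(encode_kmer(u) < encode_kmer(v), str_lt(u, v))
  }
  # comparison across k is rejected
  expect_error(encode_kmer("AC") == encode_kmer("ACG"),
               class = "seqops_k_mismatch")
})

test_that("sequence-level reverse complement handles N and matches Biostrings", {
  expect_equal(revcomp_seq("A"), "T")
  expect_equal(revcomp_seq("ACGT"), "ACGT")
  expect_equal(revcomp_seq("ANT"), "ANT")
  expect_equal(revcomp_seq(""), "")
  expect_error(revcomp_seq("ACGU"), class = "seqops_invalid_sequence")

  skip_if_not_installed("Biostrings")
  set.seed(19)
  for (i in 1:20) {
    s <- rand_dna(sample(1:200, 1L), n_rate = 0.05)
    expect_equal(revcomp_seq(s),
                 as.character(Biostrings::reverseComplement(
                   Biostrings::DNAString(s))))
  }
})
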