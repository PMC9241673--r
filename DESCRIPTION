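Package: seqops
Title: Bit-Packed K-mer Operations, Sequence Pattern Matching and
    Prefetch-Scheduled Index Queries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Sequence-analysis building blocks for short-read genomics:
    2-bit packed k-mer values with lookup-table reverse complementation,
    k-merization and splitting operators, a declarative sequence pattern
    mini-language, lazy processing pipelines with parallel and
    prefetch-scheduled execution, a k-mer hash index with read seeding,
    streaming FASTA/FASTQ input and output, and a seeded synthetic read
    generator, together with command-line entry points for common
    read-set computations (reverse complement, CpG region scanning,
    symmetric k-mer counting, k-nucleotide frequencies and index
    seeding).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    parallel,
    stats
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
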