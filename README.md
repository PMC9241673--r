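# seqops

Sequence-analysis building blocks for short-read genomics, written for
people who process FASTQ read sets and query genomic indices: 2-bit
packed k-mers, streaming read pipelines, and a k-mer hash index with a
software-prefetch query scheduler.

## What it computes

**Bit-packed k-mers.** A k-mer over {A,C,G,T} is stored as a 2k-bit
unsigned integer with f(A)=00, f(C)=01, f(G)=10, f(T)=11, first base in
the most significant bit pair (so integer order on codes equals
lexicographic order on strings, and k-mers up to k = 32 fit a machine
word; here k may reach 1024 via a byte-vector code). The base map is
chosen so f(A) = ~f(T) and f(C) = ~f(G): complementation is bitwise
NOT. Reverse complementation uses a 256-entry table `rc4` mapping every
encoded 4-mer byte to its encoded reverse complement; an arbitrary
k-mer is reverse-complemented by slicing its code into 4-mer bytes,
mapping each through `rc4` and concatenating in reverse, padding with
A-bases (and stripping the resulting T-bases) when k is not a multiple
of 4. Plain reversal then comes for free as the bit inversion of the
reverse complement.

**Pipelines.** Read processing is expressed as lazy pull-based
pipelines (`stage_map`, `stage_flatten`, `partial` application with the
`ph` placeholder). A `parallel_marker()` declares the point after which
elements may be processed concurrently in batches of 100,000
(`run_parallel`; output multiset equals the serial run, order
unspecified, `workers = 1` reproduces serial order exactly). A
`prefetch_stage(prefetch, load)` declares a suspendable index query;
`run_prefetch` schedules up to M (default 16) such tasks in a slot
ring — issue prefetch, suspend, resume to load — so one query's memory
latency overlaps another's useful work.

**Index and seeding.** `build_index` maps every unambiguous stride-1
window of a reference to its sorted 0-based positions (default k = 20,
the classic short-read hash-table configuration); `seed_reads`
k-merizes each read and totals candidate loci for the read's k-mers and
their reverse complements — the seeding step preceding alignment.

Also included: a pattern mini-language (`A`/`C`/`G`/`T` literals, `_`
single-base wildcard, `...` zero-or-more gap, anchored semantics) with
first-match dispatch; CpG-run extraction; symmetric k-mer counting;
streaming FASTA/FASTQ IO; a seeded synthetic read generator; and a
`seqops` CLI (`exec/seqops`) with subcommands
`rc | cpg | sym16 | knuc | seed | gen`.

## Worked example

```r
library(seqops)

km <- encode_kmer("ACGTA")
km
#> <5-mer ACGTA (code 108)>
revcomp_kmer(km)
#> <5-mer TACGT (code 795)>
```

`ACGTA` packs to 00·01·10·11·00 = 108; its reverse complement `TACGT`
(code 795) is produced purely by `rc4` byte lookups, exercising the
A-padding path since 5 is not a multiple of 4.

```r
cpg_regions("ACGTGGCAC")[c("count", "min_len", "max_len")]
#> $count
#> [1] 2
#> $min_len
#> [1] 2
#> $max_len
#> [1] 3
```

Two maximal C/G runs contain both letters: `CG` at [1,3) and `GGC` at
[4,7); the lone `C` at position 8 is not a region.

```r
ix <- build_index("ACGTACGTAC", k = 4)
kmer_lookup(ix, "ACGT")
#> [1] 0 4
stream_collect(seed_reads(ix, "ACGTACGT", step = 1))[[1]]$hits_forward
#> [1] 9
```

The read's five 4-mers hit the reference 2+2+2+1+2 = 9 times. Passing
`prefetch = TRUE` routes the same queries through the M-slot scheduler
and returns identical reports.

From a shell:

```sh
Rscript exec/seqops gen --what reads --out reads.fastq --n 1000 --seed 4
Rscript exec/seqops cpg --in reads.fastq
```

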