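---
title: "seqops: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{seqops: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqops)
```

This vignette explains the models and procedures the package
implements, the parameters that matter, and the design decisions taken
where more than one reasonable choice existed. It states no empirical
result beyond what the package's own tests and `scripts/acceptance.R`
compute.

## The 2-bit k-mer model

A k-mer over {A,C,G,T} is represented by a 2k-bit unsigned integer.
The base map is

| base | code |
|------|------|
| A    | 00   |
| C    | 01   |
| G    | 10   |
| T    | 11   |

with the first base in the most significant bit pair. Two constraints
drove this choice. First, the code of each base is the bitwise
complement of its Watson–Crick partner (f(A) = ~f(T), f(C) = ~f(G)),
which makes strand complementation a pure bit inversion. Second,
placing the first base in the high bits makes integer order on codes
identical to lexicographic order on k-mer strings, so sorted codes are
sorted k-mers.

Reverse complementation is performed entirely by table lookup. At
package initialization we build `rc4`, a 256-entry array whose entry
*i* is the encoded reverse complement of the 4-mer encoded as *i*
(4 bases × 2 bits = one byte). The property
rc(s₁‖s₂) = rc(s₂)‖rc(s₁) lets us reverse-complement an arbitrary
k-mer by mapping each 4-mer byte through `rc4` and concatenating the
results in reverse byte order. When k mod 4 ≠ 0 the k-mer is first
padded with A-bases to a 4-mer boundary; since rc(A) = T, the padding
reappears as leading T-bases in the result and is removed by masking
to the low 2k bits. Plain reversal (no complement) is obtained as the
bitwise NOT of the reverse complement, again masked to 2k bits.

The supported range is 1 ≤ k ≤ 1024, a generous ceiling for any
k-mer-based application. Codes wider than a machine word are held as
big-endian raw byte vectors: each byte below the zero pad is exactly
one 4-mer slice, i.e. the operand of `rc4`, so the representation *is*
the algorithm's working form. Numeric (double) codes are exposed only
for k ≤ 26, where the 53-bit mantissa is exact; beyond that the byte
vector is authoritative. `N` is representable in sequences but never
in packed k-mers — a 2-bit code has no room for ambiguity — so
k-merization skips N-containing windows rather than erroring, while
`split_seq` (which returns raw subsequences) passes them through.

Degenerate inputs are defined, not rejected: the empty sequence has
empty base counts, is trivially its own reverse complement, and yields
empty window streams; a sequence shorter than k yields an empty k-mer
stream.

### Self-reverse-complement and N

`revcomp_seq` maps N to N, so a string such as `"ANT"` equals its own
reverse complement *as a string*. `is_self_revcomp` nevertheless
returns `FALSE` for any sequence containing N: an ambiguous base has
no strand identity, so the biological property being tested is
undetermined. The same rule makes N-containing windows ineligible in
symmetric-k-mer counting. (With N excluded, odd-length sequences can
never be self-reverse-complementary — the middle base would have to
complement itself.)

## Sequence operators

Coordinates are 0-based with half-open intervals throughout; this
composes cleanly with window arithmetic (`start + k <= length`).

A *CpG region*, in this package's benchmark sense, is a maximal run of
C/G characters containing at least one C and at least one G — `CGC`
counts, `CCC` and `GGG` do not, and the minimum length is therefore 2.
This is deliberately *not* the biological CpG-island definition
(no Gardiner-Garden observed/expected ratio); it is a run-scanning
kernel. The implementation is an `rle` over the C/G indicator with
per-run C and G counts from cumulative sums; a linear character scan
serves as the test oracle.

A *symmetric* k-mer (k even) has its first half equal to the reverse
complement of its second half, i.e. it is its own reverse complement.
The benchmark command counts symmetric 16-mers over overlapping
(stride 1) windows by default — the most sensitive reading of "all
reads" — with the stride configurable for the non-overlapping reading.

## The pattern mini-language

Patterns are sequences of literal bases, `_` (exactly one base of any
kind, including N) and `...` (zero or more bases). Parsing collapses
adjacent gaps (they are semantically redundant) and rejects dot runs
whose length is not a multiple of 3, which in practice catches typos
like `A..T`. Matching is anchored at both ends; containment is
expressed by wrapping a pattern in leading and trailing `...`, which
is how subsequence search is written in this style. Literals do not
match N: a literal is a specific base call, while `_` means "any
base". Multiple gaps per pattern are supported — a strict
generalization of the leading/trailing-gap idiom.

The matcher splits the pattern at its gaps and places the gap-free
segments left to right, each at its leftmost feasible position, with
end-flanking segments anchored. For unconstrained gaps this greedy
placement is exact (the classical glob-matching argument: any feasible
placement can only move later segments right, never left), and the
worst case is O(|s|·|pattern|). The test suite checks it against an
independently derived anchored-regular-expression translation
(`_` → `.`, `...` → `.*`).

`match_dispatch` provides ordered first-match dispatch over
(pattern, tag) cases; a trailing `"..."` case acts as the default arm.

## Pipelines, parallelism, prefetch scheduling

Pipelines are pull-based and lazy: no stage materializes the stream,
and consuming m outputs touches only the source prefix needed — this
is what makes whole-file streaming viable regardless of input size.
Stages are one-in/one-out mappers, one-in/stream-out flatteners
(expanded depth-first, preserving order), or the two scheduling
constructs below. Partial application (`partial(f, ph, ...)` with
exactly one placeholder) turns multi-argument library functions into
pipeline stages; arity misuse (zero or two open slots) errors
immediately.

**Parallel stages.** A `parallel_marker()` splits the pipeline into a
serial head and a parallelizable tail. Elements are blocked into
batches of 100,000 (the conventional read-blocking granularity for
this workload class; configurable) and the tail is applied per element
via forked workers. The contract is deliberately weak: the output
*multiset* equals the serial run's, ordering is unspecified, and
`workers = 1` reproduces the serial sequence exactly. Tests therefore
compare multisets, or pin `workers = 1`. Stages after the marker must
be pure with respect to shared state. Nested parallel sections are out
of scope: exactly one marker per pipeline.

**Prefetch scheduling.** Large genomic indices defeat CPU caches;
the remedy is to issue an advisory prefetch for a query, suspend that
query, and do useful work on other queries while the memory system
catches up. The package models a suspendable query as a two-phase
task — `prefetch(x)` then suspend; `load(x)` on resume — which is the
"one suspend point, resume to completion" contract realized with
closures (R has no native coroutines; the contract, not the mechanism,
is what the scheduler relies on). `run_prefetch` keeps up to M tasks
in flight in a slot ring: it first fills empty slots from the source
(issuing each task's prefetch), then cyclically resumes suspended
tasks; each completion emits its result downstream and frees the slot
for the next source element, and after source exhaustion the remaining
at-most-M tasks are drained. M defaults to 16, a conservative
in-flight budget that saturates prefetching without starving other
cache users; it is configurable. With M = 1 the scheduler degenerates
to the serial loop, which the tests use as the ordering baseline.
Prefetch hints are semantically inert — the index counts them, and an
event-trace test verifies that with M = 2 two prefetches are issued
before the first load completes, i.e. that the transformation actually
interleaves.

Emission order for M > 1 follows completion order and is not
guaranteed; equivalence is asserted on multisets.

## The k-mer index and seeding

`build_index` records every ambiguity-free stride-1 window of the
reference in a hash map from k-mer to sorted 0-based positions;
k defaults to 20, the classic hash-table configuration for short-read
seeding. Multi-contig references are laid out in one coordinate space
with recorded per-contig offsets (windows never span a boundary).
Keys are the k-mer strings themselves — in bijection with the 2-bit
codes, and the natural hash key in R, whose environments hash
character keys natively. `seed_reads` k-merizes each read at `step`
(default k, non-overlapping seeds; `step = 1` for maximal
sensitivity) and totals candidate loci for each k-mer and its reverse
complement, since about half of all reads originate from the opposite
strand. The per-query path is expressible as a `prefetch_stage`, so
seeding runs unchanged under `run_prefetch`.

The index serializes to a versioned tab-separated text table (header,
contig lines, sorted k-mer lines) — transparent, diffable, and
round-trip tested. The FM-index family is deliberately out of scope;
only the hash index is implemented.

## Input/output and the synthetic generator

FASTA and FASTQ readers are lazy, gzip-transparent streaming parsers:
one record is parsed per pull, malformed input raises a classed format
error carrying the file and line number, and the CLI maps these to
exit code 2. Laziness is part of the module contract (pipelines must
stream arbitrarily large files), which is why the readers are written
here rather than delegated to an eager whole-file reader; the
Bioconductor string stack is instead used as an independent oracle in
the tests.

The generator emulates the study's input regime at desk scale:
uniform i.i.d. bases, 75-bp reads, constant `I` (Phred 40) qualities,
optional per-base N rate, fully determined by an integer seed (the
caller's RNG stream is saved and restored). It does **not** emulate
base-composition bias, quality decay along the read, sequencing error
models, duplicates, or paired ends — so green tests demonstrate
correctness of the operators on realistic-shaped data, not robustness
to real-machine artifacts. When the reverse-complement command writes
FASTQ, the quality string is reversed with the sequence (standard
convention, so each quality stays attached to its base). For the
seeding computation in `scripts/acceptance.R`, reads are cut from the
generated reference at seeded positions with a fair strand flip — the
standard read-simulation setup — because i.i.d. reads share
essentially no 20-mer with a random 100-kb reference and would make
the hit counts degenerate zeros.

## Problem sizes and verification

The package's own verification uses sizes chosen to keep the full
suite comfortably interactive while still exercising every code path:
exhaustive encoding identities for all 4^k k-mers up to k = 8
(revcomp oracle) and k = 6 (round-trip and reversal-by-bit-inversion),
sampled identities up to the k = 1024 ceiling; 100,000 random
(pattern, sequence) pairs against the regex oracle; 10,000 random
reads against the CpG segmentation oracle; scheduler equivalence at
M ∈ {1, 2, 16, 64} and workers ∈ {1, 4} on 1,000–10,000-element
workloads; and an end-to-end run of every benchmark command on 10,000
simulated 75-bp reads with a 100-kb reference, checked against
brute-force reimplementations (including exact pattern-dictionary
counting from Biostrings for seeding). `scripts/acceptance.R` rebuilds
the same desk-scale inputs from a command-line seed and reports the
headline quantities as JSON.

## Known limitations

- IUPAC ambiguity codes beyond N, RNA and protein alphabets are not
  supported.
- Parallel execution relies on process forking (`parallel::mclapply`)
  and falls back to serial semantics where forking is unavailable;
  ordering under `workers > 1` is unspecified by design.
- The prefetch scheduler models latency hiding semantically
  (instrumented advisory hints); it does not issue hardware prefetch
  instructions, so it demonstrates the transformation's correctness,
  not its wall-clock benefit.
- One parallel marker and one prefetch stage per pipeline; nested
  parallelism is out of scope.
- The index holds positions in memory and suits desk-scale references
  (up to a few megabases comfortably), not whole mammalian genomes.
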