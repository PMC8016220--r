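---
title: "Reverse mapping: k-mer queries against FM-indexed reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reverse mapping: k-mer queries against FM-indexed reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(revmap)
```

## The model

Conventional short-read analysis maps reads onto an indexed reference and
asks, per reference position, which reads landed there.  `revmap` reverses
the direction: the *reads* are indexed once in a compressed full-text
(FM) index, and *target sequences* — SNP-flanking windows, pathogen
genomes, curated marker k-mers — are searched against them.  The payoff is
flexibility: one index of the sample answers arbitrary sequence questions
(different k-mer lengths, new targets) without re-alignment or
re-indexing of a target database, and without the reference bias inherent
to a single linear genome.

Three stages make up a run:

1. **Query generation** — `queries_from_vcf()` turns biallelic SNPs into
   REF/ALT sequence pairs of length $2f+1$ centered on the site;
   `queries_from_fasta()` turns arbitrary FASTA records (e.g. viral
   genomes) into free-sequence queries; `read_kmer_list()` accepts
   pre-computed k-mers, optionally grouped (e.g. by gene).
2. **Read indexing** — `load_reads()` strips qualities and headers from
   FASTQ/FASTA, concatenates the reads with a sentinel, and
   `index_reads()` builds one FM-index per chunk.
3. **Search** — `run_query_search()` generates k-mers per query, filters
   them, looks them up in every chunk, and collates hits into per-query
   deduplicated read (or pair) counts.  `counts_to_vcf()` turns REF/ALT
   count pairs into genotype calls.

## The index

The read set becomes a single text over $\{A,C,G,T,N\}$ in which
consecutive reads are separated by a sentinel `$` that sorts before every
base.  Because query k-mers never contain the sentinel, no match can span
a read boundary, so occurrence counts over the concatenated text are
exactly per-read counts summed over reads.

The suffix array of this text is built by induced sorting (SA-IS, linear
time).  All sentinels share one symbol; suffix comparisons resolve
sentinel runs by the content that follows (equivalently, a virtual
end-of-text symbol below `$`), which is deterministic and
position-stable.  From the suffix array we take the Burrows–Wheeler
transform; backward search then narrows a suffix-array interval one
pattern symbol at a time using rank (occ) queries answered from
checkpointed counts at a fixed 64-symbol stride — a plain rank structure
chosen for transparency; a wavelet tree is an encoding optimization the
contract does not require.  The one subtlety of a shared sentinel symbol
is that rank-based LF-mapping is ambiguous on rows whose BWT symbol *is*
the sentinel, so those (one per read) carry precomputed LF targets.

`locate` resolves suffix-array rows to text positions by LF-stepping to a
sampled entry.  Sampling is by text position — every position divisible
by `sample_rate` is kept — which bounds each walk by `sample_rate - 1`
steps and never crosses a sentinel.  The default `sample_rate = 16`
trades roughly 16-fold less suffix-array memory for walks of at most 15
LF steps; counts and positions are invariant to the rate (asserted in the
tests over rates 1, 4 and 32).

Large read sets can be split into contiguous chunks (`n_chunks`), each
indexed independently; pairs are never split.  Every chunk records the
global ordinal of its first read, so search results from all chunks merge
into the same count table a monolithic index would give — an invariant
the test suite asserts for counts *and* flags, including under the global
filters described below.

## The search and its parameters

For each query, k-mers of length `k` are generated at step `s`:

* **centered** (`mode = "centered"`): every window covers the query's
  central position `floor(L/2)` — the SNP site.  Starts ascend from
  `max(0, c - k + 1)` by `s` up to `min(c, L - k)`; the maximal feasible
  start is appended when the stride would miss it, so both extreme
  center-covering windows always exist.  The direction and anchoring of
  this enumeration were an open design choice; ascending-from-the-left
  with a right anchor keeps the emitted set symmetric about the center
  for every stride.
* **sliding** (`mode = "sliding"`): starts `0, s, 2s, ...`, with the
  final window anchored at `L - k` always emitted — otherwise the last
  `(L - k) mod s` bases of every query would be systematically
  unsearchable.

Queries of even length have no exact middle; the VCF route always
produces odd lengths ($2f+1$), and for arbitrary sequences the center is
defined as `floor(L/2)`.

The remaining parameters, their defaults and why:

| parameter | default | meaning |
|---|---|---|
| `k` | 31 | k-mer length; longer is more specific, shorter more error-tolerant |
| `s` | 10 | step between k-mer starts; `s <= k` guarantees tiling (a warning is raised otherwise) |
| `max_occ` | 200 | per-k-mer occurrence ceiling (see below) |
| `ignore_nonunique_kmers` | on | drop k-mers attributable to >1 query, flag the queries |
| `unique_reads` | off | remove reads matching >1 query from all of them |
| `paired_mode` | off | count read pairs (mates interleaved, pair = `ordinal %/% 2`) |
| `search_rc` | on | also search each k-mer's reverse complement |
| `sample_rate` | 16 | suffix-array sampling (index-time) |
| `min_count` | 3 | genotype support threshold (post-processing) |

Two presets bundle the combinations the engine is tuned for:
`search_settings(preset = "genotype")` (k = 31, s = 10, centered,
max_occ = 200, unique k-mers) for SNP genotyping, and
`search_settings(preset = "pathogen")` (k = 30, s = 5, sliding,
max_occ = 2000, unique k-mers *and* unique reads) for foreign-sequence
detection, where a read must never be credited to two targets.

**Orientation.** Reads come from both strands, but by default only the
forward reads are indexed; each k-mer is instead searched in both
orientations and hits credit the same query.  The equivalent alternative
— indexing reverse-complement copies (`include_rc = TRUE`, each copy
sharing its primary read's ordinal) with forward-only search — is
supported and asserted equivalent in the tests.  The default keeps the
index half the size at the cost of doubling the pattern list, which is
the cheaper side of the trade at search time.

**Collation semantics.** Hits are translated to global read ordinals and
collected as *sets*: several k-mers of one query hitting the same read
count once.  Three decisions here were genuinely open and are fixed as
follows:

* `max_occ` is enforced on the **global** occurrence total across
  chunks, not per chunk.  Per-chunk enforcement would make results depend
  on the chunking; the global rule preserves chunk-merge equivalence
  exactly.  Each chunk therefore reports either positions (at or below
  the ceiling) or an overflow marker carrying its count, and the
  collation stage sums before deciding.  An over-the-ceiling k-mer
  contributes nothing and sets the `flag_overmax_kmer` flag of its
  queries.
* `unique_reads` **drops** contested reads from all queries rather than
  awarding them to any single one.  Dropping is order-independent and
  deterministic; any assignment rule would need a tie-break with no
  principled winner.
* Non-unique k-mers (under `ignore_nonunique_kmers`) are dropped and
  every affected query gets `flag_nonunique_kmer`.  With the filter off
  the k-mer keeps all owners and the flag still marks the ambiguity.

Both flags propagate into the genotype VCF as INFO tags (`NUK`, `OMK`),
so downstream consumers can discount calls built on ambiguous evidence.

**Threads.** The search stage partitions the k-mer list round-robin into
`threads` batches and reassembles results in k-mer order, so output is
bit-identical for any thread count; within one R process the setting only
structures the work.

## Genotyping

A site's REF and ALT queries are counted independently; the call is a
minimum-count rule.  The underlying rule table uses strict comparisons
and leaves equality with the threshold and double-failure undefined; the
package totalizes it by defining *supported* as `count >= min_count`:
both alleles supported → `0/1`, only REF → `0/0`, only ALT → `1/1`,
neither → `./.` (no-call).  This is the least surprising completion: it
treats the threshold as "at least this many reads" and never invents a
call from unsupported evidence.  The exhaustive rule table (all counts in
$[0,10]^2$, several thresholds) is asserted against a brute-force oracle
in the tests.  `min_count` has no universal value; 3 is the default and
should be reviewed against expected coverage (at 30× a heterozygous
allele carries ~15 reads, so 3 is conservative).

Only VCF output is implemented; proprietary consumer-genomics dialects
have no public schema to target.

## The simulator

`make_genome()`, `plant_snps()`, `simulate_reads()` and `spike_in()`
generate the study conditions the engine is validated under:

* genomes are i.i.d. uniform A/C/G/T;
* SNPs are biallelic, placed with a minimum spacing of $2f+1$ so centered
  queries never overlap, genotypes drawn 1:2:1 (hom-ref : het : hom-alt)
  by default, heterozygous alternates phased onto haplotype B;
* reads have uniform start positions, uniform strand (minus-strand reads
  are reverse-complemented), uniform haplotype for diploid input, and
  i.i.d. substitution errors; `depth` coverage yields
  `round(depth * L / read_length)` reads (for paired output, fragments
  of `fragment_length` yield interleaved mates from either end, and a
  pair covers `2 * read_length` bases in the depth accounting);
* spike-ins append exactly `n` pathogen reads to a background and record
  which names were spiked.

What the simulator does *not* emulate — indels, GC and coverage bias,
duplicates, quality-correlated errors, real transcriptome structure —
bounds what passing tests show: they validate the engine's counting,
filtering and merging semantics under its own stated error model, not
performance on real libraries.  Substitution-only errors are sufficient
for the k/s trade-off because an indel-bearing read, under exact
matching, simply behaves like a heavily substituted one.

The validation suite runs at deliberately desk-sized scale: four 5–20 kb
targets at 100× coverage (~45k reads) for total-recovery checks, a 20 kb
background with 10k reads and spikes of 0/50/500/5000 for detection, and
a 40 kb diploid genome with 200 SNPs at 30× for genotype recovery.  At
these sizes the full suite runs in minutes on one core while exercising
every code path the genome-scale setting would.

With 1% substitution errors and the pathogen preset, expected recovery
has a closed-form floor: since the step (5) divides k (30), every 100 bp
read contains three *disjoint* searched windows, so the per-read recovery
probability is at least $1 - (1 - 0.99^{30})^3 \approx 0.982$; the tests
assert observed recovery above this bound minus three binomial standard
deviations.

## Numerical and degenerate-input choices

* Sequences are uppercased and `U` mapped to `T` on ingestion; symbols
  outside $\{A,C,G,T,N\}$ are an error naming the offending record.
* `N` is kept in the text as a fifth symbol; matching is exact, so
  k-mers containing anything but A/C/G/T never match and a pattern `N`
  only matches a literal `N`.
* Patterns with symbols outside the index alphabet return the empty
  interval (count 0), not an error; a pattern containing the sentinel is
  a caller error.
* A text position falling on a sentinel during hit translation is an
  internal error by construction and is asserted, not silently skipped.
* `k` greater than the query length is an error naming the query; a
  k-mer equal to its own reverse complement is entered once.
* Index files are little-endian with a magic and version; truncated or
  foreign files fail closed.  Saving is deterministic, so repeated saves
  are byte-identical.

## Known limitations

* Exact matching only: error tolerance comes from k/s tuning, not from
  approximate search.
* The whole index lives in memory; chunking bounds construction memory
  but all chunks are held during search.
* Single R process; `threads` structures the work deterministically but
  does not parallelize within one process.
* The genotyper is a threshold rule, not a likelihood model; it reports
  evidence, flags ambiguity, and leaves statistical genotyping to
  downstream tools.

## A worked example

```{r example}
genome <- make_genome(6000, seed = 7)
snps <- plant_snps(genome, 10, seed = 8, flank = 50)
reads <- simulate_reads(list(snps$hap_a, snps$hap_b),
                        read_length = 100, depth = 30, seed = 9)$reads

ref_fa <- tempfile(fileext = ".fa"); writeLines(c(">sim1", genome), ref_fa)
vcf_in <- tempfile(fileext = ".vcf"); truth_to_vcf(snps$truth, vcf_in)

qs <- queries_from_vcf(vcf_in, ref_fa, flank = 50)
iset <- index_reads(read_store(reads), n_chunks = 2)
ct <- run_query_search(iset, qs, search_settings(preset = "genotype"))
calls <- genotype_table(ct, qs, min_count = 3)
table(called = calls$genotype, truth = snps$truth$genotype)
```
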