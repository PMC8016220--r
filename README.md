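# revmap

Reverse mapping of sequence queries against FM-indexed short reads.

Most sequencing pipelines map reads onto an indexed reference genome.
`revmap` turns the direction around: it builds a compressed full-text
(FM) index over the **raw reads** of a sample and searches **target
sequences** against it as flexible k-mer queries. One index of a read
set then answers arbitrary questions — is this pathogen present and in
how many reads? what is the genotype at these SNP sites? how often does
this curated marker k-mer occur? — without alignment, without reference
bias, and without re-indexing when the targets or the k-mer length
change.

It is aimed at people analysing short-read DNA/RNA sequencing data who
want read-level evidence for specific sequences before (or instead of)
running a full mapping pipeline.

## Method in brief

Reads are uppercased, stripped of qualities, and concatenated into one
text `r_1 $ r_2 $ … r_n $` over `{A,C,G,T,N}` with a sentinel `$` that
sorts below every base, so no match can cross a read boundary. The
suffix array of this text (SA-IS induced sorting) yields the
Burrows–Wheeler transform; backward search over the BWT with
checkpointed rank counts reports, for a pattern `P`, the suffix-array
interval `[lo, hi)` whose size is the exact occurrence count of `P`,
and a position-sampled suffix array resolves hits to text positions in
at most `sample_rate − 1` LF steps.

A query search runs in four steps:

1. **k-mer generation** — per query, k-mers of length `k` at step `s`,
   either *centered* (every window covers the query's middle base — the
   SNP site) or *sliding* (windows tile the whole query, final window
   anchored at the end);
2. **filtering** — k-mers found in more than one query are dropped and
   the affected queries flagged (`ignore_nonunique_kmers`);
3. **searching** — every retained k-mer (and, by default, its reverse
   complement) is located in every index chunk, with an occurrence
   ceiling `max_occ`;
4. **collation** — positions become global read ordinals; each query
   counts its *set* of matching reads (or pairs), so multiple k-mer
   hits in one read count once; `max_occ` is applied to the global
   total across chunks; with `unique_reads`, reads matching more than
   one query are removed from all of them.

Genotypes come from a minimum-count rule over a site's REF/ALT query
counts: an allele is *supported* when its count ≥ `min_count`; both
supported → `0/1`, only REF → `0/0`, only ALT → `1/1`, neither → `./.`.

A seeded simulator (`make_genome`, `plant_snps`, `simulate_reads`,
`spike_in`) generates the validation conditions: random genomes,
planted diploid SNPs, uniform-coverage stranded reads with optional
substitution errors, and pathogen spike-ins at fixed read counts.

## Worked example

```r
library(revmap)

genome <- make_genome(6000, seed = 7)                 # 6 kb random genome
snps   <- plant_snps(genome, 10, seed = 8, flank = 50) # 10 diploid SNPs
reads  <- simulate_reads(list(snps$hap_a, snps$hap_b),
                         read_length = 100, depth = 30, seed = 9)$reads

ref_fa <- tempfile(fileext = ".fa"); writeLines(c(">sim1", genome), ref_fa)
vcf_in <- tempfile(fileext = ".vcf"); truth_to_vcf(snps$truth, vcf_in)

qs   <- queries_from_vcf(vcf_in, ref_fa, flank = 50)   # 20 REF/ALT queries
iset <- index_reads(read_store(reads), n_chunks = 2)   # chunked FM-index
ct   <- run_query_search(iset, qs, search_settings(preset = "genotype"))
calls <- genotype_table(ct, qs, min_count = 3)
head(calls[, c("pos", "ref", "alt", "ref_count", "alt_count", "genotype")], 4)
#>   pos ref alt ref_count alt_count genotype
#>   917   A   G        24        14      0/1
#>  1406   T   C         0        30      1/1
#>  1530   G   T        34         0      0/0
#>  2115   C   G        16        16      0/1
table(calls$genotype == snps$truth$genotype)
#> TRUE
#>   10
```

The counts are deduplicated reads supporting each allele at 30×
coverage (~15 per allele for a heterozygote, ~30 for a homozygote), and
all ten planted genotypes are recovered. The same engine in
`preset = "pathogen"` mode (k = 30, s = 5, sliding, unique reads and
unique k-mers) counts reads per target genome for spike-in detection.

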