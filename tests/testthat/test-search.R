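# Enumeration oracles for k-mer generation: all windows, filtered.
oracle_centered <- function(seq, k, s) {
  L <- nchar(seq)
  centre <- L %/% 2L
  feasible <- (0:(L - k))[sapply(0:(L - k), function(a)
    a <= centre && centre < a + k)]
  a <- min(feasible); b <- max(feasible)
  sort(unique(c(seq.int(a, b, by = s), b)))
}
oracle_sliding <- function(seq, k, s) {
  L <- nchar(seq)
  sort(unique(c(seq.int(0L, L - k, by = s), L - k)))
}

test_that("centered k-mers all cover the central position", {
  got <- kmers_centered("ACGTA", 3L, 1L)
  expect_equal(got$start, c(0L, 1L, 2L))
  expect_equal(got$kmer, c("ACG", "CGT", "GTA"))
  got2 <- kmers_centered("ACGTA", 3L, 2L)
  expect_equal(got2$start, c(0L, 2L))
  expect_equal(got2$kmer, c("ACG", "GTA"))
  whole <- kmers_centered("ACGTA", 5L, 3L)
  expect_equal(whole$kmer, "ACGTA")
  expect_error(kmers_centered("ACG", 4L, 1L), "exceeds")
})

test_that("sliding k-mers tile the sequence with an end anchor", {
  got <- kmers_sliding("ACGTACG", 3L, 2L)
  expect_equal(got$start, c(0L, 2L, 4L))
  got2 <- kmers_sliding("ACGTAC", 3L, 2L)
  expect_equal(got2$start, c(0L, 2L, 3L))
  wide <- kmers_sliding("ACGTAC", 3L, 99L)
  expect_equal(wide$start, c(0L, 3L))
  expect_error(kmers_sliding("AC", 3L, 1L), "exceeds")
})

test_that("k-mer generation matches the enumeration oracles", {
  seqs <- rand_reads(12, c(5, 40), seed = 31)
  withr::with_seed(32, for (seq in seqs) {
    L <- nchar(seq)
    for (rep in 1:4) {
      k <- sample(seq_len(L), 1L)
      s <- sample(seq_len(k), 1L)
      expect_equal(kmers_centered(seq, k, s)$start, oracle_centered(seq, k, s))
      expect_equal(kmers_sliding(seq, k, s)$start, oracle_sliding(seq, k, s))
      # every emitted window covers the centre
      cc <- kmers_centered(seq, k, s)$start
      expect_true(all(cc <= L %/% 2L & L %/% 2L < cc + k))
    }
  })
})

make_qs <- function(seqs, names = paste0("q", seq_along(seqs))) {
  query_set(data.frame(query_id = seq_along(seqs) - 1L, kind = "SEQ",
                       chrom = NA_character_, pos = NA_integer_,
                       ref = NA_character_, alt = NA_character_,
                       name = names, sequence = seqs))
}

test_that("the k-mer map drops shared k-mers and flags their queries", {
  qs <- make_qs(c("ACGTA", "TACGT"))
  st <- search_settings(k = 4L, s = 1L, mode = "sliding", search_rc = FALSE,
                        ignore_nonunique_kmers = TRUE)
  km <- build_kmer_map(qs, st)
  expect_setequal(km$dropped, "ACGT")
  expect_setequal(km$kmers, c("CGTA", "TACG"))
  expect_equal(km$flagged_nonunique, c(0L, 1L))

  # a single query cannot have non-unique k-mers
  km1 <- build_kmer_map(make_qs("ACGTACGT"), st)
  expect_length(km1$dropped, 0L)
  expect_length(km1$flagged_nonunique, 0L)

  # with the filter off, shared k-mers keep both owners
  st_off <- search_settings(k = 4L, s = 1L, mode = "sliding",
                            search_rc = FALSE,
                            ignore_nonunique_kmers = FALSE)
  km_off <- build_kmer_map(qs, st_off)
  expect_equal(km_off$owners[[match("ACGT", km_off$kmers)]], c(0L, 1L))

  # a palindromic k-mer maps once even with RC search on
  st_rc <- search_settings(k = 4L, s = 1L, mode = "sliding",
                           search_rc = TRUE)
  km_rc <- build_kmer_map(make_qs("AACGTA"), st_rc)
  expect_equal(sum(km_rc$kmers == "ACGT"), 1L)

  expect_error(build_kmer_map(make_qs(c("ACGTACGT", "ACG")), st), "q2")
})

test_that("multiple k-mer hits in one read collapse to a single count", {
  # read 0 contains the query three times over; still one count
  st <- read_store(c("ACGTACGTACGT", "TTTTTTTT"))
  iset <- index_reads(st, sample_rate = 1L)
  qs <- make_qs("ACGTACGT")
  ct <- run_query_search(iset, qs, search_settings(
    k = 4L, s = 2L, mode = "sliding", search_rc = FALSE, max_occ = 100L))
  expect_equal(ct$count, 1L)

  # a query absent from the reads counts zero
  ct0 <- run_query_search(iset, make_qs("CCCCCCCC"), search_settings(
    k = 4L, s = 2L, mode = "sliding", search_rc = FALSE))
  expect_equal(ct0$count, 0L)
})

test_that("paired mode counts pairs once even when both mates match", {
  st <- read_store(c("AAACGTTT", "AAACGTTT", "GGGGGGGG", "CCCCCCCC"),
                   paired = TRUE)
  iset <- index_reads(st, sample_rate = 1L)
  qs <- make_qs("AAACGTTT")
  base <- search_settings(k = 6L, s = 1L, mode = "sliding",
                          search_rc = FALSE)
  ct_reads <- run_query_search(iset, qs, base)
  expect_equal(ct_reads$count, 2L)
  expect_equal(attr(ct_reads, "unit"), "READS")
  paired <- base; paired$paired_mode <- TRUE
  ct_pairs <- run_query_search(iset, qs, paired)
  expect_equal(ct_pairs$count, 1L)
  expect_equal(attr(ct_pairs, "unit"), "PAIRS")
})

test_that("unique_reads removes contested reads from every query", {
  # read 'AACGTACC' matches both queries; 'AACGTTTT' only q1, 'GGGTACCA' only q2
  st <- read_store(c("AACGTACC", "AACGTTTT", "GGGTACCA"))
  iset <- index_reads(st, sample_rate = 1L)
  qs <- make_qs(c("AACGT", "GTACC"))
  base <- search_settings(k = 5L, s = 1L, mode = "sliding",
                          search_rc = FALSE,
                          ignore_nonunique_kmers = FALSE)
  ct_off <- run_query_search(iset, qs, base)
  expect_equal(ct_off$count, c(2L, 2L))
  uniq <- base; uniq$unique_reads <- TRUE
  ct_on <- run_query_search(iset, qs, uniq)
  expect_equal(ct_on$count, c(1L, 1L))
  # disabling unique_reads never decreases any count
  expect_true(all(ct_off$count >= ct_on$count))
})

test_that("max_occ is enforced on the global total across chunks", {
  # 'ACGTT' occurs once per read; 6 reads split 3+3 across 2 chunks
  reads <- rep("AAACGTTCC", 6)
  st <- read_store(reads)
  qs <- make_qs("AAACGTTCC")
  set_lo <- search_settings(k = 5L, s = 1L, mode = "sliding",
                            search_rc = FALSE, max_occ = 4L)
  mono <- run_query_search(index_reads(st, 1L, sample_rate = 1L), qs, set_lo)
  split4 <- run_query_search(index_reads(st, 2L, sample_rate = 1L), qs, set_lo)
  # per-chunk counts (3) are under the ceiling, but the global total (6)
  # is not: the k-mers contribute nothing and the query is flagged
  expect_equal(mono$count, 0L)
  expect_true(mono$flag_overmax_kmer)
  expect_equal(as.data.frame(split4), as.data.frame(mono))

  set_hi <- search_settings(k = 5L, s = 1L, mode = "sliding",
                            search_rc = FALSE, max_occ = 10L)
  ct_hi <- run_query_search(index_reads(st, 2L, sample_rate = 1L), qs, set_hi)
  expect_equal(ct_hi$count, 6L)
  # lowering max_occ never increases any count
  expect_true(all(ct_hi$count >= mono$count))
})

test_that("RC-searching a forward index equals forward-searching an RC index", {
  reads <- rand_reads(40, 50, seed = 61)
  # flip half the reads to the minus strand
  flipped <- reads
  flip <- seq(1, 40, by = 2)
  flipped[flip] <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(reads[flip])))
  qs <- make_qs(substring(reads[c(2, 7, 20)], 3, 45))
  base <- search_settings(k = 15L, s = 4L, mode = "sliding",
                          max_occ = 500L)

  fwd_index <- index_reads(read_store(flipped), sample_rate = 4L)
  with_rc_search <- run_query_search(fwd_index, qs, base)

  norc <- base; norc$search_rc <- FALSE
  rc_index <- index_reads(read_store(flipped, include_rc = TRUE),
                          sample_rate = 4L)
  with_rc_index <- run_query_search(rc_index, qs, norc)
  expect_equal(as.data.frame(with_rc_search),
               as.data.frame(with_rc_index))

  # a read and its reverse complement contribute identically
  st_a <- read_store(reads[1])
  st_b <- read_store(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(reads[1]))))
  q1 <- make_qs(substring(reads[1], 5, 40))
  ct_a <- run_query_search(index_reads(st_a, sample_rate = 1L), q1, base)
  ct_b <- run_query_search(index_reads(st_b, sample_rate = 1L), q1, base)
  expect_equal(ct_a$count, ct_b$count)
})

test_that("results are identical across chunkings and thread counts", {
  reads <- rand_reads(60, 60, seed = 71)
  st <- read_store(reads)
  qs <- make_qs(c(substring(reads[5], 1, 50), substring(reads[30], 5, 55),
                  paste(rep("ACGT", 10), collapse = "")))
  for (settings in list(
    search_settings(k = 11L, s = 3L, mode = "sliding", max_occ = 200L),
    search_settings(k = 11L, s = 3L, mode = "sliding", max_occ = 5L,
                    unique_reads = TRUE),
    search_settings(k = 15L, s = 7L, mode = "centered", max_occ = 200L,
                    ignore_nonunique_kmers = FALSE))) {
    ref <- NULL
    for (n_chunks in c(1L, 4L)) {
      for (threads in c(1L, 2L, 8L)) {
        s2 <- settings; s2$threads <- threads
        ct <- run_query_search(index_reads(st, n_chunks, sample_rate = 4L),
                               qs, s2)
        if (is.null(ref)) ref <- ct else
          expect_equal(as.data.frame(ct), as.data.frame(ref))
      }
    }
  }
})

test_that("query search counts agree with a per-read matching oracle", {
  for (seed in c(81, 82, 83)) {
    reads <- rand_reads(50, 45, seed = seed)
    st <- read_store(reads)
    iset <- index_reads(st, n_chunks = 2L, sample_rate = 4L)
    qs <- make_qs(c(substring(reads[10], 1, 40), substring(reads[25], 3, 44)))
    settings <- search_settings(k = 12L, s = 12L, mode = "sliding",
                                max_occ = 1000L,
                                ignore_nonunique_kmers = FALSE)
    ct <- run_query_search(iset, qs, settings)
    for (qi in seq_len(nrow(qs))) {
      kmers <- kmers_sliding(qs$sequence[qi], 12L, 12L)$kmer
      expected <- unique(unlist(lapply(kmers, function(p)
        naive_matching_reads(reads, p))))
      expect_equal(ct$count[ct$query_id == qs$query_id[qi]],
                   length(expected))
    }
  }
})

test_that("ksearch counts deduplicated reads and tallies groups", {
  # construct reads with known per-k-mer membership
  km_a <- "ACGTACGTAA"   # in 4 reads
  km_b <- "GGGGCCCCGG"   # in 1 read
  km_c <- "TTTTAAAATT"   # absent
  reads <- c(paste0(km_a, "TT"), paste0("CC", km_a), km_a, paste0(km_a, "GG"),
             paste0(km_b, "AA"), rand_reads(5, 12, seed = 91))
  iset <- index_reads(read_store(reads), sample_rate = 1L)
  kml <- data.frame(kmer = c(km_a, km_b, km_c, km_a),
                    group = c("g1", "g1", "g2", "g1"))
  res <- ksearch(iset, kml, search_settings(search_rc = FALSE), threshold = 3L)
  expect_equal(nrow(res$counts), 3L)  # duplicate collapsed
  expect_equal(res$counts$count[res$counts$kmer == km_a], 4L)
  expect_equal(res$counts$count[res$counts$kmer == km_b], 1L)
  expect_equal(res$counts$count[res$counts$kmer == km_c], 0L)
  expect_equal(res$group_tally$n_over_threshold[
    res$group_tally$group == "g1"], 1L)
  expect_equal(res$group_tally$n_over_threshold[
    res$group_tally$group == "g2"], 0L)

  # tally definition is strictly-greater-than
  counts <- c(0L, 1L, 4L, 4L, 9L)
  expect_equal(sum(counts > 3L), 3L)
})

test_that("count tables can be written in the query-mirroring format", {
  reads <- rand_reads(10, 30, seed = 95)
  iset <- index_reads(read_store(reads), sample_rate = 1L)
  qs <- make_qs(substring(reads[1], 1, 25))
  ct <- run_query_search(iset, qs, search_settings(k = 10L, s = 5L,
                                                   mode = "sliding"))
  path <- tempfile(fileext = ".tsv")
  write_counts(ct, qs, path)
  tab <- read.delim(path)
  expect_equal(names(tab)[1:8],
               c("query_id", "kind", "chrom", "pos", "ref", "alt", "name",
                 "sequence"))
  expect_equal(tab$count, ct$count)
})
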