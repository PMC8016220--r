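test_that("genome generation is seeded and uniform", {
  g1 <- make_genome(1000, 42)
  g2 <- make_genome(1000, 42)
  expect_identical(g1, g2)
  expect_false(identical(g1, make_genome(1000, 43)))
  expect_equal(nchar(make_genome(1, 7)), 1L)

  # base frequencies within 5 sigma of 0.25 at n = 2e5
  g <- make_genome(2e5, 11)
  freq <- table(strsplit(g, "")[[1L]]) / 2e5
  sigma <- sqrt(0.25 * 0.75 / 2e5)
  expect_true(all(abs(freq - 0.25) < 5 * sigma))
})

test_that("planted SNPs respect spacing and genotype/haplotype consistency", {
  g <- make_genome(8000, 21)
  sn <- plant_snps(g, 30, seed = 22, flank = 30L)
  truth <- sn$truth
  expect_equal(nrow(truth), 30L)
  expect_true(all(diff(truth$pos) >= 61L))
  expect_true(all(truth$pos > 30L & truth$pos <= 8000L - 30L))
  expect_true(all(truth$ref != truth$alt))
  for (i in seq_len(nrow(truth))) {
    a <- substr(sn$hap_a, truth$pos[i], truth$pos[i])
    b <- substr(sn$hap_b, truth$pos[i], truth$pos[i])
    expect_equal(a, switch(truth$genotype[i], "0/0" = truth$ref[i],
                           "0/1" = truth$ref[i], "1/1" = truth$alt[i]))
    expect_equal(b, switch(truth$genotype[i], "0/0" = truth$ref[i],
                           "0/1" = truth$alt[i], "1/1" = truth$alt[i]))
  }
  # away from the SNPs the haplotypes equal the genome
  masked <- strsplit(g, "")[[1L]]
  masked[truth$pos] <- "."
  ha <- strsplit(sn$hap_a, "")[[1L]]; ha[truth$pos] <- "."
  expect_equal(ha, masked)

  expect_equal(plant_snps(g, 0L, seed = 1)$hap_b, g)
  expect_error(plant_snps(make_genome(200, 1), 50, seed = 1, flank = 30L),
               "cannot place")
})

test_that("truth sets round-trip through the VCF writer into query pairs", {
  g <- make_genome(4000, 31)
  sn <- plant_snps(g, 10, seed = 32, flank = 25L)
  vcf <- tempfile(fileext = ".vcf")
  truth_to_vcf(sn$truth, vcf)
  fa <- write_test_fasta(tempfile(fileext = ".fa"), c(sim1 = g))
  qs <- queries_from_vcf(vcf, fa, flank = 25L)
  refs <- qs[qs$kind == "REF", ]
  expect_equal(refs$pos, sn$truth$pos)
  expect_equal(refs$ref, sn$truth$ref)
  expect_equal(refs$alt, sn$truth$alt)
  # REF sequence centre equals the genome (haplotype A ref) base
  expect_equal(substr(refs$sequence, 26L, 26L), sn$truth$ref)
})

test_that("read simulation covers both strands at the requested depth", {
  g <- make_genome(10000, 41)
  sim <- simulate_reads(g, read_length = 100L, depth = 100, seed = 42)
  expect_equal(length(sim$reads), 10000L)  # depth * L / read_length
  expect_setequal(unique(sim$origin$strand), c("+", "-"))

  # error-free reads are exact substrings of the genome or its RC
  sub <- sim$reads[1:200]
  ori <- sim$origin[1:200, ]
  fwd <- ifelse(ori$strand == "+", sub,
                as.character(Biostrings::reverseComplement(
                  Biostrings::DNAStringSet(sub))))
  expect_equal(unname(fwd),
               substring(g, ori$pos, ori$pos + 99L))

  # seed determinism, including written FASTQ bytes
  sim2 <- simulate_reads(g, read_length = 100L, depth = 100, seed = 42)
  expect_identical(sim$reads, sim2$reads)
  f1 <- tempfile(fileext = ".fq"); f2 <- tempfile(fileext = ".fq")
  write_reads(sim$reads[1:50], f1)
  write_reads(sim2$reads[1:50], f2)
  expect_identical(readLines(f1), readLines(f2))

  # FASTQ output loads back into the identical read set
  st <- load_reads(f1)
  expect_equal(store_sequences(st), unname(sim$reads[1:50]))
})

test_that("substitution errors appear at the stated rate", {
  g <- make_genome(5000, 51)
  sim <- simulate_reads(g, read_length = 100L, n_reads = 2000L,
                        error_rate = 0.02, seed = 52)
  expect_equal(mean(sim$origin$n_errors) / 100, 0.02, tolerance = 0.15)
  # reads with errors differ from their source in exactly n_errors places
  ori <- sim$origin
  fwd <- ifelse(ori$strand == "+", sim$reads,
                as.character(Biostrings::reverseComplement(
                  Biostrings::DNAStringSet(sim$reads))))
  src <- substring(g, ori$pos, ori$pos + 99L)
  mismatches <- mapply(function(a, b)
    sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]]),
    fwd[1:100], src[1:100])
  expect_equal(unname(mismatches), ori$n_errors[1:100])
})

test_that("paired simulation emits interleaved mates from one fragment", {
  g <- make_genome(6000, 71)
  sim <- simulate_reads(g, read_length = 80L, n_reads = 150L, paired = TRUE,
                        fragment_length = 250L, seed = 72)
  expect_length(sim$reads, 300L)
  expect_true(all(grepl("/1$", names(sim$reads)[c(TRUE, FALSE)])))
  expect_true(all(grepl("/2$", names(sim$reads)[c(FALSE, TRUE)])))

  # error-free mates bracket the same fragment
  ori <- sim$origin
  plus <- which(ori$strand == "+" & grepl("/1$", ori$read))
  for (i in plus[1:20]) {
    frag <- substr(g, ori$pos[i], ori$pos[i] + 249L)
    expect_equal(unname(sim$reads[i]), substr(frag, 1L, 80L))
    expect_equal(unname(sim$reads[i + 1L]),
                 as.character(Biostrings::reverseComplement(
                   Biostrings::DNAString(substr(frag, 171L, 250L)))))
  }

  # depth accounting: each pair covers 2 * read_length bases
  byd <- simulate_reads(g, read_length = 100L, depth = 10, paired = TRUE,
                        seed = 73)
  expect_length(byd$reads, 2L * round(10 * 6000 / 200))

  # a paired store built from the interleaved reads counts pairs once
  st <- read_store(sim$reads, paired = TRUE)
  iset <- index_reads(st, sample_rate = 8L)
  qs <- query_set(data.frame(query_id = 0L, kind = "SEQ",
                             chrom = NA_character_, pos = NA_integer_,
                             ref = NA_character_, alt = NA_character_,
                             name = "g", sequence = g))
  settings <- search_settings(preset = "pathogen", paired_mode = TRUE)
  ct <- run_query_search(iset, qs, settings)
  expect_equal(ct$count, 150L)
  expect_equal(attr(ct, "unit"), "PAIRS")
})

test_that("spike-ins add exactly the requested reads with truth records", {
  bg <- simulate_reads(make_genome(4000, 61), read_length = 80L,
                       n_reads = 300L, seed = 62, prefix = "bg")$reads
  pathogen <- make_genome(2000, 63)
  sp0 <- spike_in(bg, pathogen, 0L, read_length = 80L, seed = 64)
  expect_identical(sp0$reads, bg)
  expect_length(sp0$spiked, 0L)

  sp <- spike_in(bg, pathogen, 120L, read_length = 80L, seed = 64)
  expect_length(sp$reads, 420L)
  expect_length(sp$spiked, 120L)
  expect_true(all(sp$spiked %in% names(sp$reads)))

  # two pathogens spiked at different counts partition the truth
  p2 <- make_genome(1500, 65)
  sp2 <- spike_in(sp$reads, p2, 50L, read_length = 80L, seed = 66,
                  label = "spike2")
  expect_length(sp2$spiked, 50L)
  expect_length(intersect(sp2$spiked, sp$spiked), 0L)
})
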