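# Independent oracles and fixture builders shared across tests.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random read sequences (uppercase A/C/G/T, optionally N).
rand_reads <- function(n, len, seed, with_n = FALSE) {
  withr::with_seed(seed, {
    alpha <- c("A", "C", "G", "T", if (with_n) "N")
    lens <- if (length(len) == 1L) rep(len, n) else
      sample(len[1]:len[2], n, replace = TRUE)
    vapply(lens, function(l)
      paste(sample(alpha, l, replace = TRUE), collapse = ""), "")
  })
}

# Naive suffix array: radix sort of all suffixes under $ < A < C < G < N < T.
naive_suffix_array <- function(text) {
  n <- nchar(text)
  suff <- substring(chartr("$ACGNT", "ABCDEF", text), 1:n, n)
  order(suff, method = "radix") - 1L
}

# Naive occurrence positions of a pattern in a text (overlaps included).
naive_positions <- function(text, pattern) {
  n <- nchar(text)
  k <- nchar(pattern)
  if (k > n) return(integer(0))
  starts <- 1:(n - k + 1L)
  starts[substring(text, starts, starts + k - 1L) == pattern] - 1L
}

# Per-read occurrence count of a pattern, via Biostrings (independent of the
# package's text concatenation and FM machinery).
naive_read_count <- function(reads, pattern) {
  sum(Biostrings::vcountPattern(pattern, Biostrings::DNAStringSet(reads)))
}

# Reads (ordinals, 0-based) containing a pattern in either orientation.
naive_matching_reads <- function(reads, pattern, both_strands = TRUE) {
  pats <- pattern
  if (both_strands)
    pats <- unique(c(pattern, as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(pattern)))))
  hit <- rep(FALSE, length(reads))
  for (p in pats)
    hit <- hit | Biostrings::vcountPattern(p,
      Biostrings::DNAStringSet(reads)) > 0L
  which(hit) - 1L
}

# Brute-force reading of the min-count genotype rule table, completed so
# that every (ref, alt) pair yields exactly one call: supported = count >= mc.
oracle_genotype <- function(ref, alt, mc) {
  if (alt < mc && ref >= mc) return("0/0")
  if (alt >= mc && ref >= mc) return("0/1")
  if (alt >= mc && ref < mc) return("1/1")
  "./."
}

# Decode an fm_index BWT back to characters.
decode_bwt <- function(index) {
  paste(c("$", "A", "C", "G", "N", "T")[as.integer(index$bwt) + 1L],
        collapse = "")
}

# Write a minimal VCF v4.3 for given sites.
write_test_vcf <- function(path, chrom, pos, ref, alt) {
  writeLines(c(
    "##fileformat=VCFv4.3",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"),
    paste(chrom, pos, ".", ref, alt, ".", ".", ".", sep = "\t")), path)
  path
}

# Write a FASTA file from a named character vector.
write_test_fasta <- function(path, seqs) {
  writeLines(paste0(">", names(seqs), "\n", seqs), path)
  path
}
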