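#' Seeded simulator for genomes, diploid SNP read sets and spike-ins
#'
#' The simulator reproduces the statistical structure the search engine is
#' designed for: uniform random genomes, planted biallelic SNPs with diploid
#' genotypes, uniform-coverage stranded reads with an optional i.i.d.
#' substitution error model, and pathogen reads spiked into a background at
#' fixed counts.  Every operation is deterministic given its seed.  Indels,
#' GC bias, duplicates and realistic quality profiles are deliberately out
#' of scope: exact k-mer matching makes indel-bearing reads behave like
#' heavily substituted ones, so substitutions alone exercise the k/s
#' sensitivity trade-off.
#'
#' @name simulate
NULL

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a uniform random genome
#'
#' @param length genome length in bases (>= 1).
#' @param seed RNG seed.
#' @return A single DNA string with i.i.d. uniform A/C/G/T bases.
#' @export
make_genome <- function(length, seed) {
  stopifnot(length >= 1)
  with_seed(seed, paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                        collapse = ""))
}

#' Plant biallelic SNPs on a genome, producing two haplotypes
#'
#' Draws SNP positions with a minimum spacing (default \code{2*flank + 1} so
#' downstream centered queries never overlap), assigns genotypes with the
#' given proportions, and substitutes alternate alleles: \code{1/1} sites on
#' both haplotypes, \code{0/1} sites on haplotype B only (arbitrary but
#' fixed phase).
#'
#' @param genome DNA string from [make_genome()] (or any A/C/G/T string).
#' @param n_snps number of SNPs to plant.
#' @param seed RNG seed.
#' @param flank flank the downstream queries will use; sites are kept at
#'   least \code{min_spacing} apart and \code{flank} away from contig ends.
#' @param min_spacing minimum distance between consecutive sites.
#' @param genotype_probs proportions for \code{0/0, 0/1, 1/1}.
#' @param chrom contig name recorded in the truth set.
#' @return List with \code{hap_a}, \code{hap_b} (DNA strings) and
#'   \code{truth}: a data.frame of \code{chrom}, \code{pos} (1-based),
#'   \code{ref}, \code{alt}, \code{genotype}.
#' @export
plant_snps <- function(genome, n_snps, seed, flank = 50L,
                       min_spacing = 2L * flank + 1L,
                       genotype_probs = c(0.25, 0.5, 0.25),
                       chrom = "sim1") {
  L <- nchar(genome)
  if (n_snps == 0L)
    return(list(hap_a = genome, hap_b = genome,
                truth = data.frame(chrom = character(0), pos = integer(0),
                                   ref = character(0), alt = character(0),
                                   genotype = character(0))))
  lo <- flank + 1L
  hi <- L - flank
  if (hi - lo < (n_snps - 1L) * min_spacing)
    stop(sprintf("cannot place %d SNPs with spacing %d on a %d bp genome",
                 n_snps, min_spacing, L), call. = FALSE)
  with_seed(seed, {
    # n_snps anchors spaced by min_spacing, with the residual slack split
    # into random gaps: positions stay sorted and spacing is guaranteed.
    slack <- (hi - lo) - (n_snps - 1L) * min_spacing
    cuts <- sort(sample.int(slack + 1L, n_snps, replace = TRUE) - 1L)
    pos <- lo + cuts + (seq_len(n_snps) - 1L) * min_spacing
    ref <- substring(genome, pos, pos)
    alt <- vapply(ref, function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), "", USE.NAMES = FALSE)
    genotype <- sample(c("0/0", "0/1", "1/1"), n_snps, replace = TRUE,
                       prob = genotype_probs)
    hap_a <- genome
    hap_b <- genome
    for (i in seq_len(n_snps)) {
      if (genotype[i] == "1/1") {
        substr(hap_a, pos[i], pos[i]) <- alt[i]
        substr(hap_b, pos[i], pos[i]) <- alt[i]
      } else if (genotype[i] == "0/1") {
        substr(hap_b, pos[i], pos[i]) <- alt[i]
      }
    }
    list(hap_a = hap_a, hap_b = hap_b,
         truth = data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                            genotype = genotype))
  })
}

#' Write a truth set as a minimal VCF (v4.3)
#'
#' @param truth truth data.frame from [plant_snps()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
truth_to_vcf <- function(truth, path) {
  header <- c("##fileformat=VCFv4.3",
              "##source=revmap simulator",
              paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", sep = "\t"))
  body <- if (nrow(truth))
    paste(truth$chrom, truth$pos, ".", truth$ref, truth$alt, ".", ".", ".",
          sep = "\t") else character(0)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Simulate uniform-coverage stranded reads
#'
#' Read start positions are uniform over the feasible range, strands are
#' uniform (minus-strand reads are reverse-complemented), and for diploid
#' input the source haplotype is uniform.  Substitution errors are i.i.d.
#' per base at \code{error_rate}.  With \code{depth} given, the read count
#' is \code{round(depth * genome_length / read_length)}.
#'
#' @param haplotypes a single DNA string or list/vector of one or two
#'   haplotype strings (equal length).
#' @param read_length read length in bases.
#' @param depth fold coverage (exactly one of \code{depth} / \code{n_reads}).
#' @param n_reads explicit read (or pair) count.
#' @param error_rate per-base substitution probability in \code{[0, 1)}.
#' @param paired emit read pairs: each fragment of \code{fragment_length}
#'   yields mate 1 from its 5' end and mate 2 as the reverse complement of
#'   its 3' end, interleaved (R1, R2, R1, R2, ...).
#' @param fragment_length fragment size for paired output
#'   (>= \code{read_length}).
#' @param seed RNG seed.
#' @param prefix read name prefix.
#' @return List with \code{reads} (named character vector; interleaved
#'   mates when paired) and \code{origin}: data.frame of \code{read},
#'   \code{haplotype}, \code{pos} (1-based start of the read or fragment on
#'   the haplotype), \code{strand}, \code{n_errors}.
#' @export
simulate_reads <- function(haplotypes, read_length = 100L, depth = NULL,
                           n_reads = NULL, error_rate = 0, paired = FALSE,
                           fragment_length = 3L * read_length, seed = 1L,
                           prefix = "read") {
  haps <- unlist(as.list(haplotypes))
  stopifnot(length(haps) %in% c(1L, 2L))
  L <- unique(nchar(haps))
  span <- if (paired) as.integer(fragment_length) else as.integer(read_length)
  stopifnot(length(L) == 1L, read_length <= span, span <= L,
            error_rate >= 0, error_rate < 1)
  if (is.null(n_reads) == is.null(depth))
    stop("give exactly one of depth or n_reads", call. = FALSE)
  if (is.null(n_reads)) {
    covered <- if (paired) 2L * read_length else read_length
    n_reads <- round(depth * L / covered)
  }
  n_units <- as.integer(n_reads)
  if (n_units == 0L)
    return(list(reads = character(0),
                origin = data.frame(read = character(0),
                                    haplotype = integer(0), pos = integer(0),
                                    strand = character(0),
                                    n_errors = integer(0))))
  with_seed(seed, {
    hap_i <- sample.int(length(haps), n_units, replace = TRUE)
    pos <- sample.int(L - span + 1L, n_units, replace = TRUE)
    strand <- sample(c("+", "-"), n_units, replace = TRUE)
    frag <- substring(haps[hap_i], pos, pos + span - 1L)
    minus <- strand == "-"
    if (any(minus)) frag[minus] <- revcomp(frag[minus])
    if (paired) {
      r1 <- substr(frag, 1L, read_length)
      r2 <- revcomp(substr(frag, span - read_length + 1L, span))
      reads <- character(2L * n_units)
      reads[c(TRUE, FALSE)] <- r1
      reads[c(FALSE, TRUE)] <- r2
      mate <- rep(1:2, n_units)
      hap_i <- rep(hap_i, each = 2L)
      pos <- rep(pos, each = 2L)
      strand <- rep(strand, each = 2L)
      nm <- sprintf("%s_%06d/%d", prefix, rep(seq_len(n_units), each = 2L),
                    mate)
    } else {
      reads <- frag
      nm <- sprintf("%s_%06d", prefix, seq_len(n_units))
    }
    n <- length(reads)
    n_err <- if (error_rate > 0)
      rbinom(n, read_length, error_rate) else integer(n)
    for (i in which(n_err > 0L)) {
      at <- sample.int(read_length, n_err[i])
      for (p in at) {
        cur <- substr(reads[i], p, p)
        substr(reads[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur),
                                         1L)
      }
    }
    names(reads) <- nm
    list(reads = reads,
         origin = data.frame(read = nm, haplotype = hap_i, pos = pos,
                             strand = strand, n_errors = n_err))
  })
}

#' Spike pathogen reads into a background read set
#'
#' Appends exactly \code{n_reads} reads simulated from a pathogen genome to
#' a background read set, recording which read names are spiked.
#'
#' @param background named character vector of background reads (as from
#'   [simulate_reads()]\code{$reads}) or a FASTQ/FASTA path.
#' @param pathogen_genome pathogen genome DNA string.
#' @param n_reads number of pathogen reads to spike (>= 0).
#' @param read_length,error_rate,seed passed to [simulate_reads()].
#' @param label prefix for the spiked read names.
#' @return List with \code{reads} (background followed by spiked reads),
#'   \code{spiked} (names of the spiked reads) and \code{origin} of the
#'   spiked reads.
#' @export
spike_in <- function(background, pathogen_genome, n_reads,
                     read_length = 100L, error_rate = 0, seed = 1L,
                     label = "spike") {
  if (is.character(background) && length(background) == 1L &&
      file.exists(background))
    background <- store_sequences(load_reads(background))
  if (n_reads == 0L)
    return(list(reads = background, spiked = character(0),
                origin = NULL))
  sim <- simulate_reads(pathogen_genome, read_length = read_length,
                        n_reads = n_reads, error_rate = error_rate,
                        seed = seed, prefix = label)
  list(reads = c(background, sim$reads), spiked = names(sim$reads),
       origin = sim$origin)
}

#' Write reads as FASTQ (constant quality) or FASTA
#'
#' FASTQ qualities are a constant high-quality string: the indexer discards
#' qualities, so only the symbol stream matters.
#'
#' @param reads named character vector of reads.
#' @param path output path; \code{.gz} suffix enables gzip compression.
#' @param format \code{"fastq"} or \code{"fasta"}.
#' @return \code{path}, invisibly.
#' @export
write_reads <- function(reads, path, format = c("fastq", "fasta")) {
  format <- match.arg(format)
  nm <- names(reads) %||% sprintf("read_%06d", seq_along(reads))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  if (format == "fastq") {
    qual <- vapply(nchar(reads), function(n)
      strrep("I", n), "", USE.NAMES = FALSE)
    writeLines(paste0("@", nm, "\n", reads, "\n+\n", qual), con)
  } else {
    writeLines(paste0(">", nm, "\n", reads), con)
  }
  invisible(path)
}

#' Write one or more genomes as FASTA
#'
#' @param genomes named character vector of genome sequences.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_genomes <- function(genomes, path) {
  nm <- names(genomes) %||% sprintf("genome_%d", seq_along(genomes))
  set <- Biostrings::DNAStringSet(unname(genomes))
  names(set) <- nm
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
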