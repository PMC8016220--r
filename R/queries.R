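#' Query sets
#'
#' A query set is a table of target sequences to be counted in the reads.
#' Three kinds exist: \code{REF}/\code{ALT} pairs centered on a biallelic SNP
#' (for genotyping), and free \code{SEQ} records (e.g. pathogen genomes).
#' REF/ALT records of a site share \code{(chrom, pos)} and differ at exactly
#' the central base of their sequences.
#'
#' @param records data.frame with columns \code{query_id}, \code{kind},
#'   \code{chrom}, \code{pos}, \code{ref}, \code{alt}, \code{name},
#'   \code{sequence}.
#' @param flank flank width used at construction (NA for SEQ-only sets).
#' @return An object of class \code{query_set} (a data.frame).
#' @export
query_set <- function(records, flank = NA_integer_) {
  need <- c("query_id", "kind", "chrom", "pos", "ref", "alt", "name",
            "sequence")
  stopifnot(all(need %in% names(records)))
  records <- records[, need]
  if (anyDuplicated(records$query_id))
    stop("duplicated query_id in query set", call. = FALSE)
  ids <- sort(records$query_id)
  if (!identical(as.integer(ids), seq_along(ids) - 1L))
    stop("query_ids must be dense 0-based integers", call. = FALSE)
  structure(records, flank = as.integer(flank),
            class = c("query_set", "data.frame"))
}

new_query_row <- function(query_id, kind, sequence, chrom = NA_character_,
                          pos = NA_integer_, ref = NA_character_,
                          alt = NA_character_, name = NA_character_) {
  data.frame(query_id = as.integer(query_id), kind = kind, chrom = chrom,
             pos = as.integer(pos), ref = ref, alt = alt, name = name,
             sequence = sequence)
}

#' Generate centered REF/ALT queries from a VCF and reference genome
#'
#' For every biallelic SNP record, extracts the reference sequence
#' \code{[pos - flank, pos + flank]} (1-based inclusive, length
#' \code{2*flank + 1}) and the same window with the central base substituted
#' by the alternate allele.  Indels, multi-allelic records and sites whose
#' window runs off a contig end are skipped with a warning tally; a SNP whose
#' REF allele disagrees with the reference genome is an error.
#'
#' @param vcf_path VCF file (v4.3, plain or gzipped).
#' @param reference_fasta_path reference genome FASTA.
#' @param flank flank width in bases; query length is \code{2*flank + 1}.
#'   The default 50 gives 101-base queries, comfortably longer than typical
#'   search k-mer lengths.
#' @return A [query_set()] of REF/ALT pairs; attribute \code{skipped} counts
#'   records skipped by reason.
#' @export
queries_from_vcf <- function(vcf_path, reference_fasta_path, flank = 50L) {
  flank <- as.integer(flank)
  if (is.na(flank) || flank < 1L) stop("flank must be >= 1", call. = FALSE)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  genome <- Biostrings::readDNAStringSet(reference_fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))

  skipped <- c(non_snp = 0L, multi_allelic = 0L, out_of_range = 0L)
  rows <- vector("list", nrow(fix))
  qid <- 0L
  for (i in seq_len(nrow(fix))) {
    chrom <- fix$CHROM[i]
    pos <- as.integer(fix$POS[i])
    ref <- toupper(fix$REF[i])
    alt <- toupper(fix$ALT[i])
    if (is.na(alt) || grepl(",", alt, fixed = TRUE)) {
      skipped["multi_allelic"] <- skipped["multi_allelic"] + 1L
      next
    }
    if (nchar(ref) != 1L || nchar(alt) != 1L || !alt %in% c("A", "C", "G", "T")) {
      skipped["non_snp"] <- skipped["non_snp"] + 1L
      next
    }
    if (!chrom %in% names(genome))
      stop("VCF contig not in reference: ", chrom, call. = FALSE)
    ctg_len <- Biostrings::width(genome[chrom])
    if (pos - flank < 1L || pos + flank > ctg_len) {
      skipped["out_of_range"] <- skipped["out_of_range"] + 1L
      next
    }
    window <- as.character(Biostrings::subseq(genome[[chrom]],
                                              pos - flank, pos + flank))
    centre <- flank + 1L
    if (substr(window, centre, centre) != ref)
      stop(sprintf("REF allele mismatch at %s:%d (VCF %s, reference %s)",
                   chrom, pos, ref, substr(window, centre, centre)),
           call. = FALSE)
    alt_window <- window
    substr(alt_window, centre, centre) <- alt
    site <- sprintf("%s:%d", chrom, pos)
    rows[[i]] <- rbind(
      new_query_row(qid, "REF", window, chrom, pos, ref, alt, site),
      new_query_row(qid + 1L, "ALT", alt_window, chrom, pos, ref, alt, site))
    qid <- qid + 2L
  }
  n_skip <- sum(skipped)
  if (n_skip > 0L)
    warning(sprintf("skipped %d VCF record(s): %s", n_skip,
                    paste(sprintf("%s=%d", names(skipped), skipped),
                          collapse = ", ")), call. = FALSE)
  records <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(records)) stop("no usable SNP records in VCF", call. = FALSE)
  qs <- query_set(records, flank = flank)
  attr(qs, "skipped") <- skipped
  qs
}

#' Generate SEQ queries from a FASTA file
#'
#' One query per FASTA record; the name is the first header token and the
#' sequence is uppercased with U mapped to T.
#'
#' @param fasta_path FASTA file (one or more records).
#' @return A [query_set()] of SEQ records.
#' @export
queries_from_fasta <- function(fasta_path) {
  set <- Biostrings::readBStringSet(fasta_path, format = "fasta")
  if (!length(set)) stop("empty FASTA: ", fasta_path, call. = FALSE)
  seqs <- normalize_seq(as.character(set))
  if (any(!nzchar(seqs)))
    stop("empty record in FASTA: ", fasta_path, call. = FALSE)
  nm <- sub("\\s.*$", "", names(set))
  assert_dna(seqs, nm)
  query_set(new_query_row(seq_along(seqs) - 1L, "SEQ", unname(seqs),
                          name = nm))
}

#' Read a plain-text k-mer list
#'
#' One k-mer per line, with an optional tab-separated second column giving a
#' group label (e.g. the gene a distinguishing k-mer belongs to).
#'
#' @param path text file path.
#' @return data.frame with columns \code{kmer} and \code{group}
#'   (NA when ungrouped).
#' @export
read_kmer_list <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty k-mer list: ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  kmer <- toupper(vapply(parts, `[`, "", 1L))
  group <- vapply(parts, function(p) if (length(p) > 1L) p[2L] else
    NA_character_, "")
  bad <- !grepl("^[ACGT]+$", kmer)
  if (any(bad))
    stop(sprintf("invalid k-mer on line %d: %s", which(bad)[1L],
                 kmer[which(bad)[1L]]), call. = FALSE)
  data.frame(kmer = kmer, group = group)
}

# --- query file format -----------------------------------------------------

#' Write / read the tab-separated query file format
#'
#' Columns: \code{query_id}, \code{kind}, \code{chrom}, \code{pos},
#' \code{ref}, \code{alt}, \code{name}, \code{sequence}; absent locus fields
#' are written as \code{.}.  The round trip is lossless.
#'
#' @param qs a [query_set()].
#' @param path file path.
#' @return \code{write_query_file} returns \code{path} invisibly;
#'   \code{read_query_file} returns the restored [query_set()].
#' @export
write_query_file <- function(qs, path) {
  stopifnot(inherits(qs, "query_set"))
  out <- as.data.frame(qs)
  for (col in names(out))
    out[[col]] <- ifelse(is.na(out[[col]]), ".", as.character(out[[col]]))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_query_file
#' @export
read_query_file <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE,
                   colClasses = "character")
  need <- c("query_id", "kind", "chrom", "pos", "ref", "alt", "name",
            "sequence")
  if (!identical(names(df), need))
    stop("malformed query file header: ", path, call. = FALSE)
  for (col in names(df)) df[[col]][df[[col]] == "."] <- NA
  bad <- is.na(df$sequence) | !grepl("^[ACGTN]+$", df$sequence)
  if (any(bad))
    stop(sprintf("malformed query file line %d", which(bad)[1L] + 1L),
         call. = FALSE)
  df$query_id <- as.integer(df$query_id)
  df$pos <- as.integer(df$pos)
  fl <- attr(df, "flank")
  query_set(df, flank = fl %||% NA_integer_)
}
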