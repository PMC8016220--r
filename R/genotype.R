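#' Genotype calls from REF/ALT read counts
#'
#' A biallelic site is genotyped from the deduplicated read counts of its
#' centered REF and ALT queries using a minimum-count rule: an allele is
#' supported when its count reaches \code{min_count}.  Both alleles
#' supported gives heterozygous \code{0/1}; only the reference,
#' homozygous-reference \code{0/0}; only the alternate, homozygous-alternate
#' \code{1/1}; neither, no-call \code{./.}.  Support is defined as
#' \code{count >= min_count}, which totalizes the rule table (equality and
#' double-failure included) with the least surprising reading.
#'
#' @param ref_count,alt_count non-negative read counts (vectorized).
#' @param min_count support threshold (>= 1).  There is no universally
#'   correct value; 3 is the package default and should be reviewed against
#'   the expected coverage.
#' @return Character vector of genotypes among
#'   \code{"0/0", "0/1", "1/1", "./."}.
#' @export
call_genotype <- function(ref_count, alt_count, min_count = 3L) {
  if (min_count < 1L) stop("min_count must be >= 1", call. = FALSE)
  if (any(ref_count < 0) || any(alt_count < 0))
    stop("counts must be non-negative", call. = FALSE)
  ref_ok <- ref_count >= min_count
  alt_ok <- alt_count >= min_count
  ifelse(ref_ok & alt_ok, "0/1",
         ifelse(ref_ok, "0/0",
                ifelse(alt_ok, "1/1", "./.")))
}

#' Genotype a count table of REF/ALT query pairs
#'
#' Pairs REF and ALT records by \code{(chrom, pos)}, applies
#' [call_genotype()], and carries the offending-k-mer flags of either query.
#'
#' @param ct count table from [run_query_search()] (must include the query
#'   metadata columns) or a plain [collate()] table plus \code{qs}.
#' @param qs the [query_set()] that was searched (REF/ALT pairs).
#' @param min_count see [call_genotype()].
#' @return data.frame with one row per site: \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, \code{ref_count}, \code{alt_count},
#'   \code{genotype}, \code{flag_nonunique_kmer}, \code{flag_overmax_kmer},
#'   sorted by (chrom, pos).
#' @export
genotype_table <- function(ct, qs, min_count = 3L) {
  stopifnot(inherits(qs, "query_set"))
  q <- as.data.frame(qs)
  counts <- as.data.frame(ct)
  i <- match(q$query_id, counts$query_id)
  q$count <- ifelse(is.na(i), 0L, counts$count[i])
  q$fn <- ifelse(is.na(i), FALSE, counts$flag_nonunique_kmer[i])
  q$fo <- ifelse(is.na(i), FALSE, counts$flag_overmax_kmer[i])
  refs <- q[q$kind == "REF", ]
  alts <- q[q$kind == "ALT", ]
  if (!nrow(refs)) stop("query set contains no REF/ALT pairs", call. = FALSE)
  key_r <- paste(refs$chrom, refs$pos)
  key_a <- paste(alts$chrom, alts$pos)
  m <- match(key_r, key_a)
  if (any(is.na(m)) || nrow(alts) != nrow(refs))
    stop("REF query without matching ALT partner", call. = FALSE)
  alts <- alts[m, ]
  out <- data.frame(
    chrom = refs$chrom, pos = refs$pos, ref = refs$ref, alt = refs$alt,
    ref_count = refs$count, alt_count = alts$count,
    genotype = call_genotype(refs$count, alts$count, min_count),
    flag_nonunique_kmer = refs$fn | alts$fn,
    flag_overmax_kmer = refs$fo | alts$fo
  )
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Write genotype calls as VCF v4.3
#'
#' One record per site with the genotype in the sample \code{GT} field,
#' per-allele read counts as \code{AD}, and offending-k-mer flags as INFO
#' tags (\code{NUK}: non-unique k-mer dropped; \code{OMK}: k-mer over the
#' occurrence ceiling).
#'
#' @param ct count table from [run_query_search()] over a REF/ALT query set.
#' @param qs the searched [query_set()].
#' @param min_count see [call_genotype()].
#' @param out_path output VCF path.
#' @param sample_name sample column name.
#' @return The genotype table (as from [genotype_table()]), invisibly.
#' @export
counts_to_vcf <- function(ct, qs, min_count = 3L, out_path,
                          sample_name = "SAMPLE") {
  has_pairs <- any(qs$kind == "REF") && nrow(as.data.frame(ct)) > 0L
  gt <- if (has_pairs) genotype_table(ct, qs, min_count) else
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), ref_count = integer(0),
               alt_count = integer(0), genotype = character(0),
               flag_nonunique_kmer = logical(0),
               flag_overmax_kmer = logical(0))
  header <- c(
    "##fileformat=VCFv4.3",
    sprintf("##source=revmap %s", as.character(packageVersion("revmap"))),
    sprintf("##revmap_min_count=%d", as.integer(min_count)),
    "##revmap_rule=allele supported iff count >= min_count; both->0/1, ref only->0/0, alt only->1/1, neither->./.",
    "##INFO=<ID=NUK,Number=0,Type=Flag,Description=\"A non-unique k-mer of this site was dropped\">",
    "##INFO=<ID=OMK,Number=0,Type=Flag,Description=\"A k-mer of this site exceeded the occurrence ceiling\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Read counts for the REF and ALT queries\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")
  )
  body <- character(0)
  if (nrow(gt)) {
    info <- ifelse(gt$flag_nonunique_kmer & gt$flag_overmax_kmer, "NUK;OMK",
                   ifelse(gt$flag_nonunique_kmer, "NUK",
                          ifelse(gt$flag_overmax_kmer, "OMK", ".")))
    body <- paste(gt$chrom, gt$pos, ".", gt$ref, gt$alt, ".", ".", info,
                  "GT:AD",
                  sprintf("%s:%d,%d", gt$genotype, gt$ref_count,
                          gt$alt_count),
                  sep = "\t")
  }
  writeLines(c(header, body), out_path)
  invisible(gt)
}
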