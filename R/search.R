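#' Search settings
#'
#' Collects the parameters of the four-step query search: k-mer generation
#' (\code{k}, \code{s}, \code{mode}), filtering
#' (\code{ignore_nonunique_kmers}), searching (\code{max_occ},
#' \code{search_rc}, \code{threads}) and collation (\code{unique_reads},
#' \code{paired_mode}).
#'
#' Two presets are provided.  \code{"genotype"} (the default) uses
#' \code{k = 31, s = 10, max_occ = 200} with non-unique k-mers ignored --
#' suited to centered searches over SNP queries.  \code{"pathogen"} uses
#' \code{k = 30, s = 5, max_occ = 2000} with both uniqueness filters on --
#' suited to sliding searches for foreign sequences, where a read must not be
#' credited to more than one target.
#'
#' @param k k-mer length.
#' @param s step between successive k-mer start positions (>= 1).  A step
#'   larger than \code{k} leaves unsearched gaps and triggers a warning.
#' @param mode \code{"centered"} (every k-mer covers the query's central
#'   position; for SNP genotyping) or \code{"sliding"} (k-mers tile the whole
#'   query; for target counting).
#' @param max_occ per-k-mer occurrence ceiling, applied to the total across
#'   all index chunks; over-occurring k-mers contribute nothing and flag
#'   their queries.
#' @param ignore_nonunique_kmers drop k-mers attributable to more than one
#'   query and flag the affected queries.
#' @param unique_reads a read (or pair) matching more than one query is
#'   removed from all of them.
#' @param paired_mode count read pairs instead of reads.
#' @param search_rc also search each k-mer's reverse complement, crediting
#'   hits to the same query; required to see reads from the opposite strand
#'   when the index holds forward reads only.
#' @param threads number of worker partitions for the search stage.  Results
#'   are identical for any value; only wall time may differ.
#' @param preset optional preset name applied before explicit arguments.
#' @return An object of class \code{search_settings}.
#' @export
search_settings <- function(k = 31L, s = 10L,
                            mode = c("centered", "sliding"),
                            max_occ = 200L, ignore_nonunique_kmers = TRUE,
                            unique_reads = FALSE, paired_mode = FALSE,
                            search_rc = TRUE, threads = 1L,
                            preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("genotype", "pathogen"))
    defaults <- switch(preset,
      genotype = list(k = 31L, s = 10L, mode = "centered", max_occ = 200L,
                      ignore_nonunique_kmers = TRUE, unique_reads = FALSE),
      pathogen = list(k = 30L, s = 5L, mode = "sliding", max_occ = 2000L,
                      ignore_nonunique_kmers = TRUE, unique_reads = TRUE))
    given <- names(match.call())[-1L]
    for (nm in setdiff(names(defaults), given))
      assign(nm, defaults[[nm]])
  }
  mode <- match.arg(toupper(mode[1L]), c("CENTERED", "SLIDING"))
  k <- as.integer(k); s <- as.integer(s)
  max_occ <- as.integer(max_occ); threads <- as.integer(threads)
  if (is.na(k) || k < 1L) stop("k must be >= 1", call. = FALSE)
  if (is.na(s) || s < 1L) stop("s must be >= 1", call. = FALSE)
  if (is.na(max_occ) || max_occ < 1L)
    stop("max_occ must be >= 1", call. = FALSE)
  if (is.na(threads) || threads < 1L)
    stop("threads must be >= 1", call. = FALSE)
  if (s > k)
    warning("step s > k leaves unsearched gaps between k-mers",
            call. = FALSE)
  structure(
    list(k = k, s = s, mode = mode, max_occ = max_occ,
         ignore_nonunique_kmers = isTRUE(ignore_nonunique_kmers),
         unique_reads = isTRUE(unique_reads),
         paired_mode = isTRUE(paired_mode),
         search_rc = isTRUE(search_rc), threads = threads),
    class = "search_settings"
  )
}

#' @export
print.search_settings <- function(x, ...) {
  cat(sprintf(
    "search_settings: k=%d s=%d mode=%s max_occ=%d%s%s%s%s threads=%d\n",
    x$k, x$s, x$mode, x$max_occ,
    if (x$ignore_nonunique_kmers) " unique-kmers" else "",
    if (x$unique_reads) " unique-reads" else "",
    if (x$paired_mode) " paired" else "",
    if (x$search_rc) " search-rc" else "", x$threads))
  invisible(x)
}

# --- k-mer generation ------------------------------------------------------

#' Centered k-mer generation
#'
#' Emits k-mers whose window covers the query's central position
#' \code{c = floor(L/2)} (0-based).  Start offsets ascend from
#' \code{max(0, c - k + 1)} in steps of \code{s} up to \code{min(c, L - k)};
#' the maximal feasible start is always emitted even when the stride would
#' miss it, so both extreme center-covering windows are present.
#'
#' @param sequence query sequence.
#' @param k k-mer length (<= sequence length).
#' @param s step size.
#' @return data.frame with columns \code{kmer} and \code{start} (0-based).
#' @export
kmers_centered <- function(sequence, k, s) {
  L <- nchar(sequence)
  if (k > L) stop("k exceeds sequence length", call. = FALSE)
  centre <- L %/% 2L
  a <- max(0L, centre - k + 1L)
  b <- min(centre, L - k)
  starts <- seq.int(a, b, by = s)
  if (starts[length(starts)] != b) starts <- c(starts, b)
  data.frame(kmer = substring(sequence, starts + 1L, starts + k),
             start = as.integer(starts))
}

#' Sliding k-mer generation
#'
#' Emits k-mers at starts \code{0, s, 2s, ...} and always anchors the final
#' window at \code{L - k}, so both ends of the sequence are searchable.
#'
#' @inheritParams kmers_centered
#' @return data.frame with columns \code{kmer} and \code{start} (0-based).
#' @export
kmers_sliding <- function(sequence, k, s) {
  L <- nchar(sequence)
  if (k > L) stop("k exceeds sequence length", call. = FALSE)
  last <- L - k
  starts <- seq.int(0L, last, by = s)
  if (starts[length(starts)] != last) starts <- c(starts, last)
  data.frame(kmer = substring(sequence, starts + 1L, starts + k),
             start = as.integer(starts))
}

# --- k-mer map -------------------------------------------------------------

#' Build the k-mer/query map
#'
#' Generates the k-mer set of every query under the settings' mode, adds
#' reverse complements when \code{search_rc} is on (mapping to the same
#' query), deduplicates within queries, and applies the non-unique filter:
#' with \code{ignore_nonunique_kmers}, any k-mer attributable to more than
#' one query is dropped and every affected query is flagged.  A k-mer equal
#' to its own reverse complement maps once.
#'
#' @param qs a [query_set()].
#' @param settings a [search_settings()].
#' @return An object of class \code{kmer_map} with fields \code{kmers}
#'   (entries actually searched), \code{owners} (query ids per entry),
#'   \code{flagged_nonunique}, \code{dropped} and \code{query_ids}.
#' @export
build_kmer_map <- function(qs, settings) {
  stopifnot(inherits(qs, "query_set"), inherits(settings, "search_settings"))
  gen <- if (settings$mode == "CENTERED") kmers_centered else kmers_sliding
  short <- nchar(qs$sequence) < settings$k
  if (any(short)) {
    lab <- qs$name[which(short)[1L]] %||% qs$query_id[which(short)[1L]]
    if (is.na(lab)) lab <- qs$query_id[which(short)[1L]]
    stop("query shorter than k: ", lab, call. = FALSE)
  }
  per_query <- lapply(seq_len(nrow(qs)), function(i) {
    km <- unique(gen(qs$sequence[i], settings$k, settings$s)$kmer)
    if (settings$search_rc) km <- unique(c(km, revcomp(km)))
    km
  })
  kmer <- unlist(per_query, use.names = FALSE)
  qid <- rep(qs$query_id, lengths(per_query))
  owners <- lapply(split(qid, kmer), function(x) sort(unique(x)))
  kmers <- names(owners)
  names(owners) <- NULL
  multi <- lengths(owners) > 1L
  flagged <- sort(unique(unlist(owners[multi])))
  dropped <- character(0)
  if (settings$ignore_nonunique_kmers && any(multi)) {
    dropped <- kmers[multi]
    kmers <- kmers[!multi]
    owners <- owners[!multi]
  }
  structure(
    list(kmers = kmers, owners = owners,
         flagged_nonunique = as.integer(flagged), dropped = dropped,
         query_ids = qs$query_id),
    class = "kmer_map"
  )
}

# --- search ----------------------------------------------------------------

#' Search the k-mer map against every index chunk
#'
#' Looks every retained k-mer up in every chunk with \code{locate}, capping
#' position enumeration at \code{max_occ} occurrences per chunk (over the
#' cap only the count is kept; the global ceiling is applied at collation).
#' Work is partitioned round-robin across \code{threads} worker batches and
#' reassembled in k-mer order, so results are bit-identical for any thread
#' count.
#'
#' @param iset an [index_set()].
#' @param km a [build_kmer_map()] result.
#' @param settings a [search_settings()].
#' @return Raw hit structure: one element per chunk, each with per-k-mer
#'   \code{count} and \code{positions} (NULL above the ceiling).
#' @export
search_kmers <- function(iset, km, settings) {
  stopifnot(inherits(iset, "index_set"), inherits(km, "kmer_map"))
  patterns <- km$kmers
  nk <- length(patterns)
  lapply(iset$bundles, function(bundle) {
    if (nk == 0L)
      return(list(count = integer(0), positions = list()))
    batch_of <- (seq_len(nk) - 1L) %% settings$threads
    count <- integer(nk)
    positions <- vector("list", nk)
    for (b in unique(batch_of)) {
      sel <- which(batch_of == b)
      res <- fm_search_batch(bundle, patterns[sel], settings$max_occ)
      count[sel] <- res$count
      positions[sel] <- res$positions
    }
    list(count = count, positions = positions)
  })
}

# --- collation -------------------------------------------------------------

#' Collate raw hits into per-query read (or pair) counts
#'
#' Translates text positions to global read ordinals through each chunk's
#' manifest (reverse-complement copies credit the primary read), unions the
#' matching read set per query across k-mers and chunks, and applies the
#' global filters: a k-mer whose summed occurrences across chunks exceed
#' \code{max_occ} contributes nothing and flags its queries; with
#' \code{unique_reads}, any read (or pair) matching more than one query is
#' removed from all of them.  The count is the cardinality of the surviving
#' set, so multiple k-mer hits in one read count once.
#'
#' @param raw_hits result of [search_kmers()].
#' @param iset the searched [index_set()].
#' @param km the [build_kmer_map()] the hits came from.
#' @param settings a [search_settings()].
#' @return An object of class \code{count_table}: a data.frame with columns
#'   \code{query_id}, \code{count}, \code{flag_nonunique_kmer},
#'   \code{flag_overmax_kmer}; attribute \code{unit} is \code{"READS"} or
#'   \code{"PAIRS"}.
#' @export
collate <- function(raw_hits, iset, km, settings) {
  nk <- length(km$kmers)
  counts_mat <- vapply(raw_hits, function(h) h$count, integer(nk))
  global <- if (nk == 0L) integer(0) else
    if (length(raw_hits) == 1L) as.integer(counts_mat) else
      as.integer(rowSums(counts_mat))
  overmax <- global > settings$max_occ
  flag_over <- sort(unique(unlist(km$owners[overmax])))
  keep <- which(!overmax & global > 0L)

  qid_all <- integer(0)
  unit_all <- integer(0)
  for (ci in seq_along(raw_hits)) {
    h <- raw_hits[[ci]]
    layout <- manifest_layout(iset$manifests[[ci]])
    pos_list <- h$positions[keep]
    n_per <- lengths(pos_list)
    if (!sum(n_per)) next
    pos <- unlist(pos_list, use.names = FALSE)
    kmer_i <- rep(keep, n_per)
    copy <- findInterval(pos, layout$offsets)
    if (any(pos - layout$offsets[copy] >= layout$copy_len[copy]))
      stop("internal error: match position falls on a sentinel",
           call. = FALSE)
    ord <- layout$copy_ordinal[copy]
    unit <- if (settings$paired_mode) ord %/% 2L else ord
    n_owners <- lengths(km$owners)[kmer_i]
    qid_all <- c(qid_all, unlist(km$owners[kmer_i], use.names = FALSE))
    unit_all <- c(unit_all, rep(unit, n_owners))
  }

  # Deduplicate (query, unit) pairs.
  if (length(qid_all)) {
    key <- as.numeric(qid_all) * 2^32 + as.numeric(unit_all)
    first <- !duplicated(key)
    qid_all <- qid_all[first]
    unit_all <- unit_all[first]
    if (settings$unique_reads) {
      contested <- unique(unit_all[duplicated(unit_all)])
      if (length(contested)) {
        drop <- unit_all %in% contested
        qid_all <- qid_all[!drop]
        unit_all <- unit_all[!drop]
      }
    }
  }

  counts <- setNames(integer(length(km$query_ids)),
                     as.character(km$query_ids))
  if (length(qid_all)) {
    tab <- table(qid_all)
    counts[names(tab)] <- as.integer(tab)
  }
  out <- data.frame(
    query_id = km$query_ids,
    count = unname(counts[as.character(km$query_ids)]),
    flag_nonunique_kmer = km$query_ids %in% km$flagged_nonunique,
    flag_overmax_kmer = km$query_ids %in% flag_over
  )
  structure(out, unit = if (settings$paired_mode) "PAIRS" else "READS",
            class = c("count_table", "data.frame"))
}

#' Run the full query search
#'
#' Orchestrates the four steps -- k-mer generation, filtering, searching and
#' collation -- over a query set and an index set.
#'
#' @param iset an [index_set()].
#' @param qs a [query_set()].
#' @param settings a [search_settings()].
#' @return A \code{count_table} (see [collate()]) with the query columns
#'   (\code{kind}, \code{chrom}, \code{pos}, \code{ref}, \code{alt},
#'   \code{name}) joined on.
#' @export
run_query_search <- function(iset, qs, settings = search_settings()) {
  km <- build_kmer_map(qs, settings)
  hits <- search_kmers(iset, km, settings)
  ct <- collate(hits, iset, km, settings)
  meta <- as.data.frame(qs)[, c("query_id", "kind", "chrom", "pos", "ref",
                                "alt", "name")]
  out <- merge(meta, as.data.frame(ct), by = "query_id", sort = TRUE)
  structure(out, unit = attr(ct, "unit"),
            class = c("count_table", "data.frame"))
}

#' Write a count table mirroring the query file format
#'
#' Reproduces the query file columns with the count and flag columns
#' appended.
#'
#' @param ct a count table from [run_query_search()] or [collate()].
#' @param qs the [query_set()] that was searched.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_counts <- function(ct, qs, path) {
  out <- merge(as.data.frame(qs),
               as.data.frame(ct)[, c("query_id", "count",
                                     "flag_nonunique_kmer",
                                     "flag_overmax_kmer")],
               by = "query_id", sort = TRUE)
  for (col in names(out))
    out[[col]] <- ifelse(is.na(out[[col]]), ".", as.character(out[[col]]))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Direct k-mer search with per-group tallies
#'
#' Searches a plain k-mer list (each k-mer its own single-k-mer query,
#' read-deduplicated) and, for grouped k-mers, tallies how many of each
#' group's k-mers exceed a count threshold -- the presence/absence readout
#' used with curated gene-distinguishing k-mer panels.
#'
#' @param iset an [index_set()].
#' @param kmers data.frame with columns \code{kmer} and optional
#'   \code{group} (as from [read_kmer_list()]), or a character vector.
#' @param settings a [search_settings()]; \code{k}/\code{s}/\code{mode} are
#'   irrelevant here (each k-mer is searched whole).
#' @param threshold group tally counts k-mers with count strictly greater
#'   than this.
#' @return List with \code{counts} (per-k-mer table: kmer, group, count,
#'   flags) and \code{group_tally} (group, n_kmers, n_over_threshold).
#' @export
ksearch <- function(iset, kmers, settings = search_settings(),
                    threshold = 3L) {
  if (is.character(kmers)) kmers <- data.frame(kmer = kmers,
                                               group = NA_character_)
  stopifnot(all(c("kmer", "group") %in% names(kmers)))
  kmers <- kmers[!duplicated(kmers$kmer), , drop = FALSE]
  qs <- query_set(new_query_row(seq_len(nrow(kmers)) - 1L, "SEQ",
                                kmers$kmer, name = kmers$kmer))
  km_settings <- settings
  km_settings$k <- min(nchar(kmers$kmer))
  km_settings$mode <- "SLIDING"
  km_settings$s <- max(nchar(kmers$kmer))  # one window: the k-mer itself
  km <- build_kmer_map_whole(qs, km_settings)
  hits <- search_kmers(iset, km, km_settings)
  ct <- collate(hits, iset, km, km_settings)
  counts <- data.frame(kmer = kmers$kmer, group = kmers$group,
                       count = ct$count[match(seq_len(nrow(kmers)) - 1L,
                                              ct$query_id)],
                       flag_nonunique_kmer = ct$flag_nonunique_kmer,
                       flag_overmax_kmer = ct$flag_overmax_kmer)
  grouped <- counts[!is.na(counts$group), , drop = FALSE]
  groups <- unique(grouped$group)
  group_tally <- data.frame(
    group = groups,
    n_kmers = vapply(groups, function(g) sum(grouped$group == g), 0L),
    n_over_threshold = vapply(groups, function(g)
      sum(grouped$count[grouped$group == g] > threshold), 0L)
  )
  list(counts = counts, group_tally = group_tally, threshold = threshold)
}

# K-mer map where each query's single k-mer is its whole sequence (ksearch).
build_kmer_map_whole <- function(qs, settings) {
  per_query <- lapply(seq_len(nrow(qs)), function(i) {
    km <- qs$sequence[i]
    if (settings$search_rc) km <- unique(c(km, revcomp(km)))
    km
  })
  kmer <- unlist(per_query, use.names = FALSE)
  qid <- rep(qs$query_id, lengths(per_query))
  owners <- lapply(split(qid, kmer), function(x) sort(unique(x)))
  kmers <- names(owners)
  names(owners) <- NULL
  multi <- lengths(owners) > 1L
  flagged <- sort(unique(unlist(owners[multi])))
  dropped <- character(0)
  if (settings$ignore_nonunique_kmers && any(multi)) {
    dropped <- kmers[multi]
    kmers <- kmers[!multi]
    owners <- owners[!multi]
  }
  structure(
    list(kmers = kmers, owners = owners,
         flagged_nonunique = as.integer(flagged), dropped = dropped,
         query_ids = qs$query_id),
    class = "kmer_map"
  )
}
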