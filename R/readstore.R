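#' Read stores: sentinel-concatenated read sets
#'
#' A read store holds a set of short reads as a single text over
#' \code{\{A,C,G,T,N\}} in which consecutive reads are separated by a sentinel
#' symbol (\code{$}) that sorts before every base.  The sentinel guarantees
#' that no sentinel-free pattern can match across a read boundary, so
#' occurrence counts over the concatenated text equal per-read occurrence
#' counts summed over reads.  The store also keeps the bookkeeping needed to
#' translate text positions back to read ordinals: per-copy start offsets,
#' lengths, and (when reverse-complement copies are included) the mapping from
#' an RC copy back to its primary forward read.
#'
#' Reads are numbered by a dense 0-based global ordinal.  Paired-end mates are
#' interleaved: mate 1 of pair \eqn{i} has ordinal \eqn{2i} and mate 2 has
#' ordinal \eqn{2i+1}, so the pair id of any ordinal is
#' \code{ordinal \%/\% 2}.  When the store is one chunk of a larger read set,
#' \code{global_ordinal_offset} records where its ordinals start.
#'
#' @param sequences character vector of read sequences (A/C/G/T/N, uppercase).
#' @param paired logical; are the reads interleaved mate pairs?
#' @param include_rc logical; append each read's reverse complement directly
#'   after it.  RC copies share the forward read's ordinal, so hits on an RC
#'   copy are credited to the primary read.
#' @param chunk_id integer chunk identifier (0-based).
#' @param global_ordinal_offset global ordinal of this chunk's first read.
#' @param source character label(s) for provenance (file names).
#' @return An object of class \code{read_store}.
#' @seealso [load_reads()], [split_chunks()], [position_to_read()]
#' @export
read_store <- function(sequences, paired = FALSE, include_rc = FALSE,
                       chunk_id = 0L, global_ordinal_offset = 0L,
                       source = "memory") {
  if (!length(sequences)) stop("empty read set", call. = FALSE)
  sequences <- normalize_seq(as.character(sequences))
  assert_dna(sequences, names(sequences))
  if (paired && length(sequences) %% 2L != 0L)
    stop("paired store requires an even number of reads", call. = FALSE)

  n <- length(sequences)
  ords <- global_ordinal_offset + seq_len(n) - 1L
  if (include_rc) {
    copies <- character(2L * n)
    copies[c(TRUE, FALSE)] <- sequences
    copies[c(FALSE, TRUE)] <- revcomp(sequences)
    copy_ordinal <- rep(ords, each = 2L)
    copy_is_rc <- rep(c(FALSE, TRUE), n)
  } else {
    copies <- sequences
    copy_ordinal <- ords
    copy_is_rc <- rep(FALSE, n)
  }
  copy_len <- nchar(copies)
  offsets <- c(0L, cumsum(copy_len + 1L))[seq_along(copies)]

  structure(
    list(
      text = paste0(paste(copies, collapse = .SENTINEL), .SENTINEL),
      offsets = as.integer(offsets),
      copy_len = as.integer(copy_len),
      copy_ordinal = as.integer(copy_ordinal),
      copy_is_rc = copy_is_rc,
      n_reads = n,
      read_lengths = nchar(sequences),
      paired = paired,
      rc_included = include_rc,
      chunk_id = as.integer(chunk_id),
      global_ordinal_offset = as.integer(global_ordinal_offset),
      source = source
    ),
    class = "read_store"
  )
}

#' @export
print.read_store <- function(x, ...) {
  cat(sprintf(
    "read_store: %d reads (%s%s), text length %d, chunk %d (ordinal offset %d)\n",
    x$n_reads, if (x$paired) "paired" else "single-end",
    if (x$rc_included) ", RC copies included" else "",
    nchar(x$text), x$chunk_id, x$global_ordinal_offset))
  invisible(x)
}

# Sniff FASTA vs FASTQ from the first non-empty line (handles gzip).
sniff_format <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) stop("empty input file: ", path, call. = FALSE)
    if (nzchar(trimws(line))) break
  }
  c1 <- substr(trimws(line), 1L, 1L)
  if (c1 == ">") "fasta" else if (c1 == "@") "fastq" else
    stop("cannot determine format (FASTA/FASTQ) of ", path, call. = FALSE)
}

read_seq_file <- function(path) {
  fmt <- sniff_format(path)
  set <- Biostrings::readBStringSet(path, format = fmt)
  if (!length(set)) stop("empty input file: ", path, call. = FALSE)
  seqs <- normalize_seq(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  assert_dna(seqs, names(seqs))
  seqs
}

#' Load reads from FASTQ/FASTA files into a read store
#'
#' Reads one or two sequence files (FASTA or FASTQ, optionally gzipped),
#' discards qualities and headers, uppercases the sequences (mapping U to T),
#' and concatenates them into a sentinel-separated store.  Paired input is
#' given either as two files with matching record counts or as a single
#' interleaved file.
#'
#' @param paths one or two file paths.
#' @param paired logical; treat input as paired-end.
#' @param include_rc logical; also index each read's reverse complement (see
#'   [read_store()]).  Off by default: the search stage instead queries each
#'   k-mer in both orientations, which costs less at indexing time.
#' @param interleaved logical; with \code{paired = TRUE} and one file, mates
#'   are taken as alternating records.
#' @return A [read_store()].
#' @export
load_reads <- function(paths, paired = FALSE, include_rc = FALSE,
                       interleaved = FALSE) {
  if (!length(paths)) stop("no input files given", call. = FALSE)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("input file not found: ", paste(missing, collapse = ", "),
         call. = FALSE)

  if (paired) {
    if (length(paths) == 2L) {
      r1 <- read_seq_file(paths[1L])
      r2 <- read_seq_file(paths[2L])
      if (length(r1) != length(r2))
        stop(sprintf("paired files differ in record count (%d vs %d)",
                     length(r1), length(r2)), call. = FALSE)
      seqs <- character(2L * length(r1))
      seqs[c(TRUE, FALSE)] <- r1
      seqs[c(FALSE, TRUE)] <- r2
    } else if (length(paths) == 1L && interleaved) {
      seqs <- read_seq_file(paths[1L])
      if (length(seqs) %% 2L != 0L)
        stop("interleaved paired file has an odd record count", call. = FALSE)
    } else {
      stop("paired input requires two files, or one file with interleaved = TRUE",
           call. = FALSE)
    }
  } else {
    if (length(paths) != 1L)
      stop("single-end input takes exactly one file", call. = FALSE)
    seqs <- read_seq_file(paths[1L])
  }
  read_store(seqs, paired = paired, include_rc = include_rc,
             source = basename(paths))
}

#' Extract the primary read sequences of a store
#'
#' @param store a [read_store()].
#' @return Character vector of the store's forward reads, in ordinal order.
#' @export
store_sequences <- function(store) {
  keep <- !store$copy_is_rc
  substring(store$text, store$offsets[keep] + 1L,
            store$offsets[keep] + store$copy_len[keep])
}

#' Split a read store into contiguous chunks
#'
#' Partitions the reads by ordinal into \code{n_chunks} contiguous chunks of
#' near-equal size, never splitting a read pair across chunks.  Each chunk
#' records the global ordinal of its first read so global read ids are
#' recoverable after independent indexing.
#'
#' @param store a [read_store()].
#' @param n_chunks number of chunks (between 1 and the number of reads or
#'   pairs).
#' @return List of [read_store()] objects with dense \code{chunk_id}s.
#' @export
split_chunks <- function(store, n_chunks) {
  unit <- if (store$paired) 2L else 1L
  n_units <- store$n_reads %/% unit
  if (n_chunks < 1L || n_chunks > n_units)
    stop(sprintf("n_chunks must be in [1, %d]", n_units), call. = FALSE)
  seqs <- store_sequences(store)
  bounds <- round(seq(0, n_units, length.out = n_chunks + 1L))
  lapply(seq_len(n_chunks), function(i) {
    lo <- bounds[i] * unit + 1L
    hi <- bounds[i + 1L] * unit
    read_store(seqs[lo:hi], paired = store$paired,
               include_rc = store$rc_included, chunk_id = i - 1L,
               global_ordinal_offset = store$global_ordinal_offset + lo - 1L,
               source = store$source)
  })
}

#' Translate a text position back to a read
#'
#' Binary-searches the store's offsets to find the read copy containing a
#' text position.  Positions inside a reverse-complement copy report the
#' primary forward read's ordinal with \code{is_rc = TRUE}.  A sentinel
#' position is an error: matches can never touch a sentinel, so hitting one
#' signals an internal search defect.
#'
#' @param store a [read_store()].
#' @param text_position 0-based position(s) in the store text.
#' @return A data.frame with columns \code{ordinal} (global), \code{offset}
#'   (0-based within the read copy) and \code{is_rc}.
#' @export
position_to_read <- function(store, text_position) {
  text_position <- as.integer(text_position)
  if (any(text_position < 0L | text_position >= nchar(store$text)))
    stop("text position out of range", call. = FALSE)
  idx <- findInterval(text_position, store$offsets)
  off <- text_position - store$offsets[idx]
  if (any(off >= store$copy_len[idx]))
    stop("text position falls on a sentinel", call. = FALSE)
  data.frame(ordinal = store$copy_ordinal[idx], offset = off,
             is_rc = store$copy_is_rc[idx])
}

#' Pair id of a read ordinal
#'
#' Under the interleaved mate convention, the pair id is
#' \code{ordinal \%/\% 2}.  For single-end stores the ordinal is returned
#' unchanged, so downstream pair-level logic degenerates to read-level logic.
#'
#' @param store a [read_store()].
#' @param ordinal global read ordinal(s).
#' @return Integer pair id(s).
#' @export
read_to_pair <- function(store, ordinal) {
  if (store$paired) as.integer(ordinal) %/% 2L else as.integer(ordinal)
}

# --- manifests -------------------------------------------------------------

# The manifest is the part of a store that must travel with a serialized
# index: enough to rebuild the position -> ordinal translation without the
# text itself.
store_manifest <- function(store) {
  list(
    format = "revmap-manifest",
    version = 1L,
    chunk_id = store$chunk_id,
    global_ordinal_offset = store$global_ordinal_offset,
    n_reads = store$n_reads,
    paired = store$paired,
    rc_included = store$rc_included,
    read_lengths = store$read_lengths,
    source = store$source
  )
}

# Reconstruct the copy layout (offsets, ordinals, rc flags) from a manifest.
manifest_layout <- function(m) {
  ords <- m$global_ordinal_offset + seq_len(m$n_reads) - 1L
  if (isTRUE(m$rc_included)) {
    copy_len <- rep(m$read_lengths, each = 2L)
    copy_ordinal <- rep(ords, each = 2L)
    copy_is_rc <- rep(c(FALSE, TRUE), m$n_reads)
  } else {
    copy_len <- m$read_lengths
    copy_ordinal <- ords
    copy_is_rc <- rep(FALSE, m$n_reads)
  }
  offsets <- c(0L, cumsum(copy_len + 1L))[seq_along(copy_len)]
  list(offsets = as.integer(offsets), copy_len = as.integer(copy_len),
       copy_ordinal = as.integer(copy_ordinal), copy_is_rc = copy_is_rc)
}

write_manifest <- function(m, path) {
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(m$format, "revmap-manifest"))
    stop("not a revmap manifest: ", path, call. = FALSE)
  m$read_lengths <- as.integer(m$read_lengths)
  m$chunk_id <- as.integer(m$chunk_id)
  m$global_ordinal_offset <- as.integer(m$global_ordinal_offset)
  m$n_reads <- as.integer(m$n_reads)
  m
}
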