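#' FM-index construction and exact search
#'
#' The index over a read store's text is the classic FM-index: the suffix
#' array of the sentinel-terminated text is built by induced sorting (SA-IS,
#' linear time), the Burrows-Wheeler transform is taken from it, symbol
#' ranks are answered from checkpointed occurrence counts at a fixed stride,
#' and a subsample of suffix-array values supports \code{locate} via
#' LF-stepping.  Sampling is by text position (every position divisible by
#' \code{sample_rate} is retained), which bounds every locate walk by
#' \code{sample_rate - 1} LF steps and never requires stepping past a read's
#' first base.
#'
#' @name fmindex
NULL

#' Build the suffix array of a sentinel-terminated text
#'
#' Suffixes are ordered lexicographically under \code{$ < A < C < G < N < T};
#' ties between suffixes that begin with runs of equal sentinels are resolved
#' by the content that follows (equivalently, by a virtual end-of-text symbol
#' smaller than the sentinel), which is deterministic and position-stable.
#'
#' @param text a string over \code{\{$,A,C,G,N,T\}} ending with \code{$}.
#' @return Integer vector of 0-based suffix start positions.
#' @export
build_suffix_array <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, nchar(text) > 0L)
  .sa_build_cpp(text)
}

#' Build an FM-index over a read store
#'
#' @param store a [read_store()].
#' @param sample_rate suffix-array sampling rate; every text position
#'   divisible by \code{sample_rate} is retained.  1 samples everything
#'   (fast locate, large index); the default 16 balances memory against
#'   locate cost.
#' @return An object of class \code{fm_index} bundling the BWT, rank
#'   checkpoints, symbol count table, sampled suffix array and the store
#'   manifest of the indexed chunk.
#' @export
build_fm_index <- function(store, sample_rate = 16L) {
  stopifnot(inherits(store, "read_store"))
  sample_rate <- as.integer(sample_rate)
  if (is.na(sample_rate) || sample_rate < 1L)
    stop("sample_rate must be a positive integer", call. = FALSE)
  core <- .fm_build_cpp(store$text, sample_rate)
  structure(
    c(core, list(chunk_id = store$chunk_id,
                 manifest = store_manifest(store))),
    class = "fm_index"
  )
}

#' @export
print.fm_index <- function(x, ...) {
  cat(sprintf(
    "fm_index: text length %d, %d reads, sample rate %d, chunk %d\n",
    x$n, x$manifest$n_reads, x$sample_rate, x$chunk_id))
  invisible(x)
}

#' Backward search: suffix-array interval of a pattern
#'
#' Narrows the suffix-array interval one symbol at a time, right to left.
#' The interval size equals the number of exact occurrences of the pattern in
#' the indexed text.  Patterns containing symbols outside the index alphabet
#' (or the sentinel) yield the empty interval.
#'
#' @param index an [build_fm_index()] object.
#' @param pattern one or more patterns (character vector).
#' @return An integer matrix with columns \code{lo}, \code{hi}: the half-open
#'   interval \code{[lo, hi)} per pattern (0-based rows of the suffix array).
#' @export
backward_search <- function(index, pattern) {
  stopifnot(inherits(index, "fm_index"))
  pattern <- as.character(pattern)
  if (!length(pattern) || any(!nzchar(pattern)))
    stop("patterns must be non-empty strings", call. = FALSE)
  out <- .fm_interval_cpp(index, pattern)
  dimnames(out) <- list(NULL, c("lo", "hi"))
  out
}

#' Overflow marker returned by [locate()]
#'
#' When a pattern occurs more often than \code{max_hits}, [locate()] does not
#' enumerate positions; it returns this marker carrying the total count, which
#' the collation stage uses to apply the global occurrence ceiling.
#'
#' @param total total occurrence count of the over-occurring pattern.
#' @return An object of class \code{fm_overflow}.
#' @export
fm_overflow <- function(total) {
  structure(list(total = as.integer(total)), class = "fm_overflow")
}

#' @rdname fm_overflow
#' @param x object to test.
#' @export
is_overflow <- function(x) inherits(x, "fm_overflow")

#' Locate all occurrences of a pattern
#'
#' @param index an [build_fm_index()] object.
#' @param pattern a single pattern (no sentinel).
#' @param max_hits occurrence ceiling: if the pattern occurs more than
#'   \code{max_hits} times, an [fm_overflow()] marker with the total count is
#'   returned instead of positions.
#' @return Sorted integer vector of 0-based text positions, or an
#'   [fm_overflow()] marker.
#' @export
locate <- function(index, pattern, max_hits = .Machine$integer.max) {
  stopifnot(inherits(index, "fm_index"), length(pattern) == 1L)
  if (grepl("$", pattern, fixed = TRUE))
    stop("pattern must not contain the sentinel", call. = FALSE)
  if (max_hits < 1L) stop("max_hits must be >= 1", call. = FALSE)
  res <- .fm_search_cpp(index, pattern, as.integer(max_hits), TRUE)
  cnt <- res$count[1L]
  if (cnt > max_hits) return(fm_overflow(cnt))
  res$positions[[1L]] %||% integer(0)
}

# Batched count+locate over many patterns (internal fast path for search).
fm_search_batch <- function(index, patterns, max_hits, locate = TRUE) {
  .fm_search_cpp(index, patterns, as.integer(max_hits), locate)
}

# Invert the BWT back to the original text (consistency checks).
invert_bwt <- function(index) .fm_invert_cpp(index)

# --- serialization ---------------------------------------------------------

.FMI_MAGIC <- charToRaw("RMFM")
.FMI_VERSION <- 1L

#' Save / load an FM-index
#'
#' The on-disk format is a little-endian binary layout: a 4-byte magic, a
#' format version, scalar metadata, the section lengths, then the BWT payload,
#' count table, rank checkpoints, sampled suffix array and sentinel LF table.
#' The chunk's store manifest is written alongside as
#' \code{<path>.manifest.json}.  Saving is deterministic: the same bundle
#' always produces byte-identical files.
#'
#' @param index an [build_fm_index()] object.
#' @param path file path for the binary index.
#' @return \code{save_index} returns \code{path} invisibly; \code{load_index}
#'   returns the restored \code{fm_index}.
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "fm_index"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(.FMI_MAGIC, con)
  ints <- c(.FMI_VERSION, index$chunk_id, index$sample_rate, index$n,
            length(index$cbefore), length(index$occ_cp), length(index$slots),
            length(index$sent_rows))
  writeBin(as.integer(ints), con, size = 4L, endian = "little")
  writeBin(index$bwt, con)
  for (part in c("cbefore", "occ_cp", "slots", "samples", "sent_rows",
                 "sent_targets"))
    writeBin(as.integer(index[[part]]), con, size = 4L, endian = "little")
  write_manifest(index$manifest, paste0(path, ".manifest.json"))
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  if (!file.exists(path)) stop("index file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 4L)
  if (!identical(magic, .FMI_MAGIC))
    stop("not a revmap index file: ", path, call. = FALSE)
  hdr <- readBin(con, "integer", n = 8L, size = 4L, endian = "little")
  if (length(hdr) < 8L) stop("truncated index file: ", path, call. = FALSE)
  if (hdr[1L] != .FMI_VERSION)
    stop(sprintf("index format version %d not supported (expected %d)",
                 hdr[1L], .FMI_VERSION), call. = FALSE)
  n <- hdr[4L]
  rd_int <- function(len) {
    v <- readBin(con, "integer", n = len, size = 4L, endian = "little")
    if (length(v) != len) stop("truncated index file: ", path, call. = FALSE)
    v
  }
  bwt <- readBin(con, "raw", n = n)
  if (length(bwt) != n) stop("truncated index file: ", path, call. = FALSE)
  cbefore <- rd_int(hdr[5L])
  occ_cp <- rd_int(hdr[6L])
  slots <- rd_int(hdr[7L])
  samples <- rd_int(hdr[7L])
  sent_rows <- rd_int(hdr[8L])
  sent_targets <- rd_int(hdr[8L])
  if (length(readBin(con, "raw", n = 1L)) != 0L)
    stop("trailing bytes in index file: ", path, call. = FALSE)
  mpath <- paste0(path, ".manifest.json")
  if (!file.exists(mpath))
    stop("missing index manifest: ", mpath, call. = FALSE)
  structure(
    list(bwt = bwt, cbefore = cbefore, occ_cp = occ_cp, slots = slots,
         samples = samples, sent_rows = sent_rows,
         sent_targets = sent_targets, n = n, sample_rate = hdr[3L],
         chunk_id = hdr[2L], manifest = read_manifest(mpath)),
    class = "fm_index"
  )
}

# --- index sets ------------------------------------------------------------

#' Index a read store as one or more chunks
#'
#' Splits the store into \code{n_chunks} contiguous chunks (pairs never
#' split), builds one FM-index per chunk, and returns the set.  Search
#' results from all chunks are merged and reconciled at collation, so the
#' chunked result is identical to a monolithic index.
#'
#' @param store a [read_store()].
#' @param n_chunks number of independent sub-indexes.
#' @param sample_rate see [build_fm_index()].
#' @return An object of class \code{index_set}.
#' @export
index_reads <- function(store, n_chunks = 1L, sample_rate = 16L) {
  chunks <- if (n_chunks == 1L) list(store) else split_chunks(store, n_chunks)
  bundles <- lapply(chunks, build_fm_index, sample_rate = sample_rate)
  index_set(bundles)
}

#' Bundle FM-indexes into an index set
#'
#' @param bundles list of \code{fm_index} objects with dense chunk ids and
#'   disjoint, contiguous global ordinal ranges.
#' @return An object of class \code{index_set}.
#' @export
index_set <- function(bundles) {
  stopifnot(length(bundles) > 0L,
            all(vapply(bundles, inherits, TRUE, "fm_index")))
  ids <- vapply(bundles, function(b) b$chunk_id, 0L)
  bundles <- bundles[order(ids)]
  ids <- sort(ids)
  if (!identical(ids, seq_along(ids) - 1L))
    stop("chunk ids must be dense from 0", call. = FALSE)
  structure(
    list(bundles = bundles,
         manifests = lapply(bundles, function(b) b$manifest)),
    class = "index_set"
  )
}

#' @export
print.index_set <- function(x, ...) {
  n <- sum(vapply(x$manifests, function(m) m$n_reads, 0L))
  cat(sprintf("index_set: %d chunk(s), %d reads total\n",
              length(x$bundles), n))
  invisible(x)
}

#' Save / load an index set under a path prefix
#'
#' Chunk \code{i} is written to \code{<prefix>.chunk<i>.fmi} (with its
#' manifest JSON alongside) and \code{<prefix>.json} records the chunk count.
#'
#' @param iset an [index_set()].
#' @param prefix path prefix.
#' @return \code{save_index_set} returns \code{prefix} invisibly;
#'   \code{load_index_set} returns the restored set.
#' @export
save_index_set <- function(iset, prefix) {
  stopifnot(inherits(iset, "index_set"))
  for (b in iset$bundles)
    save_index(b, sprintf("%s.chunk%d.fmi", prefix, b$chunk_id))
  jsonlite::write_json(
    list(format = "revmap-index-set", version = 1L,
         n_chunks = length(iset$bundles)),
    paste0(prefix, ".json"), auto_unbox = TRUE)
  invisible(prefix)
}

#' @rdname save_index_set
#' @export
load_index_set <- function(prefix) {
  meta_path <- paste0(prefix, ".json")
  if (!file.exists(meta_path))
    stop("index set metadata not found: ", meta_path, call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(meta$format, "revmap-index-set"))
    stop("not a revmap index set: ", meta_path, call. = FALSE)
  bundles <- lapply(seq_len(meta$n_chunks) - 1L, function(i)
    load_index(sprintf("%s.chunk%d.fmi", prefix, i)))
  index_set(bundles)
}
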