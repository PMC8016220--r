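# Shared internal helpers.

# Reverse-complement a character vector of DNA strings (A/C/G/T/N).
revcomp <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Uppercase and map U -> T (RNA input).
normalize_seq <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

# Validate sequences over the read alphabet; `what` names records in errors.
assert_dna <- function(x, what = names(x)) {
  bad <- !grepl("^[ACGTN]+$", x)
  if (any(bad)) {
    i <- which(bad)[1L]
    lab <- if (!is.null(what) && !is.na(what[i])) what[i] else paste0("record ", i)
    stop("sequence contains symbols outside {A,C,G,T,N}: ", lab, call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
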