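#' Merge search configuration from defaults, a settings file and overrides
#'
#' Precedence is defaults < settings file < explicit overrides.  The
#' settings file is an INI dialect with a \code{[search]} section whose keys
#' match the [search_settings()] field names, e.g.
#' \preformatted{
#' [search]
#' k = 31
#' s = 10
#' max_occ = 200
#' unique_reads = false
#' }
#' Unknown keys and unparsable values are rejected before any computation,
#' and the merged settings are re-validated through [search_settings()].
#'
#' @param settings_path optional INI file path.
#' @param overrides named list of [search_settings()] arguments taking
#'   precedence over the file.
#' @return A validated [search_settings()] object.
#' @export
parse_config <- function(settings_path = NULL, overrides = list()) {
  fields <- list(
    k = "int", s = "int", mode = "chr", max_occ = "int",
    ignore_nonunique_kmers = "lgl", unique_reads = "lgl",
    paired_mode = "lgl", search_rc = "lgl", threads = "int"
  )
  merged <- list()
  if (!is.null(settings_path)) {
    ini <- read_ini(settings_path)
    sec <- ini[["search"]] %||% list()
    extra <- c(setdiff(names(ini), "search"), setdiff(names(sec), names(fields)))
    if (length(extra))
      stop("unknown key in settings file: ", paste(extra, collapse = ", "),
           call. = FALSE)
    merged <- lapply(names(sec), function(key) {
      parse_ini_value(sec[[key]], fields[[key]], key)
    })
    names(merged) <- names(sec)
  }
  bad <- setdiff(names(overrides), names(fields))
  if (length(bad))
    stop("unknown setting: ", paste(bad, collapse = ", "), call. = FALSE)
  merged[names(overrides)] <- overrides
  do.call(search_settings, merged)
}

parse_ini_value <- function(value, type, key) {
  switch(type,
    int = {
      v <- suppressWarnings(as.integer(value))
      if (is.na(v)) stop(sprintf("setting '%s' must be an integer (got '%s')",
                                 key, value), call. = FALSE)
      v
    },
    lgl = {
      v <- tolower(value)
      if (!v %in% c("true", "false", "1", "0", "yes", "no"))
        stop(sprintf("setting '%s' must be a boolean (got '%s')", key, value),
             call. = FALSE)
      v %in% c("true", "1", "yes")
    },
    chr = value
  )
}

# Minimal INI reader: [section] headers, key = value lines, ';'/'#' comments.
read_ini <- function(path) {
  if (!file.exists(path))
    stop("settings file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !grepl("^[;#]", lines)]
  out <- list()
  section <- NA_character_
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- sub("^\\[(.+)\\]$", "\\1", ln)
      out[[section]] <- out[[section]] %||% list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.na(section))
        stop("settings line outside any [section]: ", ln, call. = FALSE)
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      out[[section]][[key]] <- val
    } else {
      stop("unparsable settings line: ", ln, call. = FALSE)
    }
  }
  out
}
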