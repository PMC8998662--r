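# Plain-text run configuration: INI-style sections of key = value lines,
# e.g. [gan] latent_dim = 100. Values are parsed as numeric vectors when
# possible (comma-separated), otherwise kept as strings.

#' Read a run configuration file
#'
#' Parses an INI-style file with `[section]` headers and `key = value`
#' lines; `#` starts a comment. Numeric-looking values (including
#' comma-separated lists) are converted to numeric vectors.
#'
#' @param path Path to the configuration file.
#' @return Named list of sections, each a named list of values.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  section <- NULL
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      cfg[[section]] <- cfg[[section]] %||% list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.null(section)) stop("key before any [section]: ", ln)
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1])
      val <- trimws(paste(kv[-1], collapse = "="))
      parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
      num <- suppressWarnings(as.numeric(parts))
      cfg[[section]][[key]] <- if (!anyNA(num)) num else val
    } else {
      stop("unparseable configuration line: ", ln)
    }
  }
  cfg
}

#' Write a run configuration file
#'
#' @param cfg Named list of sections (named lists of scalar or vector
#'   values).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  lines <- character(0)
  for (section in names(cfg)) {
    lines <- c(lines, sprintf("[%s]", section))
    for (key in names(cfg[[section]])) {
      val <- cfg[[section]][[key]]
      lines <- c(lines, sprintf("%s = %s", key,
                                paste(format(val, trim = TRUE), collapse = ", ")))
    }
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  invisible(path)
}
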