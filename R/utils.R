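# Internal helpers shared across modules.

STATES <- c("ACTIVE", "PAUSED", "SILENT")
STATE_CODES <- c(ACTIVE = "A", PAUSED = "P", SILENT = "S")

`%||%` <- function(a, b) if (is.null(a)) b else a

round1 <- function(x) round(x, 1)  # IEC 60559 half-to-even, 1 decimal

stop_validation <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' @noRd
check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_validation("'%s' must be a single number", name)
  if (strict_lower && x <= lower)
    stop_validation("'%s' must be > %g", name, lower)
  if (x < lower || x > upper)
    stop_validation("'%s' must be in [%g, %g]", name, lower, upper)
  invisible(x)
}

# Tab-delimited table with '#'-prefixed header lines; the last comment line
# carries the column names (VCF-style "#col1\tcol2...").
write_hash_table <- function(df, path, comments = character()) {
  con <- tryCatch(suppressWarnings(file(path, open = "wt",
                                        encoding = "UTF-8")),
                  error = function(e)
                    stop_validation("cannot open '%s' for writing: %s",
                                    path, conditionMessage(e)))
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(df))
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

read_hash_table <- function(path, col_types = NULL) {
  if (!file.exists(path)) stop_validation("file not found: '%s'", path)
  lines <- readLines(path, encoding = "UTF-8")
  is_comment <- startsWith(lines, "#")
  hdr_idx <- which(is_comment)
  if (!length(hdr_idx))
    stop_validation("'%s': no '#'-prefixed header line", path)
  header <- strsplit(sub("^#", "", lines[max(hdr_idx)]), "\t", fixed = TRUE)[[1]]
  body <- lines[!is_comment & nzchar(lines)]
  if (!length(body)) {
    df <- as.data.frame(stats::setNames(rep(list(character()), length(header)),
                                        header))
  } else {
    df <- utils::read.delim(text = body, header = FALSE,
                            col.names = header, stringsAsFactors = FALSE)
  }
  if (!is.null(col_types)) {
    for (nm in names(col_types)) {
      if (!nm %in% names(df)) next
      df[[nm]] <- switch(col_types[[nm]],
                         integer = as.integer(df[[nm]]),
                         numeric = as.numeric(df[[nm]]),
                         logical = as.logical(df[[nm]]),
                         character = as.character(df[[nm]]))
    }
  }
  df
}

# Sub-stream seed so each generator is individually reproducible under one
# study seed; kept within 32-bit integer range.
substream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + k) %% (.Machine$integer.max - 1L))
}
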