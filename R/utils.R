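# Shared internals: error signalling, logging, alphabet tables, line endings.

DNA_BASES <- c("A", "C", "G", "T")
GAP_CHAR <- "-"

# IUPAC ambiguity expansion: which codes *could* stand for each base.
# Used for conservative outgroup matching: an outgroup R "could be" the
# signature base A or G, so it disqualifies either signature.
IUPAC_CONTAINS <- list(
  A = c("A", "R", "W", "M", "D", "H", "V", "N"),
  C = c("C", "Y", "S", "M", "B", "H", "V", "N"),
  G = c("G", "R", "S", "K", "B", "D", "V", "N"),
  T = c("T", "Y", "W", "K", "B", "D", "H", "N")
)

ALLOWED_CHARS <- c(DNA_BASES, "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V",
                   "N", GAP_CHAR)

tm_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(paste0("taxamark_error_", class),
                                  "taxamark_error"), ...)
}

#' @noRd
log_levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L, quiet = 5L)

tm_log <- function(level, ...) {
  threshold <- getOption("taxamark.log_level", "info")
  if (log_levels[[level]] >= log_levels[[threshold]]) {
    message(sprintf("[%s] %s", toupper(level), paste0(...)))
  }
  invisible(NULL)
}

eol_for <- function(line_endings) {
  line_endings <- match.arg(line_endings, c("unix", "windows"))
  if (line_endings == "windows") "\r\n" else "\n"
}

# Write lines with an explicit terminator; binary connection so CRLF is
# emitted verbatim on every platform.
write_text <- function(lines, path, line_endings = "unix") {
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) {
                    tm_abort(sprintf("cannot write '%s': %s", path,
                                     conditionMessage(e)), "write")
                  })
  on.exit(close(con))
  writeLines(lines, con, sep = eol_for(line_endings))
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Turn an arbitrary label into a safe file-name component.
sanitize_label <- function(x) {
  gsub("[^A-Za-z0-9._]+", "_", x)
}
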