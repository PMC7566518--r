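#' Read / write trial matrices as delimited text
#'
#' Trial matrices are stored as tab-delimited text with a single header line
#' `# fs=<Hz> t0=<s>` followed by one row per trial. Unix and Windows line
#' endings are both accepted on read.
#'
#' @param w a [trial_window_set()].
#' @param path file path.
#' @return `read_trial_matrix()` returns a `trial_window_set`;
#'   `write_trial_matrix()` invisibly returns `path`.
#' @export
write_trial_matrix <- function(w, path) {
  .check_tws(w)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g t0=%.10g", w$fs, w$t0), con)
  write.table(format(w$data, digits = 17, trim = TRUE, scientific = TRUE),
              con, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_matrix
#' @export
read_trial_matrix <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  header <- readLines(path, n = 1)
  m <- regmatches(header,
                  regexec("^#\\s*fs=([0-9.eE+-]+)(\\s+t0=([0-9.eE+-]+))?",
                          header))[[1]]
  if (length(m) == 0 || m[2] == "") {
    stop(sprintf("%s line 1: missing '# fs=<Hz>' header", path))
  }
  fs <- as.numeric(m[2])
  t0 <- if (m[4] != "") as.numeric(m[4]) else 0
  widths <- count.fields(path, sep = "\t", skip = 1, comment.char = "")
  if (length(unique(widths)) != 1) {
    bad <- which(widths != widths[1])[1] + 1
    stop(sprintf("%s line %d: ragged row (expected %d fields)", path, bad,
                 widths[1]))
  }
  d <- as.matrix(read.table(path, sep = "\t", skip = 1, header = FALSE,
                            colClasses = "numeric", comment.char = ""))
  dimnames(d) <- NULL
  trial_window_set(d, fs, t0)
}

# Small rolling polynomial hash (mod 2^31 - 1) over the deparsed config:
# a stable fingerprint for reproducibility stamps, not a cryptographic hash.
.config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "\n")
  h <- 0
  for (b in as.integer(charToRaw(s))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write a tidy results table with a reproducibility stamp
#'
#' Writes a delimited results table preceded by a comment line recording the
#' package version, a hash of the configuration that produced the table, and
#' the master seed. No timestamps are written, so identical runs produce
#' byte-identical files.
#'
#' @param table a data frame.
#' @param path output file path.
#' @param config the configuration object behind the run (hashed into the
#'   stamp).
#' @param seed the master seed used.
#' @return Invisibly, `path`.
#' @export
write_results <- function(table, path, config = NULL, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mift %s config_hash=%s seed=%s",
                     as.character(packageVersion("mift")),
                     .config_hash(config),
                     if (is.null(seed)) "NA" else format(seed)), con)
  write.table(table, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  read.table(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE)
}
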