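#' Derive a reproducible sub-seed
#'
#' Maps a base seed plus a path of labels (stage, variable, tree index ...)
#' to a deterministic integer in \[1, 2^31 - 2\], so that every source of
#' randomness in a run flows from a single seed and partial reruns
#' reproduce identical numbers.
#'
#' @param seed Base integer seed.
#' @param ... Labels (coerced to character) identifying the consumer.
#' @return Integer seed.
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- as.double(seed %% 2147483647L)
  for (c in utf8ToInt(key)) h <- (h * 31 + c) %% 2147483647
  as.integer(h) + 1L
}

#' Write a tidy report CSV with a metadata header
#'
#' Prepends `#`-comment lines carrying the package version, seed and any
#' extra metadata, then the CSV body. Readable back with
#' [read_report_csv()].
#'
#' @param df data.frame to write.
#' @param path Output path (directory created if needed).
#' @param meta Named list of metadata values.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(df, path, meta = list()) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  meta <- c(list(package = paste0("phyniche ",
                                  as.character(utils::packageVersion("phyniche")))),
            meta)
  hdr <- sprintf("# %s: %s", names(meta),
                 vapply(meta, function(v) paste(format(v), collapse = " "),
                        character(1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a report CSV written by [write_report_csv()]
#'
#' @param path CSV path.
#' @return data.frame (metadata lines skipped).
#' @export
read_report_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
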