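## Internal helpers shared across modules.

## Locale-independent lexicographic sort; keeps all orderings reproducible
## across platforms regardless of LC_COLLATE.
lexSort <- function(x) sort(x, method = "radix")

lexOrder <- function(...) order(..., method = "radix")

## Median rounded half-up to an integer (median of integer counts can be x.5;
## half-up retains at least the median-typical genome count).
medianHalfUp <- function(x) {
  as.integer(floor(stats::median(x) + 0.5))
}

## Write a data.frame as TSV atomically: write to <path>.partial, then rename,
## so an interrupted run never leaves a truncated table at the final path.
writeTSVAtomic <- function(df, path) {
  tmp <- paste0(path, ".partial")
  utils::write.table(df, tmp, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  if (!file.rename(tmp, path)) {
    stop("failed to move ", tmp, " to ", path)
  }
  invisible(path)
}

readTSV <- function(path, ...) {
  if (!file.exists(path)) stop("input file not found: ", path)
  utils::read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

## md5 of an in-memory character scalar (via a temp file; tools::md5sum is
## file-based).
md5String <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(x, tf)
  unname(tools::md5sum(tf))
}

stopIfMissingCols <- function(df, cols, what) {
  miss <- setdiff(cols, colnames(df))
  if (length(miss)) {
    stop(what, " is missing required column(s): ", paste(miss, collapse = ", "))
  }
  invisible(TRUE)
}

## Simple leveled logger to stderr.
logMsg <- function(level, ...) {
  message(sprintf("[%s] %s %s", level,
                  format(Sys.time(), "%H:%M:%S"), paste0(...)))
}
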