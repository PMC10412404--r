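`%||%` <- function(a, b) if (is.null(a)) b else a

ea_msg <- function(...) {
  if (isTRUE(getOption("eadriver.verbose", TRUE))) message(...)
}

# Run `expr` under `seed` when given, otherwise in the current RNG stream.
with_opt_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Emit a load report (named skip counts) as log lines.
report_skips <- function(report, what) {
  for (nm in names(report)) {
    if (report[[nm]] > 0) {
      ea_msg(sprintf("%s: skipped %d (%s)", what, report[[nm]], nm))
    }
  }
  invisible(report)
}

# readLines through gzfile(), which transparently handles plain text too
read_text_lines <- function(path) {
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

stop_noisy <- function(...) stop(..., call. = FALSE)
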