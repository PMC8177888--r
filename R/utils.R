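# Internal helpers shared across the package.

# Validation failures get their own condition class so the command-line
# driver can map them to exit code 2 (vs 1 for unexpected errors).
stop_validation <- function(fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c("larvaconn_validation_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

is_validation_error <- function(e) inherits(e, "larvaconn_validation_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic lexicographic ordering, independent of locale.
order_lex <- function(...) {
  args <- lapply(list(...), as.character)
  do.call(order, c(args, list(method = "radix")))
}

assert_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) ||
      x < min) {
    stop_validation("`%s` must be a single integer >= %d", name, min)
  }
  invisible(as.integer(x))
}
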