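# Internal helpers shared across modules.

# Derive a deterministic sub-stream seed from a master seed. Keeps results
# of one stage invariant when another stage adds draws, and stays below
# .Machine$integer.max (R seeds are 32-bit).
sub_seed <- function(seed, stream) {
  as.integer((as.double(seed) %% 2147483647L) * 7919 + stream * 104729) %% 2147483647L
}

# Comma-joined flag sets ("" = empty set). TSV-friendly stand-in for list
# columns; variant tables round-trip through readr without quoting games.
split_flags <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  strsplit(x, ",", fixed = TRUE)
}

join_flags <- function(x) {
  vapply(x, function(el) paste(el, collapse = ","), character(1))
}

# TRUE where the flag-set string shares any element with `set`.
flags_intersect <- function(x, set) {
  vapply(split_flags(x), function(el) any(el %in% set), logical(1))
}

assert_count <- function(x, name, allow_zero = FALSE) {
  lo <- if (allow_zero) 0 else 1
  if (length(x) != 1 || !is.finite(x) || x < lo || x != round(x)) {
    abort(sprintf("`%s` must be a single %s integer, got %s",
                  name, if (allow_zero) "non-negative" else "positive",
                  paste(format(x), collapse = ", ")))
  }
  invisible(x)
}

assert_prob <- function(x, name, lo = 0, hi = 1, lo_open = FALSE, hi_open = FALSE) {
  ok <- length(x) == 1 && is.finite(x) &&
    (if (lo_open) x > lo else x >= lo) &&
    (if (hi_open) x < hi else x <= hi)
  if (!ok) {
    abort(sprintf("`%s` must be a single finite value in %s%g, %g%s, got %s",
                  name, if (lo_open) "(" else "[", lo, hi,
                  if (hi_open) ")" else "]", paste(format(x), collapse = ", ")))
  }
  invisible(x)
}

# Stable lexicographic order independent of the session locale.
c_order <- function(...) order(..., method = "radix")

c_sort <- function(x) x[c_order(x)]
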