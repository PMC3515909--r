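# Internal helpers shared across modules.

# Derive a reproducible child seed from a master seed and a string key.
# Arithmetic kept in doubles below 2^53, result in [1, 2^31 - 1].
derive_seed <- function(seed, key) {
  stopifnot(length(seed) == 1L, is.numeric(seed), length(key) == 1L)
  codes <- utf8ToInt(key)
  h <- sum(codes * seq_along(codes)) %% 2147483647
  val <- (abs(as.numeric(seed)) %% 2147483647) * 69621 + h * 7919
  as.integer(val %% 2147483646) + 1L
}

abort_config <- function(msg) abort(msg, class = "crossvote_config_error")
abort_input <- function(msg) abort(msg, class = "crossvote_input_error")

assert_count <- function(x, name, min = 1) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < min || x != round(x)) {
    abort_config(sprintf("`%s` must be a single integer >= %s", name, min))
  }
}

assert_fraction <- function(x, name, lo = 0, hi = 1,
                            lo_open = TRUE, hi_open = FALSE) {
  ok <- length(x) == 1 && is.numeric(x) && !is.na(x) &&
    (if (lo_open) x > lo else x >= lo) &&
    (if (hi_open) x < hi else x <= hi)
  if (!ok) {
    abort_config(sprintf(
      "`%s` must lie in %s%s, %s%s", name,
      if (lo_open) "(" else "[", lo, hi, if (hi_open) ")" else "]"
    ))
  }
}

# Majority label of a 0/1 vector of odd length.
majority_label <- function(labels) {
  as.integer(sum(labels) * 2L > length(labels))
}
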