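# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

# round() uses banker's rounding; published match rates need plain
# half-up rounding so that e.g. x.5 always rounds away from zero.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# floor a POSIXct to whole minutes (both systems record to the minute)
floor_minute <- function(x) {
  as.POSIXct(floor(as.numeric(x) / 60) * 60, origin = "1970-01-01", tz = "UTC")
}

# deterministic sub-seed for a named stream (e.g. one trust's extract),
# kept below 2^31 so it is always a valid R integer seed
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

is_missing_value <- function(x, sentinel = "XXXX") {
  is.na(x) | x == "" | toupper(x) == toupper(sentinel) | toupper(x) == "NULL"
}

assert_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single proportion in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}
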