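# Internal helpers shared across modules.

# Round half away from zero (base round() is half-to-even). Counts here are
# always non-negative.
round_half_up <- function(x) floor(x + 0.5)

clamp01 <- function(x) pmin(1, pmax(0, x))

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Deterministic per-replicate / per-genome sub-seed derivation. Kept within
# 32-bit integer range.
derive_seed <- function(base_seed, index) {
  as.integer((as.numeric(base_seed) * 7919 + as.numeric(index) * 104729) %% 2147483587L) + 1L
}

stop_contract <- function(...) stop(..., call. = FALSE)

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop_contract(what, " is missing column(s): ", paste(miss, collapse = ", "))
  invisible(df)
}
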