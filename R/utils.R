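#' @keywords internal
"_PACKAGE"

# Derive a reproducible child seed from a master seed and a stage offset.
# Kept strictly below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset) * 104729) %% 2147483629)
}

# Round-half-up, the arithmetic used for case counts and expansion targets.
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
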