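# Internal helpers shared across modules.

# Signal a classed error; `class` is one of "format", "domain", "config",
# "alignment", "validation", "rank", "pipeline", "undefined_correlation".
cry_abort <- function(msg, class) {
  stop(errorCondition(msg,
    class = c(paste0("cryomics_", class, "_error"), "cryomics_error")
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Half-up rounding to `digits` decimals (round() rounds half to even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# Case-insensitive key used wherever feature ids from the two omics meet.
id_key <- function(x) tolower(trimws(x))

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
}

is_scalar_num <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x)
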