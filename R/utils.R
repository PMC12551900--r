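# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Round half away from zero (half-up for non-negative input), as printed
# tables conventionally do; base round() rounds half to even. Small epsilon
# guards against values like 12.4999999 produced by binary fractions of an
# exact decimal .5.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Collapse internal whitespace, trim, uppercase: canonical key form for
# drug names and preferred terms.
normalize_key <- function(x) {
  toupper(trimws(gsub("\\s+", " ", as.character(x))))
}

# Percentage of a count vector against a total, rounded half-up.
pct_of <- function(counts, total, digits = 1) {
  if (total == 0) return(rep(NA_real_, length(counts)))
  round_half_up(100 * counts / total, digits)
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

# Fast per-case membership: which primaryids own at least one row of `sub`
# satisfying a logical mask.
ids_with <- function(ids, mask) unique(ids[mask])
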