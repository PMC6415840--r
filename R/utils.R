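# Internal helpers shared across modules.

# Round half away from zero (round() in R rounds half to even; printed
# tables in clinical reports use half-up).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Format a proportion as a percentage string at a given printed precision.
fmt_pct <- function(p, digits = 2) {
  sprintf(paste0("%.", digits, "f%%"), round_half_up(100 * p, digits))
}

stop_usage <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
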