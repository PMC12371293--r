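# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Round half away from zero (printed-table convention); base round() is
# round-half-even.
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

stop_addhrvr <- function(msg, class, call. = FALSE) {
  stop(structure(class = c(class, "addhrvr_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x == round(x)

# Seconds-since-midnight -> "HH:MM" label, for prints and logs.
fmt_clock <- function(s) {
  sprintf("%02d:%02d", s %/% 3600L, (s %% 3600L) %/% 60L)
}
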