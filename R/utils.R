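# internal helpers: classed errors, unit conversion, small numerics

stop_stemopt <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "stemopt_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

deg2rad <- function(deg) deg * pi / 180

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# FNV-1a 32-bit hash of a character scalar; returns 8 hex digits.
# Used to stamp outputs with a config fingerprint (no digest dependency).
fnv1a32 <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  h <- 2166136261
  for (b in as.integer(charToRaw(s))) {
    low <- bitwXor(h %% 256, b)
    h <- (h - h %% 256 + low) * 16777619 %% 4294967296
    h <- h %% 4294967296
  }
  sprintf("%04x%04x", floor(h / 65536), h %% 65536)
}

config_hash <- function(config) {
  fnv1a32(paste(deparse(config, control = "all"), collapse = "\n"))
}

# linear interpolation that errors outside the table range
interp1 <- function(x, y, xout) {
  if (any(xout < min(x) - 1e-9) || any(xout > max(x) + 1e-9))
    stop_stemopt("interpolation point outside table range", "range_error")
  stats::approx(x, y, xout = clamp(xout, min(x), max(x)), ties = "ordered")$y
}
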