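# classed conditions so callers can distinguish grammar errors from
# semantic validation and configuration problems

eunetError <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "eunetError", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1L))))
}

parseError <- function(fmt, ...) eunetError("eunetParseError", fmt, ...)
validationError <- function(fmt, ...) eunetError("eunetValidationError", fmt, ...)
configError <- function(fmt, ...) eunetError("eunetConfigError", fmt, ...)
argumentError <- function(fmt, ...) eunetError("eunetArgumentError", fmt, ...)

asCount <- function(x, what, min = 1L) {
  if (length(x) != 1L || is.na(x) || !is.numeric(x) || x != round(x) || x < min)
    argumentError("%s must be a single integer >= %d", what, min)
  as.integer(x)
}

asSizePair <- function(size) {
  if (length(size) == 1L) size <- c(size, size)
  if (length(size) != 2L || any(size < 1) || any(size != round(size)))
    argumentError("size must be one or two positive integers")
  as.integer(size)
}

# deterministic polynomial hash of a character string, as hex; used only to
# fingerprint graphs for provenance sidecars
strHash <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^32
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
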