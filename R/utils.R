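# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# near-equality check used by validators; tolerances come from the caller
near <- function(x, y, tol) all(abs(x - y) <= tol)

stop_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warn_ <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# rolling 32-bit digest for provenance blocks (not cryptographic; stable
# across platforms because it only uses integer arithmetic on code points)
config_digest <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x == as.integer(x) && x >= 0
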