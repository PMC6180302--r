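#' @importFrom rlang %||% abort warn inform
#' @importFrom stats phyper p.adjust pt ptukey rhyper runif sd setNames
#' @importFrom utils combn head
NULL

# Seedless, platform-stable 31-bit string hash (base-131 polynomial rolling
# hash modulo the Mersenne prime 2^31 - 1).  Intermediate products stay below
# 2^38, so arithmetic is exact in doubles on every platform.  Used for all
# structural feature identifiers so that fingerprints are reproducible across
# sessions and machines without any RNG involvement.
hash31 <- function(x) {
  p <- 2147483647
  vapply(x, function(s) {
    h <- 0
    for (v in utf8ToInt(s)) h <- (h * 131 + v) %% p
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}

# Locale-independent lexicographic sort (radix) for deterministic canonical ids
sort_cstr <- function(x) sort(x, method = "radix")

# Lexicographic comparison of two integer vectors (TRUE if a < b), with the
# shorter-prefix rule for ties.
lex_less <- function(a, b) {
  m <- min(length(a), length(b))
  if (m > 0) {
    d <- which(a[seq_len(m)] != b[seq_len(m)])
    if (length(d) > 0) return(a[d[1]] < b[d[1]])
  }
  length(a) < length(b)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
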