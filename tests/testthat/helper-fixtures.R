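# Shared fixtures built in code.

# 4-compound toy association database used throughout the prediction and
# deconvolution tests (hand-traceable).
toy_db <- function() {
  association_db(tibble::tibble(
    id = c("c1", "c2", "c3", "c4"),
    fingerprint = list(fingerprint(c(1, 2)), fingerprint(2),
                       fingerprint(3), fingerprint(c(1, 3))),
    targets = list("t1", "t1", "t2", "t2")
  ))
}

# database of exact duplicate pairs, each pair annotated to its own target
# and built on a disjoint feature block
twin_db <- function(n_pairs = 8) {
  rows <- lapply(seq_len(n_pairs), function(i) {
    f <- fingerprint(seq.int(10 * i, 10 * i + 4))
    tibble::tibble(id = sprintf("p%02d%s", i, c("a", "b")),
                   fingerprint = list(f, f),
                   targets = list(sprintf("t%02d", i), sprintf("t%02d", i)))
  })
  association_db(dplyr::bind_rows(rows))
}

random_fp <- function(n_features = 64, rate = 0.2) {
  f <- which(stats::runif(n_features) < rate) - 1L
  if (length(f) == 0) f <- 0L
  fingerprint(f)
}

# independent brute-force upper-tail hypergeometric by complete enumeration
# of all C(N, n) active assignments
enum_hyper_upper <- function(k, K, n, N) {
  sets <- utils::combn(N, n)
  marked <- seq_len(K)
  mean(apply(sets, 2, function(s) sum(s %in% marked) >= k))
}

# independent BH step-up implementation
bh_manual <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}
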