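# brute-force oracles, deliberately independent of the implementations
enum_wilcoxon_p <- function(x, y) {
  d <- (x - y)[x != y]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  mu <- sum(r) / 2
  signs <- expand.grid(rep(list(c(0, 1)), n))
  ws <- as.matrix(signs) %*% r
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

enum_mwu_p <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  rx_obs <- sum(r[seq_len(n)])
  mu <- n * (n + m + 1) / 2
  combos <- utils::combn(n + m, n)
  rxs <- apply(combos, 2, function(idx) sum(r[idx]))
  mean(abs(rxs - mu) >= abs(rx_obs - mu) - 1e-9)
}

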