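# Brute-force enumeration oracles for the rank tests, independent of the
# implementations under test.

brute_mann_whitney_p <- function(a, b) {
  n1 <- length(a); N <- n1 + length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(N, n1)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

brute_signed_rank_p <- function(before, after) {
  d <- after - before; d <- d[d != 0]
  r <- rank(abs(d)); n <- length(d)
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  ws <- apply(signs, 1, function(s) sum(r[s]))
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}
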