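# Independent brute-force oracles used to pin expected values.

# Benjamini-Hochberg by direct sort / cummin of p * m / i.
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Two-sided Fisher exact p for a 2x2 table by full hypergeometric
# enumeration: sum the probability of every table with the same margins
# whose probability does not exceed the observed one.
fisher_enum_2x2 <- function(a, b, c, d) {
  m1 <- a + b
  m2 <- c + d
  k <- a + c
  lo <- max(0L, k - m2)
  hi <- min(k, m1)
  probs <- vapply(lo:hi, function(x) {
    choose(m1, x) * choose(m2, k - x) / choose(m1 + m2, k)
  }, numeric(1))
  obs <- probs[a - lo + 1L]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p by enumeration of all group assignments
# (no ties): probability of a U statistic at least as extreme as observed.
mw_enum <- function(x, y) {
  nx <- length(x)
  vals <- c(x, y)
  stopifnot(!anyDuplicated(vals))
  combos <- utils::combn(length(vals), nx)
  u_of <- function(idx) {
    xx <- vals[idx]
    yy <- vals[-idx]
    sum(outer(xx, yy, ">"))
  }
  u_obs <- sum(outer(x, y, ">"))
  u_all <- apply(combos, 2, u_of)
  mu <- nx * (length(y)) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Upper-tail hypergeometric P(X >= ov) by direct summation.
hyper_enum <- function(ov, set_size, bg_size, query_size) {
  xs <- ov:min(set_size, query_size)
  sum(vapply(xs, function(x) {
    choose(set_size, x) * choose(bg_size - set_size, query_size - x) /
      choose(bg_size, query_size)
  }, numeric(1)))
}
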