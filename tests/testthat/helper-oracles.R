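# Independent brute-force oracles for the statistical primitives.
# These enumerate null distributions directly and never touch the package's
# own code paths.

# Exact two-sided signed-rank p by enumerating all 2^n sign assignments.
# Mirrors the doubling convention: 2 * min-tail, capped at 1.
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_all <- as.matrix(signs) %*% r
  mu <- n * (n + 1) / 4
  p <- if (v_obs > mu) mean(v_all >= v_obs) else mean(v_all <= v_obs)
  min(2 * p, 1)
}

# Exact two-sided rank-sum p by enumerating all C(nx+ny, nx) assignments of
# the combined ranks to group x.
enum_rank_sum_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  sets <- utils::combn(nx + ny, nx)
  w_all <- apply(sets, 2, function(i) sum(r[i])) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  p <- if (w_obs > mu) mean(w_all >= w_obs) else mean(w_all <= w_obs)
  min(2 * p, 1)
}

# Step-up BH by direct formula: adj_(i) = min_{j >= i} p_(j) * n / j.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- pmin(ps * n / seq_len(n), 1)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- adj
  out
}
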