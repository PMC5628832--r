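# Independent brute-force oracles: explicit marginalization over hidden
# binary states, one term per state assignment, per time point. These mirror
# the model definition directly (conditional transition probability divided
# by the target marginal) and share no code with the package's closed forms.

# P(x2 = b | x1 = a) under function f with the epsilon-softened delta;
# indefinite outputs fall back to the target marginal.
.oracle_trans <- function(f, a, b, q, epsilon) {
  out <- f$table[a + 1L]
  if (is.na(out)) return(q[b + 1L])
  if (b == out) 1 - epsilon else epsilon
}

oracle_loglik_unary <- function(src_win, tgt_win, q0, q1, f, epsilon) {
  q <- c(q0, q1)
  ll <- 0
  for (t in seq_along(src_win)) {
    factor_t <- 0
    for (a in 0:1) for (b in 0:1) {
      pa <- if (a == 1) src_win[t] else 1 - src_win[t]
      pb <- if (b == 1) tgt_win[t] else 1 - tgt_win[t]
      factor_t <- factor_t +
        .oracle_trans(f, a, b, q, epsilon) / q[b + 1L] * pa * pb
    }
    ll <- ll + log(factor_t)
  }
  ll
}

.oracle_trans2 <- function(F, a, b, c_, q, epsilon) {
  out <- F$table[a * 2L + b + 1L]
  if (is.na(out)) return(q[c_ + 1L])
  if (c_ == out) 1 - epsilon else epsilon
}

oracle_loglik_binary <- function(src_win, med_win, tgt_win, q0, q1, F,
                                 epsilon) {
  q <- c(q0, q1)
  ll <- 0
  for (t in seq_along(src_win)) {
    factor_t <- 0
    for (a in 0:1) for (b in 0:1) for (c_ in 0:1) {
      pa <- if (a == 1) src_win[t] else 1 - src_win[t]
      pb <- if (b == 1) med_win[t] else 1 - med_win[t]
      pc <- if (c_ == 1) tgt_win[t] else 1 - tgt_win[t]
      factor_t <- factor_t +
        .oracle_trans2(F, a, b, c_, q, epsilon) / q[c_ + 1L] * pa * pb * pc
    }
    ll <- ll + log(factor_t)
  }
  ll
}

# random ECDF profile of length m (ranks of Gaussian noise)
random_profile <- function(m) ecdf_transform(rnorm(m))

# small planted chain used by several suites
chain_net <- function(sd = 0.1) {
  planted_network(c("x1", "x3", "x2"),
                  data.frame(source = c("x1", "x3"), target = c("x3", "x2"),
                             f = "f1", tau = 1L, stringsAsFactors = FALSE),
                  sd = sd)
}

# write a small expression TSV fixture, returns path
write_fixture_tsv <- function(mat) {
  path <- tempfile(fileext = ".tsv")
  write_expression(mat, path)
  path
}
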