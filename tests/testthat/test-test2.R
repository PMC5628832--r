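test_that("triple probabilities are products and normalize", {
  tr <- triple_probs(rep(0.5, 4), rep(0.5, 4), rep(0.5, 4), 0, 0)
  expect_equal(unname(tr[1, ]), rep(0.125, 8))
  tr2 <- triple_probs(c(1, 1, 1), c(1, 1, 1), c(1, 1, 1), 0, 0)
  expect_equal(unname(tr2[1, ]), c(0, 0, 0, 0, 0, 0, 0, 1))
  set.seed(13)
  tr3 <- triple_probs(random_profile(12), random_profile(12),
                      random_profile(12), 3, 1)
  expect_equal(nrow(tr3), 9)
  expect_equal(rowSums(tr3), rep(1, 9), tolerance = 1e-12)
  expect_error(triple_probs(runif(5), runif(5), runif(5), 2, 3),
               "tau_prime")
})

test_that("binary likelihood vanishes on maximally uncertain profiles", {
  # all fhat 0.5: definite-output terms sum to (0.75 + 0.25)(1-e) +
  # (0.75 + 0.25) e = 1 per time point, for any epsilon
  tr <- triple_probs(rep(0.5, 6), rep(0.5, 6), rep(0.5, 6), 0, 0)
  for (eps in c(0.4, 0.05, 0.005)) {
    expect_equal(loglik_binary(tr, list(q0 = 0.5, q1 = 0.5),
                               binary_catalog()$F1, eps), 0,
                 tolerance = 1e-12)
  }
})

test_that("the AND and single-omega worked formulas match the generic form", {
  # written-out per-point brackets for the AND gate (F1) and for F11,
  # evaluated term by term from the probability columns
  set.seed(17)
  src <- random_profile(8); med <- random_profile(8); tgt <- random_profile(8)
  tr <- triple_probs(src, med, tgt, 2, 1)
  mg <- marginals(tgt)
  eps <- 0.005
  f1_hand <- sum(log(
    (tr[, "p000"] / mg$q0 + tr[, "p010"] / mg$q0 + tr[, "p100"] / mg$q0 +
       tr[, "p111"] / mg$q1) * (1 - eps) +
    (tr[, "p001"] / mg$q1 + tr[, "p011"] / mg$q1 + tr[, "p101"] / mg$q1 +
       tr[, "p110"] / mg$q0) * eps))
  expect_equal(loglik_binary(tr, mg, binary_catalog()$F1, eps), f1_hand,
               tolerance = 1e-12)
  f11_hand <- sum(log(
    (tr[, "p010"] / mg$q0 + tr[, "p100"] / mg$q0 + tr[, "p110"] / mg$q0) *
      (1 - eps) + tr[, "p000"] + tr[, "p001"] +
    (tr[, "p011"] / mg$q1 + tr[, "p101"] / mg$q1 + tr[, "p111"] / mg$q1) *
      eps))
  expect_equal(loglik_binary(tr, mg, binary_catalog()$F11, eps), f11_hand,
               tolerance = 1e-12)
})

test_that("binary closed forms equal brute-force marginalization", {
  set.seed(19)
  cat42 <- binary_catalog()
  for (i in 1:6) {
    src <- random_profile(9); med <- random_profile(9); tgt <- random_profile(9)
    tau <- sample(1:3, 1); tp <- sample(0:tau, 1)
    tr <- triple_probs(src, med, tgt, tau, tp)
    mg <- marginals(tgt)
    w <- seq_len(9 - tau)
    for (F in cat42) {
      expect_equal(loglik_binary(tr, mg, F, 0.005),
                   oracle_loglik_binary(src[w], med[w + tp], tgt[w + tau],
                                        mg$q0, mg$q1, F, 0.005),
                   tolerance = 1e-9)
    }
  }
})

test_that("a binary function that ignores the source reduces to the unary model", {
  # built ad hoc (such functions are trivial and not in the catalog): the
  # direct model nests the mediated one through them
  set.seed(23)
  cat6 <- unary_catalog()
  src <- random_profile(12); med <- random_profile(12); tgt <- random_profile(12)
  tau <- 2; tp <- 1
  tr <- triple_probs(src, med, tgt, tau, tp)
  mg <- marginals(tgt)
  w <- seq_len(12 - tau)
  b <- med[w + tp]; c_ <- tgt[w + tau]
  pairs <- cbind(p00 = (1 - b) * (1 - c_), p01 = (1 - b) * c_,
                 p10 = b * (1 - c_), p11 = b * c_)
  for (f in cat6) {
    Fp <- boolean_function("adhoc", c(f$table, f$table))  # rows (a,b) -> f(b)
    expect_equal(loglik_binary(tr, mg, Fp, 0.005),
                 loglik_unary(pairs, mg, f, 0.005),
                 tolerance = 1e-9)
  }
})

test_that("mediator candidates respect the delay-composition constraint", {
  links <- data.frame(source = c("A", "B", "A"), target = c("B", "C", "C"),
                      f = "f1", tau = c(1L, 1L, 2L), sign = "positive",
                      statistic = 5, p_value = 0.01,
                      stringsAsFactors = FALSE)
  med <- find_mediators(links, links[3, ])     # A->C, tau 2
  expect_identical(med$mediator, "B")
  expect_identical(med$tau_prime, 1L)
  expect_identical(med$tau_second, 1L)
  links2 <- links; links2$tau[3] <- 1L         # 1 + 1 > 1
  expect_identical(nrow(find_mediators(links2, links2[3, ])), 0L)
  # two eligible mediators come back sorted by id
  links3 <- rbind(links,
                  data.frame(source = c("A", "Z"), target = c("Z", "C"),
                             f = "f1", tau = 1L, sign = "positive",
                             statistic = 5, p_value = 0.01))
  med3 <- find_mediators(links3, links3[3, ])
  expect_identical(med3$mediator, c("B", "Z"))
})

test_that("a combinatorial AND regulation is called direct", {
  sim <- simulate_gate(m = 20, seed = 1, F = "F1")
  fhat <- ecdf_profiles(sim$observed)$fhat
  res <- directness_test(list(source = "x1", target = "x2", tau = sim$tau),
                         data.frame(mediator = "x3",
                                    tau_prime = sim$tau_prime,
                                    tau_second = 1L),
                         fhat, bfn_params())
  expect_identical(res$verdict, "direct")
  expect_lte(res$p_value, 0.05)
  expect_identical(res$mediator, "x3")
})

test_that("a transitive chain edge is called indirect", {
  fhat <- ecdf_profiles(simulate_network(chain_net(0.1), 20,
                                         seed = 1)$observed)$fhat
  res <- directness_test(list(source = "x1", target = "x2", tau = 2L),
                         data.frame(mediator = "x3", tau_prime = 1L,
                                    tau_second = 1L),
                         fhat, bfn_params())
  expect_identical(res$verdict, "indirect")
  expect_gt(res$p_value, 0.05)
})

test_that("links without eligible mediators are kept as unmediated", {
  fhat <- ecdf_profiles(simulate_network(chain_net(0.1), 20,
                                         seed = 1)$observed)$fhat
  res <- directness_test(list(source = "x1", target = "x2", tau = 2L),
                         data.frame(mediator = character(0),
                                    tau_prime = integer(0),
                                    tau_second = integer(0)),
                         fhat, bfn_params())
  expect_identical(res$verdict, "unmediated")
  expect_true(is.na(res$p_value))
})

test_that("the directness stage partitions and never adds links", {
  net <- chain_net(0.1)
  fhat <- ecdf_profiles(simulate_network(net, 20, seed = 1)$observed)$fhat
  links <- test1_scan(fhat, params = bfn_params())
  part <- test2_filter(links, fhat, bfn_params())
  expect_identical(nrow(part$direct) + nrow(part$indirect), nrow(links))
  key <- function(df) paste(df$source, df$target)
  expect_setequal(c(key(part$direct), key(part$indirect)), key(links))
  # the planted transitive edge lands in the indirect set
  expect_true("x2" %in% part$indirect$target[part$indirect$source == "x1"])
  # a link set with no composable delays passes through unchanged
  lonely <- links[links$source == "x1" & links$target == "x3", , drop = FALSE]
  part2 <- test2_filter(lonely, fhat, bfn_params())
  expect_identical(nrow(part2$direct), nrow(lonely))
  expect_true(all(part2$direct$verdict == "unmediated"))
})

test_that("the conservative mediator rule is at least as strict", {
  sim <- simulate_gate(m = 20, seed = 1)
  fhat <- ecdf_profiles(sim$observed)$fhat
  cands <- data.frame(mediator = "x3", tau_prime = 1L, tau_second = 1L)
  lk <- list(source = "x1", target = "x2", tau = 2L)
  res_max <- directness_test(lk, cands, fhat, bfn_params(), rule = "max")
  res_min <- directness_test(lk, cands, fhat, bfn_params(), rule = "min")
  expect_lte(res_min$statistic, res_max$statistic)
})
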