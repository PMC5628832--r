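test_that("confusion counts partition the pair universe", {
  uni <- pair_universe(c("A", "B", "C"))
  expect_identical(nrow(uni), 6L)
  pred <- data.frame(source = "A", target = "B")
  gold <- data.frame(source = c("A", "A"), target = c("B", "C"))
  cts <- confusion(pred, gold, uni)
  expect_identical(cts, list(TP = 1L, FP = 0L, FN = 1L, TN = 4L))
  # predicted == gold: no errors of either kind
  cts2 <- confusion(gold, gold, uni)
  expect_identical(cts2$FP, 0L); expect_identical(cts2$FN, 0L)
  # empty predictions
  cts3 <- confusion(pred[0, ], gold, uni)
  expect_identical(cts3$TP, 0L); expect_identical(cts3$FP, 0L)
  expect_error(confusion(data.frame(source = "A", target = "A"), gold, uni),
               "universe")
})

test_that("the seven metrics follow their defining formulas", {
  cts <- list(TP = 30L, FP = 10L, FN = 10L, TN = 50L)
  rep <- metrics(cts)
  expect_equal(rep$TPR, 0.75)
  expect_equal(rep$TNR, 50 / 60)
  expect_equal(rep$PPV, 0.75)
  expect_equal(rep$NPV, 50 / 60)
  expect_equal(rep$C1, sqrt(0.25^2 + (1 / 6)^2))
  perfect <- metrics(list(TP = 5L, FP = 0L, FN = 0L, TN = 5L))
  expect_equal(perfect$C1, 0); expect_equal(perfect$C2, 0)
  expect_equal(perfect$C3, 0)
  expect_warning(und <- metrics(list(TP = 0L, FP = 0L, FN = 2L, TN = 4L)),
                 "PPV")
  expect_true(is.na(und$PPV))
})

test_that("ideal-point distances reproduce published whole-genome rows", {
  # sensitivity/specificity and predictive-value pairs with their reported
  # distances, to the 4-decimal precision of the source table
  d <- distance_metrics(tpr = 0.3482, tnr = 0.7548, ppv = 0.0287,
                        npv = 0.9823)
  expect_equal(d$C1, 0.6964, tolerance = 1e-4)
  expect_equal(d$C2, 0.9714, tolerance = 1e-4)
  expect_equal(d$C3, 1.1697, tolerance = 1e-4)
  d2 <- distance_metrics(0.3276, 0.7585, 0.0286, 0.9811)
  expect_equal(d2$C1, 0.7144, tolerance = 1e-4)
  d3 <- distance_metrics(0.3188, 0.7561, 0.0283, 0.9803)
  expect_equal(d3$C3, 1.1867, tolerance = 1e-4)
})

test_that("correlation baseline handles exact and degenerate profiles", {
  t <- 1:12
  mat <- rbind(a = sin(t), b = sin(t), c = -sin(t), flat = rep(1, 12))
  expect_warning(
    roc <- pearson_baseline(mat, c("a"), c("b", "c"),
                            gold = data.frame(source = "a", target = "b"),
                            thresholds = c(0.999)),
    "flat")
  # both |r| = 1 edges are predicted at threshold ~1: TPR 1, FPR 1
  expect_equal(roc$TPR, 1)
  expect_equal(roc$FPR, 1)
})

test_that("ROC curves are monotone in the threshold", {
  net <- planted_network(paste0("g", 1:5),
                         data.frame(source = c("g1", "g1", "g2"),
                                    target = c("g2", "g3", "g4"),
                                    f = c("f3", "f6", "f3"),
                                    tau = c(1L, 1L, 2L)), sd = 0.6)
  sim <- simulate_network(net, 18, seed = 11)
  fhat <- ecdf_profiles(sim$observed)$fhat
  gold <- net$edges[, c("source", "target")]
  uni <- pair_universe(rownames(fhat))
  links <- test1_scan(fhat, params = bfn_params(), keep_all = TRUE)
  roc <- test1_roc(links, gold, uni, p_grid = 10^seq(-6, 0, by = 0.5))
  expect_true(all(diff(roc$TPR) >= 0))
  expect_true(all(diff(roc$FPR) >= 0))
  pe <- pearson_baseline(sim$observed, rownames(fhat), rownames(fhat), gold,
                         thresholds = seq(0, 1, 0.1))
  expect_true(all(diff(pe$TPR) <= 0))   # increasing cutoff removes edges
  expect_true(all(diff(pe$FPR) <= 0))
})

test_that("likelihood scan dominates the correlation baseline on asymmetric links", {
  # necessity/sufficiency regulation is non-linear and direction-asymmetric;
  # zero-lag Pearson correlation is a weak detector for it
  net <- planted_network(paste0("g", 1:6),
                         data.frame(source = c("g1", "g1", "g2", "g3"),
                                    target = c("g2", "g3", "g4", "g5"),
                                    f = c("f3", "f6", "f6", "f3"),
                                    tau = c(1L, 1L, 2L, 1L)), sd = 0.6)
  sim <- simulate_network(net, 18, seed = 11)
  fhat <- ecdf_profiles(sim$observed)$fhat
  gold <- net$edges[, c("source", "target")]
  uni <- pair_universe(rownames(fhat))
  links <- test1_scan(fhat, params = bfn_params(), keep_all = TRUE)
  auc_bfn <- roc_auc(test1_roc(links, gold, uni))
  auc_cor <- roc_auc(pearson_baseline(sim$observed, rownames(fhat),
                                      rownames(fhat), gold))
  expect_gte(auc_bfn, auc_cor)
})

test_that("phase succession follows the cyclic cell-cycle order", {
  phases <- c(a = "G1", b = "S", c = "M", d = "G2/M", e = "G2")
  ok <- phase_consistency(data.frame(source = "a", target = "b"), phases)
  expect_identical(ok$consistent, 1L)                 # G1 -> S
  bad <- phase_consistency(data.frame(source = "b", target = "a"), phases)
  expect_identical(bad$consistent, 0L)                # S -> G1 skips back
  same <- phase_consistency(data.frame(source = "c", target = "c2"),
                            c(phases, c2 = "M"))
  expect_identical(same$consistent, 1L)               # same phase
  # composite: S -> G2/M consistent through the G2 component
  comp <- phase_consistency(data.frame(source = "b", target = "d"), phases)
  expect_identical(comp$consistent, 1L)
  # wrap-around: G2 -> M
  wrap <- phase_consistency(data.frame(source = "e", target = "c"), phases)
  expect_identical(wrap$consistent, 1L)
  expect_error(phase_consistency(data.frame(source = "a", target = "b"),
                                 c(a = "G1", b = "Q")), "phase token")
  expect_error(phase_consistency(data.frame(source = "a", target = "zz"),
                                 phases), "zz")
})

test_that("targets group by source, function and delay", {
  links <- data.frame(source = c("tf", "tf", "tf", "tf", "tf"),
                      target = paste0("t", 1:5),
                      f = c("f1", "f1", "f1", "f1", "f1"),
                      tau = c(0L, 0L, 0L, 1L, 1L))
  grp <- group_targets(links)
  sizes <- table(paste(grp$source, grp$f, grp$tau))
  expect_identical(sort(unname(as.integer(sizes))), c(2L, 3L))
  empty <- group_targets(links[0, ])
  expect_identical(nrow(empty), 0L)
  # with 6 functions and 6 delays there can be at most 36 groups per source
  expect_lte(nrow(unique(grp[, c("source", "f", "tau")])), 36L)
})
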