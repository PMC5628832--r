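#' Joint conditional state probabilities of a (source, mediator, target) triple
#'
#' For a tested link with delay `tau` and a candidate mediator reached at
#' delay `tau_prime <= tau`, the three genes are read at times `t`,
#' `t + tau_prime` and `t + tau` for `t = 1 ... m - tau`. The eight entries
#' `p_abc(t)` are products of the three conditional state probabilities,
#' indexed source, mediator, target.
#'
#' @param src,med,tgt ECDF profiles (length `m`).
#' @param tau link delay; `tau < m`.
#' @param tau_prime source-to-mediator delay, `0 <= tau_prime <= tau`.
#' @return Matrix with `m - tau` rows and columns `p000` ... `p111`
#'   (source, mediator, target digit order); rows sum to 1.
#' @export
triple_probs <- function(src, med, tgt, tau, tau_prime) {
  m <- length(src)
  stopifnot(length(med) == m, length(tgt) == m)
  if (tau_prime < 0 || tau_prime > tau || tau >= m)
    stop("need 0 <= tau_prime <= tau < m")
  t0 <- seq_len(m - tau)
  a <- src[t0]
  b <- med[t0 + tau_prime]
  c_ <- tgt[t0 + tau]
  out <- matrix(NA_real_, m - tau, 8L)
  colnames(out) <- paste0("p", c("000", "001", "010", "011",
                                 "100", "101", "110", "111"))
  k <- 0L
  for (ai in 0:1) for (bi in 0:1) for (ci in 0:1) {
    k <- k + 1L
    out[, k] <- (if (ai == 1) a else 1 - a) *
                (if (bi == 1) b else 1 - b) *
                (if (ci == 1) c_ else 1 - c_)
  }
  out
}

#' Log-likelihood of the direct two-regulator model under a binary function
#'
#' Generalization of the unary closed form to two regulators: each time
#' point contributes \eqn{\log \sum_{a,b,c} p_{abc} w_{abc}} with weight
#' \eqn{(1-\epsilon)/q_c} when the target state matches `F(a, b)`,
#' \eqn{\epsilon/q_c} when a definite output is violated, and 1 when
#' `F(a, b)` is indefinite.
#'
#' @param triples matrix from [triple_probs()].
#' @param tgt_marg target marginals from [marginals()].
#' @param F binary `boolean_function`.
#' @param epsilon pseudo-weight in (0, 0.5).
#' @return Log-likelihood (natural log).
#' @export
loglik_binary <- function(triples, tgt_marg, F, epsilon = 0.005) {
  stopifnot(inherits(F, "boolean_function"), F$arity == 2L)
  qs <- c(tgt_marg$q0, tgt_marg$q1)
  factor_t <- numeric(nrow(triples))
  k <- 0L
  for (ai in 0:1) for (bi in 0:1) {
    out <- F$table[ai * 2L + bi + 1L]
    for (ci in 0:1) {
      k <- k + 1L
      w <- if (is.na(out)) 1
           else (if (ci == out) 1 - epsilon else epsilon) / qs[ci + 1L]
      factor_t <- factor_t + triples[, k] * w
    }
  }
  sum(log(factor_t))
}

#' Candidate mediators of a tested link
#'
#' A gene `x3` is a mediator candidate for the link `x1 -> x2` (delay `tau`)
#' when the Test-1 output contains both `x1 -> x3` (delay `tau_prime`) and
#' `x3 -> x2` (delay `tau_second`) and the delays compose:
#' `tau_prime + tau_second <= tau`.
#'
#' @param links Test-1 link data.frame.
#' @param link one-row data.frame or list with `source`, `target`, `tau`.
#' @return data.frame with columns `mediator`, `tau_prime`, `tau_second`,
#'   sorted by mediator id; zero rows when no gene qualifies.
#' @export
find_mediators <- function(links, link) {
  up <- links[links$source == link$source & links$target != link$target, ]
  down <- links[links$target == link$target & links$source != link$source, ]
  shared <- intersect(up$target, down$source)
  out <- data.frame(mediator = character(), tau_prime = integer(),
                    tau_second = integer(), stringsAsFactors = FALSE)
  for (g in sort(shared)) {
    tp <- up$tau[up$target == g][1]
    ts <- down$tau[down$source == g][1]
    if (tp + ts <= link$tau)
      out <- rbind(out, data.frame(mediator = g, tau_prime = tp,
                                   tau_second = ts,
                                   stringsAsFactors = FALSE))
  }
  out
}

#' Directness test of one link against its candidate mediators (Test 2)
#'
#' For each candidate mediator the direct model M1 (target driven by a
#' binary function of source and mediator) is maximized over the 42 binary
#' functions, and the mediated model M0 (target driven by a unary function
#' of the mediator alone, over the same time window) is maximized over the
#' 6 unary functions. The default rule follows the literal argmax: the
#' statistic is `2 * max` over mediators of `l1 - l0`; `rule = "min"` is a
#' conservative alternative in which the direct model must beat every
#' mediator's indirect model. The link is called `direct` when the
#' chi-square p-value is at most `p2`, `indirect` otherwise, and
#' `unmediated` (kept) when no candidate exists.
#'
#' @param link one row of the Test-1 output.
#' @param candidates data.frame from [find_mediators()].
#' @param fhat ECDF matrix.
#' @param params [bfn_params()].
#' @param rule `"max"` (literal) or `"min"` (conservative) aggregation over
#'   mediators.
#' @return List with `verdict` (`direct`/`indirect`/`unmediated`),
#'   `mediator`, `F` (best binary function id), `tau_prime`, `statistic`
#'   and `p_value` (`NA` when unmediated).
#' @export
directness_test <- function(link, candidates, fhat, params = bfn_params(),
                            rule = c("max", "min")) {
  rule <- match.arg(rule)
  if (nrow(candidates) == 0L)
    return(list(verdict = "unmediated", mediator = NA_character_,
                F = NA_character_, tau_prime = NA_integer_,
                statistic = NA_real_, p_value = NA_real_))
  cat42 <- binary_catalog()
  cat6 <- unary_catalog()
  tgt_marg <- marginals(fhat[link$target, ])
  m <- ncol(fhat)
  per_med <- lapply(seq_len(nrow(candidates)), function(i) {
    med <- candidates$mediator[i]
    tp <- candidates$tau_prime[i]
    triples <- triple_probs(fhat[link$source, ], fhat[med, ],
                            fhat[link$target, ], link$tau, tp)
    l1s <- vapply(cat42, loglik_binary, numeric(1), triples = triples,
                  tgt_marg = tgt_marg, epsilon = params$epsilon)
    l1 <- max(l1s)
    best_F <- names(cat42)[which.max(l1s)]
    # M0: unary mediator -> target over the same window (delay tau - tau_prime,
    # mediator read at t + tau_prime, target at t + tau)
    t0 <- seq_len(m - link$tau)
    b <- fhat[med, t0 + tp]
    c_ <- fhat[link$target, t0 + link$tau]
    pairs <- cbind(p00 = (1 - b) * (1 - c_), p01 = (1 - b) * c_,
                   p10 = b * (1 - c_), p11 = b * c_)
    l0 <- max(vapply(cat6, loglik_unary, numeric(1),
                     pairs = pairs, tgt_marg = tgt_marg,
                     epsilon = params$epsilon))
    list(mediator = med, tau_prime = tp, F = best_F, diff = l1 - l0)
  })
  diffs <- vapply(per_med, `[[`, numeric(1), "diff")
  pick <- if (rule == "max") which.max(diffs) else which.min(diffs)
  statistic <- max(2 * diffs[pick], 0)
  p <- chisq_pvalue(statistic, params$chisq_df)
  list(verdict = if (p <= params$p2) "direct" else "indirect",
       mediator = per_med[[pick]]$mediator,
       F = per_med[[pick]]$F,
       tau_prime = per_med[[pick]]$tau_prime,
       statistic = statistic, p_value = p)
}

#' Partition Test-1 links into direct and indirect sets (Test 2)
#'
#' Runs [find_mediators()] and [directness_test()] on every Test-1 link.
#' Links with no composable mediator are kept as direct (`unmediated`).
#' Test 2 never adds links: the two output sets partition the input.
#'
#' @param links Test-1 link data.frame.
#' @param fhat ECDF matrix.
#' @param params [bfn_params()].
#' @param rule mediator aggregation rule, see [directness_test()].
#' @return List with data.frames `direct` and `indirect`; both carry the
#'   added columns `verdict`, `mediator`, `mediator_delay`, `F2`, `test2_p`.
#' @export
test2_filter <- function(links, fhat, params = bfn_params(),
                         rule = c("max", "min")) {
  rule <- match.arg(rule)
  n <- nrow(links)
  verdict <- character(n); mediator <- character(n)
  med_delay <- integer(n); F2 <- character(n); p2v <- numeric(n)
  for (i in seq_len(n)) {
    res <- directness_test(links[i, ], find_mediators(links, links[i, ]),
                           fhat, params, rule)
    verdict[i] <- res$verdict
    mediator[i] <- res$mediator
    med_delay[i] <- res$tau_prime
    F2[i] <- res$F
    p2v[i] <- res$p_value
  }
  links$verdict <- verdict
  links$mediator <- mediator
  links$mediator_delay <- med_delay
  links$F2 <- F2
  links$test2_p <- p2v
  keep <- verdict %in% c("direct", "unmediated")
  list(direct = `rownames<-`(links[keep, , drop = FALSE], NULL),
       indirect = `rownames<-`(links[!keep, , drop = FALSE], NULL))
}
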