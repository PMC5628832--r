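#' Marginal state probabilities of one gene
#'
#' The hidden-state marginals are time averages of the conditional state
#' probabilities: \eqn{q_1 = \sum_t P(x(t)=1|y(t))/m} = `mean(fhat)` and
#' \eqn{q_0 = 1 - q_1}.
#'
#' @param fhat ECDF profile of one gene (values in (0,1]).
#' @return List with `q0` and `q1`, `q0 + q1 == 1`.
#' @export
marginals <- function(fhat) {
  q1 <- mean(fhat)
  q0 <- mean(1 - fhat)
  if (q0 == 0 || q1 == 0)
    stop("degenerate gene: constant hidden-state probability")
  list(q0 = q0, q1 = q1)
}

#' Joint conditional state probabilities of a delayed gene pair
#'
#' For delay `tau`, the source is read at times `1 ... m - tau` and the
#' target at `1 + tau ... m`; independence given the observations makes the
#' joint a product: `p_ab(t) = P(x1(t)=a|y1) * P(x2(t+tau)=b|y2)`.
#'
#' @param src,tgt ECDF profiles of source and target (length `m`).
#' @param tau non-negative delay, `tau < m`.
#' @return Matrix with `m - tau` rows and columns `p00`, `p01`, `p10`,
#'   `p11`; rows sum to 1.
#' @export
pair_probs <- function(src, tgt, tau) {
  m <- length(src)
  stopifnot(length(tgt) == m)
  if (tau < 0 || tau >= m) stop("tau must satisfy 0 <= tau < m")
  a <- src[seq_len(m - tau)]
  b <- tgt[seq_len(m - tau) + tau]
  cbind(p00 = (1 - a) * (1 - b), p01 = (1 - a) * b,
        p10 = a * (1 - b),       p11 = a * b)
}

#' Log-likelihood of the not-linked pair model
#'
#' In the model without a link the per-time-point factor is the total mass
#' `p00 + p01 + p10 + p11 = 1`, so the log-likelihood is identically zero;
#' the operation is kept explicit so the ratio statistic reads
#' `2 * (l_linked - l_not_linked)`.
#'
#' @param pairs matrix from [pair_probs()].
#' @return Numeric scalar, 0 up to floating-point rounding.
#' @export
loglik_not_linked <- function(pairs) {
  sum(log(rowSums(pairs)))
}

# eq: per-assignment weights for a unary function applied to pair columns.
# Definite output b* for input a contributes (1-eps)/q_{b*} when matched and
# eps/q_b when violated; an indefinite output contributes weight 1 (the
# target marginal cancels against the normalization).
.unary_weights <- function(f, q0, q1, epsilon) {
  qs <- c(q0, q1)
  w <- matrix(1, 2, 2)             # rows: a = 0,1; cols: b = 0,1
  for (a in 0:1) {
    out <- f$table[a + 1L]
    if (!is.na(out)) {
      for (b in 0:1)
        w[a + 1L, b + 1L] <- (if (b == out) 1 - epsilon else epsilon) / qs[b + 1L]
    }
  }
  w
}

#' Log-likelihood of the linked pair model under a unary function
#'
#' Closed form of the hidden-state marginalization: each time point
#' contributes \eqn{\log \sum_{a,b} p_{ab} w_{ab}} where the weight of a
#' definite transition is \eqn{(1-\epsilon)/q_b} when the target state
#' matches `f(a)` and \eqn{\epsilon/q_b} when it does not, and indefinite
#' (\eqn{\Omega}) inputs contribute their terms with weight 1. The division
#' is by the target gene's marginal.
#'
#' @param pairs matrix from [pair_probs()].
#' @param tgt_marg target marginals from [marginals()].
#' @param f unary `boolean_function`.
#' @param epsilon pseudo-weight in (0, 0.5).
#' @return Log-likelihood (natural log).
#' @export
loglik_unary <- function(pairs, tgt_marg, f, epsilon = 0.005) {
  stopifnot(inherits(f, "boolean_function"), f$arity == 1L)
  w <- .unary_weights(f, tgt_marg$q0, tgt_marg$q1, epsilon)
  sum(log(pairs[, "p00"] * w[1, 1] + pairs[, "p01"] * w[1, 2] +
          pairs[, "p10"] * w[2, 1] + pairs[, "p11"] * w[2, 2]))
}

#' Upper-tail chi-square p-value of a likelihood-ratio statistic
#'
#' @param statistic value of `2 log R`; tiny negative rounding noise is
#'   clamped to zero.
#' @param df degrees of freedom (>= 1).
#' @return p-value in \[0, 1\].
#' @export
chisq_pvalue <- function(statistic, df = 1L) {
  if (df < 1) stop("df must be >= 1")
  stats::pchisq(pmax(statistic, 0), df = df, lower.tail = FALSE)
}

#' Best unary function and delay for one ordered gene pair
#'
#' Maximizes the linked-model log-likelihood over the six unary functions
#' and all delays in `[tau_min, tau_max]`. Ties are broken toward the lower
#' function index, then the smaller delay. The statistic is
#' `2 * l_linked` at the optimum (the not-linked log-likelihood is zero);
#' a negative optimum — possible because the function catalog does not
#' contain the free saturated model — is truncated at zero, consistent with
#' the one-sided chi-square test.
#'
#' @param src,tgt ECDF profiles (length `m`).
#' @param params [bfn_params()].
#' @param tgt_marg optionally precomputed target marginals.
#' @return List with `f` (function id), `tau`, `sign`, `statistic`,
#'   `p_value` and `loglik`.
#' @export
best_function_delay <- function(src, tgt, params = bfn_params(),
                                tgt_marg = NULL) {
  m <- length(src)
  if (params$tau_max > m - 2L)
    stop("tau_max must be at most m - 2")
  if (is.null(tgt_marg)) tgt_marg <- marginals(tgt)
  cat6 <- unary_catalog()
  best <- NULL
  for (tau in params$tau_min:params$tau_max) {
    pairs <- pair_probs(src, tgt, tau)
    for (i in seq_along(cat6)) {
      ll <- loglik_unary(pairs, tgt_marg, cat6[[i]], params$epsilon)
      if (is.null(best) || ll > best$loglik) {
        best <- list(f = cat6[[i]]$id, f_index = i, tau = tau, loglik = ll)
      }
    }
  }
  statistic <- max(2 * best$loglik, 0)
  list(f = best$f, tau = best$tau,
       sign = classify_sign(cat6[[best$f_index]]),
       statistic = statistic,
       p_value = chisq_pvalue(statistic, params$chisq_df),
       loglik = best$loglik)
}

#' Scan ordered gene pairs for significant delayed links (Test 1)
#'
#' For every ordered (source, target) pair (self-pairs excluded) the best
#' unary function and delay are found and the pair is retained when its
#' chi-square p-value is at most `p1`. Supplying a transcription-factor list
#' as `sources` restricts link origins and fixes edge direction for
#' zero-delay links; with `sources = targets =` all genes both orientations
#' are evaluated.
#'
#' @param fhat ECDF matrix from [ecdf_profiles()] (genes in rows).
#' @param sources,targets character vectors of gene ids (default: all genes).
#' @param params [bfn_params()].
#' @param keep_all if `TRUE`, return every evaluated pair regardless of
#'   `p1` (used for ROC sweeps).
#' @return data.frame with columns `source`, `target`, `f`, `tau`, `sign`,
#'   `statistic`, `p_value`, ordered by source then target as supplied.
#' @export
test1_scan <- function(fhat, sources = rownames(fhat),
                       targets = rownames(fhat),
                       params = bfn_params(), keep_all = FALSE) {
  if (length(sources) == 0L)
    stop("empty source list: pass all genes explicitly to scan every pair")
  missing <- setdiff(c(sources, targets), rownames(fhat))
  if (length(missing))
    stop("genes absent from the profile matrix: ",
         paste(missing, collapse = ", "))
  if (ncol(fhat) < 10L)
    warning("fewer than 10 time points: inference is unreliable")
  marg <- lapply(stats::setNames(nm = rownames(fhat)),
                 function(g) marginals(fhat[g, ]))
  rows <- vector("list", length(sources) * length(targets))
  k <- 0L
  for (s in sources) {
    for (tg in targets) {
      if (s == tg) next
      hit <- best_function_delay(fhat[s, ], fhat[tg, ], params,
                                 tgt_marg = marg[[tg]])
      k <- k + 1L
      rows[[k]] <- data.frame(source = s, target = tg, f = hit$f,
                              tau = hit$tau, sign = hit$sign,
                              statistic = hit$statistic,
                              p_value = hit$p_value,
                              stringsAsFactors = FALSE)
    }
  }
  links <- do.call(rbind, rows[seq_len(k)])
  if (is.null(links))
    links <- data.frame(source = character(), target = character(),
                        f = character(), tau = integer(), sign = character(),
                        statistic = numeric(), p_value = numeric())
  if (params$adjust != "none")
    links$p_value <- stats::p.adjust(links$p_value, method = params$adjust)
  if (!keep_all) links <- links[links$p_value <= params$p1, , drop = FALSE]
  rownames(links) <- NULL
  links
}
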