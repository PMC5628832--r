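#' Specify a planted Boolean regulatory network
#'
#' A planted network is the generative counterpart of the pairwise link
#' model: hidden binary trajectories propagate through delayed unary
#' Boolean functions and are observed through per-state Gaussian emissions
#' with overlapping supports. Each target has at most one planted parent
#' (the inference model is pairwise); genes without a parent are roots
#' drawn i.i.d. Bernoulli.
#'
#' @param genes character vector of gene ids.
#' @param edges data.frame with columns `source`, `target`, `f` (unary
#'   function id, `"f1"`-`"f6"`), `tau` (delay >= 0).
#' @param root_activation probability a root state is 1 at each time point;
#'   also used to resolve indefinite (\eqn{\Omega}) outputs.
#' @param mean0,mean1 emission means of the inactive/active hidden state
#'   (`mean1 > mean0`).
#' @param sd emission standard deviation (shared by both states).
#' @return List of class `planted_network`.
#' @export
planted_network <- function(genes, edges,
                            root_activation = 0.5,
                            mean0 = 0, mean1 = 2, sd = 0.25) {
  stopifnot(length(genes) >= 1, !anyDuplicated(genes),
            root_activation > 0, root_activation < 1,
            mean1 > mean0, sd >= 0)
  if (nrow(edges)) {
    stopifnot(all(edges$source %in% genes), all(edges$target %in% genes),
              all(edges$f %in% names(unary_catalog())), all(edges$tau >= 0))
    if (anyDuplicated(edges$target))
      stop("at most one planted parent per target (pairwise model)")
    zero <- edges[edges$tau == 0, , drop = FALSE]
    if (nrow(zero)) {
      # a zero-delay cycle never closes: reject it
      order_ok <- tryCatch({
        .toposort(genes, zero); TRUE
      }, error = function(e) FALSE)
      if (!order_ok) stop("delay-0 cycle in planted network")
    }
  }
  structure(list(genes = genes, edges = edges,
                 root_activation = root_activation,
                 mean0 = mean0, mean1 = mean1, sd = sd),
            class = "planted_network")
}

# Kahn topological sort restricted to the given edge set.
.toposort <- function(genes, edges) {
  indeg <- stats::setNames(integer(length(genes)), genes)
  for (tg in edges$target) indeg[tg] <- indeg[tg] + 1L
  queue <- names(indeg)[indeg == 0L]
  out <- character(0)
  while (length(queue)) {
    g <- queue[1]; queue <- queue[-1]
    out <- c(out, g)
    kids <- edges$target[edges$source == g]
    for (k in kids) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(out) != length(genes)) stop("cycle detected")
  out
}

#' Simulate hidden trajectories and noisy observations of a planted network
#'
#' Root genes are i.i.d. Bernoulli(`root_activation`) at every time point.
#' A child's state at `t` is `f(parent state at t - tau)` when that output
#' is definite; indefinite outputs and the initial `tau`-point prefix are
#' drawn Bernoulli(`root_activation`). Observations are
#' `Normal(mean_state, sd)`. The same seed reproduces the result
#' bit-identically.
#'
#' @param net [planted_network()].
#' @param m number of time points (`m > max delay + 2`).
#' @param seed integer RNG seed.
#' @return List of class `bfn_simulation` with `hidden` (0/1 matrix),
#'   `observed` (expression matrix, genes in rows) and `seed`.
#' @export
simulate_network <- function(net, m, seed = 1L) {
  stopifnot(inherits(net, "planted_network"))
  max_tau <- if (nrow(net$edges)) max(net$edges$tau) else 0L
  if (m <= max_tau + 2L) stop("m must exceed the largest delay by more than 2")
  if (m < 10L) warning("fewer than 10 time points: inference is unreliable")
  set.seed(seed)
  genes <- net$genes
  n <- length(genes)
  cat6 <- unary_catalog()
  parent <- stats::setNames(rep(NA_character_, n), genes)
  pf <- stats::setNames(rep(NA_character_, n), genes)
  ptau <- stats::setNames(rep(NA_integer_, n), genes)
  if (nrow(net$edges)) {
    parent[net$edges$target] <- net$edges$source
    pf[net$edges$target] <- net$edges$f
    ptau[net$edges$target] <- net$edges$tau
  }
  # order genes so that zero-delay parents are resolved first at each t
  zero <- if (nrow(net$edges)) net$edges[net$edges$tau == 0, , drop = FALSE]
          else net$edges
  ord <- if (!is.null(zero) && nrow(zero)) .toposort(genes, zero) else genes
  hidden <- matrix(NA_integer_, n, m, dimnames = list(genes, NULL))
  for (t in seq_len(m)) {
    for (g in ord) {
      if (is.na(parent[[g]]) || t <= ptau[[g]]) {
        hidden[g, t] <- stats::rbinom(1L, 1L, net$root_activation)
      } else {
        out <- bf_evaluate(cat6[[pf[[g]]]], hidden[parent[[g]], t - ptau[[g]]])
        hidden[g, t] <- if (is.na(out))
          stats::rbinom(1L, 1L, net$root_activation) else out
      }
    }
  }
  means <- ifelse(hidden == 1L, net$mean1, net$mean0)
  observed <- matrix(stats::rnorm(n * m, mean = means, sd = net$sd), n, m,
                     dimnames = list(genes, paste0("t", seq_len(m))))
  structure(list(hidden = hidden, observed = observed, seed = seed),
            class = "bfn_simulation")
}

#' Emit noisy Gaussian observations from given hidden trajectories
#'
#' Utility for building generative structures beyond the single-parent
#' planted network (e.g. a target driven by a binary AND of two regulators):
#' construct the 0/1 hidden matrix by hand, then emit observations with the
#' same per-state Gaussian model used by [simulate_network()].
#'
#' @param hidden 0/1 integer matrix (genes in rows) with gene rownames.
#' @param mean0,mean1 emission means (`mean1 > mean0`).
#' @param sd emission standard deviation.
#' @param seed integer RNG seed.
#' @return Numeric expression matrix of the same shape.
#' @export
emit_observations <- function(hidden, mean0 = 0, mean1 = 2, sd = 0.25,
                              seed = 1L) {
  stopifnot(all(hidden %in% c(0L, 1L)), mean1 > mean0, sd >= 0)
  set.seed(seed)
  means <- ifelse(hidden == 1L, mean1, mean0)
  matrix(stats::rnorm(length(hidden), mean = means, sd = sd),
         nrow(hidden), ncol(hidden),
         dimnames = list(rownames(hidden),
                         paste0("t", seq_len(ncol(hidden)))))
}

#' Simulate a target driven by a binary Boolean function of two regulators
#'
#' Generates the three-gene combinatorial-regulation motif used to probe
#' the directness test: a root source `x1`, an independently drawn
#' co-regulator `x3` (read by the target one interval after the source) and
#' a target `x2` whose state at `t + 2` is `F(x1(t), x3(t + 1))`, with the
#' initial prefix drawn at random. Observations use the Gaussian two-mean
#' emission model. Asymmetric activation probabilities (a sparse source and
#' a dense co-regulator by default) keep both inputs of an AND gate
#' informative.
#'
#' @param m number of time points.
#' @param seed integer RNG seed.
#' @param F binary function id from [binary_catalog()] (default `"F1"`,
#'   the AND gate).
#' @param p_src,p_mod activation probabilities of source and co-regulator.
#' @param mean0,mean1,sd emission parameters, as in [planted_network()].
#' @return List of class `bfn_simulation` with `hidden`, `observed`,
#'   `seed`, and the motif delays `tau` (source to target, 2) and
#'   `tau_prime` (source to co-regulator window offset, 1).
#' @export
simulate_gate <- function(m = 20L, seed = 1L, F = "F1",
                          p_src = 0.4, p_mod = 0.8,
                          mean0 = 0, mean1 = 2, sd = 0.1) {
  stopifnot(F %in% names(.binary_tables()), m >= 10L)
  set.seed(seed)
  Fb <- binary_catalog()[[F]]
  x1 <- stats::rbinom(m, 1L, p_src)
  x3 <- stats::rbinom(m, 1L, p_mod)
  x2 <- stats::rbinom(m, 1L, 0.5)
  for (t in seq_len(m - 2L)) {
    out <- bf_evaluate(Fb, c(x1[t], x3[t + 1L]))
    x2[t + 2L] <- if (is.na(out)) stats::rbinom(1L, 1L, 0.5) else out
  }
  hidden <- rbind(x1 = x1, x3 = x3, x2 = x2)
  storage.mode(hidden) <- "integer"
  observed <- emit_observations(hidden, mean0, mean1, sd,
                                seed = seed + 1L)
  structure(list(hidden = hidden, observed = observed, seed = seed,
                 F = F, tau = 2L, tau_prime = 1L),
            class = "bfn_simulation")
}

#' Score inferred links against the planted truth
#'
#' Confusion counts and the seven accuracy metrics over the ordered-pair
#' scan universe, plus a per-planted-edge table flagging recovery and exact
#' (function, delay) agreement.
#'
#' @param links inferred link data.frame (`source`, `target`, `f`, `tau`).
#' @param net [planted_network()].
#' @param sources,targets gene sets defining the scan universe (default:
#'   all genes of the network).
#' @return List with `counts`, `metrics` and `edges` (per planted edge:
#'   `recovered`, `f_match`, `tau_match`).
#' @export
recovery_report <- function(links, net,
                            sources = net$genes, targets = net$genes) {
  universe <- pair_universe(sources, targets)
  gold <- net$edges[, c("source", "target")]
  counts <- confusion(links[, c("source", "target")], gold, universe)
  key <- paste(links$source, links$target, sep = "\r")
  per_edge <- lapply(seq_len(nrow(net$edges)), function(i) {
    e <- net$edges[i, ]
    j <- match(paste(e$source, e$target, sep = "\r"), key)
    data.frame(source = e$source, target = e$target,
               recovered = !is.na(j),
               f_match = !is.na(j) && links$f[j] == e$f,
               tau_match = !is.na(j) && links$tau[j] == e$tau,
               stringsAsFactors = FALSE)
  })
  list(counts = counts,
       metrics = suppressWarnings(metrics(counts)),
       edges = do.call(rbind, per_edge))
}
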