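.edge_key <- function(df) paste(df$source, df$target, sep = "\r")

#' All ordered pairs of a source and target set, self-pairs excluded
#'
#' @param sources,targets character vectors of gene ids.
#' @return data.frame with columns `source`, `target`.
#' @export
pair_universe <- function(sources, targets = sources) {
  g <- expand.grid(target = targets, source = sources,
                   stringsAsFactors = FALSE)
  g <- g[g$source != g$target, c("source", "target")]
  rownames(g) <- NULL
  g
}

#' Confusion counts of a predicted edge set against a gold standard
#'
#' @param predicted,gold data.frames with `source`, `target` columns; both
#'   must be subsets of the universe.
#' @param universe data.frame of ordered pairs defining the evaluation
#'   space, e.g. from [pair_universe()].
#' @return List with `TP`, `FP`, `TN`, `FN`; the four counts sum to
#'   `nrow(universe)`.
#' @export
confusion <- function(predicted, gold, universe) {
  u <- unique(.edge_key(universe))
  p <- unique(.edge_key(predicted))
  g <- unique(.edge_key(gold))
  if (!all(p %in% u)) stop("predicted edge outside the evaluation universe")
  if (!all(g %in% u)) stop("gold edge outside the evaluation universe")
  tp <- sum(p %in% g)
  list(TP = tp, FP = length(p) - tp, FN = length(g) - tp,
       TN = length(u) - length(p) - length(g) + tp)
}

#' Distances from the ideal performance point
#'
#' Euclidean distances from perfect classification in three planes:
#' `C1` in (sensitivity, specificity), `C2` in (PPV, NPV), `C3` in
#' (sensitivity, PPV). Smaller is better; the range is \[0, sqrt(2)\].
#'
#' @param tpr,tnr,ppv,npv classification rates in \[0, 1\].
#' @return List with `C1`, `C2`, `C3`.
#' @export
distance_metrics <- function(tpr, tnr, ppv, npv) {
  list(C1 = sqrt((1 - tpr)^2 + (1 - tnr)^2),
       C2 = sqrt((1 - ppv)^2 + (1 - npv)^2),
       C3 = sqrt((1 - tpr)^2 + (1 - ppv)^2))
}

#' Seven accuracy metrics from confusion counts
#'
#' Sensitivity (TPR), specificity (TNR), precision (PPV), negative
#' predictive value (NPV), and the three ideal-point distances `C1`, `C2`,
#' `C3` from [distance_metrics()]. Rates with a zero denominator are
#' reported as `NA` with a warning and propagate into the distances.
#'
#' @param counts list with `TP`, `FP`, `TN`, `FN` (see [confusion()]).
#' @return List with `TPR`, `TNR`, `PPV`, `NPV`, `C1`, `C2`, `C3`.
#' @export
metrics <- function(counts) {
  rate <- function(num, den, name) {
    if (den == 0) {
      warning(name, " undefined: zero denominator")
      return(NA_real_)
    }
    num / den
  }
  tpr <- rate(counts$TP, counts$TP + counts$FN, "TPR")
  tnr <- rate(counts$TN, counts$TN + counts$FP, "TNR")
  ppv <- rate(counts$TP, counts$TP + counts$FP, "PPV")
  npv <- rate(counts$TN, counts$TN + counts$FN, "NPV")
  c(list(TPR = tpr, TNR = tnr, PPV = ppv, NPV = npv),
    distance_metrics(tpr, tnr, ppv, npv))
}

#' Zero-lag Pearson-correlation baseline ROC
#'
#' The classical alternative to likelihood-based link discovery: an edge is
#' predicted between two genes when the absolute Pearson correlation of
#' their raw expression profiles reaches a cutoff. For each cutoff in the
#' grid the false- and true-positive rates against a gold standard are
#' returned.
#'
#' @param mat complete expression matrix (raw values, genes in rows).
#' @param sources,targets gene id vectors defining the ordered-pair
#'   universe (self-pairs excluded).
#' @param gold gold-standard edge data.frame (`source`, `target`).
#' @param thresholds absolute-correlation cutoffs; default 21-point grid.
#' @return data.frame with columns `threshold`, `FPR`, `TPR`.
#' @export
pearson_baseline <- function(mat, sources, targets, gold,
                             thresholds = seq(0, 1, by = 0.05)) {
  sds <- apply(mat, 1L, stats::sd)
  if (any(sds == 0)) {
    warning("skipping zero-variance gene(s): ",
            paste(rownames(mat)[sds == 0], collapse = ", "))
    mat <- mat[sds > 0, , drop = FALSE]
    sources <- intersect(sources, rownames(mat))
    targets <- intersect(targets, rownames(mat))
  }
  universe <- pair_universe(sources, targets)
  gold <- gold[.edge_key(gold) %in% .edge_key(universe), , drop = FALSE]
  r <- stats::cor(t(mat[sources, , drop = FALSE]) ,
                  t(mat[targets, , drop = FALSE]))
  absr <- abs(r[cbind(match(universe$source, sources),
                      match(universe$target, targets))])
  out <- lapply(thresholds, function(thr) {
    pred <- universe[absr >= thr, , drop = FALSE]
    cts <- confusion(pred, gold, universe)
    data.frame(threshold = thr,
               FPR = if (cts$FP + cts$TN > 0) cts$FP / (cts$FP + cts$TN) else NA,
               TPR = if (cts$TP + cts$FN > 0) cts$TP / (cts$TP + cts$FN) else NA)
  })
  do.call(rbind, out)
}

#' ROC of the pairwise link test over a p-value grid
#'
#' Thresholds the Test-1 p-values of a full scan (`keep_all = TRUE`) at each
#' grid point and scores against a gold standard; the directness test is not
#' part of the sweep.
#'
#' @param links full Test-1 scan (every pair, with p-values).
#' @param gold gold-standard edge data.frame.
#' @param universe ordered-pair universe data.frame.
#' @param p_grid p-value cutoffs.
#' @return data.frame with columns `threshold`, `FPR`, `TPR`.
#' @export
test1_roc <- function(links, gold, universe,
                      p_grid = c(10^seq(-10, -1, by = 0.5), 0.5, 1)) {
  gold <- gold[.edge_key(gold) %in% .edge_key(universe), , drop = FALSE]
  out <- lapply(p_grid, function(thr) {
    pred <- links[links$p_value <= thr, c("source", "target"), drop = FALSE]
    cts <- confusion(pred, gold, universe)
    data.frame(threshold = thr,
               FPR = if (cts$FP + cts$TN > 0) cts$FP / (cts$FP + cts$TN) else NA,
               TPR = if (cts$TP + cts$FN > 0) cts$TP / (cts$TP + cts$FN) else NA)
  })
  do.call(rbind, out)
}

#' Area under an ROC point set (trapezoidal, anchored at (0,0) and (1,1))
#'
#' @param roc data.frame with `FPR` and `TPR` columns.
#' @return Scalar AUC.
#' @export
roc_auc <- function(roc) {
  ok <- stats::complete.cases(roc[, c("FPR", "TPR")])
  x <- c(0, sort(roc$FPR[ok]), 1)
  y <- c(0, roc$TPR[ok][order(roc$FPR[ok])], 1)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

.phase_successor <- c(M = "G1", G1 = "S", S = "G2", G2 = "M")

#' Consistency of links with cell-cycle phase succession
#'
#' Phases follow the cyclic order M, G1, S, G2, M. A link is consistent
#' when the target's phase equals the source's phase or is its immediate
#' successor. Composite labels such as `"G2/M"` are split on `/` and the
#' link is consistent if any component pair satisfies the rule.
#'
#' @param links link data.frame (`source`, `target`).
#' @param phases named character vector mapping gene id to phase label.
#' @return List with `consistent` (count), `total`, `fraction` and a
#'   `details` data.frame.
#' @export
phase_consistency <- function(links, phases) {
  check_tokens <- function(lab) {
    toks <- strsplit(lab, "/", fixed = TRUE)[[1]]
    bad <- setdiff(toks, names(.phase_successor))
    if (length(bad)) stop("unknown phase token: ", paste(bad, collapse = ", "))
    toks
  }
  one <- function(src_lab, tgt_lab) {
    s <- check_tokens(src_lab)
    tg <- check_tokens(tgt_lab)
    any(vapply(s, function(a)
      any(tg == a | tg == .phase_successor[[a]]), logical(1)))
  }
  missing <- setdiff(unique(c(links$source, links$target)), names(phases))
  if (length(missing))
    stop("no phase label for: ", paste(missing, collapse = ", "))
  ok <- mapply(one, phases[links$source], phases[links$target])
  details <- data.frame(source = links$source, target = links$target,
                        source_phase = unname(phases[links$source]),
                        target_phase = unname(phases[links$target]),
                        consistent = as.logical(ok),
                        stringsAsFactors = FALSE)
  list(consistent = sum(ok), total = nrow(links),
       fraction = if (nrow(links)) sum(ok) / nrow(links) else NA_real_,
       details = details)
}

#' Group each source's targets by (function, delay)
#'
#' With six unary functions and a delay range of 0-5 a regulator's targets
#' fall into at most 36 groups; the grouping feeds external gene-set
#' enrichment tools.
#'
#' @param links link data.frame with `f` and `tau` columns.
#' @return data.frame with columns `source`, `f`, `tau`, `target`, sorted
#'   by source, function, delay, target.
#' @export
group_targets <- function(links) {
  if (nrow(links) == 0L)
    return(data.frame(source = character(), f = character(),
                      tau = integer(), target = character()))
  out <- links[order(links$source, links$f, links$tau, links$target),
               c("source", "f", "tau", "target")]
  rownames(out) <- NULL
  out
}
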