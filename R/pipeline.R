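#' Full BFN inference pipeline
#'
#' Preprocessing (missing-value filter, spline imputation, ECDF transform),
#' pairwise link scan (Test 1) and directness partition (Test 2) in one
#' call.
#'
#' @param mat expression matrix (genes in rows; `NA` allowed).
#' @param sources,targets gene id vectors (default: all genes surviving
#'   preprocessing).
#' @param params [bfn_params()].
#' @param max_missing per-gene missing-value tolerance, see
#'   [filter_missing()].
#' @param positive_only keep only links whose unary function is a positive
#'   regulation before the directness test.
#' @param rule mediator aggregation rule, see [directness_test()].
#' @return List with `direct`, `indirect` (link data.frames),
#'   `links_test1`, `excluded_missing`, `excluded_degenerate`, `fhat` and
#'   the `params` used.
#' @export
bfn_infer <- function(mat, sources = NULL, targets = NULL,
                      params = bfn_params(), max_missing = 3L,
                      positive_only = FALSE, rule = c("max", "min")) {
  rule <- match.arg(rule)
  flt <- filter_missing(mat, max_missing)
  complete <- impute_matrix(flt$matrix)
  prof <- ecdf_profiles(complete)
  genes <- rownames(prof$fhat)
  if (is.null(sources)) sources <- genes else sources <- intersect(sources, genes)
  if (is.null(targets)) targets <- genes else targets <- intersect(targets, genes)
  links <- test1_scan(prof$fhat, sources, targets, params)
  if (positive_only) links <- links[links$sign == "positive", , drop = FALSE]
  part <- test2_filter(links, prof$fhat, params, rule)
  list(direct = part$direct, indirect = part$indirect,
       links_test1 = links,
       excluded_missing = flt$excluded,
       excluded_degenerate = prof$degenerate,
       fhat = prof$fhat, params = params)
}

#' Write a link table as tab-separated text
#'
#' @param links link data.frame.
#' @param path output path.
#' @export
write_links <- function(links, path) {
  utils::write.table(links, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an edge list (source, target TSV with header)
#'
#' @param path file path.
#' @return data.frame with `source` and `target` columns.
#' @export
read_edges <- function(path) {
  if (!file.exists(path)) stop("edge list not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("edge list needs at least 2 columns")
  names(df)[1:2] <- c("source", "target")
  df
}

#' Run inference from files (command-line backend)
#'
#' @param config list with elements `expr` (expression TSV path), optional
#'   `sources`/`targets` (gene-list paths), `out` (output directory) and any
#'   [bfn_params()] fields, plus optional `positive_only`, `max_missing`,
#'   `rule`.
#' @return Invisibly, the [bfn_infer()] result; writes
#'   `links_direct.tsv`, `links_indirect.tsv` and `run_config.yaml`-style
#'   provenance into `config$out`.
#' @export
cmd_infer <- function(config) {
  if (is.null(config$expr)) stop("infer: config needs 'expr'")
  mat <- read_expression(config$expr)
  params <- do.call(bfn_params, config[intersect(names(config),
    c("p1", "p2", "epsilon", "tau_min", "tau_max", "chisq_df", "adjust"))])
  sources <- if (!is.null(config$sources)) read_gene_list(config$sources)
  targets <- if (!is.null(config$targets)) read_gene_list(config$targets)
  res <- bfn_infer(mat, sources, targets, params,
                   max_missing = config$max_missing %||% 3L,
                   positive_only = isTRUE(config$positive_only),
                   rule = config$rule %||% "max")
  out <- config$out %||% "."
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_links(res$direct, file.path(out, "links_direct.tsv"))
  write_links(res$indirect, file.path(out, "links_indirect.tsv"))
  writeLines(paste0(names(unlist(params)), ": ", unlist(params)),
             file.path(out, "run_config.txt"))
  message(sprintf(
    "genes kept %d | excluded missing %d | degenerate %d | test1 links %d | direct %d | indirect %d",
    nrow(res$fhat), length(res$excluded_missing),
    length(res$excluded_degenerate), nrow(res$links_test1),
    nrow(res$direct), nrow(res$indirect)))
  invisible(res)
}

#' Evaluate a predicted network against a gold standard (command-line backend)
#'
#' @param config list with `pred` and `gold` (edge-list TSV paths),
#'   `sources`/`targets` (gene-list paths or character vectors defining the
#'   universe; default: all genes appearing in either list), optional `out`.
#' @return Invisibly, the metrics list; writes `metrics.tsv` when `out` is
#'   given.
#' @export
cmd_evaluate <- function(config) {
  pred <- read_edges(config$pred)
  gold <- read_edges(config$gold)
  if (nrow(gold) == 0L) stop("empty gold standard")
  as_genes <- function(x) if (length(x) == 1L && file.exists(x))
    read_gene_list(x) else x
  sources <- as_genes(config$sources %||%
                        unique(c(pred$source, gold$source)))
  targets <- as_genes(config$targets %||%
                        unique(c(pred$target, gold$target)))
  universe <- pair_universe(sources, targets)
  dropped <- sum(!(.edge_key(gold) %in% .edge_key(universe)))
  if (dropped) message(dropped, " gold edge(s) outside the universe dropped")
  gold <- gold[.edge_key(gold) %in% .edge_key(universe), , drop = FALSE]
  rep <- metrics(confusion(pred, gold, universe))
  if (!is.null(config$out)) {
    dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(
      data.frame(metric = names(rep), value = round(unlist(rep), 4)),
      file.path(config$out, "metrics.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(rep)
}

#' Simulate a planted network to files (command-line backend)
#'
#' @param config list with `genes` (character vector or count), `edges`
#'   (data.frame or edge TSV path with f/tau columns), `m`, `seed`, `out`,
#'   and optional emission fields `root_activation`, `mean0`, `mean1`, `sd`.
#' @return Invisibly, the simulation; writes `expression.tsv` and
#'   `truth_edges.tsv`.
#' @export
cmd_simulate <- function(config) {
  genes <- config$genes
  if (is.numeric(genes)) genes <- paste0("g", seq_len(genes))
  edges <- config$edges
  if (is.character(edges)) edges <- utils::read.delim(edges, sep = "\t",
                                                      stringsAsFactors = FALSE)
  net <- planted_network(genes, edges,
                         root_activation = config$root_activation %||% 0.5,
                         mean0 = config$mean0 %||% 0,
                         mean1 = config$mean1 %||% 2,
                         sd = config$sd %||% 0.25)
  sim <- simulate_network(net, m = config$m %||% 18L,
                          seed = config$seed %||% 1L)
  out <- config$out %||% "."
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_expression(sim$observed, file.path(out, "expression.tsv"))
  utils::write.table(net$edges, file.path(out, "truth_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  message("seed: ", sim$seed)
  invisible(sim)
}

#' Benchmark the link scan on an exported time course
#'
#' Protocol for scoring the method on a small dynamical system whose time
#' course was exported to an expression TSV (e.g. an ODE model simulated
#' elsewhere): run the pairwise test over a wide delay range with a strict
#' significance cutoff, optionally apply the directness stage, and score
#' the resulting edge set against a user-supplied gold-standard edge list
#' over the all-pairs universe.
#'
#' @param expr expression matrix or path to an expression TSV.
#' @param gold gold-standard edge data.frame or path to an edge TSV.
#' @param p1 Test-1 significance cutoff (default 0.005).
#' @param tau_max largest delay searched (default 10).
#' @param tau_min smallest delay searched (default 1).
#' @param run_test2 apply the directness stage before scoring.
#' @return List with `links`, `counts` and `metrics`.
#' @export
benchmark_timecourse <- function(expr, gold, p1 = 0.005, tau_max = 10L,
                                 tau_min = 1L, run_test2 = FALSE) {
  mat <- if (is.character(expr)) read_expression(expr) else expr
  gold <- if (is.character(gold)) read_edges(gold) else gold
  if (nrow(gold) == 0L) stop("empty gold standard")
  params <- bfn_params(p1 = p1, tau_min = tau_min, tau_max = tau_max)
  prof <- ecdf_profiles(impute_matrix(filter_missing(mat)$matrix))
  links <- test1_scan(prof$fhat, params = params)
  if (run_test2) links <- test2_filter(links, prof$fhat, params)$direct
  universe <- pair_universe(rownames(prof$fhat))
  gold <- gold[.edge_key(gold) %in% .edge_key(universe), , drop = FALSE]
  counts <- confusion(links[, c("source", "target")], gold, universe)
  list(links = links, counts = counts,
       metrics = suppressWarnings(metrics(counts)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
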