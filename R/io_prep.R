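#' Read a genes-by-time expression matrix from tab-separated text
#'
#' Expected layout: a header row of time labels, a first column of gene
#' identifiers and one column per time point. Empty cells and the sentinel
#' tokens are read as missing. CRLF line endings are tolerated.
#'
#' @param path file path.
#' @param na_tokens character vector of tokens treated as missing, in
#'   addition to the empty cell.
#' @return Numeric matrix (genes in rows, time points in columns) with gene
#'   identifiers as rownames, time labels as colnames and `NA` for missing
#'   entries. Row order follows the file.
#' @export
read_expression <- function(path, na_tokens = c("", "NA", "NaN")) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          na.strings = na_tokens, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L)
    stop("expression file needs a gene-id column and at least 2 data columns")
  ids <- as.character(df[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate gene ids: ", paste(dup, collapse = ", "))
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  mat
}

#' Write an expression matrix as tab-separated text
#'
#' @param mat numeric matrix with gene rownames.
#' @param path output file path.
#' @param id_column header of the gene-identifier column.
#' @export
write_expression <- function(mat, path, id_column = "gene") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene list (one id per line, '#' comments)
#'
#' @param path file path.
#' @return character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("gene list not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- trimws(sub("#.*", "", lines))
  lines[nzchar(lines)]
}

#' Exclude genes with too many missing values
#'
#' Genes with strictly more than `max_missing` missing time points are
#' removed; with the default of 3 this excludes genes having 4 or more
#' missing values, the rule applied to the yeast alpha-factor time course.
#'
#' @param mat expression matrix with `NA` for missing entries.
#' @param max_missing largest tolerated number of missing values per gene.
#' @return List with `matrix` (retained genes, unchanged values) and
#'   `excluded` (character vector of removed gene ids).
#' @export
filter_missing <- function(mat, max_missing = 3L) {
  stopifnot(max_missing >= 0)
  n_miss <- rowSums(is.na(mat))
  drop <- n_miss > max_missing
  list(matrix = mat[!drop, , drop = FALSE],
       excluded = rownames(mat)[drop])
}

#' Impute missing values in one time series by cubic spline
#'
#' A cubic interpolating spline is fitted to the observed (time, value)
#' pairs and evaluated at the missing time points,
#' including extrapolation beyond the first/last observed point. Observed
#' values are returned bit-identical.
#'
#' @details `stats::spline(..., method = "fmm")` fits the classic
#'   Forsythe-Malcolm-Moler cubic: the polynomial through the four points
#'   nearest each end is used for extrapolation, so a series sampled from a
#'   cubic polynomial is reproduced exactly, inside and outside the observed
#'   range.
#'
#' @param series numeric vector with `NA` at missing positions.
#' @param times optional numeric time coordinates (default `seq_along`).
#' @return Complete numeric vector.
#' @export
impute_spline <- function(series, times = seq_along(series)) {
  obs <- which(!is.na(series))
  if (length(obs) == length(series)) return(series)
  if (length(obs) < 4L)
    stop("spline imputation needs at least 4 observed points")
  miss <- which(is.na(series))
  fit <- stats::spline(times[obs], series[obs], method = "fmm",
                       xout = times[miss])
  series[miss] <- fit$y
  series
}

#' Impute every incomplete gene in a matrix
#'
#' @param mat expression matrix with `NA` for missing entries (apply
#'   [filter_missing()] first so every gene has enough observed points).
#' @return Complete matrix.
#' @export
impute_matrix <- function(mat) {
  incomplete <- which(rowSums(is.na(mat)) > 0L)
  for (i in incomplete) mat[i, ] <- impute_spline(mat[i, ])
  mat
}

#' Empirical-CDF transform of one expression series
#'
#' Soft discretization: each observation is mapped to its empirical
#' cumulative probability, interpreted downstream as
#' \eqn{P(x(t) = 1 \mid y(t))}, the probability that the gene's hidden binary
#' state is active given the observed level. Ties are handled by assigning
#' every copy of a unique value \eqn{u_k} with tie count \eqn{c_k} the
#' probability \eqn{(C + c_k)/m}, where \eqn{C} counts strictly smaller
#' observations — i.e. the maximum rank divided by \eqn{m}. The largest
#' observation always maps to 1 and the transform depends on ranks only.
#'
#' @param series complete numeric vector, length \eqn{m \ge 2}.
#' @return Numeric vector of values in \eqn{(0, 1]}.
#' @examples
#' ecdf_transform(c(1, 2, 3))    # 1/3 2/3 1
#' ecdf_transform(c(5, 5, 7))    # 2/3 2/3 1
#' @export
ecdf_transform <- function(series) {
  if (anyNA(series)) stop("series must be complete; impute first")
  m <- length(series)
  if (m < 2L) stop("need at least 2 time points")
  if (length(unique(series)) == 1L)
    stop("zero-variance series: ECDF transform is degenerate")
  rank(series, ties.method = "max") / m
}

#' ECDF-standardize every gene of an expression matrix
#'
#' Zero-variance (constant) genes cannot be standardized — their hidden
#' state would have marginal probability 0 of being inactive — and are
#' dropped with a warning.
#'
#' @param mat complete expression matrix.
#' @return List with `fhat` (matrix of ECDF values in (0,1]) and
#'   `degenerate` (ids of dropped constant genes).
#' @export
ecdf_profiles <- function(mat) {
  if (anyNA(mat)) stop("matrix has missing values; impute first")
  if (ncol(mat) < 2L) stop("need at least 2 time points")
  const <- apply(mat, 1L, function(r) length(unique(r)) == 1L)
  if (any(const))
    warning("dropping zero-variance gene(s): ",
            paste(rownames(mat)[const], collapse = ", "))
  kept <- mat[!const, , drop = FALSE]
  fhat <- t(apply(kept, 1L, ecdf_transform))
  dimnames(fhat) <- dimnames(kept)
  list(fhat = fhat, degenerate = rownames(mat)[const])
}
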