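#' Boolean functions with indefinite outputs
#'
#' The BFN model describes a regulatory link by a Boolean function mapping the
#' hidden binary state of the regulator(s) to the hidden state of the target.
#' Besides the definite outputs 0 and 1, an output may be *indefinite*
#' (written \eqn{\Omega}, serialized as `"*"`): either 0 or 1 can appear for
#' that input assignment. A `boolean_function` stores the truth table as an
#' integer vector over the input assignments in lexicographic order
#' (`0`, `1` for arity 1; `(0,0), (0,1), (1,0), (1,1)` for arity 2), with
#' `NA` encoding \eqn{\Omega}.
#'
#' @param id label, e.g. `"f1"` or `"F17"`.
#' @param outputs integer vector of length `2^arity` with values 0, 1 or `NA`
#'   (\eqn{\Omega}).
#' @return An object of class `boolean_function` with fields `id`, `arity`
#'   and `table`.
#' @examples
#' f <- boolean_function("f3", c(0L, NA))
#' bf_evaluate(f, 0)
#' @export
boolean_function <- function(id, outputs) {
  outputs <- as.integer(outputs)
  if (!length(outputs) %in% c(2L, 4L))
    stop("outputs must have length 2 (arity 1) or 4 (arity 2)")
  if (!all(outputs %in% c(0L, 1L) | is.na(outputs)))
    stop("outputs must be 0, 1 or NA (indefinite)")
  if (all(is.na(outputs)))
    stop("a Boolean function needs at least one definite output")
  structure(
    list(id = as.character(id),
         arity = if (length(outputs) == 2L) 1L else 2L,
         table = outputs),
    class = "boolean_function"
  )
}

#' @export
print.boolean_function <- function(x, ...) {
  out <- ifelse(is.na(x$table), "*", x$table)
  if (x$arity == 1L) {
    cat(sprintf("%s (unary): 0->%s, 1->%s\n", x$id, out[1], out[2]))
  } else {
    cat(sprintf("%s (binary): 00->%s, 01->%s, 10->%s, 11->%s\n",
                x$id, out[1], out[2], out[3], out[4]))
  }
  invisible(x)
}

#' Catalog of the six unary Boolean functions
#'
#' All non-trivial mappings of one binary input to an output in
#' \{0, 1, \eqn{\Omega}\}: `f1` equivalence (upregulation), `f2` negation
#' (downregulation), `f3` necessity ("target cannot be on unless source is
#' on"), `f4` its negation, `f5` negated sufficiency ("source on forces
#' target off"), `f6` sufficiency ("source on forces target on").
#'
#' @return Named list of six `boolean_function` objects, `f1` to `f6`.
#' @seealso [binary_catalog()], [bf_evaluate()], [classify_sign()]
#' @export
unary_catalog <- function() {
  tabs <- list(
    f1 = c(0L, 1L),
    f2 = c(1L, 0L),
    f3 = c(0L, NA),
    f4 = c(1L, NA),
    f5 = c(NA, 0L),
    f6 = c(NA, 1L)
  )
  mapply(boolean_function, names(tabs), tabs, SIMPLIFY = FALSE)
}

# Truth tables of the 42 non-trivial binary functions, rows (0,0),(0,1),(1,0),(1,1).
# F1-F10 are the fully definite functions depending on both inputs (F1 = AND,
# F5 = OR); F11-F18, F19-F26, F27-F34, F35-F42 carry a single indefinite output
# at assignment (0,0), (0,1), (1,0), (1,1) respectively.
.binary_tables <- function() {
  list(
    F1  = c(0L, 0L, 0L, 1L),
    F2  = c(0L, 0L, 1L, 0L),
    F3  = c(0L, 1L, 0L, 0L),
    F4  = c(0L, 1L, 1L, 0L),
    F5  = c(0L, 1L, 1L, 1L),
    F6  = c(1L, 0L, 0L, 0L),
    F7  = c(1L, 0L, 0L, 1L),
    F8  = c(1L, 0L, 1L, 1L),
    F9  = c(1L, 1L, 0L, 1L),
    F10 = c(1L, 1L, 1L, 0L),
    F11 = c(NA, 0L, 0L, 0L),
    F12 = c(NA, 0L, 0L, 1L),
    F13 = c(NA, 0L, 1L, 0L),
    F14 = c(NA, 0L, 1L, 1L),
    F15 = c(NA, 1L, 0L, 0L),
    F16 = c(NA, 1L, 0L, 1L),
    F17 = c(NA, 1L, 1L, 0L),
    F18 = c(NA, 1L, 1L, 1L),
    F19 = c(0L, NA, 0L, 0L),
    F20 = c(0L, NA, 0L, 1L),
    F21 = c(0L, NA, 1L, 0L),
    F22 = c(0L, NA, 1L, 1L),
    F23 = c(1L, NA, 0L, 0L),
    F24 = c(1L, NA, 0L, 1L),
    F25 = c(1L, NA, 1L, 0L),
    F26 = c(1L, NA, 1L, 1L),
    F27 = c(0L, 0L, NA, 0L),
    F28 = c(0L, 0L, NA, 1L),
    F29 = c(0L, 1L, NA, 0L),
    F30 = c(0L, 1L, NA, 1L),
    F31 = c(1L, 0L, NA, 0L),
    F32 = c(1L, 0L, NA, 1L),
    F33 = c(1L, 1L, NA, 0L),
    F34 = c(1L, 1L, NA, 1L),
    F35 = c(0L, 0L, 0L, NA),
    F36 = c(0L, 0L, 1L, NA),
    F37 = c(0L, 1L, 0L, NA),
    F38 = c(0L, 1L, 1L, NA),
    F39 = c(1L, 0L, 0L, NA),
    F40 = c(1L, 0L, 1L, NA),
    F41 = c(1L, 1L, 0L, NA),
    F42 = c(1L, 1L, 1L, NA)
  )
}

#' Catalog of the 42 binary Boolean functions
#'
#' All non-trivial mappings of two binary inputs to \{0, 1, \eqn{\Omega}\}:
#' the ten fully definite functions that depend on both inputs (constants and
#' single-input functions are excluded as trivial) followed by the thirty-two
#' functions with exactly one indefinite output. `F1` realizes an AND gate,
#' `F5` an OR gate. These binary functions serve the directness test, where a
#' two-regulator model is compared against a mediated one-regulator model.
#'
#' @return Named list of 42 `boolean_function` objects, `F1` to `F42`.
#' @seealso [unary_catalog()]
#' @export
binary_catalog <- function() {
  tabs <- .binary_tables()
  mapply(boolean_function, names(tabs), tabs, SIMPLIFY = FALSE)
}

#' Evaluate a Boolean function on one input assignment
#'
#' @param f a `boolean_function`.
#' @param inputs vector of 0/1 values of length `f$arity`.
#' @return `0L`, `1L`, or `NA` for an indefinite (\eqn{\Omega}) output.
#' @examples
#' bf_evaluate(unary_catalog()$f2, 1)      # 0
#' bf_evaluate(binary_catalog()$F5, c(1, 0)) # 1 (OR)
#' @export
bf_evaluate <- function(f, inputs) {
  stopifnot(inherits(f, "boolean_function"))
  if (length(inputs) != f$arity)
    stop(sprintf("%s has arity %d but %d input(s) given",
                 f$id, f$arity, length(inputs)))
  if (!all(inputs %in% c(0, 1)))
    stop("inputs must be 0 or 1")
  idx <- if (f$arity == 1L) inputs + 1L else inputs[1] * 2L + inputs[2] + 1L
  f$table[[idx]]
}

#' Regulatory sign of a unary Boolean function
#'
#' A unary function is a *positive* regulation when every definite output
#' equals its input (monotone non-decreasing): equivalence `f1`, necessity
#' `f3` and sufficiency `f6`. The remaining functions `f2`, `f4`, `f5` are
#' negative regulations.
#'
#' @param f a unary `boolean_function`.
#' @return `"positive"` or `"negative"`.
#' @export
classify_sign <- function(f) {
  stopifnot(inherits(f, "boolean_function"))
  if (f$arity != 1L) stop("classify_sign is defined for unary functions only")
  definite <- which(!is.na(f$table))
  inputs <- definite - 1L
  if (all(f$table[definite] == inputs)) "positive" else "negative"
}

#' Export a function catalog as a truth-table data frame
#'
#' One row per (function, input assignment); indefinite outputs are written
#' as `"*"`. Suitable for audit or `write.table()` export.
#'
#' @param catalog list of `boolean_function`s from [unary_catalog()] or
#'   [binary_catalog()].
#' @return data.frame with columns `id`, one column per input, and `output`.
#' @export
catalog_table <- function(catalog) {
  arity <- catalog[[1]]$arity
  rows <- lapply(catalog, function(f) {
    if (f$arity != arity) stop("mixed arities in catalog")
    if (arity == 1L) {
      data.frame(id = f$id, x1 = 0:1,
                 output = ifelse(is.na(f$table), "*", as.character(f$table)),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(id = f$id, x1 = c(0L, 0L, 1L, 1L), x2 = c(0L, 1L, 0L, 1L),
                 output = ifelse(is.na(f$table), "*", as.character(f$table)),
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
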