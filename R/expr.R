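#' Expression matrix container
#'
#' A light wrapper around a genes x individuals numeric matrix carrying a
#' processing-state flag. State moves only forward through
#' `raw -> filtered -> residualized -> int` (inverse-normal transformed), the
#' order in which the preprocessing steps are meant to be applied.
#'
#' @param values numeric matrix, genes as rows (rownames = gene ids),
#'   individuals as columns (colnames = sample ids).
#' @param state one of `"raw"`, `"filtered"`, `"residualized"`, `"int"`.
#' @return An object of class `locop_expr`.
#' @export
locop_expr <- function(values, state = "raw") {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values))) stop("duplicated gene ids")
  if (anyDuplicated(colnames(values))) stop("duplicated sample ids")
  state <- match.arg(state, c("raw", "filtered", "residualized", "int"))
  structure(list(values = values, state = state), class = "locop_expr")
}

expr_states <- c("raw", "filtered", "residualized", "int")

# internal: replace values, advancing state (never backwards)
set_expr_state <- function(expr, values, state) {
  if (match(state, expr_states) < match(expr$state, expr_states))
    stop(sprintf("cannot move expression state backwards (%s -> %s)",
                 expr$state, state))
  expr$values <- values
  expr$state <- state
  expr
}

#' @export
print.locop_expr <- function(x, ...) {
  cat(sprintf("<locop_expr> %d genes x %d individuals, state = %s\n",
              nrow(x$values), ncol(x$values), x$state))
  invisible(x)
}

#' @export
dim.locop_expr <- function(x) dim(x$values)

#' Extract gene ids of an expression matrix
#' @param expr a [locop_expr] object.
#' @return Character vector of gene ids.
#' @export
gene_ids <- function(expr) rownames(expr$values)

#' Extract sample ids of an expression matrix
#' @param expr a [locop_expr] object.
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(expr) colnames(expr$values)
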