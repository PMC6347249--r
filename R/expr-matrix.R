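#' Expression matrix container
#'
#' Wraps a cells-by-features numeric matrix together with cell (row) and
#' feature (column) identifiers. The package orients data with cells as rows
#' and features as columns throughout; typically `n < d` for single-cell
#' data. Sparse matrices from the Matrix package are kept sparse; dense
#' operations coerce on demand.
#'
#' @param values numeric matrix (base or Matrix sparse), n cells x d
#'   features. All entries must be finite; counts are expected non-negative.
#' @param cell_ids optional character vector of n unique cell identifiers;
#'   defaults to `cell_1..cell_n` (or existing rownames).
#' @param feature_ids optional character vector of d unique feature
#'   identifiers; defaults to `feature_1..feature_d` (or existing colnames).
#' @param check_nonneg error on negative entries (default `TRUE`; set
#'   `FALSE` for centered or otherwise signed data).
#' @return an object of class `"expr_matrix"`: a list with elements
#'   `values`, `cell_ids`, `feature_ids`.
#' @examples
#' a <- expr_matrix(toy_matrix_values())
#' dim(a)
#' @export
expr_matrix <- function(values, cell_ids = NULL, feature_ids = NULL,
                        check_nonneg = TRUE) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!(is.matrix(values) || inherits(values, "Matrix"))) {
    stop("'values' must be a matrix or a Matrix sparse matrix")
  }
  n <- nrow(values)
  d <- ncol(values)
  if (n < 1L || d < 1L) stop("matrix must have at least one row and column")
  ent <- if (inherits(values, "sparseMatrix")) values@x else as.vector(as.matrix(values))
  if (!is.numeric(ent) && length(ent) > 0L) stop("matrix entries must be numeric")
  if (length(ent) > 0L && any(!is.finite(ent))) {
    stop("matrix entries must all be finite")
  }
  if (check_nonneg && length(ent) > 0L && any(ent < 0)) {
    stop("negative entries found; counts must be non-negative ",
         "(use check_nonneg = FALSE for signed data)")
  }
  if (is.null(cell_ids)) {
    cell_ids <- if (!is.null(rownames(values))) rownames(values)
                else paste0("cell_", seq_len(n))
  }
  if (is.null(feature_ids)) {
    feature_ids <- if (!is.null(colnames(values))) colnames(values)
                   else paste0("feature_", seq_len(d))
  }
  cell_ids <- as.character(cell_ids)
  feature_ids <- as.character(feature_ids)
  if (length(cell_ids) != n) stop("length(cell_ids) must equal nrow(values)")
  if (length(feature_ids) != d) stop("length(feature_ids) must equal ncol(values)")
  if (anyDuplicated(cell_ids)) stop("cell_ids must be unique")
  if (anyDuplicated(feature_ids)) stop("feature_ids must be unique")
  structure(list(values = values, cell_ids = cell_ids,
                 feature_ids = feature_ids),
            class = "expr_matrix")
}

#' Coerce to an expression matrix
#'
#' Plain matrices (and Matrix sparse matrices) are wrapped with generated
#' identifiers; `expr_matrix` objects pass through.
#'
#' @param x a matrix, Matrix, or `expr_matrix`.
#' @param check_nonneg forwarded to [expr_matrix()].
#' @return an `expr_matrix`.
#' @export
as_expr_matrix <- function(x, check_nonneg = TRUE) {
  if (inherits(x, "expr_matrix")) return(x)
  expr_matrix(x, check_nonneg = check_nonneg)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
as.matrix.expr_matrix <- function(x, ...) {
  m <- as.matrix(x$values)
  dimnames(m) <- list(x$cell_ids, x$feature_ids)
  m
}

#' @export
print.expr_matrix <- function(x, ...) {
  sparse <- inherits(x$values, "sparseMatrix")
  cat(sprintf("<expr_matrix> %d cells x %d features (%s)\n",
              nrow(x$values), ncol(x$values),
              if (sparse) "sparse" else "dense"))
  cat("  cells:    ", paste(utils::head(x$cell_ids, 3L), collapse = ", "),
      if (length(x$cell_ids) > 3L) ", ..." else "", "\n", sep = "")
  cat("  features: ", paste(utils::head(x$feature_ids, 3L), collapse = ", "),
      if (length(x$feature_ids) > 3L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Column-mean centering
#'
#' Subtracts the per-feature mean from each column: `A_centered = A - 1 mu'`
#' with `mu = colMeans(A)`. Centering is optional in the DCSS workflow —
#' leverage scoring is usually run on raw counts — but gives the Frobenius
#' bound an empirical-variance interpretation.
#'
#' @param a an `expr_matrix` (or coercible matrix).
#' @return list with `centered` (an `expr_matrix`, dense, signed) and `mu`
#'   (named numeric vector of column means, length d).
#' @export
center_columns <- function(a) {
  a <- as_expr_matrix(a, check_nonneg = FALSE)
  m <- as.matrix(a)
  mu <- colMeans(m)
  centered <- sweep(m, 2L, mu, "-")
  list(centered = expr_matrix(centered, a$cell_ids, a$feature_ids,
                              check_nonneg = FALSE),
       mu = stats::setNames(mu, a$feature_ids))
}
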