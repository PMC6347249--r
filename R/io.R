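#' Read an expression matrix from disk
#'
#' Supported formats: MatrixMarket coordinate (`.mtx`, kept sparse) with
#' optional sidecar identifier files, and delimited text (`.csv`/`.tsv`)
#' with a header row of feature identifiers and a first column of cell
#' identifiers. For MTX, sidecars `<path>.rownames` and `<path>.colnames`
#' (one identifier per line) are picked up automatically when present;
#' explicit paths override. The stored orientation is cells x features;
#' use `transpose = TRUE` for features x cells dumps (common in 10x-style
#' exports) — identifiers are swapped along with the matrix.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"mtx"`, `"csv"`, or `"tsv"`.
#' @param cell_id_file,feature_id_file optional sidecar identifier files
#'   (MTX only), read after any transpose so they always describe cells
#'   and features respectively.
#' @param transpose transpose the matrix (and swap any auto-detected
#'   sidecars) on read.
#' @param allow_negative downgrade negative entries from an error to a
#'   warning.
#' @return an `expr_matrix`.
#' @export
read_matrix <- function(path, format = c("auto", "mtx", "csv", "tsv"),
                        cell_id_file = NULL, feature_id_file = NULL,
                        transpose = FALSE, allow_negative = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     mtx = "mtx",
                     csv = "csv",
                     tsv = "tsv",
                     txt = "tsv",
                     stop("cannot infer format from extension '", ext,
                          "'; pass format= explicitly"))
  }
  if (format == "mtx") {
    m <- Matrix::readMM(path)
    if (inherits(m, "nMatrix")) m <- methods::as(m, "dMatrix")  # pattern file
    m <- methods::as(m, "CsparseMatrix")
    row_side <- paste0(path, ".rownames")
    col_side <- paste0(path, ".colnames")
    if (transpose) {
      m <- Matrix::t(m)
      tmp <- row_side; row_side <- col_side; col_side <- tmp
    }
    if (is.null(cell_id_file) && file.exists(row_side)) cell_id_file <- row_side
    if (is.null(feature_id_file) && file.exists(col_side)) feature_id_file <- col_side
    cell_ids <- NULL
    feature_ids <- NULL
    if (!is.null(cell_id_file)) {
      cell_ids <- readLines(cell_id_file)
      if (length(cell_ids) != nrow(m)) {
        stop(sprintf("sidecar %s has %d identifiers but the matrix has %d rows",
                     cell_id_file, length(cell_ids), nrow(m)))
      }
    }
    if (!is.null(feature_id_file)) {
      feature_ids <- readLines(feature_id_file)
      if (length(feature_ids) != ncol(m)) {
        stop(sprintf("sidecar %s has %d identifiers but the matrix has %d columns",
                     feature_id_file, length(feature_ids), ncol(m)))
      }
    }
    if (length(m@x) && any(m@x < 0)) {
      if (allow_negative) warning("matrix contains negative entries")
      else stop("matrix contains negative entries (set allow_negative = TRUE to accept)")
    }
    return(expr_matrix(m, cell_ids, feature_ids, check_nonneg = FALSE))
  }
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("malformed header: need cell-id column plus features")
  cell_ids <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric values in matrix body")
  feature_ids <- colnames(df)[-1L]
  if (transpose) {
    vals <- t(vals)
    tmp <- cell_ids; cell_ids <- feature_ids; feature_ids <- tmp
  }
  if (any(vals < 0)) {
    if (allow_negative) warning("matrix contains negative entries")
    else stop("matrix contains negative entries (set allow_negative = TRUE to accept)")
  }
  expr_matrix(vals, cell_ids, feature_ids, check_nonneg = FALSE)
}

#' Write an expression matrix to disk
#'
#' MTX output writes MatrixMarket coordinate format plus sidecars
#' `<path>.rownames` and `<path>.colnames`; CSV/TSV writes a header row
#' of feature identifiers and a leading `cell_id` column. Round-trips
#' with [read_matrix()].
#'
#' @param a an `expr_matrix` or matrix.
#' @param path output file.
#' @param format `"auto"` (by extension), `"mtx"`, `"csv"`, or `"tsv"`.
#' @return invisibly, the paths written.
#' @export
write_matrix <- function(a, path, format = c("auto", "mtx", "csv", "tsv")) {
  format <- match.arg(format)
  a <- as_expr_matrix(a, check_nonneg = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mtx = "mtx", csv = "csv", tsv = "tsv",
                     stop("cannot infer format from extension '", ext, "'"))
  }
  if (format == "mtx") {
    sm <- methods::as(Matrix::Matrix(as.matrix(a), sparse = TRUE),
                      "CsparseMatrix")
    Matrix::writeMM(sm, path)
    writeLines(a$cell_ids, paste0(path, ".rownames"))
    writeLines(a$feature_ids, paste0(path, ".colnames"))
    return(invisible(c(path, paste0(path, ".rownames"),
                       paste0(path, ".colnames"))))
  }
  sep <- if (format == "csv") "," else "\t"
  df <- data.frame(cell_id = a$cell_ids, as.matrix(a$values),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("cell_id", a$feature_ids)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a machine-readable selection report
#'
#' Serializes a selection (and optionally a bound report) to JSON with a
#' stable key order, plus a plain-text file with one selected column
#' index per line. Machine-readable indices are 0-based, declared by the
#' `index_base` field; the R API itself is 1-based.
#'
#' @param selection a `column_selection`.
#' @param path output JSON path; the index list goes to
#'   `<path minus extension>.indices.txt`.
#' @param bound_report optional `bound_report` to embed.
#' @param seed optional seed to record.
#' @return invisibly, the two paths written.
#' @export
write_selection_report <- function(selection, path, bound_report = NULL,
                                   seed = NULL) {
  stopifnot(inherits(selection, "column_selection"))
  report <- list(
    method = selection$method,
    index_base = 0L,
    k = selection$k,
    epsilon = selection$epsilon,
    n_select = selection$size,
    d = selection$d,
    size = selection$size,
    indices = as.integer(selection$indices) - 1L,
    theta = selection$theta,
    epsilon_realized = selection$epsilon_realized,
    forced_fill = selection$forced_fill,
    threshold = selection$threshold,
    seed = seed,
    package = "dcss",
    version = as.character(utils::packageVersion("dcss")))
  report <- report[!vapply(report, is.null, logical(1L))]
  if (!is.null(bound_report)) {
    stopifnot(inherits(bound_report, "bound_report"))
    report$bounds <- list(
      loewner_lower_ok = bound_report$loewner_lower_ok,
      loewner_upper_ok = bound_report$loewner_upper_ok,
      two_sided_ok = bound_report$two_sided_ok,
      min_eigenvalue_slacks = as.list(bound_report$min_eigenvalue_slacks),
      tol = bound_report$tol,
      frobenius = bound_report$frobenius)
  }
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  txt <- paste0(tools::file_path_sans_ext(path), ".indices.txt")
  writeLines(as.character(as.integer(selection$indices) - 1L), txt)
  invisible(c(path, txt))
}
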