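#' Build a 2x2 confusion matrix with one-margin-fixed semantics
#'
#' Rows are the true diagnostic classes and columns the predicted classes
#' (the usual contingency-table orientation for classifier evaluation). The
#' row margins `n1`, `n2` are treated as fixed design quantities: each row is
#' modelled as a binomial draw of size `n_i`, which is what justifies the
#' row-binomial Bayes factor in [min_log_bayes_factor()].
#'
#' @param x A 2x2 matrix (or object coercible to one, e.g. a 2x2 data frame,
#'   or a length-4 vector read row-wise) of non-negative integer counts.
#' @param row_labels,col_labels Character vectors of length 2 naming the true
#'   and predicted classes. Defaults to `c("H", "P")` (healthy controls /
#'   patients), the conventional ordering for diagnosis.
#' @return An object of class `confusion_matrix2`: a list with the count
#'   matrix `z`, row margins `n1`, `n2`, test-set size `m`, misclassified
#'   count `e` (off-diagonal sum), and the class labels.
#' @examples
#' cm <- confusion_matrix(matrix(c(80, 10, 0, 10), 2, byrow = TRUE))
#' prediction_accuracy(cm)  # 0.9
#' @export
confusion_matrix <- function(x, row_labels = c("H", "P"), col_labels = row_labels) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.vector(x) && length(x) == 4L) x <- matrix(x, 2L, 2L, byrow = TRUE)
  if (!is.matrix(x) || !identical(dim(x), c(2L, 2L)))
    stop("confusion matrix must be 2x2 (got shape ",
         paste(dim(as.matrix(x)), collapse = "x"), ")", call. = FALSE)
  if (!is.numeric(x) || anyNA(x) || any(x != round(x)))
    stop("confusion matrix cells must be integers", call. = FALSE)
  if (any(x < 0))
    stop("confusion matrix cells must be non-negative", call. = FALSE)
  if (sum(x) < 1)
    stop("empty confusion matrix: the test set must contain at least one example",
         call. = FALSE)
  stopifnot(length(row_labels) == 2L, length(col_labels) == 2L)
  z <- matrix(as.numeric(x), 2L, 2L,
              dimnames = list(true = as.character(row_labels),
                              predicted = as.character(col_labels)))
  structure(
    list(z = z,
         n1 = sum(z[1L, ]), n2 = sum(z[2L, ]),
         m = sum(z), e = z[1L, 2L] + z[2L, 1L],
         row_labels = as.character(row_labels),
         col_labels = as.character(col_labels)),
    class = "confusion_matrix2")
}

#' @export
print.confusion_matrix2 <- function(x, ...) {
  cat("2x2 confusion matrix (rows = true, cols = predicted), m =", x$m, "\n")
  print(x$z)
  invisible(x)
}

#' @export
as.matrix.confusion_matrix2 <- function(x, ...) x$z

is_confusion_matrix <- function(x) inherits(x, "confusion_matrix2")

assert_cm <- function(cm) {
  if (!is_confusion_matrix(cm))
    stop("expected a 'confusion_matrix2' object; see confusion_matrix()",
         call. = FALSE)
  invisible(cm)
}

#' Read a 2x2 confusion matrix from CSV/TSV/JSON
#'
#' CSV/TSV files are headerless 2x2 integer tables. JSON files use the schema
#' `{"matrix": [[..],[..]], "row_labels": [..], "col_labels": [..]}` (labels
#' optional). The file orientation is taken as rows = true classes,
#' columns = predicted classes.
#'
#' @param path Path to a `.csv`, `.tsv`/`.txt` or `.json` file.
#' @param row_labels,col_labels Default labels used when the file carries none.
#' @return A [confusion_matrix()] object.
#' @export
read_confusion_matrix <- function(path, row_labels = c("H", "P"),
                                  col_labels = row_labels) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- jsonlite::fromJSON(path)
    if (is.null(obj$matrix))
      stop("JSON confusion matrix must have a 'matrix' field", call. = FALSE)
    if (!is.null(obj$row_labels)) row_labels <- obj$row_labels
    if (!is.null(obj$col_labels)) col_labels <- obj$col_labels
    return(confusion_matrix(obj$matrix, row_labels, col_labels))
  }
  sep <- if (ext == "csv") "," else "\t"
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) != 2L)
    stop("confusion matrix file must have exactly 2 rows (got ",
         length(lines), ")", call. = FALSE)
  cells <- lapply(strsplit(lines, sep, fixed = TRUE), trimws)
  if (any(lengths(cells) != 2L))
    stop("confusion matrix file must have exactly 2 columns per row",
         call. = FALSE)
  vals <- suppressWarnings(as.numeric(unlist(cells)))
  if (anyNA(vals))
    stop("confusion matrix cells must be integers (non-numeric cell found)",
         call. = FALSE)
  confusion_matrix(matrix(vals, 2L, 2L, byrow = TRUE), row_labels, col_labels)
}
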