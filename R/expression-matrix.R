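#' Construct an expression matrix
#'
#' An `expression_matrix` is a numeric matrix of expression levels with rows
#' holding experimental conditions (or samples) and columns holding genes.
#' Row and column identifiers are carried as `dimnames`; missing identifiers
#' are auto-generated positional names (`cond1..I`, `gene1..J`).
#'
#' @param values Numeric matrix (or object coercible to one) of shape I x J.
#'   All entries must be finite.
#' @param row_ids Optional character vector of condition/sample labels
#'   (length I).
#' @param col_ids Optional character vector of gene labels (length J).
#' @return A numeric matrix of class `expression_matrix`.
#' @examples
#' m <- expression_matrix(matrix(c(1, 3, 2, 5), 2, 2))
#' msr(m)
#' @export
expression_matrix <- function(values, row_ids = NULL, col_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("expression matrix must have at least 1 row and 1 column")
  }
  if (!all(is.finite(values))) {
    stop("expression matrix entries must all be finite")
  }
  if (is.null(row_ids)) {
    row_ids <- rownames(values)
    if (is.null(row_ids)) row_ids <- paste0("cond", seq_len(nrow(values)))
  }
  if (is.null(col_ids)) {
    col_ids <- colnames(values)
    if (is.null(col_ids)) col_ids <- paste0("gene", seq_len(ncol(values)))
  }
  if (length(row_ids) != nrow(values)) {
    stop("row_ids length (", length(row_ids), ") != number of rows (",
         nrow(values), ")")
  }
  if (length(col_ids) != ncol(values)) {
    stop("col_ids length (", length(col_ids), ") != number of columns (",
         ncol(values), ")")
  }
  dimnames(values) <- list(as.character(row_ids), as.character(col_ids))
  class(values) <- c("expression_matrix", class(values))
  values
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d conditions x %d genes\n",
              nrow(x), ncol(x)))
  print(unclass(x), ...)
  invisible(x)
}

is_expression_matrix <- function(x) inherits(x, "expression_matrix")

as_plain_matrix <- function(m) {
  class(m) <- "matrix"
  m
}

#' Construct a bicluster index pair
#'
#' A bicluster selects a submatrix of a parent expression matrix by a subset
#' of rows (conditions) and a subset of columns (genes).  Indices are
#' 1-based, stored sorted and must be unique; bounds are checked against the
#' parent on extraction.
#'
#' @param rows Integer vector of row indices (>= 1, unique, non-empty).
#' @param cols Integer vector of column indices (>= 1, unique, non-empty).
#' @return An object of class `bicluster` with fields `rows` and `cols`.
#' @examples
#' b <- bicluster(rows = c(1, 2), cols = 2)
#' @export
bicluster <- function(rows, cols) {
  rows <- as.integer(rows)
  cols <- as.integer(cols)
  if (length(rows) < 1L || length(cols) < 1L) {
    stop("a bicluster needs at least 1 row and 1 column")
  }
  if (anyNA(rows) || anyNA(cols) || any(rows < 1L) || any(cols < 1L)) {
    stop("bicluster indices must be positive integers")
  }
  if (anyDuplicated(rows) || anyDuplicated(cols)) {
    stop("bicluster indices must be unique")
  }
  structure(list(rows = sort(rows), cols = sort(cols)), class = "bicluster")
}

#' @export
print.bicluster <- function(x, ...) {
  cat(sprintf("bicluster: %d rows x %d cols\n",
              length(x$rows), length(x$cols)))
  cat(" rows:", paste(x$rows, collapse = ","), "\n")
  cat(" cols:", paste(x$cols, collapse = ","), "\n")
  invisible(x)
}

#' Construct a gene subset mask
#'
#' A gene subset is a boolean mask over the M genes of a dataset; `R`, the
#' number of selected genes, is derived from the mask.
#'
#' @param mask Logical vector of length M (no NA).
#' @return Object of class `gene_subset` with fields `mask` and `R`.
#' @examples
#' x <- gene_subset(c(TRUE, FALSE, TRUE))
#' x$R  # 2
#' @export
gene_subset <- function(mask) {
  mask <- as.logical(mask)
  if (length(mask) < 1L || anyNA(mask)) {
    stop("mask must be a logical vector without NA")
  }
  structure(list(mask = mask, R = sum(mask)), class = "gene_subset")
}

#' @export
print.gene_subset <- function(x, ...) {
  cat(sprintf("gene_subset: %d of %d genes selected\n",
              x$R, length(x$mask)))
  invisible(x)
}

#' Construct a labeled classification dataset
#'
#' Couples an expression matrix whose rows are the N samples and whose
#' columns are the M genes with one class label per sample.  At least two
#' classes are required for classification use.
#'
#' @param matrix An [expression_matrix()] with I = N samples, J = M genes.
#' @param labels Vector (coerced to factor) of class labels, length N.
#' @return Object of class `labeled_dataset` with fields `matrix`, `labels`.
#' @export
labeled_dataset <- function(matrix, labels) {
  if (!is_expression_matrix(matrix)) matrix <- expression_matrix(matrix)
  labels <- as.factor(labels)
  if (length(labels) != nrow(matrix)) {
    stop("labels length (", length(labels), ") != number of samples (",
         nrow(matrix), ")")
  }
  structure(list(matrix = matrix, labels = labels),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("labeled_dataset: %d samples x %d genes, %d classes\n",
              nrow(x$matrix), ncol(x$matrix), nlevels(x$labels)))
  invisible(x)
}

#' Read an expression matrix from delimited text
#'
#' Canonical on-disk format is TSV with one optional header row of gene ids
#' and one optional leading column of condition ids.  With
#' `header = "auto"` / `row_ids = "auto"` their presence is detected from
#' whether the corresponding cells parse as numbers.
#'
#' @param path Path to the delimited text file.
#' @param delimiter Field delimiter, default tab.
#' @param header `"auto"`, `TRUE` or `FALSE`: is the first row a header of
#'   gene ids?
#' @param row_ids `"auto"`, `TRUE` or `FALSE`: is the first column a column
#'   of condition ids?
#' @return An [expression_matrix()].
#' @export
read_matrix <- function(path, delimiter = "\t", header = "auto",
                        row_ids = "auto") {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty matrix file: ", path)
  cells <- strsplit(lines, delimiter, fixed = TRUE)

  is_num <- function(x) !is.na(suppressWarnings(as.numeric(x)))

  has_rowids <- if (identical(row_ids, "auto")) {
    # first column non-numeric in the data body => leading id column
    body_first <- vapply(cells[-1], function(r) r[[1L]], "")
    length(cells) > 1L && !all(is_num(body_first))
  } else isTRUE(row_ids)
  has_header <- if (identical(header, "auto")) {
    first <- cells[[1L]]
    probe <- if (has_rowids && length(first) > 1L) first[-1L] else first
    !all(is_num(probe))
  } else isTRUE(header)

  col_names <- NULL
  if (has_header) {
    col_names <- cells[[1L]]
    cells <- cells[-1L]
    if (length(cells) == 0L) stop("header but no data rows in ", path)
  }
  row_names <- NULL
  if (has_rowids) {
    row_names <- vapply(cells, function(r) r[[1L]], "")
    cells <- lapply(cells, function(r) r[-1L])
    if (!is.null(col_names) && length(col_names) == length(cells[[1L]]) + 1L) {
      col_names <- col_names[-1L]  # header included a corner cell
    }
  }

  widths <- lengths(cells)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1L])[1L]
    stop(sprintf("ragged row at line %d: %d fields, expected %d",
                 bad + has_header, widths[bad], widths[1L]))
  }
  J <- widths[1L]
  values <- matrix(NA_real_, nrow = length(cells), ncol = J)
  for (i in seq_along(cells)) {
    v <- suppressWarnings(as.numeric(cells[[i]]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1L]
      stop(sprintf("non-numeric cell at row %d, column %d: '%s'",
                   i, j, cells[[i]][j]))
    }
    values[i, ] <- v
  }
  expression_matrix(values, row_ids = row_names, col_ids = col_names)
}

#' Write an expression matrix to delimited text
#'
#' Writes a header row of gene ids and a leading column of condition ids.
#' Numbers use 17 significant digits so that [read_matrix()] round-trips
#' values to full double precision and ids exactly.
#'
#' @param m An [expression_matrix()].
#' @param path Output path.
#' @param delimiter Field delimiter, default tab.
#' @return Invisibly, `path`.
#' @export
write_matrix <- function(m, path, delimiter = "\t") {
  if (!is_expression_matrix(m)) m <- expression_matrix(m)
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open for writing: ", path, " (", conditionMessage(e), ")")
  })
  on.exit(close(con))
  fmt <- function(x) sprintf("%.17g", x)
  writeLines(paste(c("id", colnames(m)), collapse = delimiter), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(c(rownames(m)[i], fmt(m[i, ])), collapse = delimiter),
               con)
  }
  invisible(path)
}

#' Extract the submatrix selected by a bicluster
#'
#' Entry (p, q) of the result equals `m[rows[p], cols[q]]`; raw index
#' vectors are taken in the order given, so permuting them permutes the
#' result accordingly.
#'
#' @param m An [expression_matrix()].
#' @param b A [bicluster()], or a list with integer fields `rows`, `cols`.
#' @return An [expression_matrix()] of shape `length(rows) x length(cols)`.
#' @export
extract_submatrix <- function(m, b) {
  if (!is_expression_matrix(m)) m <- expression_matrix(m)
  rows <- as.integer(b$rows)
  cols <- as.integer(b$cols)
  if (any(rows < 1L) || any(rows > nrow(m))) {
    stop("bicluster row index out of range [1, ", nrow(m), "]")
  }
  if (any(cols < 1L) || any(cols > ncol(m))) {
    stop("bicluster column index out of range [1, ", ncol(m), "]")
  }
  expression_matrix(unclass(m)[rows, cols, drop = FALSE])
}

#' Read a two-column labels file and join it to a matrix
#'
#' The labels file is a two-column TSV (`sample_id`, `class`), with an
#' optional header; sample ids must match the matrix row ids.
#'
#' @param m An [expression_matrix()] with samples as rows.
#' @param path Path to the labels TSV.
#' @param delimiter Field delimiter, default tab.
#' @return A [labeled_dataset()].
#' @export
read_labeled_dataset <- function(m, path, delimiter = "\t") {
  if (!file.exists(path)) stop("labels file does not exist: ", path)
  tab <- utils::read.table(path, sep = delimiter, header = FALSE,
                           colClasses = "character")
  if (ncol(tab) != 2L) stop("labels file must have exactly 2 columns")
  if (identical(tolower(tab[1L, 1L]), "sample_id")) tab <- tab[-1L, ]
  lab <- stats::setNames(tab[[2L]], tab[[1L]])
  missing <- setdiff(rownames(m), names(lab))
  if (length(missing) > 0L) {
    stop("labels missing for samples: ", paste(missing, collapse = ", "))
  }
  labeled_dataset(m, lab[rownames(m)])
}

#' Write labels of a labeled dataset to a two-column TSV
#'
#' @param d A [labeled_dataset()].
#' @param path Output path.
#' @param delimiter Field delimiter, default tab.
#' @return Invisibly, `path`.
#' @export
write_labels <- function(d, path, delimiter = "\t") {
  utils::write.table(
    data.frame(sample_id = rownames(d$matrix),
               class = as.character(d$labels)),
    path, sep = delimiter, quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  invisible(path)
}
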