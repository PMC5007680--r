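#' Mean squared residue of an expression (sub)matrix
#'
#' For a matrix B with I rows (conditions) and J columns (genes) the residue
#' of each cell is
#' \deqn{r_{ij} = b_{ij} - \bar b_{i.} - \bar b_{.j} + \bar b_{..}}
#' where \eqn{\bar b_{i.}} are the row means, \eqn{\bar b_{.j}} the column
#' means and \eqn{\bar b_{..}} the mean of the entire matrix.  The mean
#' squared residue is
#' \deqn{MSR = \frac{1}{IJ}\sum_{ij} r_{ij}^2,}
#' non-negative, zero exactly for additive matrices
#' \eqn{b_{ij} = a_i + c_j}, and lower for more coherent biclusters.
#'
#' @param m An [expression_matrix()] or plain numeric matrix.
#' @return `msr()` returns the scalar MSR.  `msr_breakdown()` returns a list
#'   of class `msr_breakdown` with all intermediates: `row_sums`,
#'   `col_sums`, `total_sum`, `row_means`, `col_means`, `overall_mean`,
#'   `residues` and `msr`.
#' @examples
#' m <- expression_matrix(matrix(c(1, 3, 2, 5), 2, 2))
#' msr(m)           # 0.0625
#' msr_breakdown(m)$residues
#' @export
msr <- function(m) {
  msr_breakdown(m)$msr
}

#' @rdname msr
#' @export
msr_breakdown <- function(m) {
  if (!is_expression_matrix(m)) m <- expression_matrix(m)
  v <- as_plain_matrix(m)
  I <- nrow(v)
  J <- ncol(v)
  row_sums <- rowSums(v)
  col_sums <- colSums(v)
  total_sum <- sum(row_sums)
  row_means <- row_sums / J
  col_means <- col_sums / I
  overall_mean <- total_sum / (I * J)
  residues <- v - outer(row_means, rep(1, J)) -
    outer(rep(1, I), col_means) + overall_mean
  structure(
    list(row_sums = row_sums, col_sums = col_sums, total_sum = total_sum,
         row_means = row_means, col_means = col_means,
         overall_mean = overall_mean, residues = residues,
         msr = sum(residues^2) / (I * J)),
    class = "msr_breakdown")
}

#' @export
print.msr_breakdown <- function(x, ...) {
  cat(sprintf("msr_breakdown: %d x %d, MSR = %g\n",
              length(x$row_means), length(x$col_means), x$msr))
  invisible(x)
}

#' Row means of an expression matrix
#'
#' @param m An [expression_matrix()] or numeric matrix.
#' @return Numeric vector of length I; entry i is the mean of row i.
#' @export
msr_row_means <- function(m) msr_breakdown(m)$row_means

#' Column means of an expression matrix
#'
#' @inheritParams msr_row_means
#' @return Numeric vector of length J; entry j is the mean of column j.
#' @export
msr_col_means <- function(m) msr_breakdown(m)$col_means

#' Mean of the entire expression matrix
#'
#' @inheritParams msr_row_means
#' @return Scalar; the grand mean over all I*J cells.
#' @export
msr_overall_mean <- function(m) msr_breakdown(m)$overall_mean

#' Residue matrix of an expression matrix
#'
#' @inheritParams msr_row_means
#' @return I x J numeric matrix of residues; every row and every column sums
#'   to zero (up to rounding).
#' @export
msr_residues <- function(m) msr_breakdown(m)$residues

#' Mean squared residue of a bicluster within a parent matrix
#'
#' Equivalent to `msr(extract_submatrix(parent, b))`.
#'
#' @param parent Parent [expression_matrix()].
#' @param b A [bicluster()] within the parent's bounds.
#' @return Scalar MSR of the selected submatrix.
#' @export
msr_of_bicluster <- function(parent, b) {
  msr(extract_submatrix(parent, b))
}
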