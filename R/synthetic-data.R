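#' Specification of a planted bicluster
#'
#' Describes a parent matrix of i.i.d. standard normal background with one
#' planted submatrix.  Structures: `"constant"` replaces planted cells by
#' `signal + noise`; `"additive"` replaces them by `a_i + c_j + noise` with
#' row and column effects drawn from `N(0, signal^2)`; `"shifted"` adds the
#' constant `signal` on top of the background values.
#'
#' @param I,J Parent matrix shape.
#' @param rows,cols Planted row and column index sets (within bounds).
#' @param structure `"constant"`, `"additive"` or `"shifted"`.
#' @param signal Signal magnitude: the constant level, the SD of the row and
#'   column effects, or the shift, respectively (default 10).
#' @param noise_sd Within-bicluster noise SD (default 1; >= 0).
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return Object of class `plant_spec`.
#' @export
plant_spec <- function(I, J, rows, cols,
                       structure = c("additive", "constant", "shifted"),
                       signal = 10, noise_sd = 1, seed = 1L) {
  structure_kind <- match.arg(structure)
  I <- as.integer(I); J <- as.integer(J)
  rows <- sort(unique(as.integer(rows)))
  cols <- sort(unique(as.integer(cols)))
  if (I < 1L || J < 1L) stop("parent shape must be at least 1x1")
  if (length(rows) < 1L || any(rows < 1L) || any(rows > I)) {
    stop("planted rows out of bounds [1, ", I, "]")
  }
  if (length(cols) < 1L || any(cols < 1L) || any(cols > J)) {
    stop("planted cols out of bounds [1, ", J, "]")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  base::structure(
    list(I = I, J = J, rows = rows, cols = cols,
         structure = structure_kind, signal = signal,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "plant_spec")
}

#' Generate an expression matrix with a planted bicluster
#'
#' Background cells are i.i.d. N(0, 1); planted cells follow the spec's
#' structure.  Identical specs (seed included) give identical matrices.
#'
#' @param spec A [plant_spec()].
#' @return List with `matrix` (an [expression_matrix()]) and `bicluster`
#'   (the ground-truth [bicluster()]).
#' @examples
#' sp <- plant_spec(10, 10, 1:4, 1:4, "additive", signal = 5, noise_sd = 0)
#' out <- make_bicluster_matrix(sp)
#' msr_of_bicluster(out$matrix, out$bicluster)  # exactly 0
#' @export
make_bicluster_matrix <- function(spec) {
  stopifnot(inherits(spec, "plant_spec"))
  with_seed(spec$seed, {
    values <- matrix(stats::rnorm(spec$I * spec$J), spec$I, spec$J)
    nr <- length(spec$rows)
    nc <- length(spec$cols)
    noise <- matrix(stats::rnorm(nr * nc, sd = spec$noise_sd), nr, nc)
    block <- switch(spec$structure,
      constant = spec$signal + noise,
      additive = outer(stats::rnorm(nr, sd = spec$signal),
                       stats::rnorm(nc, sd = spec$signal), `+`) + noise,
      shifted = values[spec$rows, spec$cols, drop = FALSE] + spec$signal)
    values[spec$rows, spec$cols] <- block
    list(matrix = expression_matrix(values),
         bicluster = bicluster(spec$rows, spec$cols))
  })
}

#' Generate a two-class microarray-like dataset with informative genes
#'
#' Produces a balanced two-class dataset of N samples by M genes: all genes
#' are N(0, noise_sd^2) noise except k informative genes whose class means
#' differ by `effect * noise_sd`.  Identical arguments give identical data.
#'
#' @param N Number of samples (even, >= 4; N/2 per class).
#' @param M Total number of genes (>= 1).
#' @param k Number of informative genes, 1 <= k <= M.
#' @param effect Between-class mean shift of informative genes, in units of
#'   the noise SD.
#' @param seed Integer seed.
#' @param noise_sd Noise standard deviation (default 1).
#' @return List with `dataset` (a [labeled_dataset()]), `subset` (the
#'   ground-truth [gene_subset()]) and `informative` (the gene indices).
#' @export
make_classification_dataset <- function(N, M, k, effect, seed = 1L,
                                        noise_sd = 1) {
  N <- as.integer(N); M <- as.integer(M); k <- as.integer(k)
  if (is.na(N) || N < 4L || N %% 2L != 0L) {
    stop("N must be an even integer >= 4 (balanced classes)")
  }
  if (is.na(M) || M < 1L) stop("M must be >= 1")
  if (is.na(k) || k < 1L || k > M) stop("k must satisfy 1 <= k <= M")
  with_seed(seed, {
    informative <- sort(sample.int(M, k))
    values <- matrix(stats::rnorm(N * M, sd = noise_sd), N, M)
    labels <- rep(c("classA", "classB"), each = N %/% 2L)
    shift <- effect * noise_sd
    values[labels == "classB", informative] <-
      values[labels == "classB", informative] + shift
    m <- expression_matrix(values,
                           row_ids = paste0("sample", seq_len(N)),
                           col_ids = paste0("gene", seq_len(M)))
    mask <- logical(M)
    mask[informative] <- TRUE
    list(dataset = labeled_dataset(m, labels),
         subset = gene_subset(mask),
         informative = informative)
  })
}
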