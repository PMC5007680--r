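test_that("read_matrix parses plain bodies, headers and id columns", {
  path <- withr::local_tempfile(fileext = ".tsv")

  writeLines(c("1\t2", "3\t5"), path)
  m <- read_matrix(path)
  expect_s3_class(m, "expression_matrix")
  expect_identical(dim(m), c(2L, 2L))
  expect_equal(unclass(m), matrix(c(1, 3, 2, 5), 2, 2),
               ignore_attr = TRUE)

  writeLines(c("g1\tg2", "1\t2"), path)
  m <- read_matrix(path)
  expect_identical(colnames(m), c("g1", "g2"))
  expect_identical(nrow(m), 1L)

  writeLines(c("id\tg1\tg2", "condA\t1\t2", "condB\t3\t5"), path)
  m <- read_matrix(path)
  expect_identical(rownames(m), c("condA", "condB"))
  expect_identical(colnames(m), c("g1", "g2"))

  # comma-delimited via the delimiter flag
  writeLines(c("1,2", "3,5"), path)
  expect_equal(unclass(read_matrix(path, delimiter = ",")),
               matrix(c(1, 3, 2, 5), 2, 2), ignore_attr = TRUE)
})

test_that("read_matrix reports ragged rows and non-numeric cells by position", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("1\t2\t3", "4\t5"), path)
  expect_error(read_matrix(path), "ragged row at line 2")

  writeLines(c("1\t2", "3\txyz"), path)
  expect_error(read_matrix(path), "row 2, column 2")

  expect_error(read_matrix(file.path(tempdir(), "no-such-file.tsv")),
               "does not exist")
})

test_that("write_matrix round-trips values to full precision and ids exactly", {
  path <- withr::local_tempfile(fileext = ".tsv")
  set.seed(42)
  for (rep in 1:10) {
    I <- sample(1:8, 1)
    J <- sample(1:8, 1)
    m <- expression_matrix(matrix(rnorm(I * J) * 10^sample(-8:8, 1), I, J),
                           row_ids = paste0("c", seq_len(I)),
                           col_ids = paste0("g", seq_len(J)))
    write_matrix(m, path)
    back <- read_matrix(path)
    expect_identical(unclass(back), unclass(m))
  }
  # negative values and the 1x1 single-cell file
  m <- expression_matrix(matrix(-pi, 1, 1))
  write_matrix(m, path)
  expect_identical(unclass(read_matrix(path)), unclass(m))
})

test_that("expression_matrix and friends enforce their invariants", {
  expect_error(expression_matrix(matrix(c(1, NA), 1, 2)), "finite")
  expect_error(expression_matrix(matrix(Inf, 1, 1)), "finite")
  expect_error(expression_matrix(matrix(1, 1, 1), row_ids = c("a", "b")),
               "row_ids")
  expect_error(bicluster(integer(0), 1), "at least 1")
  expect_error(bicluster(c(1, 1), 2), "unique")
  expect_error(bicluster(0, 1), "positive")
  expect_error(gene_subset(c(TRUE, NA)), "NA")
  expect_identical(gene_subset(c(TRUE, FALSE, TRUE))$R, 2L)
  expect_error(labeled_dataset(matrix(1:4, 2, 2), c("a")), "labels length")
})

test_that("extract_submatrix follows indices, is identity on full sets", {
  m <- expression_matrix(matrix(c(1, 3, 2, 5), 2, 2))
  expect_equal(unclass(extract_submatrix(m, bicluster(1, 2))),
               matrix(2, 1, 1), ignore_attr = TRUE)
  expect_equal(unclass(extract_submatrix(m, bicluster(2, c(1, 2)))),
               matrix(c(3, 5), 1, 2), ignore_attr = TRUE)
  expect_identical(unclass(extract_submatrix(m, bicluster(1:2, 1:2))),
                   unclass(m))
  expect_error(extract_submatrix(m, bicluster(3, 1)), "out of range")

  # permuting raw index lists permutes the extracted entries accordingly
  set.seed(7)
  big <- expression_matrix(rand_mat(6, 5))
  rows <- c(4, 1, 5)
  cols <- c(3, 5, 1, 2)
  sub <- extract_submatrix(big, list(rows = rows, cols = cols))
  for (p in seq_along(rows)) {
    for (q in seq_along(cols)) {
      expect_identical(sub[p, q], big[rows[p], cols[q]])
    }
  }
})

test_that("labels round-trip through the two-column TSV format", {
  ds <- make_classification_dataset(N = 8, M = 5, k = 2, effect = 2,
                                    seed = 3)
  mpath <- withr::local_tempfile(fileext = ".tsv")
  lpath <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(ds$dataset$matrix, mpath)
  write_labels(ds$dataset, lpath)
  back <- read_labeled_dataset(read_matrix(mpath), lpath)
  expect_identical(as.character(back$labels), as.character(ds$dataset$labels))
  expect_identical(unclass(back$matrix), unclass(ds$dataset$matrix))
})
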