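test_that("subset_fitness evaluates F(x) exactly and checks its domain", {
  cfg <- selection_config(0.75, 0.25, M = 100)
  expect_equal(subset_fitness(1.0, 0, cfg), 1.0)
  expect_equal(subset_fitness(0.8, 25, cfg), 0.7875)  # 0.75*0.8 + 0.25*0.75

  cfg0 <- selection_config(0.6, 0, M = 100)
  for (R in c(0, 50, 100)) {
    expect_equal(subset_fitness(0.5, R, cfg0), 0.6 * 0.5)
  }

  expect_error(subset_fitness(1.2, 0, cfg), "\\[0, 1\\]")
  expect_error(subset_fitness(-0.1, 0, cfg), "\\[0, 1\\]")
  expect_error(subset_fitness(0.5, 101, cfg), "0 <= R <= M")
  expect_error(selection_config(-1, 0.5, 10), "non-negative")
})

test_that("F is bounded by w1 + w2 and monotone in A and R", {
  set.seed(5)
  for (rep in 1:50) {
    w1 <- runif(1, 0, 2)
    w2 <- runif(1, 0, 2)
    M <- sample(1:500, 1)
    cfg <- selection_config(w1, w2, M)
    A <- runif(1)
    R <- sample(0:M, 1)
    f <- subset_fitness(A, R, cfg)
    expect_gte(f, 0)
    expect_lte(f, w1 + w2 + 1e-12)
    if (R < M && w2 > 0) {
      expect_lt(subset_fitness(A, R + 1, cfg), f)
    }
    if (A <= 0.9 && w1 > 0) {
      expect_gt(subset_fitness(A + 0.1, R, cfg), f)
    }
  }
})

test_that("LOOCV on a hand-enumerable 4-sample problem is exact", {
  # one selected gene, values 0,0,10,10, labels A,A,B,B: every fold trains
  # on centroids that keep the held-out sample on its own side.
  m <- expression_matrix(matrix(c(0, 0, 10, 10), ncol = 1))
  d <- labeled_dataset(m, c("A", "A", "B", "B"))
  res <- loocv_accuracy(d, gene_subset(TRUE))
  expect_equal(res$A, 1.0)
  expect_identical(res$per_fold, rep(TRUE, 4))
})

test_that("LOOCV is deterministic and validates its preconditions", {
  ds <- make_classification_dataset(N = 12, M = 20, k = 3, effect = 2,
                                    seed = 9)
  x <- ds$subset
  r1 <- loocv_accuracy(ds$dataset, x)
  r2 <- loocv_accuracy(ds$dataset, x)
  expect_identical(r1$per_fold, r2$per_fold)

  expect_error(loocv_accuracy(ds$dataset, gene_subset(rep(FALSE, 20))),
               "no genes selected")
  expect_error(loocv_accuracy(ds$dataset, gene_subset(rep(TRUE, 3))),
               "mask length")
  one_class <- labeled_dataset(ds$dataset$matrix, rep("A", 12))
  expect_error(loocv_accuracy(one_class, x), "2 classes")
})

test_that("nearest-centroid breaks ties toward the first sorted class", {
  clf <- nearest_centroid_classifier()
  model <- clf$train(matrix(c(2, 0), ncol = 1), c("zeta", "alpha"))
  # test point 1 is equidistant from both centroids
  expect_identical(clf$predict(model, matrix(1, 1, 1)), "alpha")
})

test_that("informative subsets dominate noise subsets on planted data", {
  for (seed in 1:5) {
    ds <- make_classification_dataset(N = 20, M = 40, k = 5, effect = 4,
                                      seed = seed)
    noise_mask <- !ds$subset$mask
    noise_mask[which(noise_mask)[-(1:5)]] <- FALSE  # 5 pure-noise genes
    a_inf <- loocv_accuracy(ds$dataset, ds$subset)$A
    a_noise <- loocv_accuracy(ds$dataset, gene_subset(noise_mask))$A
    expect_gte(a_inf, a_noise)
  }
})

test_that("label permutation on structureless data gives chance-level accuracy", {
  accs <- vapply(1:20, function(seed) {
    ds <- make_classification_dataset(N = 20, M = 10, k = 1, effect = 0,
                                      seed = seed)
    loocv_accuracy(ds$dataset, gene_subset(rep(TRUE, 10)))$A
  }, 0)
  expect_gt(mean(accs), 0.25)
  expect_lt(mean(accs), 0.75)
})

test_that("evaluate_subset composes LOOCV accuracy with the weighted fitness", {
  ds <- make_classification_dataset(N = 20, M = 30, k = 4, effect = 6,
                                    seed = 2)
  # perfectly separable planted subset, w1=1, w2=0 -> F = A = 1
  cfg <- selection_config(1, 0, M = 30)
  expect_equal(evaluate_subset(ds$dataset, ds$subset, cfg), 1.0)

  # selecting all M genes zeroes the size reward: F = w1 * A
  cfg2 <- selection_config(0.75, 0.25, M = 30)
  all_genes <- gene_subset(rep(TRUE, 30))
  A_all <- loocv_accuracy(ds$dataset, all_genes)$A
  expect_equal(evaluate_subset(ds$dataset, all_genes, cfg2), 0.75 * A_all)

  expect_error(evaluate_subset(ds$dataset, ds$subset,
                               selection_config(M = 10)),
               "cfg\\$M")
})
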