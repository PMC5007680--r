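test_that("step counts are 6 (partial) and 5 (full) for every matrix size", {
  sizes <- list(c(2, 3), c(4, 4), c(8, 8), c(16, 8), c(5, 7), c(3, 2))
  for (sz in sizes) {
    expect_identical(
      schedule_steps(build_msr_schedule(circuit_version("partial", sz[1], sz[2]))),
      6L)
    expect_identical(
      schedule_steps(build_msr_schedule(circuit_version("full", sz[1], sz[2]))),
      5L)
  }
})

test_that("operator requirements follow the per-version scaling rules", {
  f88 <- operator_requirements(circuit_version("partial", 8, 8))
  expect_identical(unlist(f88[c("adders", "multipliers", "dividers",
                                "converters")]),
                   c(adders = 8L, multipliers = 8L, dividers = 8L,
                     converters = 8L))
  a44 <- operator_requirements(circuit_version("full", 4, 4))
  expect_true(all(unlist(a44[1:4]) == 16L))
  a23 <- operator_requirements(circuit_version("full", 2, 3))
  expect_true(all(unlist(a23[1:4]) == 6L))
  f168 <- operator_requirements(circuit_version("partial", 16, 8))
  expect_true(all(unlist(f168[1:4]) == 16L))  # max(I, J) rule
  gs <- operator_requirements(circuit_version("gene-selection"))
  expect_true(all(unlist(gs[1:4]) == 1L))
})

test_that("per-step operator usage never exceeds each version's own budget", {
  versions <- c("f4x4", "f8x8", "f16x8", "f16x16", "f30x50", "f32x64",
                "a4x4", "a5x5")
  for (nm in versions) {
    v <- parse_circuit_name(nm)$version
    trace <- build_msr_schedule(v)
    usage <- schedule_usage(trace)
    req <- operator_requirements(v)
    for (op in c("add", "mul", "div", "conv")) {
      budget <- switch(op, add = req$adders, mul = req$multipliers,
                       div = req$dividers, conv = req$converters)
      expect_true(all(usage[, op] <= budget),
                  label = paste(nm, op, "usage within budget"))
    }
  }
  gs <- build_selection_schedule()
  expect_true(all(schedule_usage(gs) <= 1))
})

test_that("insufficient budgets fail with the step and shortfall named", {
  v <- circuit_version("full", 4, 4)
  small <- operator_budget(8, 16, 16, 16)
  expect_error(build_msr_schedule(v, small),
               "step 4 \\(residues\\).*needs I\\*J = 16 adders, have 8")
  vp <- circuit_version("partial", 4, 4)
  expect_error(build_msr_schedule(vp, operator_budget(4, 4, 4, 0)),
               "insufficient conv budget at step 1")
})

test_that("traces are dependency-sound and the validator rejects violations", {
  for (trace in list(build_msr_schedule(circuit_version("partial", 3, 4)),
                     build_msr_schedule(circuit_version("full", 3, 4)),
                     build_selection_schedule())) {
    expect_true(validate_schedule(trace))
  }
  bad <- build_selection_schedule()
  # move the conversion of M - R into step 1, where M - R is produced
  bad$steps[[1]] <- c(bad$steps[[1]], bad$steps[[2]])
  bad$steps[[2]] <- NULL
  expect_error(validate_schedule(bad), "reads same-step output: MmR")
})

test_that("the gene-selection schedule matches the printed architecture", {
  trace <- build_selection_schedule()
  expect_identical(schedule_steps(trace), 4L)
  expect_identical(step_widths(trace)[1], 3L)  # three parallel operations
  ops_used <- unique(unlist(lapply(trace$steps,
                                   function(s) lapply(s, function(g) names(g$ops)))))
  expect_setequal(ops_used, c("add", "mul", "div", "conv"))  # 4 operator types

  got <- execute_schedule(trace,
                          list(w1 = 0.75, A = 0.8, w2 = 0.25, M = 100,
                               R = 25))$value
  expect_equal(got, 0.7875)
  expect_equal(got,
               subset_fitness(0.8, 25, selection_config(0.75, 0.25, 100)))
})

test_that("executing a trace reproduces the direct fitness value exactly", {
  set.seed(101)
  for (rep in 1:30) {
    I <- sample(2:8, 1)
    J <- sample(2:8, 1)
    v <- rand_mat(I, J)
    direct <- msr(expression_matrix(v))
    for (model in c("partial", "full")) {
      trace <- build_msr_schedule(circuit_version(model, I, J))
      expect_lt(rel_diff(execute_schedule(trace, v)$value, direct), 1e-12)
    }
  }
  trace <- build_selection_schedule()
  for (rep in 1:30) {
    w1 <- runif(1)
    w2 <- runif(1)
    M <- sample(10:1000, 1)
    R <- sample(0:M, 1)
    A <- runif(1)
    expect_lt(rel_diff(
      execute_schedule(trace, list(w1 = w1, A = A, w2 = w2, M = M,
                                   R = R))$value,
      subset_fitness(A, R, selection_config(w1, w2, M))), 1e-12)
  }
  # wrong input shape is refused
  expect_error(execute_schedule(build_msr_schedule(circuit_version("partial", 2, 2)),
                                rand_mat(3, 3)),
               "built for 2x2")
})

test_that("comparator_reduce equals brute force with NF-1 comparisons", {
  res <- comparator_reduce(c(3.2, 1.1, 7.5, 0.4), "maximize")
  expect_equal(res$best, 7.5)
  expect_identical(res$index, 3L)
  expect_identical(res$rounds, 2L)
  expect_identical(res$comparisons, 3L)

  one <- comparator_reduce(42, "maximize")
  expect_equal(one$best, 42)
  expect_identical(one$rounds, 0L)
  expect_identical(one$comparisons, 0L)

  ties <- comparator_reduce(rep(1.5, 8), "minimize")
  expect_identical(ties$index, 1L)   # earlier index wins all ties
  expect_identical(ties$rounds, 3L)
  expect_identical(ties$comparisons, 7L)

  set.seed(13)
  for (n in 1:64) {
    vals <- round(runif(n, -10, 10), 1)  # rounding forces occasional ties
    for (dir in c("maximize", "minimize")) {
      res <- comparator_reduce(vals, dir)
      target <- if (dir == "maximize") max(vals) else min(vals)
      expect_equal(res$best, target)
      expect_identical(res$index, which(vals == target)[1L])
      expect_identical(res$comparisons, n - 1L)
      expect_identical(res$rounds,
                       if (n >= 2) as.integer(ceiling(log2(n))) else 0L)
    }
  }
  expect_error(comparator_reduce(numeric(0)), "at least one")
})

test_that("evaluation latency follows the batching contract", {
  trace <- build_msr_schedule(circuit_version("partial", 8, 8))
  lat <- latency_model()
  tc <- trace_cycles(trace, lat)

  # population = NF = 1: reduction-free
  r1 <- evaluation_latency(trace, lat, top_level_config(1), 1)
  expect_equal(r1$parallel_cycles, tc)

  # population = 8, NF = 8: one batch plus 3 comparator rounds
  r8 <- evaluation_latency(trace, lat, top_level_config(8), 8)
  expect_equal(r8$parallel_cycles, tc + 3 * lat$compare)

  # batching: 10 individuals on 4 units -> 3 batches
  r10 <- evaluation_latency(trace, lat, top_level_config(4), 10)
  expect_identical(r10$batches, 3)

  expect_error(evaluation_latency(trace, lat, top_level_config(4), 0),
               "population")
})

test_that("more fitness units never hurt, and speedup is at least 1", {
  lat <- latency_model()
  traces <- list(build_msr_schedule(circuit_version("partial", 8, 8)),
                 build_msr_schedule(circuit_version("full", 4, 4)),
                 build_selection_schedule())
  for (trace in traces) {
    for (population in c(1, 5, 8, 37, 100)) {
      prev <- Inf
      for (NF in c(1, 2, 4, 8, 16, 32, 64, 128, 256)) {
        rep <- evaluation_latency(trace, lat, top_level_config(NF),
                                  population)
        expect_lte(rep$parallel_cycles, prev)
        expect_gte(rep$speedup, 1)
        prev <- rep$parallel_cycles
      }
    }
  }
})

test_that("circuit names parse and the experiment grids have the printed sizes", {
  p <- parse_circuit_name("controller-f16x8-NF6-NC3")
  expect_identical(p$version$model, "partial")
  expect_identical(p$version$I, 16L)
  expect_identical(p$version$J, 8L)
  expect_identical(p$NF, 6L)
  expect_identical(p$NC, 3L)

  expect_identical(parse_circuit_name("msr-a4x4")$version$model, "full")
  expect_identical(circuit_version("partial", 8, 8)$name, "msr-f8x8")
  expect_error(parse_circuit_name("controller-f4x4-NF6-NC2"), "NC")
  expect_error(parse_circuit_name("msr-x9"), "cannot parse")

  gs <- enumerate_experiment_grid("gene-selection")
  expect_identical(nrow(gs), 36L)
  expect_setequal(unique(gs$NF), c(8L, 16L, 32L, 64L, 128L, 256L))
  expect_identical(anyDuplicated(gs$name), 0L)

  bc <- enumerate_experiment_grid("biclustering")
  expect_identical(nrow(bc), 48L)
  expect_identical(length(unique(bc$case)), 8L)
  expect_identical(anyDuplicated(bc$name), 0L)

  expect_error(enumerate_experiment_grid("protein-folding"))
})
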