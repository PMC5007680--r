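#' Evolutionary-algorithm configuration
#'
#' A seeded generational genetic algorithm with tournament selection,
#' uniform crossover, per-bit flip mutation and elitism of one.
#'
#' @param population_size Number of individuals (>= 2; default 50).
#' @param generations Number of generations (>= 1; default 100).
#' @param crossover_rate Probability of uniform crossover per offspring
#'   (default 0.9).
#' @param mutation_rate Per-bit flip probability; `NULL` (default) means
#'   `1 / genome length`.
#' @param tournament_size Tournament size (>= 2; default 2).
#' @param seed Integer seed; the whole run is a pure function of it.
#' @param eval_NF Parallel fitness units assumed for the latency report
#'   (default 8).
#' @return Object of class `ea_config`.
#' @export
ea_config <- function(population_size = 50L, generations = 100L,
                      crossover_rate = 0.9, mutation_rate = NULL,
                      tournament_size = 2L, seed = 1L, eval_NF = 8L) {
  population_size <- as.integer(population_size)
  generations <- as.integer(generations)
  tournament_size <- as.integer(tournament_size)
  if (is.na(population_size) || population_size < 2L) {
    stop("population_size must be >= 2")
  }
  if (is.na(generations) || generations < 1L) stop("generations must be >= 1")
  if (crossover_rate < 0 || crossover_rate > 1) {
    stop("crossover_rate must lie in [0, 1]")
  }
  if (!is.null(mutation_rate) &&
      (mutation_rate < 0 || mutation_rate > 1)) {
    stop("mutation_rate must lie in [0, 1]")
  }
  if (is.na(tournament_size) || tournament_size < 2L) {
    stop("tournament_size must be >= 2")
  }
  if (population_size < tournament_size) {
    stop("infeasible config: population_size (", population_size,
         ") < tournament_size (", tournament_size, ")")
  }
  structure(list(population_size = population_size,
                 generations = generations,
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 tournament_size = tournament_size,
                 seed = as.integer(seed),
                 eval_NF = as.integer(eval_NF)),
            class = "ea_config")
}

#' Problem context for the evolutionary algorithm
#'
#' Bundles genome decoding, repair, the (maximized) internal fitness and the
#' evaluation-schedule trace for one of the two problems.
#'
#' For `"selection"` the genome is the gene mask and the fitness is the
#' weighted subset fitness F(x).  For `"biclustering"` the genome is the row
#' mask concatenated with the column mask; the default internal objective
#' `"coherence"` maximizes `volume * (total variance - MSR)`.  By the
#' two-way ANOVA decomposition, total variance minus MSR is exactly the
#' per-cell variance explained by additive row and column effects, so the
#' objective is the total additive signal captured by the bicluster: it
#' grows with coherent structure and with size, and stays near zero for
#' flat, tiny or pure-noise submatrices.  `"msr"` maximizes plain `-MSR`.
#' Reported MSR values are
#' always the un-negated MSR of the decoded bicluster.
#'
#' @param problem `"selection"` or `"biclustering"`.
#' @param data A [labeled_dataset()] (selection) or an
#'   [expression_matrix()] (biclustering).
#' @param config A [selection_config()] for the selection problem; defaults
#'   to `selection_config(M = ncol(data$matrix))`.
#' @param classifier Classifier spec for LOOCV (selection problem).
#' @param objective `"coherence"` (default) or `"msr"` (biclustering).
#' @param min_rows,min_cols Minimum bicluster side sizes enforced by repair
#'   (default 2; avoids degenerate single-row/column biclusters whose MSR is
#'   identically 0).
#' @return Object of class `ea_context` consumed by [evolve()] and
#'   [evaluate_population()].
#' @export
problem_context <- function(problem = c("selection", "biclustering"), data,
                            config = NULL,
                            classifier = nearest_centroid_classifier(),
                            objective = c("coherence", "msr"),
                            min_rows = 2L, min_cols = 2L) {
  problem <- match.arg(problem)
  if (problem == "selection") {
    if (!inherits(data, "labeled_dataset")) {
      stop("selection problem needs a labeled_dataset")
    }
    M <- ncol(data$matrix)
    cfg <- config %||% selection_config(M = M)
    ctx <- list(
      problem = problem,
      data = data,
      genome_length = M,
      repair = function(genome) {
        if (!any(genome)) genome[sample.int(length(genome), 1L)] <- TRUE
        genome
      },
      decode = function(genome) gene_subset(genome),
      fitness_fun = function(genome) {
        evaluate_subset(data, gene_subset(genome), cfg, classifier)
      },
      report = function(genome) {
        x <- gene_subset(genome)
        acc <- loocv_accuracy(data, x, classifier)
        list(genes = which(genome), R = x$R, A = acc$A,
             F = subset_fitness(acc$A, x$R, cfg))
      },
      trace = build_selection_schedule())
  } else {
    if (!is_expression_matrix(data)) data <- expression_matrix(data)
    I <- nrow(data); J <- ncol(data)
    objective <- match.arg(objective)
    min_rows <- min(as.integer(min_rows), I)
    min_cols <- min(as.integer(min_cols), J)
    decode <- function(genome) {
      list(rows = which(genome[seq_len(I)]),
           cols = which(genome[I + seq_len(J)]))
    }
    score <- function(genome) {
      dc <- decode(genome)
      sub <- unclass(data)[dc$rows, dc$cols, drop = FALSE]
      bd <- msr_breakdown(sub)
      if (objective == "msr") return(-bd$msr)
      total_var <- mean((sub - bd$overall_mean)^2)
      length(dc$rows) * length(dc$cols) * (total_var - bd$msr)
    }
    ctx <- list(
      problem = problem,
      data = data,
      genome_length = I + J,
      objective = objective,
      repair = function(genome) {
        sides <- list(seq_len(I), I + seq_len(J))
        mins <- c(min_rows, min_cols)
        for (s in 1:2) {
          idx <- sides[[s]]
          short <- mins[s] - sum(genome[idx])
          if (short > 0L) {
            off <- idx[!genome[idx]]
            genome[sample(off, short)] <- TRUE
          }
        }
        genome
      },
      decode = function(genome) {
        dc <- decode(genome)
        bicluster(dc$rows, dc$cols)
      },
      fitness_fun = score,
      report = function(genome) {
        dc <- decode(genome)
        list(rows = dc$rows, cols = dc$cols,
             msr = msr_of_bicluster(data, bicluster(dc$rows, dc$cols)))
      },
      trace = build_msr_schedule(circuit_version("partial", I, J)))
  }
  structure(ctx, class = "ea_context")
}

#' Evaluate a population of individuals
#'
#' Applies the context's fitness to every individual (each fitness equals
#' the direct per-individual call -- there is no batching effect on the
#' values), selects the best via the comparator reduction tree, and reports
#' the simulated evaluation latency for `ceil(population / NF)` batches of
#' `NF` parallel fitness units.
#'
#' @param pop List of logical genomes (or of lists with a `genome` field).
#' @param context An `ea_context` from [problem_context()].
#' @param top A [top_level_config()].
#' @param lat A [latency_model()].
#' @return List with `fitness` (numeric vector), `best` (the
#'   [comparator_reduce()] result) and `latency` (the
#'   [evaluation_latency()] report).
#' @export
evaluate_population <- function(pop, context, top, lat = latency_model()) {
  stopifnot(inherits(context, "ea_context"))
  if (length(pop) == 0L) stop("population must be non-empty")
  genomes <- lapply(pop, function(ind) {
    if (is.list(ind)) ind$genome else ind
  })
  fitness <- vapply(genomes, context$fitness_fun, 0)
  list(fitness = fitness,
       best = comparator_reduce(fitness, "maximize"),
       latency = evaluation_latency(context$trace, lat, top,
                                    population = length(pop)))
}

#' Run the evolutionary algorithm
#'
#' A generational GA (tournament selection, uniform crossover, per-bit flip
#' mutation, elitism of 1) over gene subsets or biclusters.  The run is
#' deterministic given `cfg$seed`.  MSR minimization is driven through a
#' maximized internal objective; reported MSR values are un-negated.
#'
#' @param problem `"selection"` or `"biclustering"`.
#' @param data A [labeled_dataset()] or an [expression_matrix()].
#' @param cfg An [ea_config()].
#' @param ... Passed to [problem_context()] (e.g. `config`, `classifier`,
#'   `objective`, `min_rows`, `min_cols`).
#' @param lat A [latency_model()] for the latency report.
#' @return List with `best` (genome, internal fitness and the problem
#'   report: genes/R/A/F or rows/cols/msr), `history` (data.frame of
#'   per-generation best and mean internal fitness; best is monotone
#'   non-decreasing under elitism), `latency_report` (cumulative simulated
#'   sequential and NF-parallel cycles over all evaluation phases) and
#'   `config`.
#' @export
evolve <- function(problem = c("selection", "biclustering"), data, cfg,
                   ..., lat = latency_model()) {
  problem <- match.arg(problem)
  stopifnot(inherits(cfg, "ea_config"))
  context <- problem_context(problem, data, ...)
  top <- top_level_config(cfg$eval_NF)
  L <- context$genome_length
  mut <- cfg$mutation_rate %||% (1 / L)
  np <- cfg$population_size

  with_seed(cfg$seed, {
    pop <- lapply(seq_len(np), function(i) {
      context$repair(stats::runif(L) < 0.5)
    })
    ev <- evaluate_population(pop, context, top, lat)
    fitness <- ev$fitness
    par_cycles <- ev$latency$parallel_cycles
    seq_cycles <- ev$latency$sequential_cycles

    tournament <- function() {
      cand <- sample.int(np, cfg$tournament_size)
      cand[which.max(fitness[cand])]
    }
    history <- data.frame(generation = seq_len(cfg$generations),
                          best = NA_real_, mean = NA_real_)
    for (gen in seq_len(cfg$generations)) {
      elite_idx <- which.max(fitness)
      nextpop <- vector("list", np)
      nextpop[[1L]] <- pop[[elite_idx]]
      for (i in seq.int(2L, np)) {
        p1 <- pop[[tournament()]]
        child <- if (stats::runif(1) < cfg$crossover_rate) {
          p2 <- pop[[tournament()]]
          take <- stats::runif(L) < 0.5
          ifelse(take, p1, p2)
        } else p1
        flip <- stats::runif(L) < mut
        child <- xor(child, flip)
        nextpop[[i]] <- context$repair(child)
      }
      pop <- nextpop
      ev <- evaluate_population(pop, context, top, lat)
      fitness <- ev$fitness
      par_cycles <- par_cycles + ev$latency$parallel_cycles
      seq_cycles <- seq_cycles + ev$latency$sequential_cycles
      history$best[gen] <- ev$best$best
      history$mean[gen] <- mean(fitness)
    }
    best_idx <- which.max(fitness)
    best_genome <- pop[[best_idx]]
    list(best = c(list(genome = best_genome, fitness = fitness[best_idx]),
                  context$report(best_genome)),
         history = history,
         latency_report = list(
           evaluations = (cfg$generations + 1L) * np,
           parallel_cycles = par_cycles,
           sequential_cycles = seq_cycles,
           speedup = seq_cycles / par_cycles,
           NF = top$NF),
         config = unclass(cfg))
  })
}
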