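## Fine-grained evaluation schedules
##
## A schedule trace is an ordered list of macro-steps.  Steps are strictly
## sequential; within a step, task groups run concurrently and must not read
## a value written by another group of the same step.  A task group bundles
## the scalar operations of one logical task (e.g. "all row and column
## sums"): `ops` counts scalar operations per operator type, `units` says
## how many hardware units of each type the group occupies concurrently.
## Group latency is sum over types of ceil(ops/units) * per-op latency;
## step latency is the max over its groups; trace latency is the sum over
## steps.

OP_TYPES <- c("add", "mul", "div", "conv", "cmp")

#' Circuit version descriptor
#'
#' Fitness-circuit implementations are named by the parallelization model
#' and the matrix size: `msr-f8x8` is the partially parallelized
#' (row-parallel, column-sequential residues; 6 macro-steps) circuit for an
#' 8 x 8 bicluster, `msr-a4x4` the fully parallelized one (all residues
#' concurrent; 5 macro-steps) for 4 x 4.  The gene-selection circuit has no
#' size parameter.
#'
#' @param model `"partial"`, `"full"` (MSR) or `"gene-selection"`.
#' @param I,J Bicluster rows and columns (MSR models only).
#' @return Object of class `circuit_version` with fields `model`, `I`, `J`,
#'   `name`.
#' @examples
#' circuit_version("partial", 8, 8)$name  # "msr-f8x8"
#' @export
circuit_version <- function(model = c("partial", "full", "gene-selection"),
                            I = NULL, J = NULL) {
  model <- match.arg(model)
  if (model == "gene-selection") {
    return(structure(list(model = model, I = NULL, J = NULL,
                          name = "gene-selection"),
                     class = "circuit_version"))
  }
  I <- as.integer(I); J <- as.integer(J)
  if (length(I) != 1L || length(J) != 1L || is.na(I) || is.na(J) ||
      I < 1L || J < 1L) {
    stop("MSR circuit versions need integer I >= 1 and J >= 1")
  }
  letter <- if (model == "partial") "f" else "a"
  structure(list(model = model, I = I, J = J,
                 name = sprintf("msr-%s%dx%d", letter, I, J)),
            class = "circuit_version")
}

#' @export
print.circuit_version <- function(x, ...) {
  cat("circuit_version:", x$name, "\n")
  invisible(x)
}

#' Parse a circuit version / controller name
#'
#' Understands fitness-circuit names (`msr-f8x8`, `a4x4`) and controller
#' names carrying the top-level configuration
#' (`controller-f16x8-NF6-NC3`).
#'
#' @param name Canonical circuit or controller name.
#' @return A list with `version` (a [circuit_version()]) and, when present
#'   in the name, `NF` and `NC`.
#' @examples
#' parse_circuit_name("controller-f16x8-NF6-NC3")
#' @export
parse_circuit_name <- function(name) {
  stripped <- sub("^(controller-|msr-)", "", name)
  m <- regmatches(stripped,
                  regexec("^([fa])([0-9]+)x([0-9]+)(-NF([0-9]+)-NC([0-9]+))?$",
                          stripped))[[1L]]
  if (length(m) == 0L) {
    if (stripped == "gene-selection") {
      return(list(version = circuit_version("gene-selection"),
                  NF = NULL, NC = NULL))
    }
    stop("cannot parse circuit name: ", name)
  }
  model <- if (m[2L] == "f") "partial" else "full"
  out <- list(version = circuit_version(model, as.integer(m[3L]),
                                        as.integer(m[4L])),
              NF = NULL, NC = NULL)
  if (nzchar(m[5L])) {
    out$NF <- as.integer(m[6L])
    out$NC <- as.integer(m[7L])
    if (out$NC != out$NF %/% 2L) {
      stop("inconsistent name: NC must equal floor(NF/2), got NF=", out$NF,
           ", NC=", out$NC)
    }
  }
  out
}

#' Operator budget of a circuit
#'
#' Counts of floating-point operator units a circuit version instantiates.
#'
#' @param adders,multipliers,dividers,converters,comparators Non-negative
#'   unit counts; converters are integer-to-float converters.
#' @return Object of class `operator_budget`.
#' @export
operator_budget <- function(adders, multipliers, dividers, converters,
                            comparators = 0L) {
  counts <- c(adders = adders, multipliers = multipliers, dividers = dividers,
              converters = converters, comparators = comparators)
  counts <- as.integer(counts)
  if (anyNA(counts) || any(counts < 0L)) {
    stop("operator counts must be non-negative integers")
  }
  structure(as.list(stats::setNames(counts,
                                    c("adders", "multipliers", "dividers",
                                      "converters", "comparators"))),
            class = "operator_budget")
}

#' @export
print.operator_budget <- function(x, ...) {
  cat(sprintf("operator_budget: %d add, %d mul, %d div, %d conv, %d cmp\n",
              x$adders, x$multipliers, x$dividers, x$converters,
              x$comparators))
  invisible(x)
}

#' Operator requirements of a circuit version
#'
#' The partially parallelized MSR circuit instantiates `max(I, J)` units of
#' each of the four operator types (8x8 -> 8 adders, 8 multipliers, 8
#' dividers, 8 converters); the fully parallelized circuit instantiates
#' `I * J` of each (4x4 -> 16 of each).  The gene-selection circuit uses one
#' adder, one multiplier, one divider and one converter.  The `max(I, J)`
#' rule for non-square partial circuits is an extrapolation from the square
#' printed configuration and is isolated here so it can be revised without
#' touching the schedules.
#'
#' @param v A [circuit_version()].
#' @return An [operator_budget()].
#' @examples
#' operator_requirements(circuit_version("partial", 8, 8))
#' @export
operator_requirements <- function(v) {
  stopifnot(inherits(v, "circuit_version"))
  n <- switch(v$model,
              "partial" = max(v$I, v$J),
              "full" = v$I * v$J,
              "gene-selection" = 1L)
  operator_budget(n, n, n, n, comparators = 0L)
}

## -- trace construction helpers ---------------------------------------------

task_group <- function(tag, note, reads, writes, ops, units) {
  ops <- ops[ops > 0]
  units <- units[names(ops)]
  if (any(units < 1 & ops > 0)) {
    stop("internal: task group '", tag, "' has operations but no units")
  }
  list(tag = tag, note = note, reads = reads, writes = writes,
       ops = as.list(ops), units = as.list(units))
}

new_trace <- function(version, steps, budget, inputs) {
  tr <- structure(list(version = version, steps = steps, budget = budget,
                       inputs = inputs, cycles = NA_real_),
                  class = "schedule_trace")
  validate_schedule(tr)
  check_budget(tr)
  tr$cycles <- trace_cycles(tr, latency_model())
  tr
}

#' @export
print.schedule_trace <- function(x, ...) {
  cat(sprintf("schedule_trace for %s: %d macro-steps, %d cycles (default latencies)\n",
              x$version$name, length(x$steps), x$cycles))
  for (k in seq_along(x$steps)) {
    notes <- vapply(x$steps[[k]], function(g) g$note, "")
    cat(sprintf("  step %d: %s\n", k, paste(notes, collapse = " || ")))
  }
  invisible(x)
}

#' Number of macro-steps of a trace
#' @param trace A `schedule_trace`.
#' @return Integer step count.
#' @export
schedule_steps <- function(trace) length(trace$steps)

#' Concurrent task-group count per macro-step
#' @param trace A `schedule_trace`.
#' @return Integer vector, one width per step.
#' @export
step_widths <- function(trace) vapply(trace$steps, length, 1L)

#' Structural dependency check of a trace
#'
#' Verifies that no task group reads a value written by another task group
#' of the same macro-step, and that every read was produced by an earlier
#' step or is a trace input.  Called on every built trace.
#'
#' @param trace A `schedule_trace`.
#' @return `TRUE` invisibly; stops with a descriptive error otherwise.
#' @export
validate_schedule <- function(trace) {
  available <- trace$inputs
  for (k in seq_along(trace$steps)) {
    step <- trace$steps[[k]]
    step_writes <- unlist(lapply(step, function(g) g$writes))
    for (g in step) {
      foreign <- setdiff(step_writes, g$writes)
      clash <- intersect(g$reads, foreign)
      if (length(clash) > 0L) {
        stop("step ", k, " task '", g$tag, "' reads same-step output: ",
             paste(clash, collapse = ", "))
      }
      missing <- setdiff(g$reads, available)
      if (length(missing) > 0L) {
        stop("step ", k, " task '", g$tag, "' reads unavailable value: ",
             paste(missing, collapse = ", "))
      }
    }
    available <- union(available, step_writes)
  }
  invisible(TRUE)
}

budget_of <- function(budget, op) {
  switch(op, add = budget$adders, mul = budget$multipliers,
         div = budget$dividers, conv = budget$converters,
         cmp = budget$comparators)
}

#' Per-step operator usage of a trace
#'
#' @param trace A `schedule_trace`.
#' @return Matrix (steps x operator types) of concurrently occupied units.
#' @export
schedule_usage <- function(trace) {
  usage <- matrix(0L, nrow = length(trace$steps), ncol = length(OP_TYPES),
                  dimnames = list(paste0("step", seq_along(trace$steps)),
                                  OP_TYPES))
  for (k in seq_along(trace$steps)) {
    for (g in trace$steps[[k]]) {
      for (op in names(g$units)) {
        usage[k, op] <- usage[k, op] + as.integer(g$units[[op]])
      }
    }
  }
  usage
}

check_budget <- function(trace) {
  usage <- schedule_usage(trace)
  for (k in seq_len(nrow(usage))) {
    for (op in OP_TYPES) {
      have <- budget_of(trace$budget, op)
      if (usage[k, op] > have) {
        stop(sprintf(
          "insufficient %s budget at step %d: need %d, have %d (short %d)",
          op, k, usage[k, op], have, usage[k, op] - have))
      }
    }
  }
  invisible(TRUE)
}

## Split `budget` units among groups wanting `desired` units each, at least
## one per group with desired > 0.
allocate_units <- function(desired, budget, step, op) {
  active <- desired > 0
  n <- sum(active)
  if (n == 0L) return(desired)
  if (budget < n) {
    stop(sprintf(
      "insufficient %s budget at step %d: need at least %d, have %d (short %d)",
      op, step, n, budget, n - budget))
  }
  alloc <- pmin(desired, budget)
  while (sum(alloc) > budget) {
    # shave the largest allocation, never below 1
    i <- which.max(alloc * active)
    alloc[i] <- max(1L, alloc[i] - (sum(alloc) - budget))
  }
  alloc
}

## -- MSR schedules -----------------------------------------------------------

#' Build the macro-step schedule of an MSR circuit
#'
#' The partially parallelized model emits six macro-steps: (1) all row sums
#' and column sums; (2) total sum together with the row means; (3) column
#' means; (4) overall mean; (5) residues computed in parallel by rows but
#' sequentially by columns; (6) squared-residue reduction to the MSR.  The
#' fully parallelized model emits five: (1) row and column sums; (2) total
#' sum, row means and column means together; (3) overall mean; (4) all
#' residues concurrently; (5) squared-residue reduction.  Each step records
#' the operator units it occupies, never exceeding the budget.
#'
#' @param v A [circuit_version()] with model `"partial"` or `"full"`.
#' @param budget An [operator_budget()]; defaults to
#'   [operator_requirements()] of the version.
#' @return A `schedule_trace` executable with [execute_schedule()].
#' @examples
#' schedule_steps(build_msr_schedule(circuit_version("partial", 8, 8)))  # 6
#' schedule_steps(build_msr_schedule(circuit_version("full", 4, 4)))    # 5
#' @export
build_msr_schedule <- function(v, budget = operator_requirements(v)) {
  stopifnot(inherits(v, "circuit_version"))
  if (!v$model %in% c("partial", "full")) {
    stop("build_msr_schedule needs an MSR circuit version (partial or full)")
  }
  stopifnot(inherits(budget, "operator_budget"))
  I <- v$I; J <- v$J

  sums_ops <- I * (J - 1L) + J * (I - 1L)
  g_sums <- task_group(
    "row_col_sums", "row sums and column sums of all b_ij in parallel",
    reads = "b", writes = c("sum_biJ", "sum_bIj"),
    ops = c(add = sums_ops),
    units = c(add = min(budget_of(budget, "add"), max(sums_ops, 1L))))
  g_conv <- task_group(
    "const_convert", "convert I, J and I*J to floating point",
    reads = character(), writes = c("I_f", "J_f", "IJ_f"),
    ops = c(conv = 3L),
    units = c(conv = allocate_units(3L, budget_of(budget, "conv"), 1L,
                                    "conv")))
  step1 <- list(g_sums, g_conv)

  g_total <- task_group(
    "total_sum", "total sum of the matrix from the row sums",
    reads = "sum_biJ", writes = "sum_bIJ",
    ops = c(add = I - 1L),
    units = c(add = min(budget_of(budget, "add"), max(I - 1L, 1L))))
  g_rmeans <- task_group(
    "row_means", "row means: sum_biJ_i / J",
    reads = c("sum_biJ", "J_f"), writes = "biJ",
    ops = c(div = I),
    units = c(div = min(budget_of(budget, "div"), I)))
  g_cmeans <- task_group(
    "col_means", "column means: sum_bIj_j / I",
    reads = c("sum_bIj", "I_f"), writes = "bIj",
    ops = c(div = J),
    units = c(div = min(budget_of(budget, "div"), J)))
  g_omean <- task_group(
    "overall_mean", "overall mean: sum_bIJ / (I*J)",
    reads = c("sum_bIJ", "IJ_f"), writes = "bIJ",
    ops = c(div = 1L), units = c(div = 1L))
  g_msr <- task_group(
    "msr_reduce", "square residues, accumulate and divide by I*J",
    reads = c("r", "IJ_f"), writes = "msr",
    ops = c(mul = I * J, add = I * J - 1L, div = 1L),
    units = c(mul = min(budget_of(budget, "mul"), I * J),
              add = min(budget_of(budget, "add"), max(I * J - 1L, 1L)),
              div = 1L))

  if (v$model == "partial") {
    g_res <- task_group(
      "residues", "residues r_ij, parallel by rows, sequential by columns",
      reads = c("b", "biJ", "bIj", "bIJ"), writes = "r",
      ops = c(add = 3L * I * J),
      units = c(add = min(budget_of(budget, "add"), I)))
    steps <- list(step1,
                  list(g_total, g_rmeans),
                  list(g_cmeans),
                  list(g_omean),
                  list(g_res),
                  list(g_msr))
  } else {
    have_add <- budget_of(budget, "add")
    if (have_add < I * J) {
      stop(sprintf(
        "insufficient add budget at step 4 (residues): fully parallel model needs I*J = %d adders, have %d (short %d)",
        I * J, have_add, I * J - have_add))
    }
    g_res <- task_group(
      "residues", "all residues r_ij computed concurrently",
      reads = c("b", "biJ", "bIj", "bIJ"), writes = "r",
      ops = c(add = 3L * I * J),
      units = c(add = I * J))
    div_alloc <- allocate_units(c(I, J), budget_of(budget, "div"), 2L, "div")
    g_rmeans$units$div <- div_alloc[1L]
    g_cmeans$units$div <- div_alloc[2L]
    steps <- list(step1,
                  list(g_total, g_rmeans, g_cmeans),
                  list(g_omean),
                  list(g_res),
                  list(g_msr))
  }
  new_trace(v, steps, budget, inputs = "b")
}

#' Build the macro-step schedule of the gene-selection fitness circuit
#'
#' Macro-step 1 performs three operations in parallel: the multiply
#' `w1 * A(x)`, the divide `w2 / M` and the integer subtract `M - R(x)`.
#' Then follow the integer-to-float conversion of `M - R`, the multiply
#' `(w2/M) * (M - R)` and the final add -- four macro-steps over four
#' operator types (adder, multiplier, divider, converter).  The accuracy
#' A(x) arrives as a precomputed operand, as the circuit receives it from
#' the controller; classifier time is outside the latency model.
#'
#' @return A `schedule_trace` executable with [execute_schedule()].
#' @examples
#' step_widths(build_selection_schedule())[1]  # 3
#' @export
build_selection_schedule <- function() {
  v <- circuit_version("gene-selection")
  budget <- operator_requirements(v)
  steps <- list(
    list(
      task_group("acc_weight", "multiply w1 * A(x)",
                 reads = c("w1", "A"), writes = "w1A",
                 ops = c(mul = 1L), units = c(mul = 1L)),
      task_group("inv_size", "divide w2 / M",
                 reads = c("w2", "M"), writes = "w2_over_M",
                 ops = c(div = 1L), units = c(div = 1L)),
      task_group("gene_count", "integer subtract M - R(x)",
                 reads = c("M", "R"), writes = "MmR",
                 ops = c(add = 1L), units = c(add = 1L))),
    list(
      task_group("to_float", "convert M - R to floating point",
                 reads = "MmR", writes = "MmR_f",
                 ops = c(conv = 1L), units = c(conv = 1L))),
    list(
      task_group("size_term", "multiply (w2/M) * (M - R)",
                 reads = c("w2_over_M", "MmR_f"), writes = "term2",
                 ops = c(mul = 1L), units = c(mul = 1L))),
    list(
      task_group("combine", "add w1*A + w2*(M-R)/M",
                 reads = c("w1A", "term2"), writes = "F",
                 ops = c(add = 1L), units = c(add = 1L))))
  new_trace(v, steps, budget, inputs = c("w1", "A", "w2", "M", "R"))
}

## -- numeric execution -------------------------------------------------------

#' Execute a schedule trace numerically
#'
#' Interprets the macro-steps of a trace on concrete inputs, computing every
#' intermediate in the scheduled order.  The schedule is a reordering of the
#' fitness arithmetic, never a redefinition: the returned value equals
#' [msr()] of the matrix (MSR traces) or [subset_fitness()] of the operands
#' (gene-selection trace) up to floating-point rounding.
#'
#' @param trace A `schedule_trace`.
#' @param input For MSR traces, a numeric matrix of the trace's I x J shape;
#'   for the gene-selection trace, a list with `w1`, `A`, `w2`, `M`, `R`.
#' @return List with `value` (the final MSR or F) and `values` (all named
#'   intermediates).
#' @export
execute_schedule <- function(trace, input) {
  stopifnot(inherits(trace, "schedule_trace"))
  env <- new.env(parent = emptyenv())
  if (trace$version$model %in% c("partial", "full")) {
    b <- if (is_expression_matrix(input)) as_plain_matrix(input) else
      as.matrix(input)
    if (nrow(b) != trace$version$I || ncol(b) != trace$version$J) {
      stop("input matrix is ", nrow(b), "x", ncol(b),
           " but the trace was built for ", trace$version$I, "x",
           trace$version$J)
    }
    assign("b", b, envir = env)
    final <- "msr"
  } else {
    for (nm in c("w1", "A", "w2", "M", "R")) {
      if (is.null(input[[nm]])) stop("selection trace input needs '", nm, "'")
      assign(nm, as.numeric(input[[nm]]), envir = env)
    }
    final <- "F"
  }
  for (k in seq_along(trace$steps)) {
    for (g in trace$steps[[k]]) {
      for (nm in g$reads) {
        if (!exists(nm, envir = env, inherits = FALSE)) {
          stop("step ", k, " task '", g$tag, "' reads '", nm,
               "' before it is computed")
        }
      }
      execute_group(g, env)
    }
  }
  list(value = get(final, envir = env),
       values = as.list(env))
}

## Scalar-accumulation primitives: deliberately loop-based so the executor
## follows the per-operator arithmetic of the schedule rather than the
## vectorized path of msr_breakdown().
acc_sum <- function(x) {
  s <- 0
  for (v in x) s <- s + v
  s
}

execute_group <- function(g, env) {
  gv <- function(nm) get(nm, envir = env, inherits = FALSE)
  sv <- function(nm, val) assign(nm, val, envir = env)
  switch(g$tag,
    row_col_sums = {
      b <- gv("b")
      sv("sum_biJ", apply(b, 1L, acc_sum))
      sv("sum_bIj", apply(b, 2L, acc_sum))
    },
    const_convert = {
      b <- gv("b")
      sv("I_f", as.double(nrow(b)))
      sv("J_f", as.double(ncol(b)))
      sv("IJ_f", as.double(nrow(b)) * as.double(ncol(b)))
    },
    total_sum = sv("sum_bIJ", acc_sum(gv("sum_biJ"))),
    row_means = sv("biJ", gv("sum_biJ") / gv("J_f")),
    col_means = sv("bIj", gv("sum_bIj") / gv("I_f")),
    overall_mean = sv("bIJ", gv("sum_bIJ") / gv("IJ_f")),
    residues = {
      b <- gv("b"); biJ <- gv("biJ"); bIj <- gv("bIj"); bIJ <- gv("bIJ")
      r <- matrix(0, nrow(b), ncol(b))
      for (j in seq_len(ncol(b))) {        # sequential by columns
        for (i in seq_len(nrow(b))) {      # parallel by rows
          r[i, j] <- b[i, j] - biJ[i] - bIj[j] + bIJ
        }
      }
      sv("r", r)
    },
    msr_reduce = {
      r <- gv("r")
      sq <- r * r
      sv("msr", acc_sum(sq) / gv("IJ_f"))
    },
    acc_weight = sv("w1A", gv("w1") * gv("A")),
    inv_size = sv("w2_over_M", gv("w2") / gv("M")),
    gene_count = sv("MmR", gv("M") - gv("R")),
    to_float = sv("MmR_f", as.double(gv("MmR"))),
    size_term = sv("term2", gv("w2_over_M") * gv("MmR_f")),
    combine = sv("F", gv("w1A") + gv("term2")),
    stop("unknown task tag: ", g$tag))
  invisible(NULL)
}

## -- latency model & top-level ----------------------------------------------

#' Per-operator latency model
#'
#' Cycle counts per scalar operation.  The defaults (add 1, multiply 1,
#' divide 8, convert 1, compare 1) are placeholders in the spirit of
#' pipelined floating-point cores, where division is markedly slower; all
#' are overridable.
#'
#' @param add,multiply,divide,convert,compare Positive integer cycle counts.
#' @param clock_ns Optional nanoseconds per cycle for wall-clock estimates.
#' @return Object of class `latency_model`.
#' @export
latency_model <- function(add = 1L, multiply = 1L, divide = 8L,
                          convert = 1L, compare = 1L, clock_ns = NULL) {
  lat <- c(add = add, multiply = multiply, divide = divide,
           convert = convert, compare = compare)
  if (any(!is.finite(lat)) || any(lat < 1)) {
    stop("all operator latencies must be >= 1 cycle")
  }
  structure(list(add = add, multiply = multiply, divide = divide,
                 convert = convert, compare = compare, clock_ns = clock_ns),
            class = "latency_model")
}

lat_of <- function(lat, op) {
  switch(op, add = lat$add, mul = lat$multiply, div = lat$divide,
         conv = lat$convert, cmp = lat$compare)
}

#' Top-level configuration: parallel fitness units
#'
#' `NF` replicated fitness circuits evaluate `NF` individuals concurrently;
#' their results feed `NC = floor(NF/2)` first-round comparators of the
#' pairwise-halving reduction tree.
#'
#' @param NF Number of parallel fitness units (>= 1).
#' @return Object of class `top_level_config` with fields `NF`, `NC`.
#' @export
top_level_config <- function(NF) {
  NF <- as.integer(NF)
  if (length(NF) != 1L || is.na(NF) || NF < 1L) stop("NF must be >= 1")
  structure(list(NF = NF, NC = NF %/% 2L), class = "top_level_config")
}

group_cycles <- function(g, lat) {
  total <- 0
  for (op in names(g$ops)) {
    n <- g$ops[[op]]
    u <- g$units[[op]]
    if (n > 0) total <- total + ceiling(n / u) * lat_of(lat, op)
  }
  total
}

#' Latency of one pass through a trace
#'
#' Steps are sequential; within a step the concurrent task groups overlap,
#' so a step costs the maximum of its group latencies.
#'
#' @param trace A `schedule_trace`.
#' @param lat A [latency_model()].
#' @return Cycle count.
#' @export
trace_cycles <- function(trace, lat = latency_model()) {
  sum(vapply(trace$steps,
             function(step) max(vapply(step, group_cycles, 0, lat = lat)),
             0))
}

#' Latency of a fully sequential execution of a trace
#'
#' One scalar operation per cycle slot, no intra-step concurrency: the cost
#' a plain sequential loop pays for the same arithmetic.
#'
#' @inheritParams trace_cycles
#' @return Cycle count.
#' @export
sequential_cycles <- function(trace, lat = latency_model()) {
  total <- 0
  for (step in trace$steps) {
    for (g in step) {
      for (op in names(g$ops)) {
        total <- total + g$ops[[op]] * lat_of(lat, op)
      }
    }
  }
  total
}

#' Comparator-tree reduction of fitness values
#'
#' Values are compared in pairs; the winners are compared again in pairs,
#' and so on until a single best value remains (an odd value at any round
#' passes through unchanged).  Ties are won by the earlier-index value.
#'
#' @param values Numeric vector of NF fitness values (non-empty).
#' @param direction `"maximize"` or `"minimize"`.
#' @return List with `best` (the winning value), `index` (its position in
#'   `values`), `rounds` (`ceil(log2(NF))`, 0 for a single value) and
#'   `comparisons` (`NF - 1`).
#' @examples
#' comparator_reduce(c(3.2, 1.1, 7.5, 0.4), "maximize")
#' @export
comparator_reduce <- function(values, direction = c("maximize", "minimize")) {
  direction <- match.arg(direction)
  if (length(values) == 0L) stop("comparator_reduce needs at least one value")
  if (anyNA(values)) stop("comparator_reduce cannot handle NA values")
  better <- if (direction == "maximize") `>` else `<`
  idx <- seq_along(values)
  vals <- as.numeric(values)
  rounds <- 0L
  comparisons <- 0L
  while (length(vals) > 1L) {
    n <- length(vals)
    keep <- integer(0)
    for (p in seq_len(n %/% 2L)) {
      a <- 2L * p - 1L
      b <- 2L * p
      comparisons <- comparisons + 1L
      keep <- c(keep, if (better(vals[b], vals[a])) b else a)  # tie: earlier
    }
    if (n %% 2L == 1L) keep <- c(keep, n)  # bye for the unpaired value
    vals <- vals[keep]
    idx <- idx[keep]
    rounds <- rounds + 1L
  }
  list(best = vals[1L], index = idx[1L], rounds = rounds,
       comparisons = comparisons)
}

#' Simulated latency of evaluating a population
#'
#' The population is evaluated in `ceil(population / NF)` batches of up to
#' `NF` concurrent fitness units; each batch is followed by the comparator
#' reduction (`ceil(log2(min(NF, population)))` rounds) and, from the second
#' batch on, one extra comparison against the running best.  The sequential
#' baseline runs the same arithmetic one operation per cycle slot,
#' including the `population - 1` best-tracking comparisons a sequential
#' loop performs, so speedup >= 1 whenever per-operation latencies agree.
#'
#' @param trace A `schedule_trace` (one fitness evaluation).
#' @param lat A [latency_model()].
#' @param top A [top_level_config()].
#' @param population Number of individuals to evaluate (>= 1).
#' @return List with `parallel_cycles`, `sequential_cycles`, `speedup`,
#'   `batches`, `reduction_rounds` and `per_evaluation_cycles`; wall-clock
#'   nanoseconds are added when the latency model has `clock_ns`.
#' @export
evaluation_latency <- function(trace, lat = latency_model(), top,
                               population) {
  stopifnot(inherits(top, "top_level_config"))
  population <- as.integer(population)
  if (is.na(population) || population < 1L) stop("population must be >= 1")
  per_eval <- trace_cycles(trace, lat)
  batches <- ceiling(population / top$NF)
  nf_eff <- min(top$NF, population)
  rounds <- if (nf_eff >= 2L) ceiling(log2(nf_eff)) else 0L
  parallel <- batches * per_eval +
    (batches * rounds + (batches - 1L)) * lat$compare
  seq_total <- population * sequential_cycles(trace, lat) +
    (population - 1L) * lat$compare
  out <- list(parallel_cycles = parallel, sequential_cycles = seq_total,
              speedup = seq_total / parallel, batches = batches,
              reduction_rounds = batches * rounds + (batches - 1L),
              per_evaluation_cycles = per_eval)
  if (!is.null(lat$clock_ns)) {
    out$parallel_ns <- parallel * lat$clock_ns
    out$sequential_ns <- seq_total * lat$clock_ns
  }
  out
}

## -- experiment grid ---------------------------------------------------------

#' Enumerate the synthesis experiment grid
#'
#' Each design is synthesized under 3 optimization profiles (default,
#' timing performance with physical synthesis, timing performance without
#' I/O block packing) crossed with 2 operator implementations (DSP slices
#' vs logic blocks).  The gene-selection problem tests 6 top-level cases
#' (NF = 8, 16, 32, 64, 128, 256), giving 36 experiments; the biclustering
#' problem tests 8 circuit versions (f4x4, f8x8, f16x8, f16x16, f30x50,
#' f32x64, a4x4, a5x5), giving 48.
#'
#' @param problem `"gene-selection"` or `"biclustering"`.
#' @return A data.frame with one row per configuration: `name`, `case`,
#'   `profile`, `operators`, plus `NF`/`NC` (gene selection) or
#'   `model`/`I`/`J` (biclustering).
#' @export
enumerate_experiment_grid <- function(problem = c("gene-selection",
                                                  "biclustering")) {
  problem <- match.arg(problem)
  profiles <- c("default", "timing-physical", "timing-noiob")
  operators <- c("dsp", "logic")
  if (problem == "gene-selection") {
    grid <- expand.grid(NF = c(8L, 16L, 32L, 64L, 128L, 256L),
                        profile = profiles, operators = operators,
                        stringsAsFactors = FALSE)
    grid$NC <- grid$NF %/% 2L
    grid$case <- paste0("NF", grid$NF)
    grid$name <- sprintf("controller-genesel-NF%d-NC%d--%s-%s",
                         grid$NF, grid$NC, grid$profile, grid$operators)
    return(grid[, c("name", "case", "profile", "operators", "NF", "NC")])
  }
  versions <- c("f4x4", "f8x8", "f16x8", "f16x16", "f30x50", "f32x64",
                "a4x4", "a5x5")
  grid <- expand.grid(case = versions, profile = profiles,
                      operators = operators, stringsAsFactors = FALSE)
  parsed <- lapply(grid$case, function(nm) parse_circuit_name(nm)$version)
  grid$model <- vapply(parsed, function(v) v$model, "")
  grid$I <- vapply(parsed, function(v) v$I, 1L)
  grid$J <- vapply(parsed, function(v) v$J, 1L)
  grid$name <- sprintf("msr-%s--%s-%s", grid$case, grid$profile,
                       grid$operators)
  grid[, c("name", "case", "profile", "operators", "model", "I", "J")]
}

#' Export a trace as plain task-group records
#'
#' @param trace A `schedule_trace`.
#' @return List of macro-steps, each a list of records
#'   `{op, count, note}` suitable for JSON serialization.
#' @export
trace_records <- function(trace) {
  lapply(trace$steps, function(step) {
    lapply(step, function(g) {
      list(op = names(g$ops), count = unlist(g$ops, use.names = FALSE),
           note = g$note)
    })
  })
}
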