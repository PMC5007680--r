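---
title: "Fitness functions and their fine-grained parallel evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitness functions and their fine-grained parallel evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fitflow)
```

## The two fitness functions

Evolutionary algorithms for combinatorial problems in transcriptomics spend
most of their time in the fitness-evaluation phase, because the fitness is
applied to every individual of the population in every generation.  Two
representative floating-point fitness functions are implemented here.

**Gene selection for cancer classification.**  A candidate solution is a
subset $x$ of the $M$ genes of a labeled dataset of $N$ samples, encoded as
a boolean mask.  Its fitness, to be maximized, is

$$F(x) = w_1\,A(x) + w_2\,\frac{M - R(x)}{M},$$

where $A(x) \in [0,1]$ is the leave-one-out cross-validation (LOOCV)
accuracy of a classifier restricted to the selected genes and $R(x)$ is the
subset size.  The second term rewards parsimony: smaller gene signatures are
cheaper to assay and less prone to overfitting.  The classifier behind
$A(x)$ is pluggable (`train`/`predict` pair); the default is a
nearest-centroid classifier -- per-class mean expression vectors, Euclidean
distance -- because it is deterministic, dependency-free, and sufficient to
exercise the fitness.  Equidistant centroids are resolved toward the class
that sorts first, so LOOCV is bit-reproducible.  The defaults $w_1 = 0.75$,
$w_2 = 0.25$ are configuration values, never hard-coded into the arithmetic:
any non-negative weights are accepted.

**Biclustering of gene expression data.**  A bicluster is a submatrix $B$ of
an expression matrix, given by a subset of $I$ experimental conditions
(rows) and $J$ genes (columns).  With row means $b_{iJ}$, column means
$b_{Ij}$ and the grand mean $b_{IJ}$ (the total sum divided by $I \cdot J$),
the residue of a cell and the mean squared residue (MSR) are

$$r_{ij} = b_{ij} - b_{iJ} - b_{Ij} + b_{IJ}, \qquad
\mathrm{MSR}(B) = \frac{1}{IJ}\sum_{i,j} r_{ij}^2 .$$

MSR is zero exactly when $B$ is additive ($b_{ij} = a_i + c_j$), invariant
under translation, row/column offsets and permutations, and scales
quadratically with the data.  `msr_breakdown()` exposes every intermediate
(sums, means, residues) so downstream consumers -- and the schedule
executor -- can be validated term by term.  Degenerate $1 \times J$ and
$I \times 1$ inputs are allowed and give MSR $= 0$ identically; keeping
search away from such trivial solutions is the caller's job (see the
repair rule below).

## Evaluation schedules

The package models how each fitness function can be computed by a
fine-grained parallel datapath built from replicated floating-point
operators: adders, multipliers, dividers and integer-to-float converters.
A `schedule_trace` is an ordered list of *macro-steps*; macro-steps execute
strictly in sequence, while the *task groups* inside one macro-step run
concurrently and may not read a value produced by another group of the same
step (`validate_schedule()` checks this structurally on every built trace).
Each task group records how many scalar operations of each type it performs
and how many operator units it occupies; per-step unit usage must stay
within the circuit's `operator_budget()`, otherwise construction fails
naming the step and the shortfall.

Two MSR schedules are provided:

* **Partially parallelized** (versions `msr-fIxJ`), six macro-steps: (1) all
  row sums and column sums; (2) the total sum together with the row means;
  (3) the column means; (4) the overall mean; (5) the residues, computed in
  parallel across rows but sequentially across columns; (6) the
  squared-residue reduction.  It instantiates `max(I, J)` units of each
  operator type.  Only the square configuration of that rule is externally
  anchored (8x8 uses 8 of each); the extension to non-square sizes is an
  extrapolation, deliberately isolated in `operator_requirements()` so it
  can be revised without touching the schedules.
* **Fully parallelized** (versions `msr-aIxJ`), five macro-steps: step 2
  additionally computes the column means, and all $I \cdot J$ residues are
  produced concurrently in step 4 -- which is what forces the much larger
  budget of $I \cdot J$ units per type (4x4 uses 16 of each).

The gene-selection circuit has four macro-steps: step 1 performs three
operations in parallel ($w_1 A$, $w_2 / M$, and the integer subtract
$M - R$), followed by the int-to-float conversion of $M - R$, the multiply
$(w_2/M)(M-R)$, and the final add.  Four operator types appear in total.
The integer subtraction is charged to the adder latency class; the model
has no separate integer ALU.  $A(x)$ enters the schedule as a *precomputed
operand*: the datapath evaluates only the fitness arithmetic, so classifier
time is deliberately outside the latency model.

Every trace is *executable*: `execute_schedule()` interprets the macro-steps
on concrete inputs, computing sums by scalar accumulation in the scheduled
order.  The invariant -- enforced in the test suite at relative tolerance
1e-12 -- is that a schedule is a reordering of the fitness arithmetic, never
a redefinition: its value must match `msr()` / `subset_fitness()` exactly up
to floating-point rounding.

## Latency and speedup model

Per-operator cycle counts are configuration (`latency_model()`); the
defaults (add 1, multiply 1, divide 8, convert 1, compare 1) encode only the
qualitative fact that pipelined floating-point division is markedly slower
than addition or multiplication.  No claim about any specific hardware's
cycle counts is implied.  A task group costs
$\lceil \mathrm{ops}/\mathrm{units} \rceil \times \mathrm{latency}$ per
operator type; a macro-step costs the maximum over its concurrent groups; a
trace costs the sum over its steps.

At the top level, `NF` replicated fitness units evaluate a population in
$\lceil P / NF \rceil$ batches.  After each batch a comparator tree with
`NC = floor(NF/2)` first-round comparators reduces the `NF` results pairwise
($\lceil \log_2 NF \rceil$ rounds, `NF - 1` comparisons; odd values pass
through as byes; ties go to the earlier index), and from the second batch on
one extra comparison updates the running best.  The sequential baseline
charges one operation per cycle slot plus the $P - 1$ best-tracking
comparisons a sequential loop also performs; with equal per-operation
latencies this guarantees speedup $\ge 1$ and makes parallel latency
monotone non-increasing in `NF` -- both are asserted as properties, and no
numeric speedup value is treated as a reproduction target, since measured
speedups depend on physical hardware.

## The evolutionary driver

`evolve()` is a deliberately standard generational GA: tournament selection
(size 2), uniform crossover (rate 0.9), per-bit flip mutation (rate $1/L$
by default), elitism of one.  The run is a pure function of the seed.  Gene
subsets use the mask directly as genome; biclusters concatenate a row mask
and a column mask, with repair flipping random bits on until each side has
at least 2 indices (an unconstrained MSR search collapses onto single rows
or columns, whose MSR is identically zero).

**The biclustering objective.**  Minimizing MSR alone cannot recover a
planted additive bicluster from Gaussian noise of equal cell-level variance:
for *any* submatrix free of row/column mixing -- whether inside the planted
block or in pure background -- the expected MSR is the same
$\sigma^2 (I-1)(J-1)/(IJ)$, so the MSR landscape carries no information
about where the additive structure lives, only about avoiding mixed
selections.  The default internal objective therefore maximizes

$$\mathrm{volume} \times (\text{total variance} - \mathrm{MSR}),$$

where total variance is the per-cell variance around the grand mean.  By
the two-way ANOVA decomposition, total variance splits exactly into
row-effect variance + column-effect variance + MSR, so the bracket is the
per-cell variance *explained by additive row and column effects* and the
product is the total additive signal captured by the bicluster.  It is
symmetric in rows and columns (an earlier row-variance-only variant was
discarded because appending noise *columns* was cost-free to it), grows
when genuinely coherent rows/columns are added, shrinks when mixing dilutes
the structure, and is near zero for flat, tiny or pure-noise submatrices.
Pure MSR minimization remains available (`objective = "msr"`); reported MSR
values are in all cases the un-negated MSR of the decoded bicluster.

## Synthetic data: what it emulates and what it does not

`make_bicluster_matrix()` plants one bicluster -- constant level, additive
$a_i + c_j$ structure, or a constant shift -- into an i.i.d. standard normal
background, with configurable signal magnitude and within-block noise SD.
`make_classification_dataset()` builds a balanced two-class dataset in which
`k` informative genes separate the class means by `effect` noise-SDs and all
other genes are pure noise.  Defaults used throughout the recovery tests:
background $N(0,1)$, signal magnitude 10, noise SD 1 for biclustering;
$N = 20$, $M = 50$, $k = 5$, effect 3 for classification -- a strong but
not degenerate planted signal, of the kind wrapper-selection studies treat
as clearly recoverable.

The generators emulate *controllable structure in noise*, nothing more.
Real microarray or single-cell data have correlated genes, heavy-tailed and
intensity-dependent noise, batch effects and missing values; none of that is
modeled, and no normalization is performed.  A green recovery test therefore
establishes that the fitness functions and the EA do what they claim on
clean planted structure -- it does not establish performance on real
platform data.

## Numerical choices

* Double precision throughout; R has no native 32-bit float type, so
  bit-level emulation of single-precision hardware arithmetic is out of
  scope (the fitness values themselves are precision-independent at the
  tolerances used).
* Plain left-to-right summation; no compensated summation.  The oracle
  tolerances (1e-10 against an independent four-loop MSR implementation,
  1e-12 for schedule-vs-direct equivalence) absorb rounding at the matrix
  sizes involved.
* All indices are 1-based, following R convention; masks and index lists at
  the interfaces are 1-based as well.
* Ties: nearest-centroid prediction prefers the first class in sorted
  order; comparator reduction prefers the earlier index.  Both are
  conventions chosen for determinism, not externally mandated.
* The on-disk matrix format is TSV (comma selectable), with numbers written
  at 17 significant digits so read/write round-trips are exact.

## Known limitations

* The latency model is a placeholder parameterization, not a calibrated
  model of any FPGA or CPU; only directional claims (monotonicity in `NF`,
  speedup $\ge 1$) are meaningful.
* The partial-model operator-count rule for non-square matrices
  (`max(I, J)`) is an extrapolation from the square case.
* The default classifier is nearest-centroid; SVM-based accuracy terms from
  the wrapper-selection literature are intentionally not reimplemented --
  the fitness treats the classifier as a black box.
* The EA is a reference implementation for exercising the fitness
  functions, not a tuned biclustering or feature-selection method;
  multi-objective formulations are out of scope.
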