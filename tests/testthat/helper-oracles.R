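# Independent oracles, written directly from the defining formulas with no
# shared code with the package internals.

# Four-loop mean-squared-residue oracle.
naive_msr <- function(b) {
  I <- nrow(b)
  J <- ncol(b)
  biJ <- numeric(I)
  for (i in seq_len(I)) {
    s <- 0
    for (j in seq_len(J)) s <- s + b[i, j]
    biJ[i] <- s / J
  }
  bIj <- numeric(J)
  for (j in seq_len(J)) {
    s <- 0
    for (i in seq_len(I)) s <- s + b[i, j]
    bIj[j] <- s / I
  }
  s <- 0
  for (i in seq_len(I)) for (j in seq_len(J)) s <- s + b[i, j]
  bIJ <- s / (I * J)
  acc <- 0
  for (i in seq_len(I)) {
    for (j in seq_len(J)) {
      r <- b[i, j] - biJ[i] - bIj[j] + bIJ
      acc <- acc + r * r
    }
  }
  acc / (I * J)
}

rand_mat <- function(I, J, lo = -100, hi = 100) {
  matrix(stats::runif(I * J, lo, hi), I, J)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

rel_diff <- function(a, b) abs(a - b) / max(abs(a), abs(b), 1e-300)
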