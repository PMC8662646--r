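# Independent brute-force oracles and small fixture builders shared by
# the unit and acceptance tests. Oracles deliberately use plain loops
# and definitions, not the package's vectorized code paths.

aa20 <- alncons::AA20

# random gap-free alignment as a named character vector of strings
random_alignment <- function(n, L, gap_prob = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seqs <- vapply(seq_len(n), function(i) {
    r <- sample(aa20, L, replace = TRUE)
    if (gap_prob > 0) r[runif(L) < gap_prob] <- "-"
    paste(r, collapse = "")
  }, character(1))
  names(seqs) <- sprintf("s%02d", seq_len(n))
  alignment(seqs)
}

# pair similarity with gap/X/* scoring 0 against anything
.pair_sim <- function(a, b, sim) {
  if (!(a %in% aa20) || !(b %in% aa20)) 0 else sim[a, b]
}

# brute-force evolutionary-distance weights: d(i,j) = 1 - mean sim over
# columns where both carry a residue; w_i = mean_j d(i,j)
brute_weights <- function(aln, sim) {
  m <- aln$mat
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    vals <- c()
    for (x in seq_len(ncol(m))) {
      if (m[i, x] %in% aa20 && m[j, x] %in% aa20)
        vals <- c(vals, sim[m[i, x], m[j, x]])
    }
    d[i, j] <- if (length(vals) == 0) 1 else 1 - mean(vals)
  }
  w <- rowSums(d) / (n - 1)
  if (all(w == 0)) w <- rep(1 / n, n)
  w
}

# brute-force weighted sum-of-pairs column conservation
brute_valdar <- function(aln, sim, weights = NULL) {
  m <- aln$mat
  n <- nrow(m)
  if (is.null(weights)) weights <- brute_weights(aln, sim)
  sapply(seq_len(ncol(m)), function(x) {
    num <- 0; den <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      num <- num + weights[i] * weights[j] * .pair_sim(m[i, x], m[j, x], sim)
      den <- den + weights[i] * weights[j]
    }
    num / den
  })
}

# correspondence-analysis oracle computed without any SVD: the Gram
# matrix of the full set of row principal coordinates is
# Dr^{-1/2} S S' Dr^{-1/2}, and the squared singular values are the
# eigenvalues of S S' (dense symmetric eigensolver). Both are invariant
# under the rotations that make per-axis comparison ill-defined when
# singular values tie.
brute_ca <- function(ind) {
  total <- sum(ind)
  P <- ind / total
  r <- rowSums(P)
  cm <- colSums(P)
  keep <- cm > 0
  P <- P[, keep, drop = FALSE]
  cm <- cm[keep]
  S <- (P - outer(r, cm)) / sqrt(outer(r, cm))
  G <- S %*% t(S)
  gram <- G / sqrt(outer(r, r))
  lam <- pmax(eigen(G, symmetric = TRUE, only.values = TRUE)$values, 0)
  list(gram = gram, singular_values = sqrt(lam), total_inertia = sum(lam))
}

# identity similarity matrix: 1 on the diagonal, 0 elsewhere
identity_sim <- function() {
  S <- diag(1, 20)
  dimnames(S) <- list(aa20, aa20)
  S
}
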