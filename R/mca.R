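# Multiple correspondence analysis of alignment sequence space: each
# alignment column is a categorical variable with 21 levels (20 amino
# acids + gap); sequences are projected onto the leading principal
# coordinates of the one-hot indicator matrix.

MCA_SYMBOLS <- c(AA20, "-")

#' One-hot encode an alignment
#'
#' Expands every alignment column into 21 indicator columns (20 amino
#' acids and gap); `X` and `*` map to the gap category. Each sequence's
#' block for one alignment column sums to exactly 1. Low-occupancy
#' columns should be removed first with
#' [filter_columns_by_occupancy()] (cutoff 0.3 upstream of MCA).
#'
#' @param aln An `alignment`.
#' @return Binary matrix, one row per sequence, `21 * aln_length(aln)`
#'   columns named `c<column>.<symbol>`.
#' @export
one_hot_encode <- function(aln) {
  n <- nseq(aln)
  L <- aln_length(aln)
  if (n == 0L || L == 0L) stop("empty alignment")
  sym <- aln$mat
  sym[sym %in% c("X", "*")] <- "-"
  k <- length(MCA_SYMBOLS)
  ind <- matrix(0L, n, L * k,
                dimnames = list(aln_ids(aln),
                                paste0("c", rep(seq_len(L), each = k), ".",
                                       rep(MCA_SYMBOLS, L))))
  level <- match(sym, MCA_SYMBOLS)            # n x L in column-major order
  colpos <- (rep(seq_len(L), each = n) - 1L) * k + level
  ind[cbind(rep(seq_len(n), L), colpos)] <- 1L
  ind
}

#' Decode a one-hot indicator matrix back to an alignment
#'
#' Inverse of [one_hot_encode()] up to the `X`/`*` -> gap merge.
#'
#' @param ind Indicator matrix from [one_hot_encode()].
#' @return An `alignment`.
#' @export
one_hot_decode <- function(ind) {
  k <- length(MCA_SYMBOLS)
  L <- ncol(ind) / k
  stopifnot(L == round(L))
  seqs <- apply(ind, 1L, function(r) {
    lev <- ((which(r == 1L) - 1L) %% k) + 1L
    paste(MCA_SYMBOLS[lev], collapse = "")
  })
  alignment(seqs)
}

#' Multiple correspondence analysis of an indicator matrix
#'
#' Standard correspondence analysis of the one-hot indicator matrix
#' (no Benzecri inertia correction): the matrix of relative frequencies
#' is centered by row and column masses, scaled by the inverse square
#' roots of the masses, and decomposed by SVD; sequences are projected
#' onto the first `k` principal coordinates. Eigenvector signs are
#' arbitrary, so a fixed convention is applied (the first entry of each
#' dimension with magnitude above tolerance is made positive) for
#' reproducibility.
#'
#' @param ind Indicator matrix from [one_hot_encode()].
#' @param k Number of components to keep (default 3); truncated with a
#'   warning if it exceeds the available rank.
#' @param tol Singular values below `tol * max(singular value)` are
#'   treated as zero rank.
#' @return An object of class `mca_result`: list with `coordinates`
#'   (n x k matrix of principal row coordinates), `explained_inertia`
#'   (per-component share of total inertia, non-increasing),
#'   `singular_values`, `total_inertia` and `k`.
#' @export
mca_project <- function(ind, k = 3L, tol = 1e-10) {
  stopifnot(is.matrix(ind), k >= 1L)
  total <- sum(ind)
  if (total == 0) stop("indicator matrix is all zero")
  P <- ind / total
  r <- rowSums(P)
  cm <- colSums(P)
  nz <- cm > 0                           # never-observed symbols carry no mass
  P <- P[, nz, drop = FALSE]
  cm <- cm[nz]
  S <- (P - outer(r, cm)) / sqrt(outer(r, cm))
  sv <- svd(S)
  rank <- sum(sv$d > tol * max(sv$d, tol))
  if (rank == 0L) {
    warning("alignment has no variation; all coordinates are zero")
    coords <- matrix(0, nrow(ind), k,
                     dimnames = list(rownames(ind), paste0("dim", seq_len(k))))
    return(structure(list(coordinates = coords,
                          explained_inertia = rep(0, k),
                          singular_values = rep(0, k),
                          total_inertia = 0, k = k),
                     class = "mca_result"))
  }
  if (k > rank) {
    warning("k = ", k, " exceeds available rank ", rank, "; truncated")
    k <- rank
  }
  d <- sv$d[seq_len(k)]
  U <- sv$u[, seq_len(k), drop = FALSE]
  coords <- (U / sqrt(r)) * rep(d, each = nrow(U))
  # sign convention: first coordinate entry of each dimension above
  # tolerance is positive
  for (j in seq_len(k)) {
    i <- which(abs(coords[, j]) > tol)[1]
    if (!is.na(i) && coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  dimnames(coords) <- list(rownames(ind), paste0("dim", seq_len(k)))
  total_inertia <- sum(sv$d^2)
  structure(list(coordinates = coords,
                 explained_inertia = d^2 / total_inertia,
                 singular_values = d,
                 total_inertia = total_inertia, k = k),
            class = "mca_result")
}

#' @export
print.mca_result <- function(x, ...) {
  cat(sprintf("MCA: %d sequences, %d components, total inertia %.4g\n",
              nrow(x$coordinates), x$k, x$total_inertia))
  cat("  explained inertia:",
      paste(signif(x$explained_inertia, 3), collapse = " "), "\n")
  invisible(x)
}

#' Run MCA on an alignment
#'
#' Convenience wrapper: occupancy-filter the alignment (default cutoff
#' 0.3), one-hot encode, and project onto the first `k` principal
#' coordinates.
#'
#' @param aln An `alignment`.
#' @param k Components (default 3).
#' @param min_occupancy Occupancy cutoff applied before encoding
#'   (default 0.3).
#' @return An `mca_result` (see [mca_project()]) with the retained
#'   column indices in `$kept_columns`.
#' @export
mca_alignment <- function(aln, k = 3L, min_occupancy = 0.3) {
  f <- filter_columns_by_occupancy(aln, min_occupancy)
  res <- mca_project(one_hot_encode(f$alignment), k = k)
  res$kept_columns <- f$kept
  res
}
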