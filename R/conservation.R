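# Per-column conservation statistics and the bootstrapped clade
# conservation-bias statistic.

#' Construct a conservation profile
#'
#' A per-alignment-column real-valued score track tagged with its score
#' type and bounds.
#'
#' @param score_type One of `"valdar"`, `"jsd"`, `"electrostatic"`,
#'   `"hydrophobic"`, `"rna_binding"`, `"ss_agreement"`, `"bias"`.
#' @param values Numeric vector, one value per alignment column; `NA`
#'   marks columns where the score is undefined.
#' @param bounds Length-2 numeric `(lo, hi)`; `hi` may be `Inf`.
#' @return An object of class `cons_profile`.
#' @export
cons_profile <- function(score_type, values, bounds) {
  stopifnot(is.character(score_type), length(bounds) == 2L)
  ok <- !is.na(values)
  if (any(values[ok] < bounds[1] - 1e-9 | values[ok] > bounds[2] + 1e-9))
    stop("profile values outside declared bounds [",
         bounds[1], ", ", bounds[2], "]")
  structure(list(score_type = score_type, values = as.numeric(values),
                 bounds = as.numeric(bounds)),
            class = "cons_profile")
}

#' @export
print.cons_profile <- function(x, ...) {
  cat(sprintf("conservation profile '%s': %d columns, bounds [%g, %g]\n",
              x$score_type, length(x$values), x$bounds[1], x$bounds[2]))
  cat("  summary:", paste(signif(summary(x$values), 3), collapse = " "), "\n")
  invisible(x)
}

# integer-encode an alignment matrix: 1..20 for AA20, 0 for gap/X/*
.encode <- function(aln) {
  codes <- stats::setNames(rep(0L, length(ALN_ALPHABET)), ALN_ALPHABET)
  codes[AA20] <- seq_along(AA20)
  m <- matrix(codes[aln$mat], nrow = nseq(aln))
  rownames(m) <- aln_ids(aln)
  m
}

#' Default residue similarity matrix for the Valdar score
#'
#' A 20x20 symmetric similarity matrix in \[0, 1\] with unit diagonal,
#' obtained from a standard log-odds substitution matrix (BLOSUM62 by
#' default) by the per-pair affine rescaling
#' `sim(a, b) = (M(a, b) - min M) / (min(M(a, a), M(b, b)) - min M)`,
#' which maps every diagonal entry to exactly 1 and every off-diagonal
#' entry into \[0, 1). The matrix is pluggable everywhere it is used, so
#' any other stereochemical similarity table can be substituted.
#'
#' @param base Name of a substitution matrix shipped with Biostrings
#'   (e.g. `"BLOSUM62"`, `"BLOSUM50"`, `"PAM250"`).
#' @return 20x20 numeric matrix with `AA20` dimnames.
#' @export
similarity_matrix <- function(base = "BLOSUM62") {
  e <- new.env()
  utils::data(list = base, package = "Biostrings", envir = e)
  M <- e[[base]][AA20, AA20]
  mn <- min(M)
  d <- diag(M)
  denom <- outer(d, d, pmin) - mn
  S <- (M - mn) / denom
  S <- pmin(pmax(S, 0), 1)
  diag(S) <- 1
  S <- (S + t(S)) / 2  # guard against asymmetric inputs
  dimnames(S) <- list(AA20, AA20)
  S
}

# similarity matrix extended with a 0-row/col for gap/X/* (code 0)
.sim_ext <- function(sim) {
  S <- matrix(0, 21L, 21L)
  S[2:21, 2:21] <- sim[AA20, AA20]
  S
}

#' Evolutionary-distance sequence weights
#'
#' Down-weights over-represented, mutually similar sequences so that
#' densely sampled clades do not dominate column conservation. The
#' distance between two sequences is one minus the mean residue
#' similarity over the columns where both carry a residue (distance 1
#' when they share no columns); a sequence's weight is its mean distance
#' to all others. Identical sequences fall back to uniform weights.
#'
#' @param aln An `alignment` with at least two sequences.
#' @param sim Residue similarity matrix, see [similarity_matrix()].
#' @return Positive numeric vector named by sequence id.
#' @export
sequence_weights <- function(aln, sim = similarity_matrix()) {
  n <- nseq(aln)
  if (n < 2L) stop("sequence weighting needs at least two sequences")
  enc <- .encode(aln)
  S <- .sim_ext(sim)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- enc[i, ] > 0L & enc[j, ] > 0L
      d <- if (!any(shared)) 1 else
        1 - mean(S[cbind(enc[i, shared] + 1L, enc[j, shared] + 1L)])
      D[i, j] <- D[j, i] <- d
    }
  }
  w <- rowSums(D) / (n - 1L)
  if (all(w == 0)) w <- rep(1 / n, n)
  stats::setNames(w, aln_ids(aln))
}

#' Valdar weighted sum-of-pairs conservation score
#'
#' For each column x,
#' `V(x) = sum_{i<j} w_i w_j sim(s_i(x), s_j(x)) / sum_{i<j} w_i w_j`,
#' where `w` are the evolutionary-distance sequence weights and the
#' residue similarity of a gap, `X` or `*` against anything is 0. Values
#' lie in \[0, 1\]: 1 for a fully conserved gap-free column, 0 when every
#' sequence pair has similarity 0.
#'
#' @param aln An `alignment` with at least two sequences.
#' @param sim Residue similarity matrix, see [similarity_matrix()].
#' @param weights Optional precomputed sequence weights (one per row);
#'   computed from `aln` and `sim` when `NULL`.
#' @return A `cons_profile` of type `"valdar"`.
#' @export
valdar_score <- function(aln, sim = similarity_matrix(), weights = NULL) {
  n <- nseq(aln)
  if (n < 2L) stop("Valdar score needs at least two sequences")
  if (is.null(weights)) weights <- sequence_weights(aln, sim)
  stopifnot(length(weights) == n, all(weights >= 0))
  w <- as.numeric(weights)
  enc <- .encode(aln)
  S <- .sim_ext(sim)
  den <- (sum(w)^2 - sum(w^2)) / 2
  if (den <= 0) stop("degenerate weights: all pair weights are zero")
  vals <- vapply(seq_len(aln_length(aln)), function(x) {
    v <- enc[, x] + 1L
    Sm <- S[v, v, drop = FALSE]
    (as.numeric(t(w) %*% Sm %*% w) - sum(w^2 * diag(Sm))) / 2 / den
  }, numeric(1))
  cons_profile("valdar", pmin(pmax(vals, 0), 1), c(0, 1))
}

#' Jensen-Shannon divergence conservation score
#'
#' Per column, the base-2 Jensen-Shannon divergence (mixture weight 1/2)
#' between the column's amino-acid frequency distribution and a
#' background distribution, multiplied by the column's residue fraction
#' (so gappy columns are penalized), then smoothed with a symmetric
#' window: `final = (1 - window_weight) * own + window_weight * mean` of
#' up to `window` flanking columns on each side. Values lie in \[0, 1\].
#'
#' @param aln An `alignment`.
#' @param background Length-20 probability vector over [AA20] (uniform
#'   by default).
#' @param window Flank size in columns on each side (default 3).
#' @param window_weight Weight of the flank mean in \[0, 1\] (default 0.5);
#'   0 disables smoothing.
#' @return A `cons_profile` of type `"jsd"`.
#' @export
jsd_score <- function(aln, background = rep(1 / 20, 20), window = 3L,
                      window_weight = 0.5) {
  stopifnot(length(background) == 20L, all(background >= 0))
  if (abs(sum(background) - 1) > 1e-9)
    stop("background must be a probability vector summing to 1")
  if (any(background == 0))
    stop("background must be strictly positive over the 20 amino acids")
  stopifnot(window >= 0L, window_weight >= 0, window_weight <= 1)
  enc <- .encode(aln)
  n <- nseq(aln)
  L <- aln_length(aln)
  q <- as.numeric(background)
  raw <- vapply(seq_len(L), function(x) {
    v <- enc[, x]
    k <- sum(v > 0L)
    if (k == 0L) return(0)
    p <- tabulate(v[v > 0L], nbins = 20L) / k
    m <- (p + q) / 2
    kl <- function(a, b) {
      nz <- a > 0
      sum(a[nz] * log2(a[nz] / b[nz]))
    }
    jsd <- 0.5 * kl(p, m) + 0.5 * kl(q, m)
    jsd * (k / n)
  }, numeric(1))
  vals <- vapply(seq_len(L), function(x) {
    flank <- setdiff(max(1L, x - window):min(L, x + window), x)
    if (length(flank) == 0L) return(raw[x])
    (1 - window_weight) * raw[x] + window_weight * mean(raw[flank])
  }, numeric(1))
  cons_profile("jsd", pmin(pmax(vals, 0), 1), c(0, 1))
}

#' Per-residue charge table for the electrostatic conservation score
#'
#' Aspartate and glutamate score -1, arginine and lysine +1, histidine
#' +0.5; all other residues, `X`, `*` and gaps score 0.
#'
#' @return Named numeric vector over the full alignment alphabet.
#' @export
charge_table <- function() {
  ch <- stats::setNames(rep(0, length(ALN_ALPHABET)), ALN_ALPHABET)
  ch[c("D", "E")] <- -1
  ch[c("R", "K")] <- 1
  ch["H"] <- 0.5
  ch
}

#' Electrostatic conservation score
#'
#' Per column, the sum of per-residue charges over all sequences divided
#' by the total sequence count (gaps contribute 0 and dilute the score).
#' Bounds are \[-1, 1\]: -1 means a negative charge conserved across all
#' sequences, +1 a conserved positive charge.
#'
#' @param aln An `alignment`.
#' @param charges Per-symbol charge table, see [charge_table()].
#' @return A `cons_profile` of type `"electrostatic"`.
#' @export
electrostatic_score <- function(aln, charges = charge_table()) {
  missing <- setdiff(unique(as.vector(aln$mat)), names(charges))
  if (length(missing) > 0L)
    stop("charge table lacks symbols: ", paste(missing, collapse = " "))
  vals <- colSums(matrix(charges[aln$mat], nrow = nseq(aln))) / nseq(aln)
  cons_profile("electrostatic", vals, c(-1, 1))
}

#' Default per-residue hydrophobicity scale
#'
#' The package's bundled default is the Kyte-Doolittle hydropathy index
#' affinely rescaled to the range \[-2.20, 5.39\] used by the
#' conservation pipeline (isoleucine at the maximum 5.39, arginine at
#' the minimum -2.20). Any other 20-residue table can be supplied to
#' [hydrophobicity_score()] instead.
#'
#' @return Named numeric vector over [AA20] with
#'   `max = 5.39` and `min = -2.20`.
#' @export
hydrophobicity_scale <- function() {
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
          E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
          M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
          Y = -1.3, V = 4.2)
  lo <- -2.20
  hi <- 5.39
  out <- (kd - min(kd)) / (max(kd) - min(kd)) * (hi - lo) + lo
  out[AA20]
}

#' Hydrophobicity conservation score
#'
#' Per column, the mean of per-residue hydrophobicity values over all
#' sequences, with gaps, `X` and `*` contributing 0. With the default
#' scale the score is bounded between -2.20 and 5.39; a gap-free column
#' uniformly composed of the most hydrophobic residue attains the scale
#' maximum.
#'
#' @param aln An `alignment`.
#' @param scale Named numeric vector covering the 20 amino acids, see
#'   [hydrophobicity_scale()].
#' @return A `cons_profile` of type `"hydrophobic"`.
#' @export
hydrophobicity_score <- function(aln, scale = hydrophobicity_scale()) {
  if (!all(AA20 %in% names(scale)))
    stop("hydrophobicity scale must cover all 20 amino acids")
  full <- stats::setNames(rep(0, length(ALN_ALPHABET)), ALN_ALPHABET)
  full[names(scale)] <- scale
  vals <- colSums(matrix(full[aln$mat], nrow = nseq(aln))) / nseq(aln)
  lo <- min(0, min(scale))
  hi <- max(0, max(scale))
  cons_profile("hydrophobic", vals, c(lo, hi))
}

# thread per-sequence ungapped tracks through the gapped rows; returns an
# n x L numeric matrix with NA where a sequence has a gap
.thread_tracks <- function(aln, tracks, what) {
  out <- matrix(NA_real_, nseq(aln), aln_length(aln),
                dimnames = list(aln_ids(aln), NULL))
  for (id in aln_ids(aln)) {
    if (!id %in% names(tracks)) stop("missing ", what, " track for ", id)
    row <- aln$mat[id, ]
    pos <- which(row != "-")
    tr <- tracks[[id]]
    if (length(tr) != length(pos))
      stop("track length mismatch for ", id, ": track has ", length(tr),
           " values, sequence has ", length(pos), " residues")
    out[id, pos] <- tr
  }
  out
}

#' Aggregate per-sequence RNA-binding propensity tracks
#'
#' Each sequence's per-residue RNA-binding propensity vector (computed
#' externally on the ungapped sequence) is threaded through its gapped
#' alignment row; the per-column score is the mean over the sequences
#' that carry a residue at that column. Columns with no contributing
#' sequence are `NA`.
#'
#' @param aln An `alignment`.
#' @param tracks Named list: id -> numeric vector whose length equals the
#'   sequence's ungapped length.
#' @return A `cons_profile` of type `"rna_binding"`.
#' @export
rna_binding_conservation <- function(aln, tracks) {
  th <- .thread_tracks(aln, tracks, "RNA-binding")
  vals <- colMeans(th, na.rm = TRUE)
  vals[is.nan(vals)] <- NA_real_
  ok <- vals[!is.na(vals)]
  lo <- if (length(ok)) min(ok, 0) else 0
  hi <- if (length(ok)) max(ok, 1) else 1
  cons_profile("rna_binding", vals, c(lo, hi))
}

#' Secondary-structure agreement score
#'
#' Per-sequence 3-state secondary-structure strings over `{H, E, C}`
#' (helix, strand, coil; predicted on the ungapped sequences) are
#' threaded through the gapped rows; the per-column score is the
#' frequency of the modal state among contributing sequences. Ties are
#' broken toward `H < E < C` for the reported modal label; the score
#' value is unaffected. Columns with no contributing sequence are `NA`.
#'
#' @param aln An `alignment`.
#' @param ss Named list or character vector: id -> 3-state string whose
#'   length equals the sequence's ungapped length.
#' @return A `cons_profile` of type `"ss_agreement"` with the per-column
#'   modal state in `attr(, "modal_state")`.
#' @export
ss_agreement <- function(aln, ss) {
  states <- c("H", "E", "C")
  tracks <- lapply(ss, function(s) {
    v <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    bad <- setdiff(unique(v), states)
    if (length(bad)) stop("secondary-structure states must be H/E/C, got: ",
                          paste(bad, collapse = " "))
    match(v, states)
  })
  names(tracks) <- names(ss)
  th <- .thread_tracks(aln, tracks, "secondary-structure")
  L <- aln_length(aln)
  vals <- rep(NA_real_, L)
  modal <- rep(NA_character_, L)
  for (x in seq_len(L)) {
    v <- th[, x]
    v <- v[!is.na(v)]
    if (length(v) == 0L) next
    counts <- tabulate(v, nbins = 3L)
    vals[x] <- max(counts) / length(v)
    modal[x] <- states[which.max(counts)]  # which.max: first max, H < E < C
  }
  out <- cons_profile("ss_agreement", vals, c(0, 1))
  attr(out, "modal_state") <- modal
  out
}

#' Bootstrapped mean Valdar score of a large clade
#'
#' To compare conservation between clades of very different sample sizes
#' (e.g. densely sampled Holometabola vs sparse Hemimetabola), the large
#' clade is repeatedly subsampled to the small clade's size: each
#' iteration draws `n_draws` distinct sequences without replacement,
#' computes the Valdar score on the sub-alignment (sequence weights
#' recomputed per draw), and the per-column scores are averaged over
#' iterations.
#'
#' @param aln An `alignment`.
#' @param labeling A `group_labeling`.
#' @param large_group Name of the group to subsample.
#' @param n_draws Sequences per draw; typically the small group's size.
#' @param n_iterations Bootstrap iterations (default 1000).
#' @param seed Integer seed for reproducible draws.
#' @param sim Residue similarity matrix.
#' @param replace Draw with replacement instead (default `FALSE`).
#' @return A `cons_profile` of type `"valdar"` holding the per-column
#'   bootstrap mean, with `n_iterations`, `n_draws` and `seed` attached
#'   as attributes.
#' @export
bootstrap_group_score <- function(aln, labeling, large_group, n_draws,
                                  n_iterations = 1000L, seed = NULL,
                                  sim = similarity_matrix(),
                                  replace = FALSE) {
  sub <- partition_alignment(aln, labeling, large_group)
  ids <- aln_ids(sub)
  if (!replace && n_draws > length(ids))
    stop("n_draws (", n_draws, ") exceeds group size (", length(ids), ")")
  stopifnot(n_draws >= 2L, n_iterations >= 1L)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  acc <- numeric(aln_length(sub))
  for (it in seq_len(n_iterations)) {
    draw <- sample(ids, n_draws, replace = replace)
    sa <- sub
    sa$mat <- sub$mat[draw, , drop = FALSE]
    acc <- acc + valdar_score(sa, sim = sim)$values
  }
  out <- cons_profile("valdar", acc / n_iterations, c(0, 1))
  attr(out, "n_iterations") <- n_iterations
  attr(out, "n_draws") <- n_draws
  attr(out, "seed") <- seed
  out
}

#' Between-clade conservation bias
#'
#' Per column, the ratio of logarithms of the two clades' conservation
#' scores: `bias(x) = log(V_num(x)) / log(V_den(x))` after clamping both
#' scores into `[epsilon, 1 - epsilon]` (the log base cancels in the
#' ratio). A bias of 1 means equal conservation; with scores below 1,
#' bias > 1 means the numerator clade is *less* conserved at that column
#' (its log is more negative). The statistic is antisymmetric:
#' `bias(a, b) * bias(b, a) = 1` at every column.
#'
#' @param score_num,score_den Per-column scores in \[0, 1\] (numeric
#'   vectors or `cons_profile`s of equal length); conventionally the
#'   bootstrapped holometabolous mean and the direct hemimetabolous
#'   score.
#' @param epsilon Clamping constant guarding `log(0)` and `log(1)`
#'   (default 1e-6).
#' @return A `cons_profile` of type `"bias"` (positive, unbounded above).
#' @export
conservation_bias <- function(score_num, score_den, epsilon = 1e-6) {
  a <- if (inherits(score_num, "cons_profile")) score_num$values else as.numeric(score_num)
  b <- if (inherits(score_den, "cons_profile")) score_den$values else as.numeric(score_den)
  if (length(a) != length(b))
    stop("length mismatch: ", length(a), " vs ", length(b))
  stopifnot(epsilon > 0, epsilon < 0.5)
  cl <- function(x) pmin(pmax(x, epsilon), 1 - epsilon)
  vals <- log(cl(a)) / log(cl(b))
  cons_profile("bias", vals, c(0, Inf))
}

#' Clade conservation-bias analysis of an alignment
#'
#' Convenience wrapper composing the full between-clade comparison: the
#' large clade's per-column Valdar score is estimated by bootstrap
#' subsampling to the small clade's size ([bootstrap_group_score()]),
#' the small clade is scored directly, and the per-column bias is the
#' ratio of log scores ([conservation_bias()]).
#'
#' @param aln An `alignment`.
#' @param labeling A `group_labeling` with the two clades.
#' @param large_group,small_group Group names (numerator and denominator
#'   of the bias, respectively).
#' @param n_iterations Bootstrap iterations (default 1000).
#' @param seed Integer seed.
#' @param sim Residue similarity matrix.
#' @param epsilon Clamping constant for the log ratio.
#' @return An object of class `bias_result`: list with `bias`
#'   (`cons_profile`), `bootstrap_mean_group_score` (per-column numeric),
#'   `small_group_score` (per-column numeric), `n_iterations`, `n_draws`,
#'   `seed`.
#' @export
clade_bias <- function(aln, labeling, large_group, small_group,
                       n_iterations = 1000L, seed = NULL,
                       sim = similarity_matrix(), epsilon = 1e-6) {
  small <- partition_alignment(aln, labeling, small_group)
  n_draws <- nseq(small)
  boot <- bootstrap_group_score(aln, labeling, large_group,
                                n_draws = n_draws,
                                n_iterations = n_iterations,
                                seed = seed, sim = sim)
  direct <- valdar_score(small, sim = sim)
  structure(list(bias = conservation_bias(boot, direct, epsilon = epsilon),
                 bootstrap_mean_group_score = boot$values,
                 small_group_score = direct$values,
                 n_iterations = n_iterations,
                 n_draws = n_draws,
                 seed = seed),
            class = "bias_result")
}

#' Mean conservation score over a region
#'
#' Arithmetic mean of a profile over a named set of alignment columns
#' (e.g. a helix of the LOTUS domain); columns where the score is
#' undefined are excluded.
#'
#' @param profile A `cons_profile`.
#' @param reg A `region`.
#' @return A single number.
#' @export
region_mean <- function(profile, reg) {
  cols <- reg$columns
  if (length(cols) == 0L) stop("empty region: ", reg$name)
  if (any(cols < 1L | cols > length(profile$values)))
    stop("region '", reg$name, "' has columns outside the profile")
  v <- profile$values[cols]
  if (all(is.na(v))) stop("region '", reg$name, "' has no defined scores")
  mean(v, na.rm = TRUE)
}
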