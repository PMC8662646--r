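# Synthetic-data generators: alignments with plantable per-column and
# per-clade conservation, domain-hit tables with known architecture
# classes, and per-taxon sequence sets with isoform/duplicate structure.
# These are first-class, seeded generators used by the test suite and by
# anyone validating a conservation analysis end to end.

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  expr
}

#' Specify a synthetic alignment with planted conservation
#'
#' Describes a star-phylogeny alignment: independent background draws at
#' every column, except at *conserved columns* where each group carries
#' a planted residue with probability `1 - p` (its substitution
#' probability) and a background draw otherwise. Gaps are inserted
#' i.i.d. at `gap_probability`, never at conserved columns unless
#' `gap_at_conserved` is set, so planted truth stays exact.
#'
#' @param length Column count.
#' @param group_sizes Named integer vector: group name -> sequence count
#'   (all >= 1).
#' @param conserved_columns List keyed by column index (as character or
#'   via `col` fields): each element a list with `col` (column index),
#'   `residue` (planted amino acid) and `sub_prob` (either one number or
#'   a named vector of per-group substitution probabilities in \[0, 1\]).
#' @param background_frequencies Length-20 probability vector over
#'   [AA20]; uniform by default (the simplest null).
#' @param gap_probability Fraction in \[0, 1).
#' @param gap_at_conserved Allow gaps at conserved columns (default
#'   `FALSE`).
#' @param seed Integer seed; identical seeds give identical output.
#' @return An object of class `conservation_spec`.
#' @export
conservation_spec <- function(length, group_sizes = c(all = 10L),
                              conserved_columns = list(),
                              background_frequencies = rep(1 / 20, 20),
                              gap_probability = 0,
                              gap_at_conserved = FALSE, seed = NULL) {
  stopifnot(length >= 1L)
  if (is.null(names(group_sizes)) || any(group_sizes < 1L))
    stop("group_sizes must be named counts >= 1 (empty group not allowed)")
  bf <- as.numeric(background_frequencies)
  if (length(bf) != 20L || any(bf < 0) || abs(sum(bf) - 1) > 1e-9)
    stop("background_frequencies must be 20 non-negative values summing to 1")
  stopifnot(gap_probability >= 0, gap_probability < 1)
  for (cc in conserved_columns) {
    stopifnot(!is.null(cc$col), cc$col >= 1L, cc$col <= length,
              cc$residue %in% AA20,
              all(cc$sub_prob >= 0), all(cc$sub_prob <= 1))
  }
  structure(list(length = as.integer(length),
                 group_sizes = group_sizes,
                 conserved_columns = conserved_columns,
                 background_frequencies = bf,
                 gap_probability = gap_probability,
                 gap_at_conserved = gap_at_conserved,
                 seed = seed),
            class = "conservation_spec")
}

#' Generate a synthetic alignment from a conservation specification
#'
#' @param spec A `conservation_spec`.
#' @return List with `alignment` (an [alignment]; ids
#'   `<group>_<i>`, each sequence its own taxon) and `labeling` (a
#'   [group_labeling] over the spec's groups).
#' @export
make_alignment <- function(spec) {
  stopifnot(inherits(spec, "conservation_spec"))
  .with_seed(spec$seed, {
    L <- spec$length
    planted_cols <- vapply(spec$conserved_columns, function(cc)
      as.integer(cc$col), integer(1))
    groups <- list()
    seqs <- character(0)
    for (g in names(spec$group_sizes)) {
      ids <- paste0(g, "_", seq_len(spec$group_sizes[[g]]))
      groups[[g]] <- ids
      for (id in ids) {
        row <- sample(AA20, L, replace = TRUE,
                      prob = spec$background_frequencies)
        for (cc in spec$conserved_columns) {
          p <- if (length(cc$sub_prob) == 1L && is.null(names(cc$sub_prob)))
            cc$sub_prob else cc$sub_prob[[g]]
          if (is.null(p) || is.na(p))
            stop("no substitution probability for group ", g,
                 " at column ", cc$col)
          if (stats::runif(1) >= p) row[cc$col] <- cc$residue
        }
        if (spec$gap_probability > 0) {
          gap <- stats::runif(L) < spec$gap_probability
          if (!spec$gap_at_conserved && length(planted_cols))
            gap[planted_cols] <- FALSE
          row[gap] <- "-"
        }
        seqs[id] <- paste(row, collapse = "")
      }
    }
    taxon <- stats::setNames(names(seqs), names(seqs))
    list(alignment = alignment(seqs, taxon = taxon),
         labeling = group_labeling(groups))
  })
}

#' Generate a synthetic domain-hit table with truth labels
#'
#' Emits hit records for four planted architecture classes: `n_true`
#' targets with LOTUS before OSK and both E-values below 0.05 (the only
#' class satisfying the homolog definition), `n_reversed` with OSK
#' before LOTUS, `n_single` with only one domain, and `n_weak` with
#' correct order but one E-value at or above 0.05.
#'
#' @param n_true,n_reversed,n_single,n_weak Non-negative counts.
#' @param seed Integer seed.
#' @return List with `hits` (data frame as from [read_domain_hits()])
#'   and `truth` (data frame `target_id`, `class`, `is_homolog`).
#' @export
make_domain_hit_table <- function(n_true, n_reversed = 0L, n_single = 0L,
                                  n_weak = 0L, seed = NULL) {
  stopifnot(n_true >= 0L, n_reversed >= 0L, n_single >= 0L, n_weak >= 0L)
  .with_seed(seed, {
    strong <- function(k) 10^stats::runif(k, -12, -3)
    weak <- function(k) stats::runif(k, 0.05, 10)
    rows <- list(); truth <- list()
    add <- function(tg, domain, start, end, ev)
      rows[[length(rows) + 1L]] <<- data.frame(
        target_id = tg, domain = domain, start = start, end = end,
        e_value = ev, stringsAsFactors = FALSE)
    mark <- function(tg, class, is_homolog)
      truth[[length(truth) + 1L]] <<- data.frame(
        target_id = tg, class = class, is_homolog = is_homolog,
        stringsAsFactors = FALSE)
    for (i in seq_len(n_true)) {
      tg <- sprintf("true_%03d", i)
      add(tg, "LOTUS", 10L, 100L, strong(1))
      add(tg, "OSK", 150L, 400L, strong(1))
      mark(tg, "true", TRUE)
    }
    for (i in seq_len(n_reversed)) {
      tg <- sprintf("reversed_%03d", i)
      add(tg, "OSK", 10L, 260L, strong(1))
      add(tg, "LOTUS", 300L, 390L, strong(1))
      mark(tg, "reversed", FALSE)
    }
    for (i in seq_len(n_single)) {
      tg <- sprintf("single_%03d", i)
      add(tg, if (i %% 2L == 0L) "OSK" else "LOTUS", 10L, 100L, strong(1))
      mark(tg, "single", FALSE)
    }
    for (i in seq_len(n_weak)) {
      tg <- sprintf("weak_%03d", i)
      if (i %% 2L == 0L) {
        add(tg, "LOTUS", 10L, 100L, weak(1))
        add(tg, "OSK", 150L, 400L, strong(1))
      } else {
        add(tg, "LOTUS", 10L, 100L, strong(1))
        add(tg, "OSK", 150L, 400L, weak(1))
      }
      mark(tg, "weak", FALSE)
    }
    hits <- if (length(rows)) do.call(rbind, rows) else
      data.frame(target_id = character(0), domain = character(0),
                 start = integer(0), end = integer(0),
                 e_value = numeric(0), stringsAsFactors = FALSE)
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(target_id = character(0), class = character(0),
                 is_homolog = logical(0), stringsAsFactors = FALSE)
    list(hits = hits, truth = truth)
  })
}

#' Write domain hits as a HMMER 3 domtblout file
#'
#' Produces a text file in the per-domain tabular layout emitted by
#' `hmmsearch --domtblout` (comment header, whitespace-aligned fields,
#' envelope coordinates in columns 20-21, i-E-value in column 13) that
#' round-trips through [read_domain_hits()].
#'
#' @param hits Data frame with columns `target_id`, `domain`, `start`,
#'   `end`, `e_value`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domtblout <- function(hits, path) {
  hdr <- c(
    "#                                                               --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord",
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
    "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------")
  body <- vapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    qlen <- h$end - h$start + 1L
    sprintf(paste0("%-20s %-10s %5d %-20s %-10s %5d %9.2g %6.1f %5.1f ",
                   "%3d %3d %9.2g %9.2g %6.1f %5.1f %5d %5d %5d %5d %5d %5d %4.2f -"),
            h$target_id, "-", 1000L, h$domain, "-", qlen,
            h$e_value, 50.0, 0.1, 1L, 1L, h$e_value, h$e_value, 50.0, 0.1,
            1L, qlen, h$start, h$end, h$start, h$end, 0.95)
  }, character(1))
  writeLines(c(hdr, body, "#"), path)
  invisible(path)
}

# mutate exactly k positions of a residue vector to different residues
.mutate <- function(res, k) {
  if (k == 0L) return(res)
  pos <- sample(length(res), k)
  for (p in pos) res[p] <- sample(setdiff(AA20, res[p]), 1L)
  res
}

#' Generate per-taxon sequence sets with isoforms and duplicates
#'
#' Per taxon, emits one of: a singleton; an isoform pair at
#' approximately `isoform_identity` (at or above the 0.80 collapse
#' threshold, so deduplication should retain one); or a duplicate pair
#' at approximately `duplicate_identity` (below the threshold, so both
#' are retained and the taxon is flagged as a duplication). Truth labels
#' record the expected retained ids and flagged taxa.
#'
#' @param n_taxa Number of taxa.
#' @param isoform_identity Target identity of isoform pairs (>= 0.8).
#' @param duplicate_identity Target identity of duplicate pairs (< 0.8).
#' @param length Ungapped sequence length (default 100).
#' @param seed Integer seed.
#' @return List with `sequences` (named character vector), `taxon` and
#'   `e_values` (named vectors over the same ids), and `truth` (list
#'   with `retained` ids, `duplicated_taxa`, and per-taxon `kind`).
#' @export
make_taxon_sequence_set <- function(n_taxa, isoform_identity = 0.95,
                                    duplicate_identity = 0.60,
                                    length = 100L, seed = NULL) {
  stopifnot(n_taxa >= 1L, length >= 10L)
  if (!(isoform_identity >= 0.8 && isoform_identity <= 1))
    stop("isoform_identity must lie in [0.8, 1]")
  if (!(duplicate_identity >= 0 && duplicate_identity < 0.8))
    stop("duplicate_identity must lie in [0, 0.8)")
  .with_seed(seed, {
    kinds <- sample(c("singleton", "isoform", "duplicate"), n_taxa,
                    replace = TRUE)
    seqs <- character(0); taxon <- character(0); ev <- numeric(0)
    retained <- character(0); dup_taxa <- character(0)
    for (t in seq_len(n_taxa)) {
      tx <- sprintf("taxon_%03d", t)
      base <- sample(AA20, length, replace = TRUE)
      id1 <- paste0(tx, "_a")
      seqs[id1] <- paste(base, collapse = "")
      taxon[id1] <- tx
      ev[id1] <- 10^stats::runif(1, -12, -3)
      if (kinds[t] == "singleton") {
        retained <- c(retained, id1)
      } else {
        target <- if (kinds[t] == "isoform") isoform_identity else
          duplicate_identity
        k <- round(length * (1 - target))
        id2 <- paste0(tx, "_b")
        seqs[id2] <- paste(.mutate(base, k), collapse = "")
        taxon[id2] <- tx
        ev[id2] <- 10^stats::runif(1, -12, -3)
        if (kinds[t] == "isoform") {
          retained <- c(retained,
                        if (ev[id1] <= ev[id2]) id1 else id2)
        } else {
          retained <- c(retained, id1, id2)
          dup_taxa <- c(dup_taxa, tx)
        }
      }
    }
    list(sequences = seqs, taxon = taxon, e_values = ev,
         truth = list(retained = retained, duplicated_taxa = dup_taxa,
                      kind = stats::setNames(kinds,
                                             sprintf("taxon_%03d",
                                                     seq_len(n_taxa)))))
  })
}
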