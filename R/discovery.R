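# Homolog discovery rules: six-frame translation, HMMER domain-hit
# tables, the two-domain architecture criterion, per-taxon isoform
# deduplication, within-species duplication flagging, and the iterative
# discovery loop contract.

#' Six-frame translation of a nucleotide sequence
#'
#' Translates the three forward frames and the three frames of the
#' reverse complement with the standard genetic code, following the
#' trim-and-clean conventions used when screening transcriptome
#' assemblies for protein domains: codons containing `N` translate to
#' `X`; incomplete trailing codons and trailing `X` runs are trimmed;
#' remaining stop codons are emitted as `X`.
#'
#' @param nt Nucleotide sequence over `A/C/G/T/N` (case-insensitive).
#' @return Named character vector of six amino-acid sequences, frames
#'   `"+1" "+2" "+3" "-1" "-2" "-3"`.
#' @export
translate_six_frames <- function(nt) {
  nt <- toupper(nt)
  stopifnot(is.character(nt), length(nt) == 1L)
  chars <- strsplit(nt, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), c("A", "C", "G", "T", "N"))
  if (length(bad) > 0L)
    stop("non-nucleotide characters: ", paste(bad, collapse = " "))
  rc <- paste(rev(chartr("ACGTN", "TGCAN", chars)), collapse = "")
  frames <- c(`+1` = substring(nt, 1), `+2` = substring(nt, 2),
              `+3` = substring(nt, 3), `-1` = substring(rc, 1),
              `-2` = substring(rc, 2), `-3` = substring(rc, 3))
  code <- Biostrings::GENETIC_CODE
  vapply(frames, function(s) {
    n_codon <- nchar(s) %/% 3L
    if (n_codon == 0L) return("")
    codons <- substring(s, 3L * seq_len(n_codon) - 2L, 3L * seq_len(n_codon))
    aa <- ifelse(grepl("N", codons, fixed = TRUE), "X",
                 unname(code[codons]))
    out <- paste(aa, collapse = "")
    out <- sub("X+$", "", out)       # trim trailing ambiguity
    gsub("*", "X", out, fixed = TRUE)  # clean stops
  }, character(1))
}

#' Read a HMMER 3 per-domain hit table (domtblout)
#'
#' Parses the whitespace-delimited per-domain tabular output of
#' `hmmsearch --domtblout`, taking the envelope coordinates and the
#' independent (i-)E-value of each domain line; `#` comment lines are
#' ignored.
#'
#' @param path Path to a domtblout file.
#' @return Data frame of domain hits with columns `target_id`, `domain`,
#'   `start`, `end` (1-based envelope coordinates) and `e_value`.
#' @export
read_domain_hits <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  hits <- data.frame(target_id = character(0), domain = character(0),
                     start = integer(0), end = integer(0),
                     e_value = numeric(0), stringsAsFactors = FALSE)
  rows <- vector("list", sum(keep))
  k <- 0L
  for (i in which(keep)) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 22L)
      stop("malformed domtblout line ", i, ": expected >= 22 fields, got ",
           length(f))
    start <- suppressWarnings(as.integer(f[20]))
    end <- suppressWarnings(as.integer(f[21]))
    ev <- suppressWarnings(as.numeric(f[13]))
    if (is.na(start) || is.na(end) || is.na(ev))
      stop("malformed domtblout line ", i,
           ": non-numeric envelope coordinates or i-E-value")
    k <- k + 1L
    rows[[k]] <- data.frame(target_id = f[1], domain = f[4], start = start,
                            end = end, e_value = ev,
                            stringsAsFactors = FALSE)
  }
  if (k > 0L) hits <- do.call(rbind, rows[seq_len(k)])
  rownames(hits) <- NULL
  hits
}

#' Classify targets by two-domain architecture
#'
#' Implements the operational homolog definition: a sequence with a hit
#' for the N-terminal domain (LOTUS) followed, after an interdomain
#' region, by a hit for the C-terminal domain (OSK), both with E-value
#' strictly below `e_max`. Per target, the minimum-E-value hit of each
#' domain is taken; the domain-order test is non-overlap (LOTUS end <=
#' OSK start; a zero-length interdomain region is allowed). Rejected
#' targets carry a reason: `missing-domain`, `weak-evidence`,
#' `wrong-order` or `overlap`. The classification is invariant under the
#' order of the input hits.
#'
#' @param hits Data frame of domain hits as from [read_domain_hits()].
#' @param e_max E-value cutoff, strict (default 0.05).
#' @param lotus,osk Domain names of the N- and C-terminal domains.
#' @return Data frame, one row per target: `target_id`, `status`
#'   (`"homolog"`/`"rejected"`), `reason` (`NA` for homologs), and the
#'   selected hits' coordinates and E-values.
#' @export
classify_architecture <- function(hits, e_max = 0.05,
                                  lotus = "LOTUS", osk = "OSK") {
  stopifnot(is.data.frame(hits))
  targets <- sort(unique(hits$target_id))
  if (length(targets) == 0L)
    return(data.frame(target_id = character(0), status = character(0),
                      reason = character(0), lotus_start = integer(0),
                      lotus_end = integer(0), lotus_evalue = numeric(0),
                      osk_start = integer(0), osk_end = integer(0),
                      osk_evalue = numeric(0), stringsAsFactors = FALSE))
  best <- function(df) df[order(df$e_value, df$start, df$end)[1], , drop = FALSE]
  rows <- lapply(targets, function(tg) {
    h <- hits[hits$target_id == tg, , drop = FALSE]
    lh <- h[h$domain == lotus, , drop = FALSE]
    oh <- h[h$domain == osk, , drop = FALSE]
    out <- data.frame(target_id = tg, status = "rejected",
                      reason = NA_character_,
                      lotus_start = NA_integer_, lotus_end = NA_integer_,
                      lotus_evalue = NA_real_,
                      osk_start = NA_integer_, osk_end = NA_integer_,
                      osk_evalue = NA_real_, stringsAsFactors = FALSE)
    if (nrow(lh) > 0L) {
      b <- best(lh)
      out$lotus_start <- b$start; out$lotus_end <- b$end
      out$lotus_evalue <- b$e_value
    }
    if (nrow(oh) > 0L) {
      b <- best(oh)
      out$osk_start <- b$start; out$osk_end <- b$end
      out$osk_evalue <- b$e_value
    }
    if (nrow(lh) == 0L || nrow(oh) == 0L) {
      out$reason <- "missing-domain"
    } else if (out$lotus_evalue >= e_max || out$osk_evalue >= e_max) {
      out$reason <- "weak-evidence"
    } else if (out$lotus_end <= out$osk_start) {
      out$status <- "homolog"
    } else if (out$osk_end <= out$lotus_start) {
      out$reason <- "wrong-order"
    } else {
      out$reason <- "overlap"
    }
    out
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Pairwise percent identity of two aligned sequences
#'
#' Identity = matching columns / counted columns, where columns gapped
#' in both sequences are excluded from the denominator and a gap against
#' a residue counts as a mismatch. This is one minus the normalized
#' Hamming distance on the informative columns.
#'
#' @param a,b Gapped sequences of equal length (strings).
#' @return Fraction in \[0, 1\]; `NA` if no column is counted.
#' @export
pairwise_identity <- function(a, b) {
  va <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  vb <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  if (length(va) != length(vb))
    stop("length mismatch: ", length(va), " vs ", length(vb))
  counted <- !(va == "-" & vb == "-")
  if (!any(counted)) return(NA_real_)
  sum(va[counted] == vb[counted]) / sum(counted)
}

# connected components by union-find over an adjacency condition
.components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (length(edges)) for (e in edges) {
    ri <- find(e[1]); rj <- find(e[2])
    if (ri != rj) parent[rj] <- ri
  }
  vapply(seq_len(n), find, integer(1))
}

#' Collapse isoforms and assembly artifacts within one taxon
#'
#' Sequences from the same organism that are nearly identical (pairwise
#' identity at or above `identity_threshold`, default 0.80) are treated
#' as isoforms or assembly artifacts of one gene: pairs at or above the
#' threshold are connected into components, and within each component
#' only the member with the lowest E-value is kept (ties broken toward
#' the lexicographically smallest id). Dissimilar sequences survive, so
#' true within-species gene duplications are retained. Applying the
#' operation twice equals applying it once.
#'
#' @param seqs Named character vector of aligned (equal-length) gapped
#'   sequences from one taxon.
#' @param e_values Named numeric vector of E-values covering every id.
#' @param identity_threshold Collapse threshold on pairwise identity.
#' @return Named character vector of retained sequences (subset of
#'   `seqs`, input order preserved).
#' @export
deduplicate_taxon_group <- function(seqs, e_values,
                                    identity_threshold = 0.80) {
  ids <- names(seqs)
  stopifnot(!is.null(ids), !anyDuplicated(ids))
  if (!all(ids %in% names(e_values)))
    stop("missing E-value for: ",
         paste(setdiff(ids, names(e_values)), collapse = " "))
  n <- length(seqs)
  if (n <= 1L) return(seqs)
  edges <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    pid <- pairwise_identity(seqs[i], seqs[j])
    if (!is.na(pid) && pid >= identity_threshold)
      edges[[length(edges) + 1L]] <- c(i, j)
  }
  comp <- .components(n, edges)
  keep <- logical(n)
  for (cc in unique(comp)) {
    members <- which(comp == cc)
    ord <- members[order(e_values[ids[members]], ids[members])]
    keep[ord[1]] <- TRUE
  }
  seqs[keep]
}

#' Flag within-species gene duplications
#'
#' After deduplication, a taxon retaining two or more sequences whose
#' pairwise identities are all below `identity_threshold` (default 0.80)
#' is flagged as carrying a within-species duplication.
#'
#' @param seqs Named character vector of aligned gapped sequences
#'   (already deduplicated).
#' @param taxon Named character vector: id -> taxon.
#' @param identity_threshold Duplication threshold on pairwise identity.
#' @return List of duplication events; each event is a list with
#'   `taxon`, `member_ids` and `identity` (the pairwise identity matrix).
#' @export
flag_duplications <- function(seqs, taxon, identity_threshold = 0.80) {
  ids <- names(seqs)
  if (!all(ids %in% names(taxon)))
    stop("missing taxon label for: ",
         paste(setdiff(ids, names(taxon)), collapse = " "))
  events <- list()
  for (tx in unique(taxon[ids])) {
    members <- ids[taxon[ids] == tx]
    if (length(members) < 2L) next
    m <- diag(1, length(members))
    dimnames(m) <- list(members, members)
    for (i in seq_len(length(members) - 1L))
      for (j in (i + 1L):length(members))
        m[i, j] <- m[j, i] <- pairwise_identity(seqs[members[i]],
                                                seqs[members[j]])
    off <- m[upper.tri(m)]
    if (all(!is.na(off) & off < identity_threshold))
      events[[length(events) + 1L]] <-
        list(taxon = tx, member_ids = members, identity = m)
  }
  events
}

#' Iterative homolog discovery loop
#'
#' Runs the search -> classify -> filter cycle until convergence: each
#' iteration calls the search backend (which encapsulates profile-HMM
#' search and any model rebuilding) with the current homolog set,
#' classifies the returned domain hits by architecture, optionally
#' filters the accepted ids, and stops when an iteration adds no new
#' homolog id.
#'
#' @param search_backend Function `(homolog_ids, iteration) -> hits data
#'   frame` (columns as in [read_domain_hits()]); must be deterministic
#'   for fixed inputs.
#' @param e_max E-value cutoff for [classify_architecture()].
#' @param filter Optional function `(ids, calls) -> ids` applied to the
#'   accepted ids each iteration (e.g. per-taxon deduplication).
#' @param max_iterations Guard against non-termination (default 25).
#' @param lotus,osk Domain names passed to [classify_architecture()].
#' @return List with `homologs` (sorted character vector of converged
#'   ids), `iterations`, `converged` (logical), and `audit` (data frame
#'   with per-iteration additions and totals).
#' @export
iterate_discovery <- function(search_backend, e_max = 0.05, filter = NULL,
                              max_iterations = 25L,
                              lotus = "LOTUS", osk = "OSK") {
  stopifnot(is.function(search_backend), max_iterations >= 1L)
  homologs <- character(0)
  audit <- data.frame(iteration = integer(0), n_new = integer(0),
                      n_total = integer(0))
  converged <- FALSE
  it <- 0L
  while (it < max_iterations) {
    it <- it + 1L
    hits <- tryCatch(search_backend(homologs, it), error = function(e)
      stop("search backend failed at iteration ", it, ": ",
           conditionMessage(e)))
    calls <- classify_architecture(hits, e_max = e_max,
                                   lotus = lotus, osk = osk)
    found <- calls$target_id[calls$status == "homolog"]
    if (!is.null(filter)) found <- filter(found, calls)
    new_ids <- setdiff(found, homologs)
    homologs <- union(homologs, new_ids)
    audit <- rbind(audit, data.frame(iteration = it,
                                     n_new = length(new_ids),
                                     n_total = length(homologs)))
    if (length(new_ids) == 0L) { converged <- TRUE; break }
  }
  list(homologs = sort(homologs), iterations = it, converged = converged,
       audit = audit)
}
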