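# Alignment data model, I/O, column filtering, reference-coordinate
# mapping and group partitioning shared by every analysis stage.

#' Amino-acid alphabet used throughout the package
#'
#' The 20 standard amino acids. Alignments may additionally contain `X`
#' (unknown residue, e.g. from Transeq-cleaned six-frame translations),
#' `*` (translated stop) and `-` (gap).
#'
#' @format Character vector of length 20.
#' @export
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

ALN_ALPHABET <- c(AA20, "X", "*", "-")

#' Construct a protein multiple sequence alignment
#'
#' An `alignment` is the central object of the package: a set of
#' equal-length gapped amino-acid sequences with unique identifiers and
#' optional per-sequence taxon labels.
#'
#' @param seqs Named character vector of gapped sequences (equal length,
#'   alphabet: 20 amino acids, `X`, `*`, `-`). Names are the sequence ids.
#' @param taxon Optional named character vector mapping id -> taxon name.
#' @return An object of class `alignment` with fields `mat` (character
#'   matrix, one row per sequence) and `taxon`.
#' @examples
#' aln <- alignment(c(s1 = "MK-A", s2 = "MKLA"))
#' aln_length(aln)
#' @export
alignment <- function(seqs, taxon = NULL) {
  if (length(seqs) == 0L) stop("empty input: alignment needs at least one sequence")
  ids <- names(seqs)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("every sequence must be named with an identifier")
  if (anyDuplicated(ids)) stop("sequence identifiers must be unique")
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("length mismatch: all aligned rows must have identical length (got ",
         paste(sort(unique(lens)), collapse = ", "), ")")
  if (lens[1] == 0L) stop("zero-length alignment")
  chars <- strsplit(seqs, "", fixed = TRUE)
  bad <- setdiff(unique(unlist(chars)), ALN_ALPHABET)
  if (length(bad) > 0L)
    stop("illegal character(s) in alignment: ", paste(bad, collapse = " "))
  mat <- matrix(unlist(chars), nrow = length(seqs), byrow = TRUE,
                dimnames = list(ids, NULL))
  if (!is.null(taxon)) {
    taxon <- taxon[ids]
    if (anyNA(taxon)) stop("taxon labels must cover every sequence id")
    names(taxon) <- ids
  }
  structure(list(mat = mat, taxon = taxon), class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("alignment: %d sequences x %d columns\n", nseq(x), aln_length(x)))
  show <- utils::head(aln_ids(x), 5L)
  for (id in show) {
    s <- paste(x$mat[id, seq_len(min(50L, aln_length(x)))], collapse = "")
    cat(sprintf("  %-20s %s%s\n", id, s, if (aln_length(x) > 50L) "..." else ""))
  }
  if (nseq(x) > 5L) cat(sprintf("  ... and %d more\n", nseq(x) - 5L))
  invisible(x)
}

#' Number of sequences in an alignment
#' @param aln An `alignment`.
#' @export
nseq <- function(aln) nrow(aln$mat)

#' Number of columns in an alignment
#' @param aln An `alignment`.
#' @export
aln_length <- function(aln) ncol(aln$mat)

#' Sequence identifiers of an alignment
#' @param aln An `alignment`.
#' @export
aln_ids <- function(aln) rownames(aln$mat)

#' Extract sequences as gapped strings
#' @param aln An `alignment`.
#' @return Named character vector of gapped sequences.
#' @export
aln_strings <- function(aln) {
  out <- apply(aln$mat, 1L, paste, collapse = "")
  names(out) <- aln_ids(aln)
  out
}

#' Read an aligned FASTA file
#'
#' Residues are uppercased; ragged (unequal-length) records, empty files
#' and characters outside the supported alphabet are rejected.
#'
#' @param path Path to an aligned FASTA file.
#' @param taxon Optional named character vector of taxon labels.
#' @return An `alignment`.
#' @export
read_alignment <- function(path, taxon = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty input: no FASTA records in ", path)
  seqs <- as.character(set)
  # FASTA descriptions: keep the first whitespace-delimited token as id
  names(seqs) <- sub("\\s.*$", "", names(set))
  alignment(seqs, taxon = taxon)
}

#' Write an alignment to aligned FASTA
#'
#' @param aln An `alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  set <- Biostrings::BStringSet(aln_strings(aln))
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Per-column occupancy of an alignment
#'
#' Occupancy is the fraction of non-gap symbols in a column; `X` and `*`
#' count as occupied, only `-` is a gap.
#'
#' @param aln An `alignment`.
#' @return Numeric vector of length `aln_length(aln)` in \[0, 1\].
#' @export
column_occupancy <- function(aln) {
  colMeans(aln$mat != "-")
}

#' Remove low-occupancy alignment columns
#'
#' Keeps exactly the columns whose non-gap fraction is at least
#' `min_occupancy` (threshold comparison is "keep when >= cutoff",
#' mirroring trimal's column removal below a cutoff). The returned index
#' vector allows per-column scores computed on the filtered alignment to
#' be mapped back to original coordinates.
#'
#' @param aln An `alignment`.
#' @param min_occupancy Fraction in \[0, 1\]; e.g. 0.3 before MCA.
#' @return List with `alignment` (the filtered alignment) and `kept`
#'   (integer vector of retained 1-based original column indices).
#' @export
filter_columns_by_occupancy <- function(aln, min_occupancy) {
  stopifnot(is.numeric(min_occupancy), length(min_occupancy) == 1L,
            min_occupancy >= 0, min_occupancy <= 1)
  keep <- which(column_occupancy(aln) >= min_occupancy)
  sub <- aln  # may legitimately keep zero columns
  sub$mat <- aln$mat[, keep, drop = FALSE]
  list(alignment = sub, kept = keep)
}

#' Map alignment columns to reference-sequence residue numbers
#'
#' Residue k (1-based) of the ungapped reference sequence maps to the
#' alignment column that holds it, so that per-column scores can be
#' reported against structural residue labels such as "S457".
#'
#' @param aln An `alignment`.
#' @param reference_id Id of the reference row (e.g. the *D. melanogaster*
#'   sequence).
#' @return An object of class `ref_map` with fields `reference_id`,
#'   `column_to_residue` (integer vector over alignment columns, `NA` at
#'   reference gaps) and `residue_to_column` (integer vector over
#'   reference residues).
#' @export
map_reference <- function(aln, reference_id) {
  if (!reference_id %in% aln_ids(aln))
    stop("unknown reference id: ", reference_id)
  row <- aln$mat[reference_id, ]
  nongap <- which(row != "-")
  col2res <- rep(NA_integer_, aln_length(aln))
  col2res[nongap] <- seq_along(nongap)
  structure(list(reference_id = reference_id,
                 column_to_residue = col2res,
                 residue_to_column = nongap),
            class = "ref_map")
}

#' Alignment columns of a reference-residue interval
#'
#' Builds a named region (e.g. the LOTUS alpha-5 helix) from an interval
#' of reference residue numbers.
#'
#' @param map A `ref_map` from [map_reference()].
#' @param start_residue,end_residue 1-based reference residue interval
#'   (inclusive).
#' @param name Region name.
#' @return An object of class `region` with fields `name` and `columns`
#'   (1-based alignment column indices).
#' @export
region_from_reference <- function(map, start_residue, end_residue, name) {
  stopifnot(start_residue <= end_residue)
  n_res <- length(map$residue_to_column)
  if (start_residue < 1L || end_residue > n_res)
    stop("unmapped residue: reference covers residues 1..", n_res)
  structure(list(name = name,
                 columns = map$residue_to_column[start_residue:end_residue]),
            class = "region")
}

#' Define a region directly from alignment columns
#' @param name Region name.
#' @param columns 1-based alignment column indices.
#' @export
region <- function(name, columns) {
  structure(list(name = name, columns = as.integer(columns)), class = "region")
}

#' Construct a group labeling
#'
#' A partition of sequence ids into named, disjoint groups (e.g.
#' holometabolous vs hemimetabolous clades, or dimeric vs monomeric
#' LOTUS families).
#'
#' @param groups Named list; each element a character vector of ids.
#' @return An object of class `group_labeling`.
#' @export
group_labeling <- function(groups) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  all_ids <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_ids))
    stop("groups must be disjoint: ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = " "))
  structure(list(groups = groups), class = "group_labeling")
}

#' Extract the sub-alignment of one group
#'
#' Splits the alignment by clade membership; the column set is unchanged
#' so per-column scores of the partitions remain comparable.
#'
#' @param aln An `alignment`.
#' @param labeling A `group_labeling`.
#' @param group Group name.
#' @return An `alignment` containing exactly that group's rows.
#' @export
partition_alignment <- function(aln, labeling, group) {
  if (!group %in% names(labeling$groups)) stop("unknown group: ", group)
  ids <- labeling$groups[[group]]
  if (length(ids) == 0L) stop("empty group: ", group)
  missing <- setdiff(ids, aln_ids(aln))
  if (length(missing) > 0L)
    stop("labeled ids absent from alignment: ", paste(missing, collapse = " "))
  sub <- aln
  sub$mat <- aln$mat[ids, , drop = FALSE]
  if (!is.null(sub$taxon)) sub$taxon <- sub$taxon[ids]
  sub
}

#' Read sequence group labels from TSV
#'
#' Expected columns: `id`, `taxon`, `group` (tab-separated, with header).
#'
#' @param path Path to the TSV file.
#' @return List with `taxon` (named character vector) and `labeling`
#'   (a `group_labeling`).
#' @export
read_group_labels <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  need <- c("id", "taxon", "group")
  if (!all(need %in% names(df)))
    stop("group-label TSV needs columns: ", paste(need, collapse = ", "))
  taxon <- stats::setNames(df$taxon, df$id)
  groups <- split(df$id, df$group)
  list(taxon = taxon, labeling = group_labeling(groups))
}

#' Write sequence group labels to TSV
#'
#' @param aln An `alignment` (source of ids and taxon labels).
#' @param labeling A `group_labeling`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_group_labels <- function(aln, labeling, path) {
  rows <- do.call(rbind, lapply(names(labeling$groups), function(g) {
    ids <- labeling$groups[[g]]
    data.frame(id = ids,
               taxon = if (is.null(aln$taxon)) ids else unname(aln$taxon[ids]),
               group = g, stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export per-column conservation scores as CSV
#'
#' One row per alignment column: 1-based column index, the reference
#' residue number at that column when a reference map is supplied, and
#' one field per score type. Undefined values (e.g. columns with no
#' contributing sequence for a track-based score) are written as `NA`.
#'
#' @param profiles List of `cons_profile` objects sharing one alignment
#'   length; list names override the profiles' score types as CSV headers.
#' @param path Output path.
#' @param map Optional `ref_map`; adds a `ref_residue` column.
#' @return The exported data frame, invisibly.
#' @export
write_scores <- function(profiles, path, map = NULL) {
  stopifnot(is.list(profiles), length(profiles) > 0L)
  lens <- vapply(profiles, function(p) length(p$values), integer(1))
  if (length(unique(lens)) != 1L)
    stop("length mismatch among score profiles: ",
         paste(unique(lens), collapse = ", "))
  nm <- names(profiles)
  types <- vapply(profiles, function(p) p$score_type, character(1))
  if (is.null(nm)) nm <- types else nm[nm == ""] <- types[nm == ""]
  df <- data.frame(column = seq_len(lens[1]))
  if (!is.null(map)) df$ref_residue <- map$column_to_residue
  for (i in seq_along(profiles)) df[[nm[i]]] <- profiles[[i]]$values
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}
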