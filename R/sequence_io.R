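# Sequence, label-track and paired-dataset I/O.

#' Canonical amino-acid alphabet
#'
#' The 20 canonical one-letter amino-acid codes, optionally with the unknown
#' residue placeholder \code{"X"}.
#'
#' @param with_x Include the unknown-residue code \code{"X"}.
#' @return Character vector of single letters.
#' @export
aa_alphabet <- function(with_x = TRUE) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (with_x) c(aa, "X") else aa
}

# uppercase and map everything outside the 21-letter alphabet to 'X';
# returns the cleaned sequence and the number of substitutions
clean_sequence <- function(seq) {
  seq <- toupper(seq)
  chars <- strsplit(seq, "")[[1]]
  bad <- !(chars %in% aa_alphabet())
  if (any(bad)) chars[bad] <- "X"
  list(sequence = paste(chars, collapse = ""), n_mapped = sum(bad))
}

#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased and any character outside the 20 canonical
#' amino-acid letters plus \code{'X'} is mapped to \code{'X'} with a warning,
#' so sequence length is always preserved.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences; names are the FASTA ids
#'   (first whitespace-delimited token of each header).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file contains no records: ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (anyNA(ids) || any(!nzchar(ids))) stop("FASTA header with empty id in ", path)
  if (anyDuplicated(ids)) stop("duplicate FASTA ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- as.character(set)
  empty <- !nzchar(seqs)
  if (any(empty)) stop("empty sequence for header(s): ",
                       paste(ids[empty], collapse = ", "))
  cleaned <- lapply(seqs, clean_sequence)
  n_mapped <- sum(vapply(cleaned, `[[`, numeric(1), "n_mapped"))
  if (n_mapped > 0) {
    warning(sprintf("%d non-canonical residue(s) mapped to 'X'", n_mapped))
  }
  out <- vapply(cleaned, `[[`, character(1), "sequence")
  names(out) <- ids
  out
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(length(seqs) > 0, !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read per-residue binary label tracks
#'
#' The label file is FASTA-like: a \code{">id"} header line followed by one or
#' more lines of \code{'0'}/\code{'1'} characters, one per residue.
#'
#' @param path Path to a label-track file.
#' @return Named list of integer vectors with values in \{0, 1\}.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("label file is empty: ", path)
  headers <- grepl("^>", lines)
  if (!headers[1]) stop("label file must start with a '>' header line")
  idx <- cumsum(headers)
  ids <- sub("^>\\s*", "", lines[headers])
  ids <- vapply(strsplit(ids, "\\s+"), `[`, character(1), 1L)
  if (any(!nzchar(ids))) stop("label header with empty id")
  if (anyDuplicated(ids)) stop("duplicate label ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  tracks <- vector("list", length(ids))
  names(tracks) <- ids
  for (k in seq_along(ids)) {
    body <- lines[idx == k & !headers]
    if (length(body) == 0L) stop("no label line for id '", ids[k], "'")
    track <- paste(trimws(body), collapse = "")
    chars <- strsplit(track, "")[[1]]
    bad <- which(!(chars %in% c("0", "1")))
    if (length(bad) > 0) {
      stop(sprintf("invalid label character '%s' for id '%s' at position %d",
                   chars[bad[1]], ids[k], bad[1]))
    }
    tracks[[k]] <- as.integer(chars)
  }
  tracks
}

#' Write per-residue binary label tracks
#'
#' @param labels Named list of 0/1 integer vectors.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_labels <- function(labels, path) {
  stopifnot(length(labels) > 0, !is.null(names(labels)))
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(labels)) {
    writeLines(c(paste0(">", id), paste(labels[[id]], collapse = "")), con)
  }
  invisible(path)
}

#' Pair sequences with label tracks into a labeled dataset
#'
#' Pairing is by exact id. Unmatched ids on either side are an error, as is
#' any length mismatch between a sequence and its label track.
#'
#' @param sequences Named character vector, as from [read_fasta()].
#' @param labels Named list of 0/1 integer vectors, as from [read_labels()].
#' @return An object of class \code{"labeled_dataset"}: a list with elements
#'   \code{sequences} and \code{labels}, aligned by name.
#' @export
labeled_dataset <- function(sequences, labels) {
  stopifnot(length(sequences) > 0, length(labels) > 0)
  only_seq <- setdiff(names(sequences), names(labels))
  only_lab <- setdiff(names(labels), names(sequences))
  if (length(only_seq) || length(only_lab)) {
    stop("ids do not match between sequences and labels; ",
         "sequence-only: [", paste(only_seq, collapse = ", "), "] ",
         "label-only: [", paste(only_lab, collapse = ", "), "]")
  }
  labels <- labels[names(sequences)]
  len_seq <- nchar(sequences)
  len_lab <- vapply(labels, length, integer(1))
  bad <- which(len_seq != len_lab)
  if (length(bad) > 0) {
    stop(sprintf("length mismatch for id '%s': sequence %d vs labels %d",
                 names(sequences)[bad[1]], len_seq[bad[1]], len_lab[bad[1]]))
  }
  structure(list(sequences = sequences, labels = labels),
            class = "labeled_dataset")
}

#' Summary statistics of a labeled dataset
#'
#' Reports the number of proteins, binding (positive) and non-binding
#' (negative) residues, and the percentage of binding residues rounded to two
#' decimals, the convention used for benchmark dataset tables in this field.
#'
#' @param ds A \code{labeled_dataset}.
#' @return List with \code{n_proteins}, \code{n_pos}, \code{n_neg},
#'   \code{pct_pos}.
#' @export
dataset_stats <- function(ds) {
  stopifnot(inherits(ds, "labeled_dataset"))
  n_pos <- sum(vapply(ds$labels, sum, numeric(1)))
  n_tot <- sum(vapply(ds$labels, length, integer(1)))
  if (n_tot == 0L) stop("dataset has zero residues")
  list(n_proteins = length(ds$sequences),
       n_pos = as.integer(n_pos),
       n_neg = as.integer(n_tot - n_pos),
       pct_pos = round(100 * n_pos / n_tot, 2))
}

#' @export
print.labeled_dataset <- function(x, ...) {
  s <- dataset_stats(x)
  cat(sprintf("labeled_dataset: %d proteins, %d residues (%.2f%% binding)\n",
              s$n_proteins, s$n_pos + s$n_neg, s$pct_pos))
  invisible(x)
}
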