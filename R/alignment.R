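#' @keywords internal
"_PACKAGE"

NUC_ALPHABET  <- c("A", "C", "G", "T", "N", "-")
PROT_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                   "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X", "*", "-")

#' Construct an alignment of sequences
#'
#' An alignment is an ordered set of equal-length sequences over the
#' nucleotide alphabet \code{A,C,G,T,N,-} or the amino-acid alphabet
#' (plus \code{X} and \code{-}).  Lowercase input is uppercased; any
#' character outside the declared alphabet is an error.
#'
#' @param ids character vector of unique, non-empty labels.
#' @param seqs character vector of sequences, same length as \code{ids}.
#' @param kind \code{"nucleotide"} or \code{"protein"}.
#' @param aligned if \code{TRUE} (default) all sequences must have equal
#'   length.
#' @return an object of class \code{aln} with elements \code{id},
#'   \code{seq} and \code{kind}.
#' @export
alignment <- function(ids, seqs, kind = c("nucleotide", "protein"),
                      aligned = TRUE) {
  kind <- match.arg(kind)
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs))
    stop("ids and seqs must have the same length")
  if (length(ids) == 0L) stop("empty alignment")
  if (any(!nzchar(ids))) stop("sequence ids must be non-empty")
  if (anyDuplicated(ids))
    stop("duplicate sequence id: ", ids[duplicated(ids)][1L])
  if (any(!nzchar(seqs))) stop("empty sequence: ", ids[!nzchar(seqs)][1L])
  if (aligned && length(unique(nchar(seqs))) != 1L)
    stop("sequences have unequal lengths; input must be aligned")
  alpha <- if (kind == "nucleotide") NUC_ALPHABET else PROT_ALPHABET
  bad <- setdiff(unique(strsplit(paste(seqs, collapse = ""), "")[[1L]]), alpha)
  if (length(bad))
    stop("characters outside the ", kind, " alphabet: ",
         paste(bad, collapse = " "))
  structure(list(id = ids, seq = seqs, kind = kind), class = "aln")
}

#' @export
print.aln <- function(x, ...) {
  cat(sprintf("%s alignment: %d sequences x %d columns\n",
              x$kind, length(x$id), nchar(x$seq[1L])))
  invisible(x)
}

#' @export
length.aln <- function(x) length(x$id)

#' Number of alignment columns
#' @param aln an \code{aln} object.
#' @return integer column count.
#' @export
aln_width <- function(aln) nchar(aln$seq[1L])

#' Alignment as a character matrix (rows = sequences)
#' @param aln an \code{aln} object.
#' @return character matrix with rownames from sequence ids.
#' @export
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seq, ""))
  rownames(m) <- aln$id
  m
}

aln_from_matrix <- function(m, kind) {
  alignment(rownames(m), apply(m, 1L, paste, collapse = ""), kind)
}

#' Read an aligned FASTA file
#'
#' @param path path to a FASTA file.
#' @param kind \code{"nucleotide"} or \code{"protein"}.
#' @param aligned require equal lengths (default \code{TRUE}).
#' @return an \code{aln} object, records in file order, uppercased, gaps
#'   (\code{-}) preserved.
#' @export
read_fasta <- function(path, kind = c("nucleotide", "protein"),
                       aligned = TRUE) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no sequences in ", path)
  ids <- sub("\\s.*$", "", names(set))
  alignment(ids, as.character(set), kind, aligned = aligned)
}

#' Write an alignment to FASTA (80-column wrapping)
#'
#' @param aln an \code{aln} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(aln, path) {
  set <- Biostrings::BStringSet(aln$seq)
  names(set) <- aln$id
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Remove every column containing a gap in any sequence
#'
#' Complete-deletion gap handling: a column is dropped when one or more
#' sequences carry \code{-} there.  Idempotent.
#'
#' @param aln an \code{aln} object.
#' @return the gap-free alignment, with attribute \code{kept_columns}
#'   giving the original (1-based) index of each retained column.
#' @export
strip_gap_columns <- function(aln) {
  m <- aln_matrix(aln)
  keep <- which(colSums(m == "-") == 0L)
  if (length(keep) == 0L) stop("all columns contain gaps")
  out <- aln_from_matrix(m[, keep, drop = FALSE], aln$kind)
  attr(out, "kept_columns") <- keep
  out
}

#' Declare a nucleotide alignment to be in-frame coding sequence
#'
#' @param aln a nucleotide \code{aln}, gap-stripped.
#' @param frame_offset 0-based column where codon 1 starts (default 0).
#' @param allow_stops keep internal stop codons instead of failing.
#' @return a \code{codon_aln} object.
#' @export
codon_alignment <- function(aln, frame_offset = 0L, allow_stops = FALSE) {
  if (aln$kind != "nucleotide") stop("codon alignment requires nucleotides")
  if (any(grepl("-", aln$seq, fixed = TRUE)))
    stop("gaps present; apply strip_gap_columns() first")
  w <- aln_width(aln) - frame_offset
  if (w < 3L || w %% 3L != 0L)
    stop("length minus frame offset (", w, ") is not a positive multiple of 3")
  obj <- structure(list(aln = aln, frame_offset = as.integer(frame_offset)),
                   class = "codon_aln")
  if (!allow_stops) {
    cd <- codon_array(obj)
    aa <- apply(cd, c(1L, 2L), translate_codon)
    stop_hit <- which(aa[, -ncol(aa), drop = FALSE] == "*", arr.ind = TRUE)
    if (nrow(stop_hit))
      stop(sprintf("internal stop codon in '%s' at codon %d",
                   aln$id[stop_hit[1L, 1L]], stop_hit[1L, 2L]))
    if (any(aa[, ncol(aa)] == "*") && !all(aa[, ncol(aa)] %in% c("*", "X")))
      stop("terminal stop codon present in some but not all sequences")
  }
  obj
}

#' @export
print.codon_aln <- function(x, ...) {
  cat(sprintf("codon alignment: %d sequences x %d codons (frame offset %d)\n",
              length(x$aln$id), n_codons(x), x$frame_offset))
  invisible(x)
}

#' Number of codons in a codon alignment
#' @param codon_aln a \code{codon_aln}.
#' @return integer codon count.
#' @export
n_codons <- function(codon_aln)
  (aln_width(codon_aln$aln) - codon_aln$frame_offset) %/% 3L

# sequences x codons character array of 3-letter codons
codon_array <- function(codon_aln) {
  m <- aln_matrix(codon_aln$aln)
  off <- codon_aln$frame_offset
  nc <- n_codons(codon_aln)
  out <- matrix("", nrow(m), nc, dimnames = list(rownames(m), NULL))
  for (j in seq_len(nc)) {
    cols <- off + (3L * (j - 1L) + 1L):(3L * j)
    out[, j] <- paste0(m[, cols[1L]], m[, cols[2L]], m[, cols[3L]])
  }
  out
}

GENETIC_CODE_TABLE <- Biostrings::GENETIC_CODE

translate_codon <- function(codon) {
  if (grepl("N", codon, fixed = TRUE)) return("X")
  aa <- GENETIC_CODE_TABLE[[codon]]
  if (is.null(aa)) "X" else aa
}

#' Translate an in-frame codon alignment to protein
#'
#' Codons containing \code{N} become \code{X}; a terminal stop shared by
#' the alignment is dropped; an internal stop is an error naming the
#' sequence and codon index.
#'
#' @param codon_aln a \code{codon_aln}.
#' @return a protein \code{aln}.
#' @export
translate_codons <- function(codon_aln) {
  cd <- codon_array(codon_aln)
  aa <- apply(cd, c(1L, 2L), translate_codon)
  if (is.null(dim(aa))) aa <- matrix(aa, nrow = nrow(cd))
  internal <- which(aa[, -ncol(aa), drop = FALSE] == "*", arr.ind = TRUE)
  if (nrow(internal))
    stop(sprintf("internal stop codon in '%s' at codon %d",
                 rownames(cd)[internal[1L, 1L]], internal[1L, 2L]))
  if (all(aa[, ncol(aa)] %in% c("*", "X")) && any(aa[, ncol(aa)] == "*"))
    aa <- aa[, -ncol(aa), drop = FALSE]
  if (any(aa == "*"))
    stop("stop codon present in final column of some sequences only")
  alignment(rownames(cd), apply(aa, 1L, paste, collapse = ""), "protein")
}
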