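#' Read protein sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings::readAAStringSet()] that validates every
#' record against the canonical 20-letter alphabet and returns package-native
#' objects. Record ids must be unique.
#'
#' @param path FASTA file (arbitrary line wrapping).
#' @return A list of [ProteinSeq-class] objects, named by id.
#' @export
readProteinFasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (!length(set)) stop("no records in FASTA file: ", path)
  full <- names(set)
  ids <- sub("\\s.*$", "", full)
  desc <- sub("^\\S+\\s*", "", full)
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- lapply(seq_along(set), function(i)
    ProteinSeq(ids[i], as.character(set[[i]]), desc[i]))
  names(out) <- ids
  out
}

#' Write protein sequences to FASTA
#'
#' Writes multi-record FASTA wrapped at 60 columns via
#' [Biostrings::writeXStringSet()].
#'
#' @param seqs list of [ProteinSeq-class] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeProteinFasta <- function(seqs, path) {
  if (is(seqs, "ProteinSeq")) seqs <- list(seqs)
  set <- Biostrings::AAStringSet(vapply(seqs, residues, character(1L)))
  nm <- vapply(seqs, seqId, character(1L))
  dd <- vapply(seqs, function(s) s@description, character(1L))
  names(set) <- ifelse(nzchar(dd), paste(nm, dd), nm)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read an aligned FASTA file as an MSA character matrix
#'
#' All records must have equal (aligned) length; gap characters `-` and `.`
#' are preserved (`.` normalized to `-`). Used to build the
#' conservation-informed transition matrix.
#'
#' @param path aligned FASTA file.
#' @return Character matrix, rows = sequences, columns = alignment columns.
#' @export
readAlignedFasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) < 2L) stop("alignment needs at least 2 sequences")
  lens <- Biostrings::width(set)
  if (length(unique(lens)) != 1L)
    stop("aligned sequences differ in length")
  rows <- lapply(as.character(set), function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    chars[chars == "."] <- "-"
    chars
  })
  m <- do.call(rbind, rows)
  rownames(m) <- sub("\\s.*$", "", names(set))
  m
}
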