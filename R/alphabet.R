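#' The 20 canonical amino-acid letters
#'
#' One-letter codes of the twenty proteinogenic amino acids, in alphabetical
#' order. Every sequence handled by the package is restricted to this
#' alphabet; ambiguity codes (X, B, Z) and the rare residues U/O are rejected
#' at the parsing boundary because the downstream mutation strategies and
#' fitness models all assume a 20-symbol state space.
#'
#' @format A character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# residues -> 1..20 index; NA for anything non-canonical
.aa_index <- function(x) match(x, AA_ALPHABET)

.check_residue_string <- function(residues, what = "residues") {
  if (!is.character(residues) || length(residues) != 1L || is.na(residues))
    stop(what, " must be a single character string")
  if (nchar(residues) == 0L)
    stop(what, " must be non-empty")
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad))
    stop("non-canonical residue letter(s) in ", what, ": ",
         paste(bad, collapse = ", "),
         " (only the 20 canonical amino-acid letters are accepted)")
  invisible(chars)
}
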