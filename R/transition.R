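#' TransitionMatrix: amino-acid substitution probabilities
#'
#' A 20x20 row-stochastic matrix indexed by (from, to) residue. The diagonal
#' is zero: proposing a self-substitution would waste an evaluation, since a
#' mutant must differ from its parent. Rows sum to 1 within 1e-9.
#'
#' @slot probs numeric 20x20 matrix with `AA_ALPHABET` dimnames.
#' @export
setClass("TransitionMatrix", representation(probs = "matrix"))

setValidity("TransitionMatrix", function(object) {
  p <- object@probs
  if (!is.numeric(p) || !identical(dim(p), c(20L, 20L)))
    return("probs must be a numeric 20x20 matrix")
  if (!identical(rownames(p), AA_ALPHABET) ||
      !identical(colnames(p), AA_ALPHABET))
    return("probs must have the canonical alphabet as row and column names")
  if (any(p < 0)) return("negative substitution probability")
  if (any(diag(p) != 0)) return("diagonal (self-substitution) must be zero")
  if (any(abs(rowSums(p) - 1) > 1e-9))
    return("rows must sum to 1 within 1e-9")
  TRUE
})

#' @param probs 20x20 numeric matrix (rows: from-residue, cols: to-residue).
#' @rdname TransitionMatrix-class
#' @export
TransitionMatrix <- function(probs) {
  dimnames(probs) <- list(AA_ALPHABET, AA_ALPHABET)
  new("TransitionMatrix", probs = probs)
}

#' @describeIn TransitionMatrix-class the probability matrix
#' @param x a `TransitionMatrix`
#' @export
setGeneric("transitionProbs", function(x) standardGeneric("transitionProbs"))

#' @export
setMethod("transitionProbs", "TransitionMatrix", function(x) x@probs)

setMethod("show", "TransitionMatrix", function(object) {
  offdiag <- object@probs[row(object@probs) != col(object@probs)]
  cat("TransitionMatrix 20x20, off-diagonal range [",
      format(min(offdiag), digits = 4), ", ",
      format(max(offdiag), digits = 4), "]\n", sep = "")
})

#' Uniform baseline substitution matrix
#'
#' Every residue substitutes to each of the 19 alternatives with equal
#' probability 1/19; self-substitutions are excluded. This is the
#' no-information control against which informed strategies are compared.
#'
#' @return A [TransitionMatrix-class].
#' @examples
#' transitionProbs(basicMatrix())["A", "G"]  # 1/19
#' @export
basicMatrix <- function() {
  p <- matrix(1 / 19, 20L, 20L)
  diag(p) <- 0
  TransitionMatrix(p)
}

#' Conservation-informed substitution matrix from an alignment
#'
#' Builds the "Smart" matrix from column-wise co-occurrence in a multiple
#' sequence alignment of homologs. For every alignment column, each ordered
#' pair of residues from two distinct sequences (gaps skipped) counts as one
#' from-to substitution event; same-residue pairs are discarded. Rows are
#' normalized to probabilities; a residue never observed substituting falls
#' back to the uniform [basicMatrix()] row, so the matrix is always usable
#' as a proposal distribution.
#'
#' @param msa character matrix (rows = aligned sequences, from
#'   [readAlignedFasta()]) or a character vector of equal-length aligned
#'   strings. `-` marks gaps; letters outside the canonical alphabet are
#'   treated as gaps.
#' @return A [TransitionMatrix-class].
#' @examples
#' smartMatrix(c("AG", "AG", "GG"))
#' @export
smartMatrix <- function(msa) {
  if (!is.matrix(msa)) {
    if (!is.character(msa)) stop("msa must be a character matrix or vector")
    if (!length(msa)) stop("empty alignment")
    if (length(unique(nchar(msa))) != 1L)
      stop("aligned sequences differ in length")
    msa <- do.call(rbind, strsplit(toupper(msa), "", fixed = TRUE))
  }
  if (nrow(msa) < 2L) stop("alignment needs at least 2 sequences")
  counts <- matrix(0, 20L, 20L, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  for (j in seq_len(ncol(msa))) {
    col <- msa[, j]
    col <- col[col %in% AA_ALPHABET]
    if (length(col) < 2L) next
    tab <- table(factor(col, levels = AA_ALPHABET))
    # ordered pairs from distinct sequences: n_a * n_b for a != b
    pair <- outer(as.numeric(tab), as.numeric(tab))
    diag(pair) <- 0
    counts <- counts + pair
  }
  basic_row <- rep(1 / 19, 20L)
  probs <- matrix(0, 20L, 20L, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  for (i in seq_len(20L)) {
    s <- sum(counts[i, ])
    if (s > 0) {
      probs[i, ] <- counts[i, ] / s
    } else {
      probs[i, ] <- basic_row
      probs[i, i] <- 0
    }
  }
  TransitionMatrix(probs)
}

#' Read/write a transition matrix as CSV
#'
#' 20x20 CSV with residue-letter row and column headers.
#'
#' @param x a [TransitionMatrix-class].
#' @param path CSV file path.
#' @return `writeTransitionMatrix`: `path` invisibly;
#'   `readTransitionMatrix`: a [TransitionMatrix-class].
#' @export
writeTransitionMatrix <- function(x, path) {
  stopifnot(is(x, "TransitionMatrix"))
  utils::write.csv(as.data.frame(x@probs), path, row.names = TRUE)
  invisible(path)
}

#' @rdname writeTransitionMatrix
#' @export
readTransitionMatrix <- function(path) {
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  m <- as.matrix(df)
  if (!identical(rownames(m), AA_ALPHABET) ||
      !identical(colnames(m), AA_ALPHABET))
    stop("transition-matrix CSV must carry the 20 canonical letters as ",
         "row and column headers, alphabetically ordered")
  TransitionMatrix(m)
}
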