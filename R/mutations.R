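#' Mutation: a single amino-acid substitution
#'
#' Standard point-mutation notation, e.g. `"K2A"`: wild-type residue K at
#' 1-based position 2 replaced by A. No-op substitutions (identical wild-type
#' and replacement letters) are rejected.
#'
#' @slot position 1-based residue index in the parent sequence.
#' @slot wt single wild-type letter.
#' @slot new single replacement letter, different from `wt`.
#' @export
setClass("Mutation",
  representation(position = "integer", wt = "character", new = "character"))

setValidity("Mutation", function(object) {
  if (length(object@position) != 1L || is.na(object@position) ||
      object@position < 1L)
    return("position must be a single integer >= 1")
  for (s in c(object@wt, object@new)) {
    if (length(s) != 1L || !s %in% AA_ALPHABET)
      return("wt and new must each be one canonical amino-acid letter")
  }
  if (object@wt == object@new)
    return("wt and new residues are identical (no-op mutation)")
  TRUE
})

#' Construct a Mutation
#' @param position 1-based position.
#' @param wt wild-type residue letter.
#' @param new replacement residue letter.
#' @return A [Mutation-class] object.
#' @export
Mutation <- function(position, wt, new) {
  new("Mutation", position = as.integer(position), wt = wt, new = new)
}

setMethod("show", "Mutation", function(object) {
  cat("Mutation ", formatMutation(object), "\n", sep = "")
})

#' Parse and format mutation tokens
#'
#' `parseMutation` reads a token like `"K2A"`; `formatMutation` writes it
#' back. `parseMutationList`/`formatMutationList` handle comma-joined lists
#' (`"M1A,T3S"`). Round-tripping is the identity.
#'
#' @param text a mutation token such as `"K2A"`.
#' @return `parseMutation`: a [Mutation-class]; `formatMutation`: a string.
#' @examples
#' parseMutation("K2A")
#' formatMutation(Mutation(10, "G", "P"))
#' @export
parseMutation <- function(text) {
  if (!is.character(text) || length(text) != 1L)
    stop("mutation token must be a single string")
  m <- regmatches(text, regexec("^([A-Z])([0-9]+)([A-Z])$", text))[[1L]]
  if (length(m) != 4L)
    stop("malformed mutation token: '", text,
         "' (expected <letter><position><letter>, e.g. K2A)")
  Mutation(as.integer(m[3L]), m[2L], m[4L])
}

#' @rdname parseMutation
#' @param m a [Mutation-class] object.
#' @export
formatMutation <- function(m) {
  stopifnot(is(m, "Mutation"))
  paste0(m@wt, m@position, m@new)
}

#' @rdname parseMutation
#' @export
parseMutationList <- function(text) {
  if (!nzchar(text)) return(list())
  lapply(strsplit(text, ",", fixed = TRUE)[[1L]], parseMutation)
}

#' @rdname parseMutation
#' @param mutations a list of [Mutation-class] objects.
#' @export
formatMutationList <- function(mutations) {
  paste(vapply(mutations, formatMutation, character(1L)), collapse = ",")
}

# sort a mutation list by position (positions are distinct by contract)
.sort_mutations <- function(mutations) {
  if (!length(mutations)) return(mutations)
  pos <- vapply(mutations, function(m) m@position, integer(1L))
  mutations[order(pos)]
}

#' Apply point mutations to a parent sequence
#'
#' Substitutes each mutation's replacement letter at its position. Positions
#' must be distinct and in range, and each mutation's wild-type letter must
#' match the parent at that position; violations raise distinct errors.
#'
#' @param parent a [ProteinSeq-class].
#' @param mutations list of [Mutation-class] objects.
#' @return A new [ProteinSeq-class] differing from `parent` exactly at the
#'   mutated positions; the id gains a mutation-list suffix.
#' @examples
#' p <- ProteinSeq("p", "MKT")
#' residues(applyMutations(p, list(parseMutation("K2A"))))
#' @export
applyMutations <- function(parent, mutations) {
  stopifnot(is(parent, "ProteinSeq"))
  if (!length(mutations))
    return(parent)
  pos <- vapply(mutations, function(m) m@position, integer(1L))
  if (anyDuplicated(pos))
    stop("duplicate mutation positions: ",
         paste(unique(pos[duplicated(pos)]), collapse = ", "))
  L <- seqLength(parent)
  if (any(pos < 1L | pos > L))
    stop("mutation position out of range [1, ", L, "]: ",
         paste(pos[pos < 1L | pos > L], collapse = ", "))
  chars <- strsplit(parent@residues, "", fixed = TRUE)[[1L]]
  for (m in mutations) {
    if (chars[m@position] != m@wt)
      stop("wild-type mismatch at position ", m@position, ": parent has ",
           chars[m@position], ", mutation says ", m@wt)
    chars[m@position] <- m@new
  }
  suffix <- formatMutationList(.sort_mutations(mutations))
  ProteinSeq(paste0(parent@id, "|", suffix),
             paste(chars, collapse = ""), parent@description)
}

#' Hamming distance between equal-length sequences
#'
#' @param a,b [ProteinSeq-class] objects or plain residue strings of equal
#'   length.
#' @return Integer count of differing positions.
#' @export
hammingDistance <- function(a, b) {
  sa <- if (is(a, "ProteinSeq")) a@residues else a
  sb <- if (is(b, "ProteinSeq")) b@residues else b
  if (nchar(sa) != nchar(sb))
    stop("sequences differ in length (", nchar(sa), " vs ", nchar(sb), ")")
  sum(charToRaw(sa) != charToRaw(sb))
}

#' Recover the mutation list separating two sequences
#'
#' The inverse of [applyMutations()]: positions where `mutant` differs from
#' `parent`, as sorted [Mutation-class] objects.
#'
#' @param parent,mutant equal-length [ProteinSeq-class] objects or strings.
#' @return List of [Mutation-class] sorted by position.
#' @export
mutationsBetween <- function(parent, mutant) {
  sa <- if (is(parent, "ProteinSeq")) parent@residues else parent
  sb <- if (is(mutant, "ProteinSeq")) mutant@residues else mutant
  if (nchar(sa) != nchar(sb))
    stop("sequences differ in length")
  ca <- strsplit(sa, "", fixed = TRUE)[[1L]]
  cb <- strsplit(sb, "", fixed = TRUE)[[1L]]
  idx <- which(ca != cb)
  lapply(idx, function(i) Mutation(i, ca[i], cb[i]))
}

#' MutantRecord: one evolved individual
#'
#' A mutated sequence together with its provenance (parent id, mutation
#' list relative to that parent's wild type) and any attached scores.
#' Validity enforces that the mutation count equals the Hamming distance
#' implied by the mutation list (distinct positions, all real changes).
#'
#' @slot parentId id of the wild-type/parent sequence.
#' @slot mutations list of [Mutation-class], sorted by position.
#' @slot sequence the mutated [ProteinSeq-class].
#' @slot scores named numeric vector of fitness metrics.
#' @export
setClass("MutantRecord",
  representation(parentId = "character", mutations = "list",
                 sequence = "ProteinSeq", scores = "numeric"),
  prototype(scores = numeric(0L)))

setValidity("MutantRecord", function(object) {
  if (length(object@parentId) != 1L || !nzchar(object@parentId))
    return("parentId must be a single non-empty string")
  pos <- vapply(object@mutations, function(m) m@position, integer(1L))
  if (anyDuplicated(pos))
    return("mutation positions must be distinct")
  if (length(pos) && any(pos > seqLength(object@sequence)))
    return("mutation position beyond sequence length")
  TRUE
})

#' Construct a MutantRecord
#' @param parentId parent sequence id.
#' @param mutations list of [Mutation-class] relative to the parent.
#' @param sequence mutated [ProteinSeq-class].
#' @param scores named numeric vector of metric values.
#' @return A [MutantRecord-class].
#' @export
MutantRecord <- function(parentId, mutations, sequence,
                         scores = numeric(0L)) {
  new("MutantRecord", parentId = parentId,
      mutations = .sort_mutations(mutations), sequence = sequence,
      scores = scores)
}

#' @describeIn MutantRecord-class number of mutations relative to the parent
#' @param x a `MutantRecord`
#' @export
setGeneric("nMutations", function(x) standardGeneric("nMutations"))

#' @export
setMethod("nMutations", "MutantRecord", function(x) length(x@mutations))

#' @describeIn MutantRecord-class attached scores (named numeric)
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @export
setMethod("scores", "MutantRecord", function(x) x@scores)

#' @export
setMethod("residues", "MutantRecord", function(x) x@sequence@residues)

setMethod("show", "MutantRecord", function(object) {
  cat("MutantRecord parent=", object@parentId, " [",
      formatMutationList(object@mutations), "]", sep = "")
  if (length(object@scores))
    cat(" scores: ",
        paste(names(object@scores), round(object@scores, 4), sep = "=",
              collapse = ", "), sep = "")
  cat("\n")
})
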