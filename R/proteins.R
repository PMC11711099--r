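#' @import methods
NULL

#' ProteinSeq: a fixed-alphabet protein sequence
#'
#' The unit the genetic algorithm evolves: an identifier plus a residue
#' string over the 20-letter amino-acid alphabet. Validity enforces a
#' non-empty id and canonical residues only.
#'
#' @slot id single non-empty identifier string.
#' @slot residues residue string, uppercase canonical letters only.
#' @slot description optional free-text description (may be empty).
#'
#' @examples
#' p <- ProteinSeq("wt1", "MKTAYIAK")
#' seqLength(p)
#' residues(p)
#' @export
setClass("ProteinSeq",
  representation(id = "character", residues = "character",
                 description = "character"),
  prototype(description = ""))

setValidity("ProteinSeq", function(object) {
  if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
    return("id must be a single non-empty string")
  ok <- tryCatch({
    .check_residue_string(object@residues)
    TRUE
  }, error = function(e) conditionMessage(e))
  if (!isTRUE(ok)) return(ok)
  if (length(object@description) != 1L)
    return("description must be a single string")
  TRUE
})

#' Construct a ProteinSeq
#'
#' @param id identifier, unique within any collection it joins.
#' @param residues uppercase residue string over the canonical alphabet.
#' @param description optional description.
#' @return A [ProteinSeq-class] object.
#' @export
ProteinSeq <- function(id, residues, description = "") {
  new("ProteinSeq", id = as.character(id), residues = as.character(residues),
      description = as.character(description))
}

#' @describeIn ProteinSeq-class sequence identifier
#' @param x,object a `ProteinSeq`
#' @export
setGeneric("seqId", function(x) standardGeneric("seqId"))

#' @export
setMethod("seqId", "ProteinSeq", function(x) x@id)

#' @describeIn ProteinSeq-class residue string
#' @export
setGeneric("residues", function(x) standardGeneric("residues"))

#' @export
setMethod("residues", "ProteinSeq", function(x) x@residues)

#' @describeIn ProteinSeq-class number of residues
#' @export
setGeneric("seqLength", function(x) standardGeneric("seqLength"))

#' @export
setMethod("seqLength", "ProteinSeq", function(x) nchar(x@residues))

setMethod("show", "ProteinSeq", function(object) {
  r <- object@residues
  shown <- if (nchar(r) > 50) paste0(substr(r, 1, 47), "...") else r
  cat("ProteinSeq ", object@id, " (", nchar(r), " aa): ", shown, "\n",
      sep = "")
})
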