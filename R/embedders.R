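#' Embedder plug-in contract and built-in embedders
#'
#' An embedder maps a molecule line-notation string or a protein residue
#' string to a fixed-length numeric vector. The contract: a function with an
#' integer `"embed_dim"` attribute, deterministic (same input, same vector), whose
#' output length always equals the declared dimension. Adapters to
#' pretrained chemistry/protein models can be supplied by the user behind
#' the same contract; the package ships two synthetic embedders:
#'
#' * `hashEmbedder(dim)` — deterministic hash projection into `[-1, 1]^dim`.
#'   Carries no chemical or biological signal; used for plumbing tests and
#'   as a fallback for strings outside a lookup table.
#' * `tableEmbedder(table)` — looks strings up in a latent-coordinate table
#'   (as produced by [makeReactionDataset()]), so models trained on its
#'   output can be checked against the generator's known ground truth.
#'   Unknown strings fall back to a hash embedding of the same dimension.
#'
#' @param dim embedding dimension.
#' @param seed integer mixed into the hash.
#' @return A function `string -> numeric(dim)` with an `"embed_dim"` attribute.
#' @examples
#' e <- hashEmbedder(4)
#' e("CCO")
#' embedderDim(e)
#' @export
hashEmbedder <- function(dim, seed = 0L) {
  force(dim); force(seed)
  f <- function(x) {
    vapply(seq_len(dim), function(j)
      2 * .string_hash(x, seed * 1000L + j) - 1, numeric(1L))
  }
  attr(f, "embed_dim") <- as.integer(dim)
  f
}

#' @rdname hashEmbedder
#' @param table numeric matrix with one row per known string; row names are
#'   the strings.
#' @export
tableEmbedder <- function(table, seed = 0L) {
  stopifnot(is.matrix(table), !is.null(rownames(table)))
  dim <- ncol(table)
  fallback <- hashEmbedder(dim, seed)
  f <- function(x) {
    i <- match(x, rownames(table))
    if (is.na(i)) fallback(x) else as.numeric(table[i, ])
  }
  attr(f, "embed_dim") <- as.integer(dim)
  f
}

#' @rdname hashEmbedder
#' @param e an embedder function.
#' @export
embedderDim <- function(e) {
  d <- attr(e, "embed_dim")
  if (is.null(d)) stop("not an embedder: missing embed_dim attribute")
  as.integer(d)
}

# embed a string and check the declared dimension
.embed_checked <- function(e, x, what) {
  v <- e(x)
  if (length(v) != embedderDim(e))
    stop(what, " embedder returned length ", length(v),
         ", declared dimension ", embedderDim(e))
  as.numeric(v)
}
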