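#' StrategyConfig: how candidate mutations are proposed
#'
#' Bundles the knobs of the three interchangeable proposal strategies:
#' `"llm"` (masked-predictor plug-in), `"smart"` (alignment-derived
#' transition matrix) and `"basic"` (uniform matrix). The number of
#' mutations per offspring is drawn uniformly from `1..maxMutations`;
#' `maxMutations` is the hard per-sequence cap, always measured against the
#' original wild type.
#'
#' @slot strategy one of `"llm"`, `"smart"`, `"basic"`.
#' @slot maxMutations maximum mutations per sequence (e.g. 5, 10 or 15).
#' @slot region integer of length 2: editable region, 1-based inclusive;
#'   `NA` means the whole sequence.
#' @slot candidatesPerPosition number of top predictor candidates forming
#'   the pool at each masked position (llm strategy; default 3).
#' @slot candidateMode `"sample"` draws uniformly from the candidate pool,
#'   `"argmax"` always takes the top-ranked legal candidate.
#' @export
setClass("StrategyConfig",
  representation(strategy = "character", maxMutations = "integer",
                 region = "integer", candidatesPerPosition = "integer",
                 candidateMode = "character"),
  prototype(region = NA_integer_, candidatesPerPosition = 3L,
            candidateMode = "sample"))

setValidity("StrategyConfig", function(object) {
  if (!object@strategy %in% c("llm", "smart", "basic"))
    return("strategy must be one of 'llm', 'smart', 'basic'")
  if (length(object@maxMutations) != 1L || is.na(object@maxMutations) ||
      object@maxMutations < 1L)
    return("maxMutations must be a single integer >= 1")
  if (!(length(object@region) == 1L && is.na(object@region))) {
    if (length(object@region) != 2L || any(is.na(object@region)) ||
        object@region[1L] < 1L || object@region[2L] < object@region[1L])
      return("region must be NA or c(start, end) with 1 <= start <= end")
    if (object@maxMutations > object@region[2L] - object@region[1L] + 1L)
      return("maxMutations exceeds the editable-region length")
  }
  if (object@candidatesPerPosition < 1L)
    return("candidatesPerPosition must be >= 1")
  if (!object@candidateMode %in% c("sample", "argmax"))
    return("candidateMode must be 'sample' or 'argmax'")
  TRUE
})

#' @param strategy,maxMutations,region,candidatesPerPosition,candidateMode
#'   see slot documentation.
#' @rdname StrategyConfig-class
#' @export
StrategyConfig <- function(strategy = "basic", maxMutations = 5L,
                           region = NA, candidatesPerPosition = 3L,
                           candidateMode = "sample") {
  new("StrategyConfig", strategy = strategy,
      maxMutations = as.integer(maxMutations),
      region = as.integer(region),
      candidatesPerPosition = as.integer(candidatesPerPosition),
      candidateMode = candidateMode)
}

setMethod("show", "StrategyConfig", function(object) {
  reg <- if (length(object@region) == 2L)
    paste0("[", object@region[1L], ",", object@region[2L], "]") else
      "whole sequence"
  cat("StrategyConfig ", object@strategy, ", maxMutations=",
      object@maxMutations, ", region=", reg, "\n", sep = "")
})

# resolve editable region against a concrete parent length
.resolve_region <- function(cfg, L) {
  if (length(cfg@region) == 2L) {
    if (cfg@region[2L] > L)
      stop("editable region [", cfg@region[1L], ",", cfg@region[2L],
           "] exceeds sequence length ", L)
    cfg@region
  } else c(1L, L)
}

#' Sample distinct mutation positions inside an editable region
#'
#' Uniform sampling without replacement — the masking step shared by all
#' three proposal strategies. Reproducible for a fixed RNG state.
#'
#' @param region integer `c(start, end)`, 1-based inclusive.
#' @param k number of positions to draw.
#' @return Sorted integer vector of `k` distinct positions.
#' @export
samplePositions <- function(region, k) {
  pool <- seq.int(region[1L], region[2L])
  if (k > length(pool))
    stop("cannot draw ", k, " distinct positions from a region of size ",
         length(pool))
  sort(pool[sample.int(length(pool), k)])
}

# one mutated child at the character level (no S4 objects): draws the
# mutation count, samples positions, fills replacements from the strategy
# backend. The predictor is consulted once for all masked positions.
.mutate_chars <- function(parent_chars, parent_str, cfg, backend, region) {
  k <- sample.int(cfg@maxMutations, 1L)
  pos <- samplePositions(region, k)
  chars <- parent_chars
  if (cfg@strategy == "llm") {
    cand_list <- backend(parent_str, pos, cfg@candidatesPerPosition)
    for (j in seq_along(pos)) {
      p <- pos[j]
      cand <- utils::head(cand_list[[j]], cfg@candidatesPerPosition)
      legal <- cand$residue[cand$residue != parent_chars[p] &
                              cand$residue %in% AA_ALPHABET]
      if (!length(legal))
        stop("masked predictor returned no legal candidate at position ",
             p)
      chars[p] <- if (cfg@candidateMode == "argmax") legal[1L]
        else legal[sample.int(length(legal), 1L)]
    }
  } else {
    probs <- backend@probs
    for (p in pos)
      chars[p] <- AA_ALPHABET[sample.int(20L, 1L,
                                         prob = probs[parent_chars[p], ])]
  }
  list(chars = chars, new_idx = pos)
}

#' Propose mutant offspring of a parent sequence
#'
#' The mutation operator shared by the three strategies. For each offspring,
#' a mutation count is drawn uniformly from `1..maxMutations`, positions are
#' sampled inside the editable region, and each position receives a
#' replacement residue: from the top predictor candidates (`llm`) or from
#' the parent residue's transition-matrix row (`smart`/`basic`). Candidates
#' equal to the current residue are never proposed. Offspring are unique
#' within the returned list; duplicates are resampled up to `maxRetries`
#' times, after which fewer offspring are returned with a warning.
#'
#' @param parent a [ProteinSeq-class].
#' @param cfg a [StrategyConfig-class].
#' @param backend a predictor function (for `strategy = "llm"`; see
#'   [hashPredictor()]) or a [TransitionMatrix-class] (`smart`/`basic`).
#' @param nOffspring number of mutants wanted.
#' @param maxRetries resampling budget on duplicate offspring.
#' @return List of [MutantRecord-class], each at Hamming distance between 1
#'   and `maxMutations` from `parent`.
#' @examples
#' set.seed(1)
#' p <- ProteinSeq("wt", "MKTAYIAKQR")
#' proposeMutants(p, StrategyConfig("basic", 2), basicMatrix(), 3)
#' @export
proposeMutants <- function(parent, cfg, backend, nOffspring,
                           maxRetries = 50L) {
  stopifnot(is(parent, "ProteinSeq"), is(cfg, "StrategyConfig"))
  if (cfg@strategy == "llm") {
    if (!is.function(backend))
      stop("strategy 'llm' needs a predictor function backend")
  } else if (!is(backend, "TransitionMatrix")) {
    stop("strategy '", cfg@strategy, "' needs a TransitionMatrix backend")
  }
  L <- seqLength(parent)
  region <- .resolve_region(cfg, L)
  parent_str <- residues(parent)
  parent_chars <- strsplit(parent_str, "", fixed = TRUE)[[1L]]
  seen <- character(0L)
  out <- vector("list", nOffspring)
  n_done <- 0L
  retries <- 0L
  while (n_done < nOffspring) {
    mut <- .mutate_chars(parent_chars, parent_str, cfg, backend, region)
    chars <- mut$chars
    s <- paste(chars, collapse = "")
    if (s %in% seen || s == residues(parent)) {
      retries <- retries + 1L
      if (retries > maxRetries) {
        warning("offspring neighbourhood exhausted after ", maxRetries,
                " retries; returning ", n_done, " of ", nOffspring,
                " offspring")
        break
      }
      next
    }
    seen <- c(seen, s)
    n_done <- n_done + 1L
    muts <- lapply(which(chars != parent_chars), function(i)
      Mutation(i, parent_chars[i], chars[i]))
    out[[n_done]] <- MutantRecord(seqId(parent), muts,
      ProteinSeq(paste0(seqId(parent), "_m", n_done), s))
  }
  out[seq_len(n_done)]
}
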