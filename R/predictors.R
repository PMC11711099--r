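# deterministic polynomial string hash into [0, 1); pure arithmetic so the
# value is identical across platforms and sessions
.string_hash <- function(s, salt = 0L) {
  codes <- utf8ToInt(s)
  h <- 2166136261 + as.numeric(salt) * 16777619
  h <- h %% 2147483647
  for (c in codes) h <- (h * 31 + c) %% 2147483647
  h / 2147483647
}

#' Masked-residue predictor plug-in contract
#'
#' A masked predictor stands in for a protein language model: given a residue
#' string and a set of masked positions, it returns for each masked position
#' a ranked list of candidate replacement residues with scores. The contract:
#'
#' * signature `function(residues, positions, k)` with `residues` a plain
#'   string, `positions` 1-based masked indices, `k` the number of candidates
#'   wanted per position;
#' * returns a list, one element per masked position (in input order), each a
#'   `data.frame(residue, score)` sorted by decreasing score with at least
#'   `min(k, 3)` rows, all residues canonical letters;
#' * deterministic: identical inputs give identical output.
#'
#' `hashPredictor()` is a deterministic context-sensitive predictor with no
#' biological signal, for plumbing and comparison baselines: candidate scores
#' are arithmetic hashes of (sequence, position, residue).
#' `targetBiasedPredictor()` is an informative predictor that ranks the
#' residue of a hidden target sequence first at every position — the
#' synthetic analogue of a well-trained language model on a landscape whose
#' optimum is that target.
#'
#' @param seed integer mixed into the hash so different predictor instances
#'   disagree.
#' @return A predictor function implementing the contract above.
#' @examples
#' pred <- hashPredictor(1)
#' pred("MKTAY", c(2, 4), 3)
#' @export
hashPredictor <- function(seed = 0L) {
  force(seed)
  function(residues, positions, k = 3L) {
    lapply(positions, function(p) {
      sc <- vapply(AA_ALPHABET, function(aa)
        .string_hash(paste0(residues, ":", p, ":", aa), seed), numeric(1L))
      ord <- order(sc, decreasing = TRUE)
      utils::head(data.frame(residue = AA_ALPHABET[ord], score = sc[ord],
                             row.names = NULL), max(k, 3L))
    })
  }
}

#' @rdname hashPredictor
#' @param target a [ProteinSeq-class] or residue string: the sequence whose
#'   residues the predictor favours.
#' @param strength score assigned to the target residue (all other residues
#'   score below `strength`).
#' @export
targetBiasedPredictor <- function(target, strength = 10) {
  tchars <- strsplit(if (is(target, "ProteinSeq")) residues(target) else
    target, "", fixed = TRUE)[[1L]]
  force(strength)
  function(residues, positions, k = 3L) {
    lapply(positions, function(p) {
      sc <- vapply(AA_ALPHABET, function(aa)
        .string_hash(paste0(p, ":", aa), 7L), numeric(1L))
      if (p <= length(tchars)) sc[AA_ALPHABET == tchars[p]] <- strength
      ord <- order(sc, decreasing = TRUE)
      utils::head(data.frame(residue = AA_ALPHABET[ord], score = sc[ord],
                             row.names = NULL), max(k, 3L))
    })
  }
}
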