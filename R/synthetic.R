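#' Random protein sequence
#'
#' Uniform i.i.d. residues over the 20-letter alphabet; reproducible for a
#' fixed seed.
#'
#' @param length number of residues (>= 1).
#' @param seed optional integer seed (sets the RNG).
#' @param id sequence identifier.
#' @return A [ProteinSeq-class].
#' @export
randomProtein <- function(length, seed = NULL, id = "synthetic") {
  if (length < 1L) stop("length must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  ProteinSeq(id, paste(sample(AA_ALPHABET, length, replace = TRUE),
                       collapse = ""))
}

#' Synthetic alignment with controlled conservation
#'
#' Builds a toy multiple sequence alignment around a consensus sequence:
#' each position of each row keeps the consensus residue with probability
#' `conservation` and is otherwise drawn uniformly from the alphabet. The
#' resulting column statistics feed [smartMatrix()] with a tunable
#' conservation signal.
#'
#' @param consensus a [ProteinSeq-class] or residue string.
#' @param n number of aligned sequences (default 20).
#' @param conservation per-position probability of the consensus residue.
#' @param seed RNG seed.
#' @return Character matrix (rows = sequences).
#' @export
makeSyntheticMsa <- function(consensus, n = 20L, conservation = 0.7,
                             seed = 1L) {
  chars <- strsplit(if (is(consensus, "ProteinSeq")) residues(consensus)
                    else consensus, "", fixed = TRUE)[[1L]]
  set.seed(seed)
  L <- length(chars)
  m <- matrix("", n, L)
  for (i in seq_len(n)) {
    keep <- stats::runif(L) < conservation
    m[i, ] <- ifelse(keep, chars,
                     sample(AA_ALPHABET, L, replace = TRUE))
  }
  m
}

#' Specify a synthetic fitness landscape
#'
#' Two landscape families with a closed-form optimum, standing in for the
#' trained fitness models during GA testing:
#'
#' * `"target_match"`: score = fraction of positions equal to a hidden
#'   target sequence; optimum 1 at the target.
#' * `"additive"`: score = sum of per-site weights `weights[residue, site]`;
#'   optimum = sum of column maxima.
#'
#' Optional Gaussian observation noise (`noiseSd`) is added on evaluation.
#'
#' @param kind `"target_match"` or `"additive"`.
#' @param target hidden target ([ProteinSeq-class] or string), for
#'   `"target_match"`.
#' @param weights 20 x L numeric matrix with `AA_ALPHABET` rownames, for
#'   `"additive"`.
#' @param noiseSd standard deviation of evaluation noise (default 0).
#' @return A `landscapeSpec` list.
#' @export
landscapeSpec <- function(kind = c("target_match", "additive"),
                          target = NULL, weights = NULL, noiseSd = 0) {
  kind <- match.arg(kind)
  if (kind == "target_match") {
    if (is.null(target)) stop("target_match landscape needs a target")
    target <- if (is(target, "ProteinSeq")) residues(target) else target
  } else {
    if (is.null(weights) || !is.matrix(weights) || nrow(weights) != 20L)
      stop("additive landscape needs a 20 x L weight matrix")
    rownames(weights) <- AA_ALPHABET
  }
  structure(list(kind = kind, target = target, weights = weights,
                 noiseSd = noiseSd), class = "landscapeSpec")
}

#' Build the scoring function of a synthetic landscape
#'
#' @param spec a [landscapeSpec()].
#' @return `function(residue_string) -> numeric`, with the closed-form
#'   optimum attached as attribute `"optimum"`.
#' @examples
#' f <- makeLandscape(landscapeSpec("target_match", target = "MKT"))
#' f("MKT")  # 1
#' f("MAT")  # 2/3
#' @export
makeLandscape <- function(spec) {
  stopifnot(inherits(spec, "landscapeSpec"))
  if (spec$kind == "target_match") {
    t_raw <- charToRaw(spec$target)
    L <- length(t_raw)
    f <- function(s) {
      if (nchar(s) != L) stop("sequence length mismatch with target")
      base <- sum(charToRaw(s) == t_raw) / L
      if (spec$noiseSd > 0) base + stats::rnorm(1L, 0, spec$noiseSd)
      else base
    }
    attr(f, "optimum") <- 1
  } else {
    W <- spec$weights
    L <- ncol(W)
    f <- function(s) {
      if (nchar(s) != L) stop("sequence length mismatch with weights")
      idx <- .aa_index(strsplit(s, "", fixed = TRUE)[[1L]])
      base <- sum(W[cbind(idx, seq_len(L))])
      if (spec$noiseSd > 0) base + stats::rnorm(1L, 0, spec$noiseSd)
      else base
    }
    attr(f, "optimum") <- sum(apply(W, 2L, max))
  }
  f
}

# unique syntactically valid placeholder line notations: unbranched
# carbon chains with ether-oxygen separators encoding the index in base
# 20, so distinct indices can never collide
.placeholder_smiles <- function(i, prefix = "") {
  a <- i %% 20L + 1L
  b <- (i %/% 20L) %% 20L + 1L
  d <- i %/% 400L + 1L
  paste0(prefix, strrep("C", a), "O", strrep("C", b), "O", strrep("C", d))
}

#' Specify a synthetic labeled reaction dataset
#'
#' Gaussian latent-class model emulating a curated reported/random corpus
#' with controllable difficulty. Each reaction row gets latent coordinates
#' per component (substrate, product, enzyme), standard normal with a class
#' shift of total Euclidean size `delta` between "reported" and "random"
#' (split evenly across the three components' first coordinates). The
#' Bayes-optimal AUC is therefore the closed form `pnorm(delta / sqrt(2))`,
#' giving model-recovery tests an analytic ceiling. The turnover number is
#' `kcatFunction(latents)` on the log10 scale plus Gaussian log-scale noise
#' (log-normal noise on the natural scale, the situation the log transform
#' is meant for).
#'
#' @param nReported,nRandom class sizes (default 250 each).
#' @param embedDim latent dimension per component (default 4).
#' @param delta class separation (default 3).
#' @param kcatFunction `function(z_sub, z_prod, z_enz) -> log10 kcat`;
#'   default `z_sub[1] + 0.5 * z_enz[1]`, monotone in two coordinates.
#' @param noiseSd log10-scale kcat noise (default 0).
#' @param seed RNG seed.
#' @return A `reactionSpec` list.
#' @export
reactionSpec <- function(nReported = 250L, nRandom = 250L, embedDim = 4L,
                         delta = 3, kcatFunction = NULL, noiseSd = 0,
                         seed = 1L) {
  if (is.null(kcatFunction))
    kcatFunction <- function(z_sub, z_prod, z_enz)
      z_sub[1L] + 0.5 * z_enz[1L]
  structure(list(nReported = as.integer(nReported),
                 nRandom = as.integer(nRandom),
                 embedDim = as.integer(embedDim), delta = delta,
                 kcatFunction = kcatFunction, noiseSd = noiseSd,
                 seed = as.integer(seed)), class = "reactionSpec")
}

#' Generate a synthetic labeled reaction dataset
#'
#' Draws the latent-class model of [reactionSpec()] and materializes it as
#' a reaction table with placeholder molecule strings and random protein
#' sequences. The returned `embedders` are [tableEmbedder()]s that map each
#' stored string back to its latent coordinates, so models trained on the
#' table can be validated against the generator's ground truth; `latents`
#' exposes the coordinates directly for oracle checks.
#'
#' @param spec a [reactionSpec()].
#' @return List with `records` (reaction table), `latents` (list of three
#'   matrices), and `embedders` (named list of substrate/product/enzyme
#'   embedders).
#' @export
makeReactionDataset <- function(spec) {
  stopifnot(inherits(spec, "reactionSpec"))
  set.seed(spec$seed)
  n <- spec$nReported + spec$nRandom
  d <- spec$embedDim
  labels <- c(rep("reported", spec$nReported), rep("random", spec$nRandom))
  shift <- ifelse(labels == "reported", 1, -1) *
    spec$delta / (2 * sqrt(3))
  lat <- lapply(c(substrate = 1, product = 2, enzyme = 3), function(k) {
    z <- matrix(stats::rnorm(n * d), n, d)
    z[, 1L] <- z[, 1L] + shift
    z
  })
  subs <- vapply(seq_len(n), function(i) .placeholder_smiles(i, ""),
                 character(1L))
  prods <- vapply(seq_len(n), function(i) .placeholder_smiles(i, "N"),
                  character(1L))
  enz <- character(n)
  for (i in seq_len(n)) {
    repeat {
      s <- paste(sample(AA_ALPHABET, 30L, replace = TRUE), collapse = "")
      if (!s %in% enz[seq_len(i - 1L)]) break
    }
    enz[i] <- s
  }
  log_kcat <- vapply(seq_len(n), function(i)
    spec$kcatFunction(lat$substrate[i, ], lat$product[i, ],
                      lat$enzyme[i, ]), numeric(1L))
  if (spec$noiseSd > 0)
    log_kcat <- log_kcat + stats::rnorm(n, 0, spec$noiseSd)
  records <- data.frame(substrate_smiles = subs, product_smiles = prods,
                        enzyme_seq = enz, label = labels,
                        kcat_s1 = 10^log_kcat,
                        ec_class = NA_character_,
                        stringsAsFactors = FALSE)
  rownames(lat$substrate) <- subs
  rownames(lat$product) <- prods
  rownames(lat$enzyme) <- enz
  list(records = records, latents = lat,
       embedders = list(substrate = tableEmbedder(lat$substrate, 11L),
                        product = tableEmbedder(lat$product, 12L),
                        enzyme = tableEmbedder(lat$enzyme, 13L)))
}

#' Specify a synthetic wild-type/mutant dihedral trajectory pair
#'
#' Emulates equilibrated dihedral time series: every residue has a base
#' angle plus a shared slow sinusoidal drift (so unperturbed pairs are
#' strongly correlated), and each trajectory adds independent thermal
#' noise. The mutant may additionally carry a localized perturbation: a
#' constant angular offset plus extra local noise (increased flexibility)
#' inside a residue x snapshot window — the synthetic analogue of a
#' helix-breaking mutation.
#'
#' @param nResidues residue count (default 30).
#' @param nSnapshots snapshot count (default 200; at 100 ps spacing this
#'   spans the 20 ns analysis window).
#' @param spacingPs snapshot spacing in ps (default 100).
#' @param thermalNoiseSd per-snapshot angular noise, degrees (default 10).
#' @param driftAmplitude amplitude of the shared slow drift (default 25).
#' @param perturbation `NULL`, or a list with `residues` (indices),
#'   `window` (snapshot-index range `c(from, to)`) and `amplitude`
#'   (degrees).
#' @param seed RNG seed.
#' @return A `trajectorySpec` list.
#' @export
trajectorySpec <- function(nResidues = 30L, nSnapshots = 200L,
                           spacingPs = 100, thermalNoiseSd = 10,
                           driftAmplitude = 25, perturbation = NULL,
                           seed = 1L) {
  if (!is.null(perturbation)) {
    stopifnot(all(c("residues", "window", "amplitude") %in%
                    names(perturbation)))
    if (any(perturbation$window < 1L) ||
        any(perturbation$window > nSnapshots) ||
        any(perturbation$residues < 1L) ||
        any(perturbation$residues > nResidues))
      stop("perturbation window outside the trajectory grid")
  }
  structure(list(nResidues = as.integer(nResidues),
                 nSnapshots = as.integer(nSnapshots),
                 spacingPs = spacingPs, thermalNoiseSd = thermalNoiseSd,
                 driftAmplitude = driftAmplitude,
                 perturbation = perturbation, seed = as.integer(seed)),
            class = "trajectorySpec")
}

.wrap_deg <- function(x) {
  ((x + 180) %% 360) - 180
}

#' Generate a wild-type/mutant trajectory pair
#'
#' @param spec a [trajectorySpec()].
#' @param angleKind `"phi"` or `"psi"`.
#' @return List with elements `wt` and `mut`
#'   ([DihedralTrajectory-class]).
#' @export
makeTrajectoryPair <- function(spec, angleKind = "phi") {
  stopifnot(inherits(spec, "trajectorySpec"))
  set.seed(spec$seed)
  nr <- spec$nResidues; nt <- spec$nSnapshots
  times <- (seq_len(nt) - 1) * spec$spacingPs
  base_angle <- stats::runif(nr, -150, 150)
  phase <- stats::runif(nr, 0, 2 * pi)
  drift <- spec$driftAmplitude *
    sin(outer(phase, 2 * pi * seq_len(nt) / nt, `+`))
  base <- matrix(base_angle, nr, nt) + drift
  wt <- base + matrix(stats::rnorm(nr * nt, 0, spec$thermalNoiseSd),
                      nr, nt)
  mut <- base + matrix(stats::rnorm(nr * nt, 0, spec$thermalNoiseSd),
                       nr, nt)
  if (!is.null(spec$perturbation)) {
    p <- spec$perturbation
    win <- p$window[1L]:p$window[2L]
    extra <- matrix(stats::rnorm(length(p$residues) * length(win), 0,
                                 p$amplitude / 3),
                    length(p$residues), length(win))
    mut[p$residues, win] <- mut[p$residues, win] + p$amplitude + extra
  }
  list(wt = DihedralTrajectory(.wrap_deg(wt), times, angleKind),
       mut = DihedralTrajectory(.wrap_deg(mut), times, angleKind))
}
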