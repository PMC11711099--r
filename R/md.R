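#' DihedralTrajectory: backbone torsion angles over an MD trajectory
#'
#' A residues-by-snapshots matrix of phi or psi dihedral angles (degrees,
#' in `[-180, 180)`) at uniformly spaced snapshot times, as exported from
#' any trajectory-analysis tool. This is the input to the deviation
#' statistic [fSim()] and the correlation analysis; the package never reads
#' coordinate trajectories itself.
#'
#' @slot angleKind `"phi"` or `"psi"`.
#' @slot times snapshot times in ps, uniformly spaced (typically 100 ps).
#' @slot angles numeric matrix, rows = residues, columns = snapshots.
#' @slot residueIds 1-based residue indices matching the rows.
#' @export
setClass("DihedralTrajectory",
  representation(angleKind = "character", times = "numeric",
                 angles = "matrix", residueIds = "integer"))

setValidity("DihedralTrajectory", function(object) {
  if (!object@angleKind %in% c("phi", "psi"))
    return("angleKind must be 'phi' or 'psi'")
  if (length(object@times) < 2L)
    return("need at least 2 snapshots")
  d <- diff(object@times)
  if (any(d <= 0) || any(abs(d - d[1L]) > 1e-6))
    return("snapshot times must be strictly increasing and uniformly spaced within 1e-6 ps")
  if (!is.numeric(object@angles))
    return("angles must be numeric")
  if (nrow(object@angles) != length(object@residueIds) ||
      ncol(object@angles) != length(object@times))
    return("angles matrix must be residues x snapshots")
  if (any(object@angles < -180 | object@angles >= 180))
    return("angles must lie in [-180, 180) degrees")
  TRUE
})

#' @param angles residues x snapshots numeric matrix, degrees.
#' @param times snapshot times (ps); default `0, 100, 200, ...`.
#' @param angleKind `"phi"` or `"psi"`.
#' @param residueIds 1-based residue ids (default `1:nrow(angles)`).
#' @rdname DihedralTrajectory-class
#' @export
DihedralTrajectory <- function(angles, times = NULL, angleKind = "phi",
                               residueIds = NULL) {
  angles <- as.matrix(angles)
  if (is.null(times)) times <- (seq_len(ncol(angles)) - 1) * 100
  if (is.null(residueIds)) residueIds <- seq_len(nrow(angles))
  new("DihedralTrajectory", angleKind = angleKind,
      times = as.numeric(times), angles = angles,
      residueIds = as.integer(residueIds))
}

setMethod("show", "DihedralTrajectory", function(object) {
  cat("DihedralTrajectory (", object@angleKind, "): ",
      nrow(object@angles), " residues x ", ncol(object@angles),
      " snapshots, ", object@times[2L] - object@times[1L],
      " ps spacing\n", sep = "")
})

#' @describeIn DihedralTrajectory-class number of snapshots
#' @param x a `DihedralTrajectory`
#' @export
setGeneric("nSnapshots", function(x) standardGeneric("nSnapshots"))

#' @export
setMethod("nSnapshots", "DihedralTrajectory",
          function(x) ncol(x@angles))

#' @describeIn DihedralTrajectory-class snapshot times in ps
#' @export
setGeneric("snapshotTimes", function(x) standardGeneric("snapshotTimes"))

#' @export
setMethod("snapshotTimes", "DihedralTrajectory", function(x) x@times)

#' @describeIn DihedralTrajectory-class the angle matrix
#' @export
setGeneric("angleMatrix", function(x) standardGeneric("angleMatrix"))

#' @export
setMethod("angleMatrix", "DihedralTrajectory", function(x) x@angles)

.check_grids_match <- function(wt, mut) {
  if (!identical(wt@residueIds, mut@residueIds))
    stop("trajectories cover different residue sets")
  if (length(wt@times) != length(mut@times) ||
      any(abs(wt@times - mut@times) > 1e-6))
    stop("trajectories have different snapshot grids")
}

#' HelixAnnotation: alpha-helical residue ranges
#'
#' Non-overlapping 1-based inclusive `[start, end]` ranges marked as
#' alpha-helix; each must span at least 5 residues so a poly-proline
#' insertion fits.
#'
#' @slot ranges integer matrix with columns `start`, `end`.
#' @export
setClass("HelixAnnotation", representation(ranges = "matrix"))

setValidity("HelixAnnotation", function(object) {
  r <- object@ranges
  if (!is.numeric(r) || ncol(r) != 2L || nrow(r) < 1L)
    return("ranges must be a matrix with columns start, end")
  if (any(r[, 1L] < 1L) || any(r[, 2L] < r[, 1L]))
    return("each range needs 1 <= start <= end")
  if (any(r[, 2L] - r[, 1L] + 1L < 5L))
    return("each helix must span at least 5 residues")
  if (nrow(r) > 1L) {
    o <- order(r[, 1L])
    if (any(r[o[-1L], 1L] <= r[o[-nrow(r)], 2L]))
      return("helix ranges must not overlap")
  }
  TRUE
})

#' @param ranges two-column matrix (or list of `c(start, end)`) of helix
#'   ranges.
#' @rdname HelixAnnotation-class
#' @export
HelixAnnotation <- function(ranges) {
  if (is.list(ranges)) ranges <- do.call(rbind, ranges)
  ranges <- matrix(as.integer(ranges), ncol = 2L,
                   dimnames = list(NULL, c("start", "end")))
  new("HelixAnnotation", ranges = ranges)
}

#' Signed minimal difference between two angles on the circle
#'
#' Wrap-aware difference `a - b` mapped into `(-180, 180]` degrees, so the
#' +/-180 seam never inflates a deviation. Vectorized.
#'
#' @param a,b angles in degrees.
#' @return Signed difference in `(-180, 180]`.
#' @examples
#' angularDifference(170, -170)  # -20
#' angularDifference(-180, 180)  # 0
#' @export
angularDifference <- function(a, b) {
  d <- (a - b + 180) %% 360 - 180
  d[d == -180] <- 180
  d
}

#' Dihedral-deviation statistic between wild-type and mutant trajectories
#'
#' Quantifies how far a mutant's backbone dihedrals drift from the wild
#' type from snapshot `tPrime` onward:
#'
#' \deqn{f_{sim}(t') = \frac{\sum_{t=t'}^{t_{max}} \sum_{i=1}^{i_{max}}
#'   (\theta_i^{wt}(t') - \theta_i^{mut}(t))^2}{(t_{max} - t')\, i_{max}}}
#'
#' where \eqn{i_{max}} is the residue count and \eqn{t_{max}} the last
#' snapshot index. The default (`variant = "printed"`) compares the mutant
#' at every running time `t` against the wild type frozen at `tPrime`,
#' exactly as the formula reads; `variant = "time-matched"` uses
#' \eqn{\theta^{wt}(t)} instead, comparing the two trajectories snapshot by
#' snapshot. The denominator uses \eqn{t_{max} - t'} even though the sum
#' has one more term, again following the formula as printed;
#' `tPrime = t_max` is rejected to avoid division by zero. All angle
#' differences are wrap-aware ([angularDifference()]).
#'
#' @param wt,mut [DihedralTrajectory-class] objects on identical residue
#'   and snapshot grids.
#' @param tPrime 1-based snapshot index, `< nSnapshots`.
#' @param variant `"printed"` (default) or `"time-matched"`.
#' @return Non-negative deviation (squared degrees).
#' @examples
#' wt <- DihedralTrajectory(matrix(10, 1, 3))
#' mut <- DihedralTrajectory(matrix(c(10, 20, 40), 1))
#' fSim(wt, mut, 1)  # (0 + 100 + 900) / (2 * 1) = 500
#' @export
fSim <- function(wt, mut, tPrime, variant = c("printed", "time-matched")) {
  variant <- match.arg(variant)
  .check_grids_match(wt, mut)
  tmax <- ncol(wt@angles)
  imax <- nrow(wt@angles)
  if (tPrime < 1L || tPrime >= tmax)
    stop("tPrime must satisfy 1 <= tPrime < ", tmax,
         " (the denominator (t_max - t') must be positive)")
  ts <- tPrime:tmax
  ref <- if (variant == "printed")
    wt@angles[, rep(tPrime, length(ts)), drop = FALSE] else
    wt@angles[, ts, drop = FALSE]
  d <- angularDifference(ref, mut@angles[, ts, drop = FALSE])
  sum(d^2) / ((tmax - tPrime) * imax)
}

#' Deviation profile over a time window
#'
#' Evaluates [fSim()] at every admissible `t'` inside a window — by default
#' the final 20 ns of the trajectory, the equilibrated portion analyzed
#' after production MD.
#'
#' @param wt,mut [DihedralTrajectory-class] objects on identical grids.
#' @param windowNs length of the trailing analysis window in ns (default
#'   20); `Inf` means the whole trajectory.
#' @param variant see [fSim()].
#' @return data.frame with columns `t_prime` (snapshot index), `time_ps`
#'   and `f_sim`.
#' @export
fSimProfile <- function(wt, mut, windowNs = 20,
                        variant = c("printed", "time-matched")) {
  variant <- match.arg(variant)
  .check_grids_match(wt, mut)
  tmax <- ncol(wt@angles)
  start_time <- max(wt@times) - windowNs * 1000
  idx <- which(wt@times >= start_time)
  idx <- idx[idx < tmax]
  if (!length(idx)) stop("empty analysis window")
  data.frame(t_prime = idx, time_ps = wt@times[idx],
             f_sim = vapply(idx, function(tp)
               fSim(wt, mut, tp, variant), numeric(1L)))
}

#' Per-residue dihedral correlations between wild type and mutant
#'
#' Pearson correlation between the wild-type and mutant time series of each
#' residue's dihedral angle: values near 1 mean the mutant's backbone
#' fluctuations track the wild type; structural disruption pushes them
#' down. Residues whose series have zero variance in either trajectory are
#' skipped with a warning (their correlation is undefined).
#'
#' @param wt,mut [DihedralTrajectory-class] objects on identical grids with
#'   at least 3 snapshots.
#' @return data.frame with columns `residue` and `pearson_r`.
#' @export
dihedralCorrelations <- function(wt, mut) {
  .check_grids_match(wt, mut)
  if (ncol(wt@angles) < 3L)
    stop("need at least 3 snapshots for correlations")
  sd_wt <- apply(wt@angles, 1L, stats::sd)
  sd_mut <- apply(mut@angles, 1L, stats::sd)
  ok <- sd_wt > 0 & sd_mut > 0
  if (any(!ok))
    warning(sum(!ok), " residue(s) skipped (zero-variance angle series)")
  if (!any(ok)) return(data.frame(residue = integer(0L),
                                  pearson_r = numeric(0L)))
  data.frame(residue = wt@residueIds[ok],
             pearson_r = vapply(which(ok), function(i)
               stats::cor(wt@angles[i, ], mut@angles[i, ]), numeric(1L)))
}

#' Summarize a correlation distribution
#'
#' Median and interquartile range of per-residue correlations, the summary
#' reported per angle kind when contrasting mutants and controls.
#'
#' @param corr output of [dihedralCorrelations()].
#' @return List with `median`, `iqr` and `n`.
#' @export
correlationSummary <- function(corr) {
  r <- corr$pearson_r
  list(median = stats::median(r), iqr = stats::IQR(r), n = length(r))
}

#' Random-mutation control mutants
#'
#' Controls for the specificity of an optimized mutant: each control
#' mutates exactly the same positions as the best mutant, but draws the
#' replacement uniformly from the alphabet excluding the best mutant's
#' residue at that position — and, by default, also the wild-type residue,
#' so every control is a genuine mutation at every position (set
#' `excludeWildType = FALSE` for the looser rule that excludes only the
#' best mutant's choice).
#'
#' @param wt the wild-type [ProteinSeq-class].
#' @param best the optimized [MutantRecord-class] (>= 1 mutation).
#' @param n number of controls (default 5, the per-reaction control count).
#' @param excludeWildType also exclude the wild-type residue.
#' @return List of `n` [MutantRecord-class] controls.
#' @export
makeRandomControls <- function(wt, best, n = 5L, excludeWildType = TRUE) {
  stopifnot(is(wt, "ProteinSeq"), is(best, "MutantRecord"))
  if (n < 1L) stop("n must be >= 1")
  if (!length(best@mutations))
    stop("best mutant carries no mutations")
  wt_chars <- strsplit(residues(wt), "", fixed = TRUE)[[1L]]
  lapply(seq_len(n), function(ctl) {
    muts <- lapply(best@mutations, function(m) {
      banned <- if (excludeWildType) c(m@new, m@wt) else m@new
      pool <- setdiff(AA_ALPHABET, c(banned, wt_chars[m@position]))
      Mutation(m@position, wt_chars[m@position],
               pool[sample.int(length(pool), 1L)])
    })
    rec <- applyMutations(wt, muts)
    MutantRecord(seqId(wt), muts,
                 ProteinSeq(paste0(seqId(wt), "_ctl", ctl),
                            residues(rec)))
  })
}

#' Poly-proline control mutant
#'
#' A disruption control: five consecutive prolines substituted (length
#' preserved) entirely inside one uniformly chosen alpha-helix. Proline's
#' restricted backbone breaks helices, so this control bounds the
#' structural-deviation scale that [fSim()] and the correlation analysis
#' should report for a genuinely disruptive mutant.
#'
#' @param wt the wild-type [ProteinSeq-class].
#' @param helices a [HelixAnnotation-class] (every range is long enough by
#'   construction).
#' @return One [MutantRecord-class]; its mutation list holds the positions
#'   actually changed (residues already proline are untouched).
#' @export
makeProlineControl <- function(wt, helices) {
  stopifnot(is(wt, "ProteinSeq"), is(helices, "HelixAnnotation"))
  L <- seqLength(wt)
  r <- helices@ranges
  if (any(r[, 2L] > L))
    stop("helix annotation extends beyond the sequence")
  h <- r[sample.int(nrow(r), 1L), ]
  start <- h[1L] + sample.int(h[2L] - h[1L] - 3L, 1L) - 1L
  wt_chars <- strsplit(residues(wt), "", fixed = TRUE)[[1L]]
  span <- start:(start + 4L)
  idx <- span[wt_chars[span] != "P"]
  muts <- lapply(idx, function(i) Mutation(i, wt_chars[i], "P"))
  chars <- wt_chars
  chars[span] <- "P"
  MutantRecord(seqId(wt), muts,
               ProteinSeq(paste0(seqId(wt), "_proline"),
                          paste(chars, collapse = "")))
}

#' Read/write dihedral tables
#'
#' Tabular dihedral exports with columns `time_ps`, `residue`, `phi_deg`,
#' `psi_deg` (TSV or CSV by extension), one file per trajectory — the
#' interchange format of standard trajectory-analysis tools. Reading
#' returns both angle kinds as [DihedralTrajectory-class] objects.
#'
#' @param path table path (`.tsv`/`.txt` tab-separated, `.csv` comma).
#' @return `readDihedralTable`: list with elements `phi` and `psi`.
#' @export
readDihedralTable <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep)
  need <- c("time_ps", "residue", "phi_deg", "psi_deg")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("dihedral table missing column(s): ",
         paste(miss, collapse = ", "))
  times <- sort(unique(df$time_ps))
  resid <- sort(unique(df$residue))
  build <- function(col) {
    m <- matrix(NA_real_, length(resid), length(times))
    m[cbind(match(df$residue, resid), match(df$time_ps, times))] <- df[[col]]
    if (anyNA(m)) stop("incomplete residue x time grid in ", path)
    m
  }
  list(phi = DihedralTrajectory(build("phi_deg"), times, "phi", resid),
       psi = DihedralTrajectory(build("psi_deg"), times, "psi", resid))
}

#' @rdname readDihedralTable
#' @param phi,psi [DihedralTrajectory-class] objects on identical grids.
#' @export
writeDihedralTable <- function(phi, psi, path) {
  .check_grids_match(phi, psi)
  grid <- expand.grid(residue = phi@residueIds,
                      time_ps = phi@times, KEEP.OUT.ATTRS = FALSE)
  df <- data.frame(time_ps = grid$time_ps, residue = grid$residue,
                   phi_deg = as.vector(phi@angles),
                   psi_deg = as.vector(psi@angles))
  df <- df[order(df$time_ps, df$residue), ]
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Foldability-prediction interface stub
#'
#' Per-residue structure-confidence scoring (such as pLDDT from a folding
#' model) is outside this package's scope: it requires a pretrained folding
#' model. This stub documents the plug-in contract — a function taking a
#' residue string and returning per-residue scores in [0, 100] — and fails
#' with an informative error when called without a user-supplied backend.
#'
#' @param sequence residue string.
#' @param backend optional `function(sequence) -> numeric` implementing the
#'   contract.
#' @return Per-residue confidence scores, if a backend is supplied.
#' @export
predictFoldability <- function(sequence, backend = NULL) {
  if (is.null(backend))
    stop("foldability scoring needs a user-supplied backend ",
         "(function(sequence) -> per-residue scores in [0, 100]); ",
         "no pretrained folding model ships with this package")
  out <- backend(sequence)
  if (length(out) != nchar(sequence) || any(out < 0 | out > 100))
    stop("foldability backend must return one score in [0, 100] per residue")
  out
}
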