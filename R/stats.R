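#' Mutant-versus-wild-type score differences
#'
#' For each reaction, the shift a mutant induces in a fitness metric:
#' `delta = x_mutant - x_wt`. Inputs are matched by reaction id; an id
#' present in only one vector is an error.
#'
#' @param wt,mutant numeric vectors of scores, named by reaction id (or
#'   unnamed and parallel).
#' @return data.frame with columns `reaction_id`, `x_wt`, `x_mutant`,
#'   `delta`.
#' @examples
#' deltaScores(c(r1 = 0.4), c(r1 = 0.9))
#' @export
deltaScores <- function(wt, mutant) {
  if (is.null(names(wt)) && is.null(names(mutant))) {
    if (length(wt) != length(mutant))
      stop("unnamed score vectors must have equal length")
    ids <- as.character(seq_along(wt))
    names(wt) <- names(mutant) <- ids
  }
  only_wt <- setdiff(names(wt), names(mutant))
  only_mut <- setdiff(names(mutant), names(wt))
  if (length(only_wt) || length(only_mut))
    stop("unpaired reaction id(s): ",
         paste(c(only_wt, only_mut), collapse = ", "))
  ids <- names(wt)
  data.frame(reaction_id = ids, x_wt = unname(wt),
             x_mutant = unname(mutant[ids]),
             delta = unname(mutant[ids] - wt), stringsAsFactors = FALSE)
}

# U statistic of group A from pooled midranks
.u_stat <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

#' Mann-Whitney U rank test
#'
#' Rank test for a location shift between two independent groups, as used
#' to compare mutant-induced score shifts between reaction subsets. The U
#' statistic for group A counts pairs `(a, b)` with `a > b` (ties count
#' one half). The p-value is exact — by complete enumeration of all
#' `choose(nA+nB, nA)` group assignments — when the combined sample size is
#' at most 12 and there are no ties; otherwise a normal approximation with
#' tie correction and continuity correction is used. The switch point keeps
#' the exact branch cheap while removing approximation error exactly where
#' enumeration is feasible.
#'
#' @param a,b numeric vectors (both non-empty).
#' @param alternative `"two.sided"` (default), `"greater"` (A shifted
#'   right of B) or `"less"`.
#' @param exactMax combined-size threshold for the exact branch.
#' @return List with elements `statistic` (U of group A), `p.value`, and
#'   `method` (`"exact"` or `"normal_approx"`).
#' @examples
#' mannWhitneyU(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
#' @export
mannWhitneyU <- function(a, b,
                         alternative = c("two.sided", "greater", "less"),
                         exactMax = 12L) {
  alternative <- match.arg(alternative)
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  if (anyNA(a) || anyNA(b)) stop("NA values not allowed")
  nA <- length(a); nB <- length(b)
  u <- .u_stat(a, b)
  pooled <- c(a, b)
  has_ties <- anyDuplicated(pooled) > 0L
  if (nA + nB <= exactMax && !has_ties) {
    combos <- utils::combn(nA + nB, nA)
    us <- apply(combos, 2L, function(idx)
      .u_stat(pooled[idx], pooled[-idx]))
    p_le <- mean(us <= u)
    p_ge <- mean(us >= u)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                greater = p_ge, less = p_le)
    return(list(statistic = u, p.value = p, method = "exact"))
  }
  n <- nA + nB
  mu <- nA * nB / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- nA * nB / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0)
    return(list(statistic = u, p.value = 1, method = "normal_approx"))
  sigma <- sqrt(sigma2)
  cc <- 0.5  # continuity correction
  p <- switch(alternative,
    two.sided = {
      z <- (abs(u - mu) - cc) / sigma
      min(1, 2 * stats::pnorm(max(z, 0), lower.tail = FALSE))
    },
    greater = stats::pnorm((u - mu - cc) / sigma, lower.tail = FALSE),
    less = stats::pnorm((u - mu + cc) / sigma))
  list(statistic = u, p.value = p, method = "normal_approx")
}

#' Split values into low/high groups around the median
#'
#' The median split used to contrast reactions with low versus high
#' starting scores: `low` holds values strictly below the median, `high`
#' values at or above it, so every value lands in exactly one group.
#'
#' @param values numeric vector (length >= 2), optionally named by
#'   reaction id.
#' @return List with elements `low`, `high` and `median`.
#' @examples
#' splitByMedian(c(1, 2, 3, 4))
#' @export
splitByMedian <- function(values) {
  if (length(values) < 2L)
    stop("median split needs at least 2 values")
  if (anyNA(values)) stop("NA values not allowed")
  m <- stats::median(values)
  list(low = values[values < m], high = values[values >= m], median = m)
}
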