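# Independent brute-force oracles used to cross-check the package's
# implementations. Each deliberately takes a different computational route
# from the code under test.

# circular difference via trig, avoiding the modulo arithmetic of the
# implementation
oracle_ang_diff <- function(a, b) {
  r <- (a - b) * pi / 180
  atan2(sin(r), cos(r)) * 180 / pi
}

# naive double-loop dihedral deviation statistic
oracle_fsim <- function(wt_mat, mut_mat, t_prime,
                        variant = c("printed", "time-matched")) {
  variant <- match.arg(variant)
  tmax <- ncol(wt_mat)
  imax <- nrow(wt_mat)
  acc <- 0
  for (t in t_prime:tmax) {
    for (i in seq_len(imax)) {
      ref <- if (variant == "printed") wt_mat[i, t_prime] else wt_mat[i, t]
      acc <- acc + oracle_ang_diff(ref, mut_mat[i, t])^2
    }
  }
  acc / ((tmax - t_prime) * imax)
}

# U statistic by direct pair counting (no rank sums)
oracle_u <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

# exact two-sided p by enumerating every group assignment
oracle_mw_exact_p <- function(a, b,
                              alternative = c("two.sided", "greater",
                                              "less")) {
  alternative <- match.arg(alternative)
  pooled <- c(a, b)
  nA <- length(a)
  u_obs <- oracle_u(a, b)
  combos <- utils::combn(length(pooled), nA)
  us <- apply(combos, 2L, function(idx)
    oracle_u(pooled[idx], pooled[-idx]))
  switch(alternative,
         two.sided = min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs))),
         greater = mean(us >= u_obs),
         less = mean(us <= u_obs))
}

# optimal-transport W1: equal sample sizes solved by brute force over all
# assignments; unequal sizes by dense numeric integration of |Fx - Fy|
oracle_wasserstein <- function(x, y) {
  if (length(x) == length(y) && length(x) <= 7) {
    perms <- function(v) {
      if (length(v) <= 1) return(list(v))
      out <- list()
      for (i in seq_along(v))
        for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
      out
    }
    costs <- vapply(perms(seq_along(y)), function(p)
      mean(abs(x - y[p])), numeric(1))
    return(min(costs))
  }
  lo <- min(x, y)
  hi <- max(x, y)
  if (hi == lo) return(0)
  grid <- seq(lo, hi, length.out = 200001)
  fx <- ecdf(x)(grid)
  fy <- ecdf(y)(grid)
  sum(abs(fx - fy)) * (hi - lo) / length(grid)
}

# sort-and-slice survivor selection oracle
oracle_select <- function(strings, scores, fraction) {
  keep <- ceiling(fraction * length(scores))
  ord <- order(-scores, strings, method = "radix")
  ord[seq_len(keep)]
}

# deterministic tiny fixture builders ----------------------------------

random_trajectory_pair <- function(nres, nsnap, seed) {
  set.seed(seed)
  list(wt = matrix(runif(nres * nsnap, -180, 179.9), nres, nsnap),
       mut = matrix(runif(nres * nsnap, -180, 179.9), nres, nsnap))
}

tiny_reaction_table <- function(n = 6) {
  data.frame(
    substrate_smiles = paste0("C", strrep("C", seq_len(n)), "O"),
    product_smiles = paste0("O", strrep("C", seq_len(n)), "N"),
    enzyme_seq = vapply(seq_len(n), function(i) {
      set.seed(1000 + i)
      paste(sample(enzopt::AA_ALPHABET, 12, replace = TRUE), collapse = "")
    }, character(1)),
    label = rep(c("reported", "random"), length.out = n),
    kcat_s1 = seq_len(n) + 0.5,
    ec_class = NA_character_,
    stringsAsFactors = FALSE)
}
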