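# Independent oracles used to cross-check the statistics implementations.
# These deliberately use naive, explicit computations.

# Large-sample rank-sum z statistic for two groups, computed by direct
# ranking (tie-corrected variance), independent of dunn_posthoc().
ranksum_z_oracle <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  N <- length(pooled)
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties)
  var_term <- N * (N + 1) / 12 - tie_term / (12 * (N - 1))
  mx <- mean(r[seq_along(x)])
  my <- mean(r[length(x) + seq_along(y)])
  (mx - my) / sqrt(var_term * (1 / length(x) + 1 / length(y)))
}

# OLS coefficients by explicit normal equations.
ols_oracle <- function(X, y) solve(t(X) %*% X, t(X) %*% y)

# Exhaustive-permutation p-value of the Kruskal-Wallis H statistic for small
# samples: every assignment of the pooled values to the group sizes.
kw_perm_p_oracle <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  sizes <- lengths(groups)
  n <- length(x)
  h_of <- function(vals) {
    gl <- rep(seq_along(sizes), sizes)
    kruskal_wallis(split(vals, gl))$H
  }
  h_obs <- h_of(x)
  idx_perms <- combn(n, sizes[1])
  count <- 0L; total <- 0L
  # enumerate assignments recursively over group partitions
  enumerate <- function(remaining, acc) {
    if (length(acc) == length(sizes)) {
      vals <- x[unlist(acc)]
      count <<- count + (h_of(vals) >= h_obs - 1e-12)
      total <<- total + 1L
      return(invisible())
    }
    g <- length(acc) + 1L
    picks <- combn(remaining, sizes[g])
    for (c_ in seq_len(ncol(picks))) {
      enumerate(setdiff(remaining, picks[, c_]), c(acc, list(picks[, c_])))
    }
  }
  enumerate(seq_len(n), list())
  count / total
}

# Small phantom spec used across tests (48^3 keeps registration fast while
# every region retains >= 30 voxels).
test_phantom_spec <- function(...) {
  phantom_spec(shape = c(48, 48, 48), ...)
}
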