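# Independent oracles used across tests. These deliberately re-derive results
# by the most literal route available (sample-by-sample scans, enumeration,
# direct DFT summation) rather than calling the implementation under test.

# Exhaustive trough scan: walk every sample, track sub-threshold excursions,
# emit the index of the minimum of each excursion.
brute_force_troughs <- function(x, thr) {
  idx <- integer(0)
  in_exc <- FALSE
  best_i <- 0L
  best_v <- Inf
  for (i in seq_along(x)) {
    if (x[i] < thr) {
      if (!in_exc) {
        in_exc <- TRUE
        best_i <- i
        best_v <- x[i]
      } else if (x[i] < best_v) {
        best_i <- i
        best_v <- x[i]
      }
    } else if (in_exc) {
      idx <- c(idx, best_i)
      in_exc <- FALSE
      best_v <- Inf
    }
  }
  if (in_exc) idx <- c(idx, best_i)
  idx
}

# Direct DFT power at bin k (0-based) of x, one-sided normalization matching
# "bin sum equals mean square".
direct_dft_power <- function(x, k) {
  n <- length(x)
  j <- seq_len(n) - 1
  re <- sum(x * cos(-2 * pi * k * j / n))
  im <- sum(x * sin(-2 * pi * k * j / n))
  p <- (re^2 + im^2) / n^2
  if (k > 0 && !(n %% 2 == 0 && k == n / 2)) p <- 2 * p
  p
}

# Full-enumeration two-sided Mann-Whitney permutation p-value (no ties).
mw_permutation_p <- function(a, b) {
  m <- length(a); n <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combs <- utils::combn(m + n, m)
  u_all <- apply(combs, 2, function(ix) sum(r[ix]) - m * (m + 1) / 2)
  crit <- function(u) pmin(u, m * n - u)
  mean(crit(u_all) <= crit(u_obs))
}

# Hand sums-of-squares decomposition for a balanced two-factor layout with
# replicates: returns F statistics for A, B and interaction.
balanced_twoway_F <- function(y, fa, fb) {
  fa <- factor(fa); fb <- factor(fb)
  gm <- mean(y)
  a_means <- tapply(y, fa, mean)
  b_means <- tapply(y, fb, mean)
  cell_means <- tapply(y, list(fa, fb), mean)
  n_cell <- table(fa, fb)[1, 1]
  ssa <- sum(table(fa) * (a_means - gm)^2)
  ssb <- sum(table(fb) * (b_means - gm)^2)
  ss_cells <- n_cell * sum((cell_means - gm)^2)
  ssab <- ss_cells - ssa - ssb
  sse <- sum((y - cell_means[cbind(fa, fb)])^2)
  dfa <- nlevels(fa) - 1; dfb <- nlevels(fb) - 1
  dfab <- dfa * dfb
  dfe <- length(y) - nlevels(fa) * nlevels(fb)
  mse <- sse / dfe
  c(FA = (ssa / dfa) / mse, FB = (ssb / dfb) / mse,
    FAB = (ssab / dfab) / mse)
}
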