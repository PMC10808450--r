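## independent oracles used across test files

## brute-force paired-sine distance: evaluates the raw residual
## sum directly on a dense psi grid (no quartic reduction, no refinement).
## res[s, k] = x_s^2 + y_s^2 - 2 x_s y_s cos(psi_k) - sin(psi_k)^2,
## computed as a rank-3 matrix product and squared explicitly.
brute_force_pair_sine <- function(x, y, n_grid = 1e5, chunk = 1e5) {
  psig <- seq(0, pi, length.out = n_grid)
  U <- cbind(x * x + y * y, x * y, 1)
  best <- Inf
  best_psi <- NA_real_
  for (start in seq(1, n_grid, by = chunk)) {
    ps <- psig[start:min(start + chunk - 1, n_grid)]
    V <- rbind(1, -2 * cos(ps), -sin(ps)^2)
    res <- U %*% V
    eps <- colMeans(res * res)
    k <- which.min(eps)
    if (eps[k] < best) {
      best <- eps[k]
      best_psi <- ps[k]
    }
  }
  list(epsilon = best, psi_hat = best_psi)
}

## same dense-grid oracle evaluated through the 3x3 Gram matrix of
## U = [x^2+y^2, xy, 1]: colSums((U V)^2) = colSums(V * (U'U V)), so the
## million-point grid costs O(9 * n_grid) instead of O(S * n_grid).
## Mathematically identical to brute_force_pair_sine (same residual, same
## grid); no quartic reduction and no refinement step.
grid_pair_sine <- function(x, y, n_grid = 1e6) {
  psig <- seq(0, pi, length.out = n_grid)
  U <- cbind(x * x + y * y, x * y, 1)
  M <- crossprod(U)
  V <- rbind(1, -2 * cos(psig), -sin(psig)^2)
  eps <- colSums(V * (M %*% V)) / length(x)
  k <- which.min(eps)
  list(epsilon = eps[k], psi_hat = psig[k])
}

## exhaustive hypergeometric upper tail by enumerating every n-subset of the
## background (feasible for N <= 12)
enumerate_hyper_p <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  in_a <- seq_len(K)
  overlaps <- apply(draws, 2, function(d) sum(d %in% in_a))
  mean(overlaps >= k)
}

## log-space hypergeometric upper tail via lchoose (direct formula)
logspace_hyper_p <- function(N, K, n, k) {
  i <- k:min(K, n)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

## least-squares sinusoid-fit periodogram: explained sum of squares of the
## projection onto span{cos(wt), sin(wt)} over twice the sample variance
lsq_periodogram <- function(y, t, freqs) {
  yc <- y - mean(y)
  s2 <- stats::var(y)
  vapply(freqs, function(f) {
    w <- 2 * pi * f
    fit <- stats::lm(yc ~ 0 + I(cos(w * t)) + I(sin(w * t)))
    sum(stats::fitted(fit)^2) / (2 * s2)
  }, numeric(1))
}

## Kolmogorov-Smirnov statistic against Uniform(0,1)
ks_stat_unif <- function(p) {
  n <- length(p)
  s <- sort(p)
  max(pmax(abs(seq_len(n) / n - s), abs(s - (seq_len(n) - 1) / n)))
}

## alpha = 0.01 asymptotic KS critical value
ks_crit_01 <- function(n) 1.628 / sqrt(n)

## sensitivity/precision of an oscillator call against generator ground truth
recovery_rates <- function(call, truth) {
  planted <- truth$genes$gene[truth$genes$label == "oscillator"]
  tp <- sum(call$oscillators %in% planted)
  list(sensitivity = tp / length(planted),
       precision = if (length(call$oscillators)) {
         tp / length(call$oscillators)
       } else NA_real_)
}
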