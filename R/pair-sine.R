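#' Rescale one gene's expression vector to the canonical [-1, 1] range
#'
#' The paired-sine model assumes amplitude-normalized inputs: two genes
#' sharing a frequency trace an ellipse only after each vector is linearly
#' mapped so its minimum is -1 and its maximum is +1
#' (`x -> 2 * (x - min) / (max - min) - 1`).
#'
#' @param values numeric vector, not constant.
#' @return Numeric vector in `[-1, 1]` with min -1 and max +1.
#' @examples
#' rescale_to_unit(c(0, 5, 10))
#' @export
rescale_to_unit <- function(values) {
  check_that(is.numeric(values) && length(values) >= 2,
             "values must be a numeric vector of length >= 2")
  check_that(all(is.finite(values)), "values must be finite")
  rng <- range(values)
  if (rng[1] == rng[2])
    stop("cannot rescale a constant vector (degenerate input; ",
         "the variance filter removes such genes upstream)", call. = FALSE)
  2 * (values - rng[1]) / (rng[2] - rng[1]) - 1
}

## --- paired-sine objective --------------------------------------------------
##
## For rescaled vectors x, y the per-cell residual at phase shift psi is
##   r_s(psi) = x_s^2 + y_s^2 - 2 x_s y_s cos(psi) - sin(psi)^2
## and the distance is eps = min_psi mean_s r_s(psi)^2.  Writing c = cos(psi)
## and u_s = x_s^2 + y_s^2 - 1, b_s = x_s y_s gives r_s = u_s + c^2 - 2 b_s c,
## so the objective is an exact quartic in c:
##   f(c) = c^4 - 4 mb c^3 + (4 mb2 + 2 mu) c^2 - 4 mub c + mu2
## with the five data moments mb = mean(b), mb2 = mean(b^2), mu = mean(u),
## mub = mean(u b), mu2 = mean(u^2).  Minimization follows the documented
## scheme (uniform psi grid + bounded local refinement); the quartic reduction
## only makes each evaluation O(1) after the one-off O(S) moment pass.

pair_quartic_coefs <- function(x, y) {
  b <- x * y
  u <- x * x + y * y - 1
  list(a3 = -4 * mean(b),
       a2 = 4 * mean(b * b) + 2 * mean(u),
       a1 = -4 * mean(u * b),
       a0 = mean(u * u))
}

## vectorized minimizer over psi in [0, pi] for quartic coefficient vectors;
## grid of n_grid psi values then ternary refinement to tol (radians).
minimize_pair_quartic <- function(co, n_grid = 1000, tol = 1e-8) {
  f <- function(cc) cc^4 + co$a3 * cc^3 + co$a2 * cc^2 + co$a1 * cc + co$a0
  n <- length(co$a3)
  psig <- seq(0, pi, length.out = n_grid)
  best <- rep(Inf, n)
  best_psi <- rep(0, n)
  for (k in seq_len(n_grid)) {
    v <- f(cos(psig[k]))
    sel <- v < best
    if (any(sel)) {
      best[sel] <- v[sel]
      best_psi[sel] <- psig[k]
    }
  }
  step <- pi / (n_grid - 1)
  lo <- pmax(0, best_psi - step)
  hi <- pmin(pi, best_psi + step)
  while (max(hi - lo) > tol) {
    m1 <- lo + (hi - lo) / 3
    m2 <- hi - (hi - lo) / 3
    sel <- f(cos(m1)) < f(cos(m2))
    hi[sel] <- m2[sel]
    lo[!sel] <- m1[!sel]
  }
  psi <- (lo + hi) / 2
  ## mean of squares: clamp the tiny negative values floating point can leave
  list(epsilon = pmax(0, f(cos(psi))), psi_hat = psi)
}

#' Paired-sine distance between two rescaled gene vectors
#'
#' Scores how well two genes fit a common-frequency, phase-shifted sinusoid
#' model across cells. The residual for cell `s` at phase shift `psi` is
#' `x_s^2 + y_s^2 - 2 x_s y_s cos(psi) - sin(psi)^2`; the distance `epsilon`
#' is the mean squared residual minimized over `psi` in `[0, pi]`
#' (minimizing over a half period suffices because cosine is even). A
#' perfectly co-oscillating pair -- `x = sin(theta)`, `y = sin(theta + psi)`
#' on any phase sample -- has `epsilon = 0` at the true shift.
#'
#' Minimization uses a uniform `n_grid`-point grid on `[0, pi]` followed by
#' bounded ternary refinement of the bracketing interval to `tol` radians;
#' the objective is evaluated through its exact quartic reduction in
#' `cos(psi)` (see source), so the result is identical to brute force up to
#' the refinement tolerance.
#'
#' @param x,y numeric vectors of equal length >= 3, each within `[-1, 1]`
#'   (see [rescale_to_unit()]).
#' @param n_grid number of grid points for the initial search.
#' @param tol refinement tolerance in radians.
#' @return List with `epsilon` (>= 0, mean-per-cell) and `psi_hat` (radians
#'   in `[0, pi]`).
#' @examples
#' th <- seq(0, 2 * pi, length.out = 40)
#' pair_sine_distance(sin(th), sin(th + pi / 2))  # epsilon ~ 0, psi ~ pi/2
#' @export
pair_sine_distance <- function(x, y, n_grid = 1000, tol = 1e-8) {
  check_that(is.numeric(x) && is.numeric(y), "x and y must be numeric")
  check_that(length(x) == length(y),
             sprintf("length mismatch: %d vs %d", length(x), length(y)))
  check_that(length(x) >= 3, "need at least 3 cells")
  check_that(all(is.finite(x)) && all(is.finite(y)),
             "x and y must be finite")
  eps_rng <- 1e-8
  check_that(min(x) >= -1 - eps_rng && max(x) <= 1 + eps_rng &&
               min(y) >= -1 - eps_rng && max(y) <= 1 + eps_rng,
             "x and y must lie in [-1, 1]; rescale with rescale_to_unit()")
  res <- minimize_pair_quartic(pair_quartic_coefs(x, y),
                               n_grid = n_grid, tol = tol)
  list(epsilon = res$epsilon[1], psi_hat = res$psi_hat[1])
}

## all-pairs moment computation via matrix cross products.
## R: rescaled gene x cell matrix with rownames.  Returns the pair index
## (i < j in lexicographic gene order) and the five moment vectors.
all_pair_moments <- function(R) {
  R <- R[order(rownames(R)), , drop = FALSE]
  S <- ncol(R)
  R2 <- R * R
  R3 <- R2 * R
  m_xy <- tcrossprod(R) / S
  m_x2y2 <- tcrossprod(R2) / S
  rm2 <- rowMeans(R2)
  rm4 <- rowMeans(R2 * R2)
  m_x3y <- tcrossprod(R3, R) / S
  idx <- which(upper.tri(m_xy), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  mb <- m_xy[idx]
  list(genes = rownames(R), i = i, j = j,
       co = list(a3 = -4 * mb,
                 a2 = 4 * m_x2y2[idx] + 2 * (rm2[i] + rm2[j] - 1),
                 a1 = -4 * (m_x3y[idx] + t(m_x3y)[idx] - mb),
                 a0 = rm4[i] + rm4[j] + 1 + 2 * m_x2y2[idx] -
                   2 * (rm2[i] + rm2[j])))
}

#' Paired-sine statistics for all gene pairs of a rescaled matrix
#'
#' Computes [pair_sine_distance()] for every unordered gene pair of a
#' rescaled gene x cell matrix. Pairs are ordered `gene_i < gene_j`
#' lexicographically so results are deterministic.
#'
#' @param rescaled numeric matrix with unique rownames; every row in
#'   `[-1, 1]` (each gene passed through [rescale_to_unit()]).
#' @param n_grid,tol passed to the minimizer; see [pair_sine_distance()].
#' @return data.frame with columns `gene_i`, `gene_j`, `epsilon`, `psi_hat`.
#' @export
all_pair_statistics <- function(rescaled, n_grid = 1000, tol = 1e-8) {
  check_that(is.matrix(rescaled) && nrow(rescaled) >= 2,
             "need a matrix with at least 2 genes")
  check_that(!is.null(rownames(rescaled)) && !anyDuplicated(rownames(rescaled)),
             "rescaled must have unique rownames")
  mo <- all_pair_moments(rescaled)
  fit <- minimize_pair_quartic(mo$co, n_grid = n_grid, tol = tol)
  data.frame(gene_i = mo$genes[mo$i], gene_j = mo$genes[mo$j],
             epsilon = fit$epsilon, psi_hat = fit$psi_hat,
             stringsAsFactors = FALSE)
}

#' Pooled permutation null for the paired-sine distance
#'
#' Draws `n_perm` random gene pairs from the rescaled matrix, independently
#' permutes each gene's values across cells (destroying any co-oscillation
#' while preserving marginals), and records the paired-sine distance of each
#' permuted pair. The null is pooled across pairs within a cluster: under
#' exchangeability this is statistically equivalent to per-pair nulls at a
#' fraction of the cost.
#'
#' @param rescaled rescaled gene x cell matrix (>= 2 genes).
#' @param n_perm number of permuted pairs (>= 1).
#' @param seed integer seed; identical seed reproduces the sample.
#' @param n_grid,tol minimizer settings.
#' @return Numeric vector of `n_perm` null epsilon values.
#' @export
permutation_null <- function(rescaled, n_perm = 1000, seed = 1L,
                             n_grid = 1000, tol = 1e-8) {
  check_that(is.matrix(rescaled) && nrow(rescaled) >= 2,
             "need at least 2 genes for a permutation null")
  check_that(is_count(n_perm, min = 1), "n_perm must be an integer >= 1")
  G <- nrow(rescaled)
  S <- ncol(rescaled)
  with_seed(seed, {
    gi <- sample.int(G, n_perm, replace = TRUE)
    ## second gene distinct from the first
    gj <- (gi + sample.int(G - 1, n_perm, replace = TRUE) - 1L) %% G + 1L
    Xp <- matrix(0, n_perm, S)
    Yp <- matrix(0, n_perm, S)
    for (b in seq_len(n_perm)) {
      Xp[b, ] <- rescaled[gi[b], sample.int(S)]
      Yp[b, ] <- rescaled[gj[b], sample.int(S)]
    }
    bb <- Xp * Yp
    uu <- Xp * Xp + Yp * Yp - 1
    co <- list(a3 = -4 * rowMeans(bb),
               a2 = 4 * rowMeans(bb * bb) + 2 * rowMeans(uu),
               a1 = -4 * rowMeans(uu * bb),
               a0 = rowMeans(uu * uu))
    minimize_pair_quartic(co, n_grid = n_grid, tol = tol)$epsilon
  })
}

#' Left-tail permutation p-value with add-one correction
#'
#' Small epsilon means a better sinusoidal fit, so significance is assessed
#' in the left tail: `p = (1 + #(null <= epsilon_obs)) / (B + 1)`.
#'
#' @param epsilon_obs observed epsilon value(s).
#' @param null_sample non-empty numeric vector of null epsilon values.
#' @return p-value(s) in `(0, 1]`, vectorized over `epsilon_obs`.
#' @export
pair_pvalue <- function(epsilon_obs, null_sample) {
  check_that(is.numeric(null_sample) && length(null_sample) >= 1,
             "null_sample must be non-empty")
  check_that(is.numeric(epsilon_obs) && length(epsilon_obs) >= 1,
             "epsilon_obs must be numeric")
  B <- length(null_sample)
  (1 + findInterval(epsilon_obs, sort(null_sample))) / (B + 1)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false discovery rate adjustment:
#' `q_i = min over ranks j >= rank(i) of m * p_(j) / j`, capped at 1.
#' Delegates to [stats::p.adjust()] with `method = "BH"`, which implements
#' exactly this formula.
#'
#' @param p_values numeric vector with all values in `(0, 1]`.
#' @return q-values, order-preserving in `p_values`.
#' @export
bh_adjust <- function(p_values) {
  check_that(is.numeric(p_values) && length(p_values) >= 1,
             "p_values must be a non-empty numeric vector")
  check_that(all(is.finite(p_values)) && all(p_values > 0) &&
               all(p_values <= 1),
             "all p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}
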