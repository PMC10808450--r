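#' Specification of one planted co-oscillating gene group
#'
#' Genes in a group share a relative frequency (cycles per revolution of the
#' latent cell phase) and differ only in their gene-specific phase offsets, so
#' any two of them trace an ellipse on a scatter plot across cells.
#'
#' @param n_genes number of genes in the group (>= 2; a co-oscillation group
#'   needs at least a pair).
#' @param relative_frequency positive real; cycles of the gene's sinusoid per
#'   revolution of the latent phase. Groups with different values oscillate at
#'   different frequencies and should not co-oscillate.
#' @param amplitude sinusoid amplitude in expression units (> 0).
#' @param phase_dispersion gene phases are drawn uniformly from
#'   `[0, phase_dispersion)` radians; `2*pi` (default) spreads phases over the
#'   whole cycle, `0` gives identical phases.
#' @return An `oscillator_group` spec (list).
#' @export
oscillator_group <- function(n_genes = 20, relative_frequency = 1,
                             amplitude = 2, phase_dispersion = 2 * pi) {
  check_that(is_count(n_genes, min = 2), "n_genes must be an integer >= 2")
  check_that(is_number(relative_frequency) && relative_frequency > 0,
             "relative_frequency must be > 0")
  check_that(is_number(amplitude) && amplitude > 0, "amplitude must be > 0")
  check_that(is_number(phase_dispersion) && phase_dispersion >= 0 &&
               phase_dispersion <= 2 * pi,
             "phase_dispersion must lie in [0, 2*pi]")
  structure(list(n_genes = as.integer(n_genes),
                 relative_frequency = relative_frequency,
                 amplitude = amplitude,
                 phase_dispersion = phase_dispersion),
            class = "oscillator_group")
}

#' Specification of a synthetic expression matrix with planted oscillators
#'
#' The defaults encode the reference simulation used throughout the package's
#' validation: 300 unsynchronized cells, one 20-gene oscillator group at
#' signal-to-noise ratio amplitude/noise_sd = 4, 180 non-oscillating genes,
#' and 10% uniform dropout. The baseline is chosen so that an oscillator's
#' trough (baseline - amplitude = 0.5) sits at the noise floor: strong
#' ultradian oscillators approach zero expression at their trough, yet a gene
#' must remain detected in at least 80% of cells to enter inference at all,
#' so the trough stays just above zero.
#'
#' @param n_cells number of cells (>= 2).
#' @param groups list of [oscillator_group()] specs (may be empty).
#' @param n_noise_genes number of non-oscillating genes.
#' @param baseline_mean baseline expression level (a.u., >= 0) shared by all
#'   genes.
#' @param noise_sd additive Gaussian noise SD (a.u., >= 0).
#' @param dropout_rate probability in `[0, 1]` that any entry is zeroed.
#' @param dropout_model `"uniform"` (entrywise Bernoulli, independent of
#'   expression; default) or `"magnitude"` (dropout probability
#'   `dropout_rate * exp(-value / baseline_mean)`, so low values drop more).
#' @param seed integer seed; identical spec + seed reproduces the matrix
#'   bit-for-bit.
#' @return A `synth_matrix_spec` (list).
#' @export
matrix_spec <- function(n_cells = 300,
                        groups = list(oscillator_group()),
                        n_noise_genes = 180,
                        baseline_mean = 2.5,
                        noise_sd = 0.5,
                        dropout_rate = 0.1,
                        dropout_model = c("uniform", "magnitude"),
                        seed = 1L) {
  check_that(is_count(n_cells, min = 2), "n_cells must be an integer >= 2")
  check_that(is.list(groups) &&
               all(vapply(groups, inherits, logical(1), "oscillator_group")),
             "groups must be a list of oscillator_group() specs")
  check_that(is_count(n_noise_genes), "n_noise_genes must be a count")
  n_osc <- sum(vapply(groups, function(g) g$n_genes, integer(1)))
  check_that(n_osc + n_noise_genes >= 1, "at least one gene in total")
  check_that(is_number(baseline_mean) && baseline_mean >= 0,
             "baseline_mean must be >= 0")
  check_that(is_number(noise_sd) && noise_sd >= 0, "noise_sd must be >= 0")
  check_that(is_number(dropout_rate) && dropout_rate >= 0 && dropout_rate <= 1,
             "dropout_rate must lie in [0, 1]")
  dropout_model <- match.arg(dropout_model)
  check_that(is_count(seed) || is_number(seed), "seed must be an integer")
  structure(list(n_cells = as.integer(n_cells), groups = groups,
                 n_noise_genes = as.integer(n_noise_genes),
                 baseline_mean = baseline_mean, noise_sd = noise_sd,
                 dropout_rate = dropout_rate, dropout_model = dropout_model,
                 seed = as.integer(seed)),
            class = "synth_matrix_spec")
}

#' Generate an expression matrix with planted co-oscillating gene groups
#'
#' Each cell `s` carries a latent circular phase `theta_s ~ Uniform[0, 2*pi)`
#' drawn independently per cell (the population is unsynchronized). An
#' oscillator gene `g` in group `k` with phase `phi_g` takes the pre-dropout
#' value
#' `max(0, baseline_mean + amplitude_k * sin(freq_k * theta_s + phi_g) + N(0, noise_sd))`;
#' a noise gene takes `max(0, baseline_mean + N(0, noise_sd))`. Each entry is
#' then independently zeroed with probability `dropout_rate`. Negative values
#' are clipped at zero (expression is non-negative); the realized clipping
#' rate is reported in the ground truth so the distortion is documented.
#'
#' @param spec a [matrix_spec()].
#' @return A list with elements
#' \describe{
#'   \item{matrix}{an [expression_matrix()] (all cells labelled `"cluster1"`).}
#'   \item{truth}{ground truth: `genes` (data.frame with columns `gene`,
#'     `label` ("oscillator"/"noise"), `group` (integer or NA), `phase`
#'     (radians or NA)), `latent_phase` (named numeric, radians per cell),
#'     `clip_rate` (fraction of entries clipped at 0 before dropout), and the
#'     generating `spec`.}
#' }
#' @examples
#' sim <- generate_cosc_matrix(matrix_spec(n_cells = 50, seed = 7))
#' table(sim$truth$genes$label)
#' @export
generate_cosc_matrix <- function(spec) {
  check_that(inherits(spec, "synth_matrix_spec"),
             "spec must be created by matrix_spec()")
  n_osc <- sum(vapply(spec$groups, function(g) g$n_genes, integer(1)))
  n_genes <- n_osc + spec$n_noise_genes

  with_seed(spec$seed, {
    theta <- stats::runif(spec$n_cells, 0, 2 * pi)
    gene_names <- character(0)
    labels <- character(0)
    group_of <- integer(0)
    phases <- numeric(0)
    values <- matrix(0, nrow = n_genes, ncol = spec$n_cells)
    row <- 0L
    for (k in seq_along(spec$groups)) {
      grp <- spec$groups[[k]]
      phi <- stats::runif(grp$n_genes, 0, max(grp$phase_dispersion, 0))
      if (grp$phase_dispersion == 0) phi <- rep(0, grp$n_genes)
      for (i in seq_len(grp$n_genes)) {
        row <- row + 1L
        values[row, ] <- spec$baseline_mean +
          grp$amplitude * sin(grp$relative_frequency * theta + phi[i]) +
          stats::rnorm(spec$n_cells, 0, spec$noise_sd)
      }
      gene_names <- c(gene_names, sprintf("OSC%d_%03d", k, seq_len(grp$n_genes)))
      labels <- c(labels, rep("oscillator", grp$n_genes))
      group_of <- c(group_of, rep(k, grp$n_genes))
      phases <- c(phases, phi)
    }
    if (spec$n_noise_genes > 0) {
      noise <- matrix(spec$baseline_mean +
                        stats::rnorm(spec$n_noise_genes * spec$n_cells,
                                     0, spec$noise_sd),
                      nrow = spec$n_noise_genes)
      values[(row + 1L):n_genes, ] <- noise
      gene_names <- c(gene_names, sprintf("NOISE%03d", seq_len(spec$n_noise_genes)))
      labels <- c(labels, rep("noise", spec$n_noise_genes))
      group_of <- c(group_of, rep(NA_integer_, spec$n_noise_genes))
      phases <- c(phases, rep(NA_real_, spec$n_noise_genes))
    }
    clip_rate <- mean(values < 0)
    values[values < 0] <- 0
    if (spec$dropout_rate > 0) {
      u <- matrix(stats::runif(length(values)), nrow = n_genes)
      p <- if (spec$dropout_model == "uniform") spec$dropout_rate
           else spec$dropout_rate *
             exp(-values / max(spec$baseline_mean, .Machine$double.eps))
      values[u < p] <- 0
    }
    cells <- sprintf("cell%04d", seq_len(spec$n_cells))
    mat <- expression_matrix(values, gene_ids = gene_names, cell_ids = cells,
                             clusters = "cluster1")
    truth <- list(
      genes = data.frame(gene = gene_names, label = labels,
                         group = group_of, phase = phases,
                         stringsAsFactors = FALSE),
      latent_phase = stats::setNames(theta, cells),
      clip_rate = clip_rate,
      spec = spec)
    list(matrix = mat, truth = truth)
  })
}

#' Specification of a synthetic fluorescence trace
#'
#' Defaults emulate a live-imaging acquisition: a 17 h ultradian period
#' sampled every 20 minutes for 70 h, on a positive intensity offset.
#' A duration of more than twice the period and a sampling interval below a
#' quarter period are recommended for period recovery; violations warn.
#'
#' @param period_h oscillation period in hours (> 0).
#' @param duration_h acquisition length in hours.
#' @param sampling_interval_h sampling step in hours.
#' @param amplitude sinusoid amplitude (a.u.).
#' @param offset mean intensity level (a.u., > 0).
#' @param trend_type `"none"`, `"linear"` (slope `trend_slope` per hour) or
#'   `"slow-sinusoid"` (period `4 * duration_h`, amplitude
#'   `abs(trend_slope) * duration_h / 2`, i.e. the same total excursion as the
#'   linear ramp).
#' @param trend_slope slow trend slope in a.u. per hour.
#' @param noise_sd additive Gaussian noise SD (a.u.).
#' @param drop_fraction fraction of timepoints removed at random to create
#'   uneven sampling (0 keeps the regular grid).
#' @param seed integer seed.
#' @return A `synth_trace_spec` (list).
#' @export
trace_spec <- function(period_h = 17, duration_h = 70,
                       sampling_interval_h = 1 / 3,
                       amplitude = 1, offset = 10,
                       trend_type = c("none", "linear", "slow-sinusoid"),
                       trend_slope = 0, noise_sd = 0,
                       drop_fraction = 0, seed = 1L) {
  check_that(is_number(period_h) && period_h > 0, "period_h must be > 0")
  check_that(is_number(duration_h) && duration_h > 0, "duration_h must be > 0")
  check_that(is_number(sampling_interval_h) && sampling_interval_h > 0,
             "sampling_interval_h must be > 0")
  check_that(is_number(amplitude) && amplitude >= 0, "amplitude must be >= 0")
  check_that(is_number(offset) && offset > 0, "offset must be > 0")
  trend_type <- match.arg(trend_type)
  check_that(is_number(trend_slope), "trend_slope must be a number")
  check_that(is_number(noise_sd) && noise_sd >= 0, "noise_sd must be >= 0")
  check_that(is_number(drop_fraction) && drop_fraction >= 0 && drop_fraction < 1,
             "drop_fraction must lie in [0, 1)")
  if (duration_h <= 2 * period_h)
    warning("duration_h <= 2 * period_h: period recovery may be unreliable")
  if (sampling_interval_h >= period_h / 4)
    warning("sampling_interval_h >= period_h / 4: sampling is too coarse")
  structure(list(period_h = period_h, duration_h = duration_h,
                 sampling_interval_h = sampling_interval_h,
                 amplitude = amplitude, offset = offset,
                 trend_type = trend_type, trend_slope = trend_slope,
                 noise_sd = noise_sd, drop_fraction = drop_fraction,
                 seed = as.integer(seed)),
            class = "synth_trace_spec")
}

#' Generate a synthetic fluorescence trace with known period
#'
#' Intensity at time `t` is
#' `offset + amplitude * sin(2*pi*t / period_h) + trend(t) + N(0, noise_sd)`
#' on the grid `0, sampling_interval_h, ..., duration_h`, optionally thinned
#' by removing a random `drop_fraction` of timepoints (uneven sampling is the
#' regime the Lomb-Scargle periodogram is designed for).
#'
#' @param spec a [trace_spec()].
#' @param trace_id label for the trace.
#' @param condition,channel optional labels carried into the output.
#' @return A data.frame with columns `time_h`, `intensity`, `trace_id`,
#'   `condition`, `channel`.
#' @examples
#' tr <- generate_trace(trace_spec(noise_sd = 0.1, seed = 3))
#' head(tr)
#' @export
generate_trace <- function(spec, trace_id = "trace1",
                           condition = "condition1", channel = "signal") {
  check_that(inherits(spec, "synth_trace_spec"),
             "spec must be created by trace_spec()")
  with_seed(spec$seed, {
    t <- seq(0, spec$duration_h, by = spec$sampling_interval_h)
    trend <- switch(spec$trend_type,
      none = rep(0, length(t)),
      linear = spec$trend_slope * t,
      `slow-sinusoid` = abs(spec$trend_slope) * spec$duration_h / 2 *
        sin(2 * pi * t / (4 * spec$duration_h)))
    y <- spec$offset + spec$amplitude * sin(2 * pi * t / spec$period_h) +
      trend + stats::rnorm(length(t), 0, spec$noise_sd)
    if (spec$drop_fraction > 0) {
      keep <- sort(sample(length(t),
                          size = ceiling(length(t) * (1 - spec$drop_fraction))))
      t <- t[keep]; y <- y[keep]
    }
    data.frame(time_h = t, intensity = y, trace_id = trace_id,
               condition = condition, channel = channel,
               stringsAsFactors = FALSE)
  })
}

#' Generate named gene lists with a constructed pairwise overlap
#'
#' Builds gene sets over a synthetic symbol universe such that the first two
#' sets share exactly `forced_overlap` symbols; further sets are random draws.
#' Used to validate list-algebra and overlap statistics against known counts.
#'
#' @param universe_size size of the symbol universe.
#' @param set_sizes integer vector of set sizes (>= 2 sets when
#'   `forced_overlap` is used).
#' @param forced_overlap exact intersection size of the first two sets.
#' @param seed integer seed.
#' @return Named list of [gene_set()] objects (`set1`, `set2`, ...) with the
#'   universe attached as attribute `"universe"`.
#' @export
generate_genelist_fixture <- function(universe_size, set_sizes,
                                      forced_overlap = 0, seed = 1L) {
  check_that(is_count(universe_size, 1), "universe_size must be a count >= 1")
  check_that(is.numeric(set_sizes) && length(set_sizes) >= 1 &&
               all(vapply(set_sizes, is_count, logical(1))),
             "set_sizes must be counts")
  check_that(all(set_sizes <= universe_size),
             "every set size must be <= universe_size")
  check_that(is_count(forced_overlap), "forced_overlap must be a count")
  if (length(set_sizes) >= 2) {
    check_that(forced_overlap <= min(set_sizes[1:2]),
               "forced_overlap must be <= min(set_sizes)")
    check_that(set_sizes[1] + set_sizes[2] - forced_overlap <= universe_size,
               "union of the first two sets exceeds the universe")
  } else {
    check_that(forced_overlap == 0,
               "forced_overlap needs at least two sets")
  }
  with_seed(seed, {
    universe <- sprintf("GENE%04d", seq_len(universe_size))
    shuffled <- sample(universe)
    sets <- vector("list", length(set_sizes))
    a <- shuffled[seq_len(set_sizes[1])]
    sets[[1]] <- gene_set("set1", a)
    if (length(set_sizes) >= 2) {
      b_shared <- if (forced_overlap > 0) a[seq_len(forced_overlap)] else character(0)
      b_rest <- shuffled[set_sizes[1] + seq_len(set_sizes[2] - forced_overlap)]
      sets[[2]] <- gene_set("set2", c(b_shared, b_rest))
      if (length(set_sizes) > 2) {
        for (i in 3:length(set_sizes))
          sets[[i]] <- gene_set(sprintf("set%d", i),
                                sample(universe, set_sizes[i]))
      }
    }
    names(sets) <- sprintf("set%d", seq_along(sets))
    attr(sets, "universe") <- universe
    sets
  })
}
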