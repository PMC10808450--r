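test_that("spec validation names the violated invariant", {
  expect_error(matrix_spec(n_cells = 1), "n_cells")
  expect_error(matrix_spec(dropout_rate = 1.2), "dropout_rate")
  expect_error(matrix_spec(noise_sd = -1), "noise_sd")
  expect_error(matrix_spec(groups = list(), n_noise_genes = 0),
               "at least one gene")
  expect_error(oscillator_group(n_genes = 1), "n_genes")
  expect_error(oscillator_group(amplitude = 0), "amplitude")
  expect_error(trace_spec(period_h = -3), "period_h")
})

test_that("complete dropout yields an all-zero matrix failing the zero filter", {
  spec <- matrix_spec(n_cells = 30, dropout_rate = 1, seed = 11,
                      groups = list(oscillator_group(n_genes = 3)),
                      n_noise_genes = 5)
  sim <- generate_cosc_matrix(spec)
  expect_true(all(sim$matrix$values == 0))
  expect_length(zero_filter(sim$matrix, "cluster1", 0.8), 0)
})

test_that("noise-free genes of identical phase are identical after rescaling", {
  spec <- matrix_spec(n_cells = 40, noise_sd = 0, dropout_rate = 0,
                      baseline_mean = 3,
                      groups = list(oscillator_group(n_genes = 2,
                                                     phase_dispersion = 0)),
                      n_noise_genes = 0, seed = 5)
  sim <- generate_cosc_matrix(spec)
  a <- rescale_to_unit(sim$matrix$values[1, ])
  b <- rescale_to_unit(sim$matrix$values[2, ])
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("matrix generation is bit-for-bit reproducible given the seed", {
  spec <- matrix_spec(seed = 42)
  s1 <- generate_cosc_matrix(spec)
  s2 <- generate_cosc_matrix(spec)
  expect_identical(s1$matrix$values, s2$matrix$values)
  expect_identical(s1$truth$latent_phase, s2$truth$latent_phase)
  s3 <- generate_cosc_matrix(matrix_spec(seed = 43))
  expect_false(identical(s1$matrix$values, s3$matrix$values))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(generate_cosc_matrix(matrix_spec(n_cells = 10, seed = 7,
                                             n_noise_genes = 5,
                                             groups = list())))
  expect_identical(runif(1), before)
})

test_that("ground truth labels partition the gene set", {
  sim <- generate_cosc_matrix(matrix_spec(seed = 2))
  tg <- sim$truth$genes
  expect_setequal(tg$gene, sim$matrix$gene_ids)
  expect_true(all(tg$label %in% c("oscillator", "noise")))
  osc <- tg[tg$label == "oscillator", ]
  expect_true(all(!is.na(osc$group)) && all(!is.na(osc$phase)))
  expect_true(all(is.na(tg$group[tg$label == "noise"])))
})

test_that("zero fraction of a clip-free matrix converges to the dropout rate", {
  ## high baseline so clipping at zero is (measurably) absent pre-dropout
  spec <- matrix_spec(n_cells = 400, baseline_mean = 50, noise_sd = 1,
                      dropout_rate = 0.3, seed = 8,
                      groups = list(oscillator_group(amplitude = 5)),
                      n_noise_genes = 100)
  sim <- generate_cosc_matrix(spec)
  expect_equal(sim$truth$clip_rate, 0)
  n <- length(sim$matrix$values)
  se <- sqrt(0.3 * 0.7 / n)
  expect_lt(abs(mean(sim$matrix$values == 0) - 0.3), 3 * se)
})

test_that("latent cell phases are uniform on [0, 2*pi)", {
  ok <- vapply(1:20, function(s) {
    sim <- generate_cosc_matrix(matrix_spec(n_cells = 300, seed = s,
                                            groups = list(), n_noise_genes = 1))
    th <- sim$truth$latent_phase / (2 * pi)
    ks_stat_unif(th) < ks_crit_01(length(th))
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("trace generation honours amplitude, cycles, and determinism", {
  const <- generate_trace(trace_spec(amplitude = 0, noise_sd = 0, offset = 4,
                                     period_h = 17, duration_h = 70))
  expect_true(all(abs(const$intensity - 4) < 1e-12))

  tr <- generate_trace(trace_spec(period_h = 17, duration_h = 68,
                                  sampling_interval_h = 1 / 3, noise_sd = 0))
  ## 68 h of a 17 h sinusoid holds exactly 4 full cycles: endpoints agree
  ## and there are 4 upward zero-crossings of the centered signal
  y <- tr$intensity - mean(tr$intensity)
  up <- sum(diff(sign(y)) > 0 & abs(y[-1]) > 1e-9)
  expect_equal(up, 4)
  expect_equal(tr$intensity[1], tr$intensity[nrow(tr)], tolerance = 1e-9)

  s1 <- generate_trace(trace_spec(noise_sd = 0.5, seed = 10))
  s2 <- generate_trace(trace_spec(noise_sd = 0.5, seed = 10))
  expect_identical(s1, s2)
})

test_that("trace thinning produces uneven sampling of the stated size", {
  tr <- generate_trace(trace_spec(drop_fraction = 0.3, seed = 3))
  full <- length(seq(0, 70, by = 1 / 3))
  expect_equal(nrow(tr), ceiling(full * 0.7))
  expect_gt(max(diff(tr$time_h)), 1 / 3 + 1e-9)
})

test_that("gene-list fixture constructs the requested overlap structure", {
  eq <- generate_genelist_fixture(10, c(5, 5), forced_overlap = 5, seed = 1)
  expect_setequal(eq$set1$genes, eq$set2$genes)

  disj <- generate_genelist_fixture(20, c(6, 7), forced_overlap = 0, seed = 2)
  expect_length(intersect(disj$set1$genes, disj$set2$genes), 0)

  fx <- generate_genelist_fixture(100, c(30, 40), forced_overlap = 12, seed = 3)
  expect_length(intersect(fx$set1$genes, fx$set2$genes), 12)
  expect_length(fx$set1$genes, 30)
  expect_length(fx$set2$genes, 40)

  expect_error(generate_genelist_fixture(10, c(5, 5), forced_overlap = 6),
               "forced_overlap")
  expect_error(generate_genelist_fixture(8, c(5, 5), forced_overlap = 0),
               "universe")
})
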