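test_that("gene_set trims, deduplicates and sorts symbols", {
  s <- gene_set("s", c(" SOX2", "JUNB", "SOX2 ", "", "  "))
  expect_identical(s$genes, c("JUNB", "SOX2"))
  expect_equal(length(s), 2)
  n <- gene_set("s", c("Sox2", "SOX2"), normalize_case = TRUE)
  expect_identical(n$genes, "SOX2")
})

test_that("shared_across unions within groups then intersects across them", {
  same <- shared_across(list(c("A", "B"), c("A", "B")))
  expect_identical(same$genes, c("A", "B"))

  expect_length(shared_across(list(c("A"), c("B"), c("C")))$genes, 0)

  ## tumours with subclusters: union first, then intersect
  tum1 <- list(gene_set("s1", c("A", "B")), gene_set("s2", c("C")))
  tum2 <- list(gene_set("s1", c("B", "C")), gene_set("s2", c("D")))
  out <- shared_across(list(tum1, tum2))
  expect_identical(out$genes, c("B", "C"))

  expect_error(shared_across(list()), "at least 2")
  expect_error(shared_across(list(c("A"))), "at least 2")

  fx <- generate_genelist_fixture(100, c(30, 40), forced_overlap = 12, seed = 3)
  expect_length(shared_across(list(fx$set1, fx$set2))$genes, 12)
})

test_that("union_all deduplicates by inclusion-exclusion", {
  expect_length(union_all(list(c("a", "b", "c"), c("d", "e", "f", "g")))$genes, 7)
  expect_identical(union_all(list(c("x", "y")))$genes, c("x", "y"))
  fx <- generate_genelist_fixture(100, c(30, 40), forced_overlap = 12, seed = 3)
  expect_length(union_all(list(fx$set1, fx$set2))$genes, 30 + 40 - 12)
})

test_that("derive_nonoscillators is expressed-minus-oscillators", {
  expect_length(derive_nonoscillators(list(c("a", "b")), list(c("a", "b")))$genes, 0)
  expect_identical(derive_nonoscillators(list(c("a", "b")), list())$genes,
                   c("a", "b"))
  out <- derive_nonoscillators(list(c("a", "b", "c", "d")),
                               list(c("b", "d", "e")))
  expect_identical(out$genes, c("a", "c"))
})

test_that("hypergeometric overlap matches exhaustive enumeration for N <= 12", {
  bg10 <- sprintf("G%02d", 1:10)
  r <- hypergeometric_overlap(bg10[1:5], bg10[1:5], bg10)
  expect_equal(r$p_hypergeometric, 1 / 252, tolerance = 1e-12)
  expect_equal(r$p_hypergeometric, enumerate_hyper_p(10, 5, 5, 5),
               tolerance = 1e-12)

  set.seed(77)
  for (rep in 1:12) {
    N <- sample(6:12, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    bg <- sprintf("G%02d", 1:N)
    a <- bg[seq_len(K)]
    b <- sample(bg, n)
    r <- hypergeometric_overlap(a, b, bg)
    expect_equal(r$p_hypergeometric,
                 enumerate_hyper_p(N, K, n, r$overlap_count),
                 tolerance = 1e-12)
  }
})

test_that("hypergeometric overlap matches the log-space sum for large N", {
  set.seed(88)
  N <- 10000
  bg <- sprintf("G%05d", 1:N)
  a <- sample(bg, 300)
  b <- sample(bg, 500)
  r <- hypergeometric_overlap(a, b, bg)
  expect_equal(r$p_hypergeometric,
               logspace_hyper_p(N, 300, 500, r$overlap_count),
               tolerance = 1e-10)
  expect_equal(r$fold_enrichment,
               (r$overlap_count / 500) / (300 / N))
})

test_that("hypergeometric edge cases: forced overlap and zero overlap", {
  bg <- sprintf("G%02d", 1:20)
  full <- hypergeometric_overlap(bg, bg[3:7], bg)  # A = background -> k = n
  expect_equal(full$overlap_count, 5)
  expect_equal(full$p_hypergeometric, 1)

  disjoint <- hypergeometric_overlap(bg[1:5], bg[6:10], bg)  # k = 0
  expect_equal(disjoint$p_hypergeometric, 1)

  expect_warning(r <- hypergeometric_overlap(c(bg[1:3], "ALIEN"), bg[2:5], bg),
                 "outside the background")
  expect_equal(r$size_a, 3)
  expect_error(hypergeometric_overlap(bg[1:2], bg[1:2], character(0)),
               "background")
})

test_that("motif_fraction restricts to evaluable TFs and reports NA at 0/0", {
  ev <- c("A", "B", "C", "D")
  expect_equal(motif_fraction(c("A", "B"), c("A", "B"), ev), 100)
  expect_equal(motif_fraction(c("A", "B"), character(0), ev), 0)
  expect_equal(motif_fraction(c("A", "B", "C", "D"), c("A", "C"), ev), 50)
  ## non-evaluable members are excluded from the denominator
  expect_equal(motif_fraction(c("A", "Z"), c("A"), ev), 100)
  expect_true(is.na(motif_fraction(c("Y", "Z"), c("A"), ev)))
  expect_error(motif_fraction(c("A"), c("Q"), ev), "subset")
})

test_that("low-cycling classification follows the top-3 downregulated rule", {
  rec <- function(set, dir, p, rank) {
    data.frame(gene_set_name = set, direction = dir, adjusted_p = p,
               rank_within_direction = rank, stringsAsFactors = FALSE)
  }
  expect_true(classify_low_cycling(rec("E2F Targets", "down", 0.01, 1)))
  expect_true(classify_low_cycling(rec("HALLMARK_G2M_CHECKPOINT", "down",
                                       0.05, 3)))
  ## no cell-cycle set in the top 3 downregulated
  expect_false(classify_low_cycling(rbind(
    rec("Hypoxia", "down", 0.01, 1),
    rec("E2F Targets", "down", 0.01, 4))))
  ## direction must be down
  expect_false(classify_low_cycling(rec("G2M Checkpoint", "up", 0.01, 1)))
  ## must clear the significance cutoff (strict <)
  expect_false(classify_low_cycling(rec("Mitotic Spindle", "down", 0.1, 1)))
  expect_true(classify_low_cycling(rec("Mitotic Spindle", "down", 0.099, 1)))
})

test_that("quiescence candidates are the triple intersection", {
  expect_length(quiescence_candidates(character(0), c("A"), c("A"))$genes, 0)
  s <- c("SOX2", "JUNB", "FOS")
  expect_identical(quiescence_candidates(s, s, s)$genes, sort(s))
  out <- quiescence_candidates(c("SOX2", "JUNB", "HES1", "OLIG2"),
                               c("SOX2", "JUNB", "FOS"),
                               c("SOX2", "JUNB", "TSC22D1"))
  expect_identical(out$genes, c("JUNB", "SOX2"))
})
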