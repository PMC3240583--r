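test_that("coverage masks union overlapping matches and match brute force", {
  m <- kmer_coverage_mask("AGAAGACCC", "AGAAGA")
  expect_equal(m, c(rep(TRUE, 6), rep(FALSE, 3)))
  expect_false(any(kmer_coverage_mask("CCCCCCCC", "AGAAGA")))
  # overlapping self-matches (AGAAGA at shift 3) are unioned
  m2 <- kmer_coverage_mask("AGAAGAAGA", c("AGAAGA"))
  expect_equal(m2, oracle_coverage_mask("AGAAGAAGA", "AGAAGA"))
  for (seed in 1:3) {
    s <- rnd_dna(2000, seed = 100 + seed)
    kset <- c("AGAAGA", "GAAGAA", "TTTTTT", "ACGTAC")
    expect_equal(kmer_coverage_mask(s, kset), oracle_coverage_mask(s, kset))
  }
  expect_error(kmer_coverage_mask("ACGT", c("AA", "AAA")), "share one length")
})

test_that("contingency tables cross-tabulate coverage by conservation", {
  tab <- build_contingency(rep(TRUE, 7), rep(TRUE, 7))
  expect_equal(unname(tab), matrix(c(7, 0, 0, 0), 2))
  cov <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE)
  cons <- c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  tab2 <- build_contingency(cov, cons)
  expect_equal(unname(tab2), matrix(c(2, 2, 2, 2), 2))
  expect_equal(sum(tab2), 8)
  expect_error(build_contingency(cov, cons[-1]), "equal length")
})

test_that("fisher_exact equals full enumeration on all small fixed-margin tables", {
  expect_equal(fisher_exact(c(5, 5, 5, 5)), 1)
  expect_equal(fisher_exact(c(3, 1, 1, 3)), 34 / 70)
  expect_equal(fisher_exact(c(10, 0, 0, 10)), 2 / choose(20, 10))
  # exhaustive check over tables with total <= 20
  set.seed(53)
  for (rep in 1:200) {
    cells <- as.vector(stats::rmultinom(1, sample(4:20, 1), rep(1 / 4, 4)))
    a <- cells[1]; b <- cells[2]; c_ <- cells[3]; d <- cells[4]
    expect_equal(fisher_exact(c(a, b, c_, d)),
                 oracle_fisher_enum(a, b, c_, d),
                 tolerance = 1e-12,
                 label = paste(cells, collapse = ","))
  }
  # agreement with the reference implementation on larger tables
  for (tab in list(c(40, 160, 55, 745), c(3, 500, 9, 488), c(120, 80, 60, 140))) {
    m <- matrix(tab, 2, byrow = TRUE)
    expect_equal(fisher_exact(m), stats::fisher.test(m)$p.value,
                 tolerance = 1e-9)
  }
  expect_error(fisher_exact(c(-1, 2, 3, 4)), "nonnegative")
})

test_that("two-sided Fisher p dominates one-sided and stays in (0, 1]", {
  set.seed(59)
  for (rep in 1:50) {
    cells <- as.vector(stats::rmultinom(1, 60, c(0.1, 0.3, 0.25, 0.35)))
    p2 <- fisher_exact(cells)
    pg <- fisher_exact(cells, alternative = "greater")
    pl <- fisher_exact(cells, alternative = "less")
    expect_gte(p2 + 1e-12, min(pg, pl))
    expect_true(p2 > 0 && p2 <= 1)
  }
})

test_that("chi2_2x2 matches the closed-form statistic; Yates shrinks it", {
  got <- chi2_2x2(c(20, 80, 10, 90))
  n <- 200
  want <- n * (20 * 90 - 80 * 10)^2 / (100 * 100 * 30 * 170)
  expect_equal(got$statistic, want)
  expect_equal(got$statistic, oracle_chi2_cells(20, 80, 10, 90))
  expect_equal(got$p, pchisq(want, 1, lower.tail = FALSE))
  # proportional rows: statistic 0, p 1
  flat <- chi2_2x2(c(10, 90, 20, 180))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)
  yates <- chi2_2x2(c(20, 80, 10, 90), continuity_correction = TRUE)
  expect_lt(yates$statistic, got$statistic)
  expect_error(chi2_2x2(c(0, 0, 5, 5)), "zero margins")
})

test_that("conserved_fraction recovers generator settings", {
  expect_equal(conserved_fraction(rep(TRUE, 10)), 1)
  expect_equal(conserved_fraction(rep(FALSE, 10)), 0)
  expect_error(conserved_fraction(logical(0)), "empty")
  s <- rnd_dna(306, seed = 61)  # poison-exon-sized
  m <- generate_conservation(s, 0.48, motif_bias = 1, seed = 62)
  expect_lt(abs(conserved_fraction(m) - 0.48), 4 * sqrt(0.48 * 0.52 / 306))
})

test_that("independent masks give odds ratios near one, biased masks enrich", {
  s <- rnd_dna(20000, seed = 67)
  kset <- vapply(1:24, function(i) rnd_dna(6), character(1))
  m_null <- generate_conservation(s, 0.48, motif_bias = 1, seed = 68)
  res <- conservation_test(s, kset, m_null)
  expect_lt(abs(log(res$odds_ratio)), 0.5)
  expect_equal(sum(res$table), 20000)
  # conservation drawn to favour the planted motif is detected
  set.seed(69)
  s2 <- paste(vapply(1:10, function(i) paste0(rnd_dna(294), "AGAAGA"),
                     character(1)), collapse = "")
  m_bias <- generate_conservation(s2, 0.3, motif_bias = 25, seed = 70,
                                  motif = "AGAAGA")
  res2 <- conservation_test(s2, "AGAAGA", m_bias)
  expect_lt(res2$fisher_p, 0.05)
  expect_lt(res2$chi2_p, 0.05)
  expect_gt(res2$odds_ratio, 1)
})
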