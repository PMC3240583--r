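fabricate_table <- function(n = 40, seed = 71, ese = 4, ess = -4) {
  set.seed(seed)
  octs <- unique(vapply(seq_len(n), function(i) rnd_dna(8), character(1)))
  octamer_score_table(setNames(runif(length(octs), -6, 6), octs),
                      ese_threshold = ese, ess_threshold = ess)
}

test_that("z-score profiles are exact octamer lookups with neutral missing scores", {
  tab <- octamer_score_table(c(AAAAAAAA = 5), 4, -4)
  s <- "CCAAAAAAAACC"
  prof <- zscore_profile(s, tab)
  expect_equal(length(prof$values), nchar(s) - 7)
  expect_equal(unname(prof$values), c(0, 0, 5, 0, 0))
  expect_equal(prof$n_unknown, 4)
  expect_error(zscore_profile("ACGTACG", tab), "at least 8")
  expect_error(zscore_profile(s, tab, missing = "error"), "absent")
  # brute-force oracle on random sequence and fabricated table
  tab2 <- fabricate_table(200, seed = 72)
  s2 <- rnd_dna(500, seed = 73)
  expect_equal(unname(zscore_profile(s2, tab2)$values),
               oracle_zscore_profile(s2, tab2$scores))
})

test_that("region calling merges adjacent super-threshold windows", {
  tab <- octamer_score_table(c(AAAAAAAA = 5, CCCCCCCC = -5), 4, -4)
  flat <- zscore_profile("ACGTACGTACGT", tab)
  expect_equal(nrow(call_regions(flat)), 0)
  # two adjacent scored windows merge into one ESE spanning both octamers
  prof <- zscore_profile("GGAAAAAAAAAGG", tab)  # AAAAAAAA at starts 2 and 3
  calls <- call_regions(prof)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$type, "ESE")
  expect_equal(calls$start, 2)
  expect_equal(calls$end, 3 + 8)
  expect_equal(calls$peak, 5)
  # ESS called symmetrically below threshold
  both <- zscore_profile("AAAAAAAATTCCCCCCCC", tab)
  cb <- call_regions(both)
  expect_setequal(cb$type, c("ESE", "ESS"))
  expect_equal(cb$peak[cb$type == "ESS"], -5)
})

test_that("a planted strong octamer yields exactly one containing ESE", {
  set.seed(79)
  strong <- "GAAGAAGA"
  tab <- octamer_score_table(setNames(6, strong), 4, -4)
  s <- paste0(rnd_dna(60), strong, rnd_dna(60))
  calls <- call_regions(zscore_profile(s, tab))
  ese <- calls[calls$type == "ESE", ]
  expect_equal(nrow(ese), 1)
  expect_true(ese$start <= 60 && ese$end >= 60 + 8)
})

test_that("mutation design equals the exhaustive brute-force oracle", {
  # small alphabet-dense table so many substitutions change scores
  set.seed(83)
  seqs <- Biostrings::mkAllStrings(c("A", "G"), 8)  # all AG octamers
  scores <- setNames(runif(length(seqs), -6, 6), seqs)
  tab <- octamer_score_table(scores, 3, -3)
  s <- paste(sample(c("A", "G"), 40, TRUE), collapse = "")
  scores[substr(s, 11, 18)] <- 5.5  # guarantee a called ESE inside s
  tab <- octamer_score_table(scores, 3, -3)
  prof <- zscore_profile(s, tab)
  calls <- call_regions(prof)
  ese <- calls[calls$type == "ESE", ][1, ]
  expect_false(is.na(ese$start))
  plans <- design_disrupting_mutation(s, ese, tab)
  # oracle: recompute validity for every substitution in the interval
  for (r in seq_len(nrow(plans))) {
    p <- plans[r, ]
    mut <- paste0(substr(s, 1, p$position), p$alt_base,
                  substr(s, p$position + 2, nchar(s)))
    after <- oracle_zscore_profile(mut, scores)
    tgt <- after[(ese$win_from:ese$win_to) + 1]
    valid <- all(tgt < 3) && !any(after < -3)
    expect_equal(p$valid, valid,
                 label = paste("pos", p$position, p$alt_base))
    # stored after-scores match full recomputation (locality invariant)
    aff <- as.integer(names(p$after_scores[[1]]))
    expect_equal(unname(p$after_scores[[1]]), after[aff + 1])
    untouched <- setdiff(seq_along(after) - 1L, aff)
    expect_equal(after[untouched + 1], unname(prof$values)[untouched + 1])
  }
  # plans sorted by post-mutation peak, identity mutations never proposed
  expect_true(!is.unsorted(plans$peak_after))
  expect_true(all(plans$alt_base != plans$ref_base))
  # exhaustive count: 3 substitutions per interval position
  expect_equal(nrow(plans), 3 * (ese$end - ese$start))
})

test_that("a substitution creating a silencer is marked invalid", {
  tab <- octamer_score_table(c(AAAAAAAA = 5, AAAACAAA = -5), 4, -4)
  s <- "GGGAAAAAAAAGGG"
  calls <- call_regions(zscore_profile(s, tab))
  ese <- calls[calls$type == "ESE", ][1, ]
  plans <- design_disrupting_mutation(s, ese, tab)
  bad <- plans[plans$alt_base == "C" & plans$position == ese$start + 4, ]
  expect_false(any(bad$valid))
  # substitutions to unscored octamers are valid
  expect_true(any(plans$valid))
  ok <- plans[plans$valid, ][1, ]
  after_prof <- zscore_profile(apply_mutation(s, ok$position, ok$alt_base), tab)
  expect_true(all(after_prof$values < 4) && all(after_prof$values > -4))
})
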