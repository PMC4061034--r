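test_that("consensus score reproduces the worked candidate rows", {
  # TOLERATED + disease_causing, GERP 5.17: one of two votes, conserved
  r <- consensus_score(sift = "TOLERATED", mutation_taster = "disease_causing",
                       gerp = 5.17)
  expect_equal(r$damaging_votes, 1)
  expect_equal(r$votes_available, 2)
  expect_true(r$conserved)
  expect_equal(r$score, 1 / 2 + 0.25)
  # DAMAGING + disease_causing, GERP 5.34: both votes damaging
  r <- consensus_score(sift = "DAMAGING", mutation_taster = "disease causing",
                       gerp = 5.34)
  expect_equal(r$damaging_votes, 2)
  expect_equal(r$votes_available, 2)
  expect_true(r$conserved)
  # four damaging calls at an unconserved site
  r <- consensus_score("DAMAGING", "disease_causing", "damaging",
                       "pathological", gerp = 0)
  expect_equal(r$damaging_votes, 4)
  expect_equal(r$votes_available, 4)
  expect_false(r$conserved)
  expect_equal(r$score, 1)
})

test_that("all-missing predictor profiles are undefined and flagged", {
  r <- consensus_score(gerp = 5)
  expect_true(is.na(r$score))
  expect_false(r$score_defined)
  expect_true(r$conserved)
})

test_that("flipping any predictor to damaging never lowers the score", {
  set.seed(31)
  vocab <- list(sift = c("DAMAGING", "TOLERATED", NA),
                mutation_taster = c("disease_causing", "polymorphism", NA),
                polyphen2 = c("damaging", "benign", NA),
                pmut = c("pathological", "neutral", NA))
  damaging <- c(sift = "DAMAGING", mutation_taster = "disease_causing",
                polyphen2 = "damaging", pmut = "pathological")
  for (k in 1:60) {
    prof <- lapply(vocab, sample, size = 1)
    gerp <- runif(1, -2, 6)
    base <- do.call(consensus_score, c(prof, list(gerp = gerp)))
    for (p in names(vocab)) {
      if (identical(prof[[p]], damaging[[p]])) next
      flipped <- prof; flipped[[p]] <- damaging[[p]]
      new <- do.call(consensus_score, c(flipped, list(gerp = gerp)))
      if (!is.na(base$score)) expect_gte(new$score, base$score)
    }
  }
})

test_that("panel-absent candidates outrank panel-positive ones", {
  cand <- data.frame(gene = c("THBS1", "DLG1"), gerp = c(5.78, 5.17))
  sc <- consensus_score(sift = c("TOLERATED", "TOLERATED"),
                        mutation_taster = rep("disease_causing", 2),
                        gerp = cand$gerp)
  sc$score <- c(0.75, 0.75)    # force equal scores; panel decides
  r <- rank_candidates(cand, sc, control_carriers = c(3, 0))
  expect_equal(r$gene, c("DLG1", "THBS1"))
  expect_equal(r$rank, 1:2)
})

test_that("ranking is total, deterministic and input-order invariant", {
  set.seed(17)
  n <- 40
  cand <- data.frame(gene = sprintf("G%02d", sample(n)),
                     gerp = round(runif(n, -2, 6), 2))
  sc <- consensus_score(
    sift = sample(c("DAMAGING", "TOLERATED", NA), n, TRUE),
    mutation_taster = sample(c("disease_causing", "polymorphism", NA), n, TRUE),
    gerp = cand$gerp)
  cc <- sample(0:2, n, TRUE, prob = c(.6, .3, .1))
  ref <- rank_candidates(cand, sc, cc)
  for (k in 1:5) {
    perm <- sample(n)
    got <- rank_candidates(cand[perm, , drop = FALSE],
                           sc[perm, , drop = FALSE], cc[perm])
    expect_equal(got$gene, ref$gene)
    expect_equal(got$rank, ref$rank)
  }
  # identical records except gene break ties lexicographically
  tie <- data.frame(gene = c("BBB", "AAA"), gerp = c(3, 3))
  tsc <- consensus_score(sift = c("DAMAGING", "DAMAGING"), gerp = c(3, 3))
  expect_equal(rank_candidates(tie, tsc, c(0, 0))$gene, c("AAA", "BBB"))
  # undefined scores rank last
  mix <- data.frame(gene = c("DEF", "UND"), gerp = c(1, 6))
  msc <- consensus_score(sift = c("TOLERATED", NA), gerp = c(1, 6))
  expect_equal(rank_candidates(mix, msc, c(0, 0))$gene, c("DEF", "UND"))
})

test_that("the bundled 22-candidate table ranks the panel-absent genes first", {
  cand <- example_candidates()
  sc <- consensus_score(sift = cand$sift, mutation_taster = cand$mutation_taster,
                        gerp = cand$gerp)
  r <- rank_candidates(cand, sc, control_carriers = as.integer(cand$hc_positive))
  expect_equal(nrow(r), 22L)
  first_block <- r$gene[seq_len(sum(!cand$hc_positive))]
  expect_true(all(!r$hc_positive[seq_along(first_block)]))
  expect_lt(which(r$gene == "DLG1"), which(r$gene == "THBS1"))
})
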