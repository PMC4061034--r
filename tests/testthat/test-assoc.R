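test_that("panel screening counts carriers, alleles and missing", {
  controls <- c(rep("hom_ref", 400), "het")
  cases <- c(rep("hom_ref", 277), "het")
  r <- screen_panel(cases, controls)
  expect_equal(r$control_carriers, 1)
  expect_equal(r$control_alt, 1)
  expect_equal(r$control_alleles, 802)
  expect_equal(r$case_carriers, 1)
  expect_equal(r$case_alleles, 556)
  expect_false(r$degenerate)
  # hom_alt contributes two alternate alleles; missing leaves denominators
  r <- screen_panel(c("hom_alt", "missing"), c("hom_ref"))
  expect_equal(r$case_alt, 2)
  expect_equal(r$case_alleles, 2)
  expect_equal(r$n_missing, 1)
  # all-missing panel is degenerate
  r <- screen_panel(rep("missing", 5), rep("missing", 5))
  expect_true(r$degenerate)
  expect_equal(r$case_alleles, 0)
})

test_that("allelic chi-square matches the closed form and its null cases", {
  # hand-evaluated: chi2 = 1362*(3*802)^2 / (560*802*3*1359) = 4.3059130
  r <- allelic_chisq(contingency_2x2(3, 557, 0, 802))
  expect_equal(r$chi2, 4.3059129612, tolerance = 1e-9)
  expect_equal(r$p, 0.0379801044, tolerance = 1e-8)
  expect_true(r$or_corrected)                 # zero cell -> Haldane-Anscombe
  expect_equal(r$odds_ratio, (3.5 * 802.5) / (557.5 * 0.5), tolerance = 1e-12)
  # equal proportions: no association
  r <- allelic_chisq(contingency_2x2(5, 95, 5, 95))
  expect_equal(r$chi2, 0)
  expect_equal(r$p, 1)
  expect_false(r$or_corrected)
  # monomorphic table: not applicable
  r <- allelic_chisq(contingency_2x2(0, 560, 0, 802))
  expect_true(is.na(r$p))
  expect_match(r$reason, "zero margin")
})

test_that("allelic chi-square agrees with the stats oracle on random tables", {
  set.seed(41)
  for (k in 1:50) {
    cells <- rmultinom(1, sample(40:400, 1), runif(4, 0.05, 1))[, 1]
    if (any(c(cells[1] + cells[2], cells[3] + cells[4],
              cells[1] + cells[3], cells[2] + cells[4]) == 0)) next
    r <- allelic_chisq(contingency_2x2(cells[1], cells[2], cells[3], cells[4]))
    o <- suppressWarnings(chisq.test(matrix(cells, 2, byrow = TRUE),
                                     correct = FALSE))
    expect_equal(r$chi2, unname(o$statistic), tolerance = 1e-10)
    expect_equal(r$p, o$p.value, tolerance = 1e-10)
    expect_gte(r$chi2, 0)
    # invariant under simultaneous row and column swaps
    sw <- allelic_chisq(contingency_2x2(cells[4], cells[3], cells[2], cells[1]))
    expect_equal(sw$chi2, r$chi2, tolerance = 1e-10)
  }
})

test_that("Fisher enumeration reproduces the worked carrier table", {
  # genotypic carrier table: 3 of 280 cases vs 0 of 401 controls
  expect_equal(fisher_exact(contingency_2x2(3, 277, 0, 401)),
               0.0690686920, tolerance = 1e-8)
  expect_equal(fisher_exact(contingency_2x2(1, 9, 1, 9)), 1)
  expect_equal(fisher_exact(contingency_2x2(0, 10, 0, 10)), 1)
})

test_that("Fisher enumeration matches brute-force hypergeometric probabilities", {
  # independent oracle built from binomial coefficients only
  oracle_two_sided <- function(a, b, c, d) {
    r1 <- a + b; r2 <- c + d; k <- a + c
    supp <- max(0, k - r2):min(k, r1)
    pr <- choose(r1, supp) * choose(r2, k - supp) / choose(r1 + r2, k)
    sum(pr[pr <= pr[supp == a] * (1 + 1e-7)])
  }
  # exhaustive over every table with N <= 25 (one vectorized check per N)
  for (N in 1:25) {
    got <- want <- numeric(0)
    for (r1 in 0:N) {
      for (k in 0:N) {
        r2 <- N - r1
        for (a in max(0, k - r2):min(k, r1)) {
          t <- contingency_2x2(a, r1 - a, k - a, r2 - (k - a))
          got <- c(got, fisher_exact(t))
          want <- c(want, oracle_two_sided(a, r1 - a, k - a, r2 - (k - a)))
        }
      }
    }
    expect_equal(got, want, tolerance = 1e-12)
  }
  # random coverage of larger tables up to N = 60, against both oracles
  set.seed(43)
  for (rep in 1:300) {
    N <- sample(26:60, 1)
    r1 <- sample(0:N, 1); k <- sample(0:N, 1); r2 <- N - r1
    supp <- max(0, k - r2):min(k, r1); a <- supp[sample.int(length(supp), 1)]
    t <- contingency_2x2(a, r1 - a, k - a, r2 - (k - a))
    p <- fisher_exact(t)
    expect_equal(p, oracle_two_sided(a, r1 - a, k - a, r2 - (k - a)),
                 tolerance = 1e-12)
    if (r1 > 0 && r2 > 0 && k > 0 && k < N) {
      o <- fisher.test(matrix(c(a, r1 - a, k - a, r2 - (k - a)), 2,
                              byrow = TRUE))
      expect_equal(p, o$p.value, tolerance = 1e-7)
    }
  }
})

test_that("Fisher tail properties hold", {
  set.seed(47)
  for (rep in 1:100) {
    N <- sample(2:60, 1)
    r1 <- sample(0:N, 1); k <- sample(0:N, 1); r2 <- N - r1
    supp <- max(0, k - r2):min(k, r1); a <- supp[sample.int(length(supp), 1)]
    t <- contingency_2x2(a, r1 - a, k - a, r2 - (k - a))
    expect_lte(fisher_exact(t, "one"), fisher_exact(t, "two") + 1e-12)
    # enumeration probabilities over fixed margins sum to one
    supp <- max(0, k - r2):min(k, r1)
    expect_equal(sum(dhyper(supp, r1, r2, k)), 1, tolerance = 1e-12)
  }
})

test_that("chi-square and Fisher p agree on large balanced tables", {
  set.seed(53)
  for (rep in 1:10) {
    a <- 300 + sample(0:20, 1); b <- 300 + sample(0:20, 1)
    c <- 300 + sample(0:20, 1); d <- 300 + sample(0:20, 1)
    t <- contingency_2x2(a, b, c, d)
    pc <- allelic_chisq(t)$p
    pf <- fisher_exact(t)
    expect_lt(abs(pc - pf) / pf, 0.10)
  }
})
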