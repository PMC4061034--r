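test_that("a fixed seed yields a byte-identical bundle", {
  d1 <- file.path(tempdir(), "bundle_a")
  d2 <- file.path(tempdir(), "bundle_b")
  simulate_family_bundle(sim_config(seed = 99, n_variants = 300), d1)
  simulate_family_bundle(sim_config(seed = 99, n_variants = 300), d2)
  files <- list.files(d1)
  expect_gt(length(files), 6)
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  # a different seed produces a different world
  d3 <- file.path(tempdir(), "bundle_c")
  simulate_family_bundle(sim_config(seed = 100, n_variants = 300), d3)
  expect_false(identical(readLines(file.path(d1, "quartet.vcf")),
                         readLines(file.path(d3, "quartet.vcf"))))
})

test_that("every simulated trio genotype is Mendelian-consistent", {
  for (seed in c(1, 2, 3)) {
    b <- simulate_family_bundle(sim_config(seed = seed, n_variants = 400))
    res <- mendelian_consistency(b$cohort, b$pedigree)
    expect_true(all(res[!is.na(res)]))
  }
})

test_that("founder genotypes track the configured allele frequency", {
  # 1000 unrelated founders at AF 0.10: observed AF within 3 binomial SE
  ped <- pedigree(data.frame(
    id = sprintf("F%04d", 1:1000), father = NA, mother = NA,
    sex = "unknown", affected = "unaffected"))
  set.seed(123)
  af <- rep(0.10, 50)
  gt <- famvar:::simulate_pedigree_genotypes(ped, af)
  obs <- rowMeans(gt) / 2
  se <- sqrt(0.10 * 0.90 / (2 * 1000))
  expect_true(all(abs(obs - 0.10) < 3 * se + 0.015))
  expect_lt(abs(mean(obs) - 0.10), 3 * se / sqrt(50))
})

test_that("the planted causal variant is constructed to survive everything", {
  b <- simulate_family_bundle(sim_config(seed = 5, n_variants = 500))
  tr <- b$truth[b$truth$causal, ]
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$consequence, "missense")
  expect_equal(tr$region, "target")
  expect_false(tr$db_reject)
  expect_false(tr$in_dbsnp)
  i <- match(tr$id, b$cohort$sites$id)
  aff <- b$pedigree$id[b$pedigree$affected == "affected"]
  unaff <- setdiff(b$pedigree$id, aff)
  expect_true(all(b$cohort$geno[i, intersect(aff, b$cohort$samples)] == "het"))
  expect_true(all(b$cohort$geno[i, intersect(unaff, b$cohort$samples)] ==
                    "hom_ref"))
  # relatives are hom_ref at the causal site, so co-segregation holds
  rel <- b$relatives[b$relatives$id == tr$id, ]
  expect_equal(nrow(rel), 10L)
  expect_true(all(rel$geno == "hom_ref"))
  # planted panel carriers: one sporadic case, no controls
  pan <- b$panel[b$panel$id == tr$id, ]
  expect_equal(sum(pan$geno != "hom_ref" & pan$group == "case"), 1L)
  expect_equal(sum(pan$geno != "hom_ref" & pan$group == "control"), 0L)
})

test_that("configuration validation rejects impossible worlds", {
  expect_error(sim_config(frac_flank = 0.7, frac_offtarget = 0.5), "exceeds 1")
  expect_error(sim_config(frac_rare = 1.2), "probabilities")
  expect_warning(sim_config(rare_af_range = c(1e-4, 0.02)), "rejection threshold")
})

test_that("expected_survivors follows the product rule and the plant", {
  cfg <- sim_config(seed = 1, n_variants = 1000)
  exp <- expected_survivors(cfg)
  expect_equal(exp$stage[1], "total_calls")
  # counts are monotone down the per-sample cascade
  per <- exp$expected_control[exp$stream == "per_sample"]
  expect_true(all(diff(per) <= 1e-9))
  # the causal contributes exactly +1 to case streams
  expect_equal(exp$expected_case - 1,
               ifelse(is.na(exp$expected_control),
                      exp$expected_case - 1, exp$expected_control),
               tolerance = 1e-12)
  expect_true(all(exp$expected_case[exp$stream == "shared"] >= 1))
  # trivial product rule: halving the disrupting fraction halves the
  # protein-disrupting stage expectation (passenger part)
  cfg2 <- sim_config(seed = 1, n_variants = 1000, frac_disrupting = 0.0625)
  exp2 <- expected_survivors(cfg2)
  i <- match("protein_disrupting", exp$stage)
  expect_equal(exp2$expected_control[i], exp$expected_control[i] / 2,
               tolerance = 1e-9)
})

test_that("simulated stage counts match the analytic expectations", {
  cfg <- sim_config(seed = 77, n_variants = 2000)
  b <- simulate_family_bundle(cfg)
  run <- run_pipeline(b)
  exp <- expected_survivors(cfg)
  per <- exp[exp$stream == "per_sample", ]
  for (i in seq_len(nrow(per))) {
    row <- run$stages[run$stages$stage == per$stage[i], ]
    expect_lt(abs(row$DAUGHTER - per$expected_case[i]), 4 * per$se[i] + 1)
    expect_lt(abs(row$MOTHER - per$expected_control[i]), 4 * per$se[i] + 1)
  }
})
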