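quartet_geno <- function(father, daughter, mother, grandmother) {
  matrix(c(father, daughter, mother, grandmother), 1, 4,
         dimnames = list("v1", c("FATHER", "DAUGHTER", "MOTHER",
                                 "GRANDMOTHER")))
}

test_that("dominant filter keeps case-shared, control-absent variants", {
  cases <- c("FATHER", "DAUGHTER"); ctrls <- c("MOTHER", "GRANDMOTHER")
  keep <- function(...) unname(dominant_shared_filter(quartet_geno(...),
                                                      cases, ctrls))[1]
  expect_true(keep("het", "het", "hom_ref", "hom_ref"))
  expect_false(keep("het", "hom_ref", "hom_ref", "hom_ref"))  # not shared
  expect_false(keep("het", "het", "het", "hom_ref"))          # in a control
  expect_false(keep("het", "het", "hom_alt", "hom_ref"))      # hom_alt control
  expect_true(keep("hom_alt", "het", "hom_ref", "hom_ref"))   # hom_alt carries
})

test_that("edge cohorts behave as defined", {
  g <- quartet_geno("het", "het", "hom_ref", "het")
  # empty control set reduces to an intersection over cases
  expect_true(unname(dominant_shared_filter(g, c("FATHER", "DAUGHTER"),
                                            character(0)))[1])
  # empty case set yields the empty set
  expect_false(unname(dominant_shared_filter(g, character(0),
                                             c("MOTHER")))[1])
  expect_error(dominant_shared_filter(g, c("FATHER", "NOBODY"), "MOTHER"),
               "config error")
})

test_that("missing genotypes drop under strict mode, flag under permissive", {
  g <- quartet_geno("het", "missing", "hom_ref", "hom_ref")
  cases <- c("FATHER", "DAUGHTER"); ctrls <- c("MOTHER", "GRANDMOTHER")
  expect_false(unname(dominant_shared_filter(g, cases, ctrls, "strict"))[1])
  perm <- dominant_shared_filter(g, cases, ctrls, "permissive")
  expect_true(unname(perm)[1])
  expect_true(attr(perm, "flagged")[1])
})

test_that("co-segregation partitions candidates and names carriers", {
  g <- matrix("hom_ref", 5, 3,
              dimnames = list(paste0("v", 1:5), paste0("R", 1:3)))
  g["v2", "R1"] <- "het"
  g["v4", c("R1", "R2", "R3")] <- c("het", "hom_alt", "het")
  res <- cosegregation_check(g)
  expect_setequal(res$passing, c("v1", "v3", "v5"))
  expect_setequal(res$failing$id, c("v2", "v4"))
  expect_equal(res$failing$carriers[res$failing$id == "v4"], "R1,R2,R3")
  # partition: passing and failing are disjoint and exhaustive
  expect_setequal(c(res$passing, res$failing$id), rownames(g))
  expect_length(intersect(res$passing, res$failing$id), 0)
})

test_that("zero genotyped relatives passes vacuously with a warning", {
  g <- matrix(character(0), 3, 0, dimnames = list(paste0("v", 1:3), NULL))
  expect_warning(res <- cosegregation_check(g), "vacuously")
  expect_setequal(res$passing, paste0("v", 1:3))
})

test_that("relatives with unknown or affected status are excluded", {
  ped <- pedigree(data.frame(
    id = c("R1", "R2", "R3"), father = NA, mother = NA,
    sex = "unknown", affected = c("unaffected", "affected", "unknown")))
  g <- matrix(c("het", "het", "het"), 1, 3,
              dimnames = list("v1", c("R1", "R2", "R3")))
  expect_message(res <- cosegregation_check(g, ped), "R2, R3")
  expect_equal(res$failing$carriers, "R1")
  expect_setequal(res$excluded, c("R2", "R3"))
})

test_that("trio consistency matches exhaustive transmission enumeration", {
  states <- c("hom_ref", "het", "hom_alt")
  alleles <- list(hom_ref = list(c(0, 0)), het = list(c(0, 1)),
                  hom_alt = list(c(1, 1)))
  # independent oracle: enumerate every paternal x maternal allele pick
  oracle <- function(child, father, mother) {
    fa <- alleles[[father]][[1]]; mo <- alleles[[mother]][[1]]
    ch <- paste(sort(alleles[[child]][[1]]), collapse = "")
    possible <- apply(expand.grid(fa, mo), 1,
                      function(p) paste(sort(p), collapse = ""))
    ch %in% possible
  }
  grid <- expand.grid(child = states, father = states, mother = states,
                      stringsAsFactors = FALSE)
  got <- mendelian_consistent(grid$child, grid$father, grid$mother)
  want <- mapply(oracle, grid$child, grid$father, grid$mother)
  expect_equal(got, unname(want))
  expect_equal(sum(got), 15L)   # 15 of the 27 trio combinations are legal
  # spot checks of the transmission rule
  expect_false(mendelian_consistent("het", "hom_ref", "hom_ref"))
  expect_true(mendelian_consistent("het", "het", "hom_ref"))
  expect_true(is.na(mendelian_consistent("het", "missing", "hom_ref")))
})

test_that("cohort-level Mendelian screen flags planted violations", {
  ped <- family_a_pedigree(0)
  g <- matrix("hom_ref", 2, 4,
              dimnames = list(NULL, c("GRANDMOTHER", "MOTHER", "FATHER",
                                      "DAUGHTER")))
  g[2, "DAUGHTER"] <- "hom_alt"   # impossible: both parents hom_ref
  x <- make_cohort(g)
  res <- mendelian_consistency(x, ped)
  expect_equal(colnames(res), "DAUGHTER")
  expect_equal(unname(res[, 1]), c(TRUE, FALSE))
})
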