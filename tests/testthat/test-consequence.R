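test_that("classify_snv reproduces the worked single-exon examples", {
  m <- toy_plus_model()
  r <- classify_snv("chr1", 106, "A", "G", m)
  expect_equal(r$consequence, "synonymous")      # AAA -> AAG, both Lys
  expect_equal(r$codon_change, "AAA6AAG")
  r <- classify_snv("chr1", 104, "A", "G", m)
  expect_equal(r$consequence, "missense")        # AAA -> GAA, K -> E
  expect_equal(r$aa_change, "p.K2E")
  r <- classify_snv("chr1", 104, "A", "T", m)
  expect_equal(r$consequence, "nonsense")        # AAA -> TAA
  r <- classify_snv("chr1", 50, "A", "G", m)
  expect_equal(r$consequence, "intergenic")      # outside the gene span
})

test_that("classify_snv matches the brute-force translation oracle, both strands", {
  bases <- c("A", "C", "G", "T")
  for (model in list(toy_plus_model(), toy_minus_model(), toy_spliced_model())) {
    coding <- unlist(mapply(seq, model$cds_start, model$cds_end,
                            SIMPLIFY = FALSE))
    for (pos in coding) {
      ref <- model_ref_base(pos, model)
      for (alt in setdiff(bases, ref)) {
        got <- classify_snv(model$chrom, pos, ref, alt, model)
        expect_equal(got$consequence, oracle_classify(pos, alt, model),
                     info = sprintf("%s pos %d %s>%s", model$gene, pos, ref, alt))
      }
    }
  }
})

test_that("minus-strand model mirrors its plus-strand twin", {
  plus <- toy_plus_model()     # CDS 101..109, seq ATGAAATAA
  minus <- toy_minus_model()   # CDS 201..209, same sense sequence
  # position at CDS index ci maps to 101+ci-1 (plus) and 209-ci+1 (minus)
  for (ci in 1:9) {
    sense_ref <- substr(plus$cds_seq, ci, ci)
    for (sense_alt in setdiff(c("A", "C", "G", "T"), sense_ref)) {
      rp <- classify_snv("chr1", 100 + ci, sense_ref, sense_alt, plus)
      rm <- classify_snv("chr1", 210 - ci,
                         chartr("ACGT", "TGCA", sense_ref),
                         chartr("ACGT", "TGCA", sense_alt), minus)
      expect_equal(rm$consequence, rp$consequence)
      expect_equal(rm$aa_change, rp$aa_change)
      expect_equal(rm$codon_change, rp$codon_change)
    }
  }
})

test_that("splice-site window and in-gene noncoding classification", {
  m <- toy_spliced_model()     # CDS 101..106 and 201..206
  # within 2 bp of the internal edges (106, 201) -> splice_site
  expect_equal(classify_snv("chr1", 107, "A", "G", m)$consequence, "splice_site")
  expect_equal(classify_snv("chr1", 108, "A", "G", m)$consequence, "splice_site")
  expect_equal(classify_snv("chr1", 199, "A", "G", m)$consequence, "splice_site")
  # deeper intronic positions collapse to in-gene noncoding
  expect_equal(classify_snv("chr1", 150, "A", "G", m)$consequence,
               "noncoding_in_gene")
  # outside the outermost CDS bounds -> intergenic (no splice call there)
  expect_equal(classify_snv("chr1", 99, "A", "G", m)$consequence, "intergenic")
  expect_equal(classify_snv("chr1", 208, "A", "G", m)$consequence, "intergenic")
})

test_that("reference-allele mismatches raise an annotation error", {
  expect_error(classify_snv("chr1", 104, "C", "G", toy_plus_model()),
               "mismatch")
})

test_that("transcript model invariants are enforced", {
  expect_error(transcript_model("G", "chr1", "+", 101, 108, "ATGAAATA"),
               "divisible by 3")
  expect_error(transcript_model("G", "chr1", "+", 101, 109, "ATGAAA"),
               "does not match")
  expect_error(transcript_model("G", "chr1", "+", c(101, 104), c(106, 109),
                                "ATGAAATAAATG"), "overlap")
})

test_that("protein-disrupting filter retains exactly the damaging classes", {
  g <- matrix("het", 4, 1, dimnames = list(NULL, "S1"))
  x <- make_cohort(g)
  out <- filter_protein_disrupting(
    x, c("missense", "synonymous", "intronic", "nonsense"))
  expect_equal(n_sites(out), 2L)
  expect_equal(attr(out, "n_dropped"), 2L)
  # empty input -> empty output
  empty <- subset_sites(x, integer(0))
  expect_equal(n_sites(filter_protein_disrupting(empty, character(0))), 0L)
  # all-disrupting input is untouched
  out <- filter_protein_disrupting(x, rep("missense", 4))
  expect_equal(n_sites(out), 4L)
  expect_error(filter_protein_disrupting(x, c("missense", "weird",
                                              "intronic", "nonsense")),
               "weird")
})
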