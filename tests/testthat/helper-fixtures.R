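# shared fixtures: tiny cohorts, toy transcript models, text VCFs

make_cohort <- function(geno, chrom = "chr1", pos = NULL,
                        ref = "A", alt = "G", ...) {
  geno <- as.matrix(geno)
  n <- nrow(geno)
  if (is.null(pos)) pos <- seq(1000L, by = 100L, length.out = n)
  sites <- data.frame(chrom = chrom, pos = pos,
                      ref = rep_len(ref, n), alt = rep_len(alt, n),
                      stringsAsFactors = FALSE)
  variant_cohort(sites, colnames(geno), geno, ...)
}

# single-exon toy model: CDS 101..109 on the plus strand, Met-Lys-stop
toy_plus_model <- function() {
  transcript_model("TOY", "chr1", "+", 101, 109, "ATGAAATAA")
}

# minus-strand mirror of the same protein at 201..209: the genome
# plus-strand sequence there is revcomp("ATGAAATAA") = "TTATTTCAT"
toy_minus_model <- function() {
  transcript_model("TOYM", "chr1", "-", 201, 209, "ATGAAATAA")
}

# two-exon model with an internal splice junction (plus strand)
toy_spliced_model <- function() {
  transcript_model("TOYS", "chr1", "+", c(101, 201), c(106, 206),
                   "ATGAAACCCTAA")
}

write_mini_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DB,Number=0,Type=Flag,Description=\"dbSNP membership\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    lines), path)
  path
}

# independent consequence oracle: translate the whole mutated CDS with
# Biostrings and compare proteins codon-by-codon
oracle_classify <- function(pos, alt, model) {
  widths <- model$cds_end - model$cds_start + 1
  hit <- which(pos >= model$cds_start & pos <= model$cds_end)
  stopifnot(length(hit) == 1)
  if (model$strand == "+") {
    ci <- (if (hit > 1) sum(widths[seq_len(hit - 1)]) else 0) +
      pos - model$cds_start[hit] + 1
    sense_alt <- alt
  } else {
    ci <- (if (hit < length(widths)) sum(widths[seq(hit + 1, length(widths))]) else 0) +
      model$cds_end[hit] - pos + 1
    sense_alt <- chartr("ACGT", "TGCA", alt)
  }
  mutated <- model$cds_seq
  substr(mutated, ci, ci) <- sense_alt
  aa_ref <- as.character(Biostrings::translate(
    Biostrings::DNAString(model$cds_seq), no.init.codon = TRUE))
  aa_alt <- as.character(Biostrings::translate(
    Biostrings::DNAString(mutated), no.init.codon = TRUE))
  k <- (ci - 1) %/% 3 + 1
  r <- substr(aa_ref, k, k); a <- substr(aa_alt, k, k)
  if (r == a) "synonymous" else if (a == "*") "nonsense"
  else if (r == "*") "stoploss" else "missense"
}

# genome plus-strand reference base at a coding position of a model
model_ref_base <- function(pos, model) {
  widths <- model$cds_end - model$cds_start + 1
  hit <- which(pos >= model$cds_start & pos <= model$cds_end)
  if (model$strand == "+") {
    ci <- (if (hit > 1) sum(widths[seq_len(hit - 1)]) else 0) +
      pos - model$cds_start[hit] + 1
    substr(model$cds_seq, ci, ci)
  } else {
    ci <- (if (hit < length(widths)) sum(widths[seq(hit + 1, length(widths))]) else 0) +
      model$cds_end[hit] - pos + 1
    chartr("ACGT", "TGCA", substr(model$cds_seq, ci, ci))
  }
}

# genotype matrix for the worked 22-candidate co-segregation example:
# 10 unaffected relatives, the KLF4 variant heterozygous in exactly one
example_relative_genotypes <- function(carrier_relative = 1L) {
  cand <- example_candidates()
  rel <- sprintf("REL%02d", 1:10)
  g <- matrix("hom_ref", nrow(cand), length(rel),
              dimnames = list(cand$id, rel))
  g[cand$gene == "KLF4", carrier_relative] <- "het"
  g
}
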