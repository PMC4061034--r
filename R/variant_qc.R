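#' Restrict variants to capture targets plus flanks
#'
#' Keeps exactly the sites whose position falls within any target
#' interval expanded by `flank` bp on both sides (1-based inclusive on
#' both endpoints).  Detection outside the enriched regions is
#' unreliable, so everything else is dropped and counted.
#'
#' @param x a [variant_cohort()]
#' @param targets `GRanges` (e.g. from [read_targets()]) or a data.frame
#'   with `chrom`, `start`, `end` columns (1-based inclusive)
#' @param flank non-negative flank in bp (default 200)
#' @return the restricted cohort, with attribute `n_dropped`
#' @export
restrict_to_targets <- function(x, targets, flank = 200) {
  stopifnot(inherits(x, "variant_cohort"), flank >= 0)
  if (is.data.frame(targets)) {
    targets <- GenomicRanges::GRanges(
      targets$chrom, IRanges::IRanges(targets$start, targets$end))
  }
  unknown <- setdiff(as.character(GenomicRanges::seqnames(targets)),
                     unique(x$sites$chrom))
  if (length(unknown)) {
    warning("ignoring target interval(s) on chromosome(s) absent from the ",
            "variant set: ", paste(unknown, collapse = ", "))
    targets <- targets[!as.character(GenomicRanges::seqnames(targets)) %in% unknown]
  }
  expanded <- GenomicRanges::resize(targets,
                                    GenomicRanges::width(targets) + 2 * flank,
                                    fix = "center")
  sites_gr <- GenomicRanges::GRanges(
    x$sites$chrom, IRanges::IRanges(x$sites$pos, width = 1L))
  keep <- IRanges::overlapsAny(sites_gr, expanded)
  out <- subset_sites(x, keep)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Apply the four SNV quality-control criteria
#'
#' A SNV call is discarded if any of the four criteria holds:
#' (i) genotype quality below `min_genotype_quality`;
#' (ii) covering reads below `min_depth`;
#' (iii) estimated copy number above `max_copy_number`;
#' (iv) distance to the nearest SNP below `min_snp_distance_bp`, unless
#' the site is already in dbSNP (the exception attaches to criterion iv
#' only).  Criteria are evaluated in order i..iv and the first failure
#' labels the call for the audit trail; since a single failing criterion
#' discards, the order affects only the label, never the outcome.
#'
#' @param gq,dp,cn,nsd numeric vectors of genotype quality, depth, copy
#'   number and nearest-SNP distance (`NA` = field missing,
#'   `Inf` allowed for `nsd` = no nearby SNP)
#' @param in_dbsnp logical vector, dbSNP membership of the site
#' @param thresholds a [qc_thresholds()]
#' @param missing_policy what a missing field means for the criterion
#'   that needs it: `"fail"` (default, conservative) or `"pass"`
#' @return character vector: `"pass"` or `"fail_i"` .. `"fail_iv"`
#' @export
qc_snv <- function(gq, dp, cn, nsd, in_dbsnp,
                   thresholds = qc_thresholds(),
                   missing_policy = c("fail", "pass")) {
  missing_policy <- match.arg(missing_policy)
  miss <- missing_policy == "fail"
  crit <- function(bad, field_na) ifelse(field_na, miss, bad)
  f1 <- crit(gq < thresholds$min_genotype_quality, is.na(gq))
  f2 <- crit(dp < thresholds$min_depth, is.na(dp))
  f3 <- crit(cn > thresholds$max_copy_number, is.na(cn))
  f4 <- crit(nsd < thresholds$min_snp_distance_bp, is.na(nsd)) & !in_dbsnp
  out <- rep("pass", length(f1))
  out[f4] <- "fail_iv"; out[f3] <- "fail_iii"; out[f2] <- "fail_ii"; out[f1] <- "fail_i"
  n_miss <- sum(is.na(gq)) + sum(is.na(dp)) + sum(is.na(cn)) + sum(is.na(nsd))
  if (n_miss > 0)
    message(n_miss, " missing quality field value(s) treated as '",
            missing_policy, "' for their criterion")
  out
}

#' Call indel zygosity from the indel-supporting read fraction
#'
#' The supporting-read fraction f = supporting/total is banded:
#' f in [0.30, 0.70] (closed band) is heterozygous, f > 0.70 is
#' homozygous, and f < 0.30 yields no call (the variant is dropped from
#' downstream stages and counted).  Zero total reads is a no-call with a
#' zero-depth reason.
#'
#' @param supporting,total numeric vectors of indel-supporting and total
#'   read counts, `0 <= supporting <= total`
#' @param thresholds a [qc_thresholds()] supplying the band endpoints
#' @return character vector: `"het"`, `"hom"` or `"no_call"`; the
#'   attribute `reason` marks zero-depth no-calls
#' @export
call_indel_zygosity <- function(supporting, total, thresholds = qc_thresholds()) {
  if (any(!is.na(supporting) & !is.na(total) &
          (supporting < 0 | supporting > total)))
    stop("supporting reads must lie in [0, total]")
  zero <- !is.na(total) & total == 0
  f <- ifelse(zero, NA_real_, supporting / total)
  out <- ifelse(is.na(f), "no_call",
         ifelse(f > thresholds$het_fraction_hi, "hom",
         ifelse(f >= thresholds$het_fraction_lo, "het", "no_call")))
  reason <- rep(NA_character_, length(out))
  reason[zero] <- "zero-depth"
  attr(out, "reason") <- reason
  out
}

#' Apply quality control across a cohort
#'
#' Marks, per sample, which calls survive: SNV calls must pass the four
#' criteria of [qc_snv()]; indel calls are re-called from read support by
#' [call_indel_zygosity()] (no-calls are dropped; when read support is
#' unavailable the input genotype is kept).  A "call" is a non-reference,
#' non-missing genotype.
#'
#' @param x a [variant_cohort()]
#' @param thresholds a [qc_thresholds()]
#' @param missing_policy forwarded to [qc_snv()]
#' @return list with `active` (logical site x sample matrix: call exists
#'   and passed QC), `geno` (genotype matrix with indel re-calls
#'   applied), and `fail_counts` (per-sample table of failure labels)
#' @export
qc_cohort <- function(x, thresholds = qc_thresholds(),
                      missing_policy = "fail") {
  stopifnot(inherits(x, "variant_cohort"))
  snv <- x$sites$vclass == "SNV"
  geno <- x$geno
  called <- geno == "het" | geno == "hom_alt"
  active <- called
  labels <- matrix("not_called", n_sites(x), length(x$samples),
                   dimnames = list(NULL, x$samples))
  for (j in seq_along(x$samples)) {
    idx <- which(called[, j] & snv)
    if (length(idx)) {
      res <- suppressMessages(qc_snv(
        x$gq[idx, j], x$dp[idx, j], x$cn[idx, j], x$nsd[idx, j],
        x$sites$in_dbsnp[idx], thresholds, missing_policy))
      labels[idx, j] <- res
      active[idx, j] <- res == "pass"
    }
    idx <- which(called[, j] & !snv)
    if (length(idx)) {
      have <- !is.na(x$indel_total[idx, j])
      z <- call_indel_zygosity(x$indel_support[idx, j][have],
                               x$indel_total[idx, j][have], thresholds)
      g <- geno[idx, j]
      g[have] <- c(het = "het", hom = "hom_alt", no_call = "missing")[z]
      geno[idx, j] <- g
      ok <- g %in% c("het", "hom_alt")
      active[idx, j] <- ok
      labels[idx, j] <- ifelse(ok, "pass", "indel_no_call")
    }
  }
  fail_counts <- apply(labels, 2, function(l) table(factor(
    l, levels = c("pass", "fail_i", "fail_ii", "fail_iii", "fail_iv",
                  "indel_no_call", "not_called"))))
  list(active = active, geno = geno, fail_counts = fail_counts)
}
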