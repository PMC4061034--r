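#' Variant cohort container
#'
#' A `variant_cohort` holds one multi-sample set of called variants in a
#' column-aligned form: a site table (one row per biallelic variant), a
#' per-sample zygosity matrix, and per-sample site-quality matrices.
#' Multi-allelic records are decomposed upstream ([read_variants()]) so
#' every row is biallelic.
#'
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `alt` and
#'   optionally `vclass` (recomputed when absent) and `in_dbsnp`.
#' @param samples character vector of sample ids (unique).
#' @param geno character matrix `nrow(sites)` x `length(samples)` with
#'   entries in `hom_ref`, `het`, `hom_alt`, `missing`.
#' @param gq,dp,cn,nsd numeric matrices of per-sample site quality:
#'   phred genotype quality, read depth, estimated copy number and
#'   distance (bp) to the nearest other SNP (`Inf` = none nearby).
#'   `NA` means the field was missing in the input.
#' @param indel_support,indel_total numeric matrices of indel-supporting
#'   and total read counts (NA for SNVs or when unavailable).
#' @return An object of class `variant_cohort`.
#' @export
variant_cohort <- function(sites, samples, geno,
                           gq = NULL, dp = NULL, cn = NULL, nsd = NULL,
                           indel_support = NULL, indel_total = NULL) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  n <- nrow(sites)
  s <- length(samples)
  if (anyDuplicated(samples)) stop("duplicate sample ids in cohort")
  if (!all(sites$pos >= 1)) stop("positions must be >= 1 (1-based VCF convention)")
  if (any(sites$ref == sites$alt)) stop("ref and alt alleles must differ")
  if (is.null(sites$vclass)) sites$vclass <- variant_class(sites$ref, sites$alt)
  ok <- ifelse(sites$vclass == "SNV",
               nchar(sites$ref) == 1L & nchar(sites$alt) == 1L, TRUE)
  if (!all(ok)) stop("vclass inconsistent with allele lengths")
  if (is.null(sites$in_dbsnp)) sites$in_dbsnp <- FALSE
  sites$id <- variant_id(sites$chrom, sites$pos, sites$ref, sites$alt)

  mat <- function(m, default = NA_real_) {
    if (is.null(m)) m <- matrix(default, n, s)
    m <- as.matrix(m)
    stopifnot(nrow(m) == n, ncol(m) == s)
    dimnames(m) <- list(NULL, samples)
    m
  }
  geno <- mat(geno, "missing")
  bad <- setdiff(unique(as.vector(geno)), c("hom_ref", "het", "hom_alt", "missing"))
  if (length(bad)) stop("unknown zygosity label(s): ", paste(bad, collapse = ", "))

  structure(list(
    sites = sites, samples = samples, geno = geno,
    gq = mat(gq), dp = mat(dp), cn = mat(cn), nsd = mat(nsd),
    indel_support = mat(indel_support), indel_total = mat(indel_total)
  ), class = "variant_cohort")
}

#' @export
print.variant_cohort <- function(x, ...) {
  cat("variant_cohort:", nrow(x$sites), "sites x", length(x$samples), "samples\n")
  cat("  samples:", paste(x$samples, collapse = ", "), "\n")
  tab <- table(x$sites$vclass)
  cat("  classes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Number of variant sites in a cohort
#' @param x a `variant_cohort`
#' @export
n_sites <- function(x) nrow(x$sites)

#' Subset a cohort to a set of site rows
#'
#' Keeps the site table and all per-sample matrices aligned.
#' @param x a `variant_cohort`
#' @param i logical or integer row index over sites
#' @return the subsetted `variant_cohort`
#' @export
subset_sites <- function(x, i) {
  stopifnot(inherits(x, "variant_cohort"))
  x$sites <- x$sites[i, , drop = FALSE]
  rownames(x$sites) <- NULL
  for (f in c("geno", "gq", "dp", "cn", "nsd", "indel_support", "indel_total"))
    x[[f]] <- x[[f]][i, , drop = FALSE]
  x
}

#' Classify alleles into SNV / insertion / deletion
#' @param ref,alt allele strings (VCF convention)
#' @return character vector in `SNV`, `insertion`, `deletion`
#' @export
variant_class <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNV",
         ifelse(nchar(alt) > nchar(ref), "insertion", "deletion"))
}

#' Canonical variant identifier `chrom_pos_ref_alt`
#' @param chrom,pos,ref,alt site fields
#' @export
variant_id <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = "_")
}

#' Carrier status from zygosity
#'
#' A carrier holds at least one alternate allele (het or hom_alt).
#' @param geno character vector/matrix of zygosity labels
#' @return logical of the same shape; `NA` for `missing`
#' @export
is_carrier <- function(geno) {
  out <- geno == "het" | geno == "hom_alt"
  out[geno == "missing"] <- NA
  out
}

#' Default quality-control thresholds
#'
#' The four SNP quality criteria and related cutoffs: minimum phred
#' genotype quality 20, minimum covering reads 4, maximum estimated copy
#' number 2, minimum distance to the nearest SNP 5 bp (waived for sites
#' already in dbSNP), capture-target flank 200 bp, indel heterozygous
#' read-fraction band [0.30, 0.70], and the population allele-frequency
#' rejection threshold 0.005 (0.5%).
#'
#' @param min_genotype_quality,min_depth,max_copy_number,min_snp_distance_bp
#'   SNV quality-control cutoffs (criteria i-iv).
#' @param af_reject_threshold population AF above which a database hit is
#'   rejected (strict inequality).
#' @param het_fraction_lo,het_fraction_hi closed indel-heterozygous band on
#'   the indel-supporting read fraction.
#' @param target_flank_bp flank added to each capture target interval.
#' @return a list of class `qc_thresholds`
#' @export
qc_thresholds <- function(min_genotype_quality = 20, min_depth = 4,
                          max_copy_number = 2, min_snp_distance_bp = 5,
                          af_reject_threshold = 0.005,
                          het_fraction_lo = 0.30, het_fraction_hi = 0.70,
                          target_flank_bp = 200) {
  stopifnot(het_fraction_lo > 0, het_fraction_lo < het_fraction_hi,
            het_fraction_hi <= 1, target_flank_bp >= 0,
            af_reject_threshold >= 0, af_reject_threshold <= 1)
  structure(list(
    min_genotype_quality = min_genotype_quality, min_depth = min_depth,
    max_copy_number = max_copy_number, min_snp_distance_bp = min_snp_distance_bp,
    af_reject_threshold = af_reject_threshold,
    het_fraction_lo = het_fraction_lo, het_fraction_hi = het_fraction_hi,
    target_flank_bp = target_flank_bp
  ), class = "qc_thresholds")
}

#' 2x2 allele-count contingency table
#'
#' Cells follow the case/control x alt/ref convention used by the basic
#' allelic association test: `a` case alternate alleles, `b` case
#' reference alleles, `c` control alternate alleles, `d` control
#' reference alleles.
#' @param a,b,c,d non-negative integer cell counts, N = a+b+c+d > 0
#' @return a list of class `contingency_2x2`
#' @export
contingency_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cells must be non-negative integers")
  if (sum(cells) <= 0) stop("empty table")
  structure(as.list(cells), class = "contingency_2x2")
}
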