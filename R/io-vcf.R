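#' Default mapping of cohort quality fields onto VCF FORMAT keys
#'
#' Caller-specific quality fields (copy number, nearest-SNP distance) do
#' not map 1:1 onto standard VCF tags, so the mapping is configuration.
#' `gq`/`dp` default to the reserved GQ/DP keys; `cn`/`nsd` to the custom
#' keys the bundled simulator writes.  Indel read support is taken from
#' the allelic-depth key (`ad`).
#' @return named character vector mapping cohort fields to FORMAT IDs
#' @export
default_format_map <- function() {
  c(gq = "GQ", dp = "DP", cn = "CN", nsd = "NSD", ad = "AD")
}

gt_to_zygosity <- function(gt, alt_index) {
  # gt: "0/1", "1|2", "./.", ...; zygosity with respect to allele alt_index
  out <- character(length(gt))
  alleles <- strsplit(gt, "[/|]")
  for (i in seq_along(gt)) {
    al <- alleles[[i]]
    if (length(al) == 0L || any(al == ".") || any(is.na(al))) {
      out[i] <- "missing"
    } else {
      nalt <- sum(al == as.character(alt_index[i]))
      out[i] <- c("hom_ref", "het", "hom_alt")[nalt + 1L]
    }
  }
  out
}

#' Read called variants from a VCF file
#'
#' Parses a VCF 4.x file (via `VariantAnnotation::readVcf`), decomposes
#' multi-allelic records into one biallelic site per alternate allele,
#' and extracts per-sample zygosity plus the quality fields the QC
#' criteria consume.  dbSNP membership is taken from the standard `DB`
#' INFO flag.  A quality field whose FORMAT key is absent from the file
#' header is a configuration error; a field that is declared but missing
#' at individual records becomes `NA` with a warning.
#'
#' @param path VCF file path
#' @param format_map named character vector mapping the cohort fields
#'   `gq`, `dp`, `cn`, `nsd`, `ad` to FORMAT keys; see
#'   [default_format_map()].  Fields mapped to `NA` are skipped.
#' @return a [variant_cohort()]
#' @export
read_variants <- function(path, format_map = default_format_map()) {
  if (!file.exists(path)) stop("no such VCF file: ", path)
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path, genome = "unspecified")),
    error = function(e) stop("malformed VCF '", path, "': ", conditionMessage(e)))
  rr <- SummarizedExperiment::rowRanges(vcf)
  samples <- colnames(vcf)
  if (length(samples) == 0L) stop("VCF has no sample columns: ", path)
  header_keys <- rownames(VariantAnnotation::geno(VariantAnnotation::header(vcf)))
  if (!"GT" %in% header_keys) stop("VCF lacks a GT FORMAT field: ", path)

  map_key <- function(field)
    if (field %in% names(format_map)) format_map[[field]] else NA_character_
  gmat <- function(field) {
    key <- map_key(field)
    if (is.null(key) || is.na(key)) return(NULL)
    if (!key %in% header_keys) {
      # a key the caller remapped must exist; an absent default key just
      # means the caller did not emit that optional field
      if (!identical(key, default_format_map()[[field]]))
        stop("config error: FORMAT key '", key, "' (for field '", field,
             "') not declared in VCF header of ", path)
      warning("FORMAT key '", key, "' absent from ", basename(path),
              "; field '", field, "' treated as missing")
      return(NULL)
    }
    VariantAnnotation::geno(vcf)[[key]]
  }

  alt_list <- VariantAnnotation::alt(vcf)
  n_alts <- S4Vectors::elementNROWS(alt_list)
  rec <- rep(seq_along(n_alts), n_alts)          # source record of each site
  alt_index <- unlist(lapply(n_alts, seq_len), use.names = FALSE)

  sites <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr))[rec],
    pos = GenomicRanges::start(rr)[rec],
    ref = as.character(VariantAnnotation::ref(vcf))[rec],
    alt = as.character(unlist(alt_list, use.names = FALSE)),
    stringsAsFactors = FALSE)
  db <- VariantAnnotation::info(vcf)$DB
  sites$in_dbsnp <- if (is.null(db)) FALSE else as.logical(db)[rec]

  gt <- VariantAnnotation::geno(vcf)$GT
  geno <- matrix("missing", nrow(sites), length(samples),
                 dimnames = list(NULL, samples))
  for (j in seq_along(samples))
    geno[, j] <- gt_to_zygosity(gt[rec, j], alt_index)

  num_field <- function(field) {
    m <- gmat(field)
    if (is.null(m)) return(NULL)
    out <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m)))
    out[rec, , drop = FALSE]
  }
  gq <- num_field("gq"); dp <- num_field("dp")
  cn <- num_field("cn"); nsd <- num_field("nsd")

  indel_support <- indel_total <- NULL
  ad_key <- map_key("ad")
  if (!is.null(ad_key) && !is.na(ad_key) && ad_key %in% header_keys) {
    ad <- suppressWarnings(gmat("ad"))             # list-matrix: (ref, alt1, ...)
    indel_support <- indel_total <- matrix(NA_real_, nrow(sites), length(samples))
    for (j in seq_along(samples)) {
      for (i in seq_len(nrow(sites))) {
        v <- ad[[rec[i], j]]
        if (length(v) >= alt_index[i] + 1L && !all(is.na(v))) {
          indel_support[i, j] <- v[alt_index[i] + 1L]
          indel_total[i, j] <- sum(v, na.rm = TRUE)
        }
      }
    }
  }

  for (f in list(list(gq, "gq"), list(dp, "dp"))) {
    if (!is.null(f[[1]]) && anyNA(f[[1]]))
      warning(sum(is.na(f[[1]])), " missing ", f[[2]],
              " value(s) in ", basename(path), "; kept as missing")
  }

  variant_cohort(sites, samples, geno, gq = gq, dp = dp, cn = cn, nsd = nsd,
                 indel_support = indel_support, indel_total = indel_total)
}

fmt_num <- function(x, digits = 6) {
  out <- ifelse(is.na(x), ".",
         ifelse(is.infinite(x), "99999999",
                formatC(x, format = "g", digits = digits)))
  out
}

#' Write a cohort back to a multi-sample VCF 4.2 file
#'
#' Emits one biallelic record per site with GT plus the mapped quality
#' FORMAT fields and the `DB` INFO flag, such that
#' `read_variants(write_variants(x))` round-trips chrom, pos, ref, alt
#' and zygosity.
#' @param x a [variant_cohort()]
#' @param path output file path
#' @param format_map field-to-FORMAT-key mapping, as in [read_variants()]
#' @return `path`, invisibly
#' @export
write_variants <- function(x, path, format_map = default_format_map()) {
  stopifnot(inherits(x, "variant_cohort"))
  km <- function(f, d) if (!is.null(format_map[[f]]) && !is.na(format_map[[f]])) format_map[[f]] else d
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=famvar",
    "##INFO=<ID=DB,Number=0,Type=Flag,Description=\"dbSNP membership\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    sprintf("##FORMAT=<ID=%s,Number=1,Type=Integer,Description=\"Genotype quality\">", km("gq", "GQ")),
    sprintf("##FORMAT=<ID=%s,Number=1,Type=Integer,Description=\"Read depth\">", km("dp", "DP")),
    sprintf("##FORMAT=<ID=%s,Number=1,Type=Float,Description=\"Estimated copy number\">", km("cn", "CN")),
    sprintf("##FORMAT=<ID=%s,Number=1,Type=Integer,Description=\"Distance to nearest SNP (bp)\">", km("nsd", "NSD")),
    sprintf("##FORMAT=<ID=%s,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">", km("ad", "AD")),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$samples), collapse = "\t"))
  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")
  n <- n_sites(x)
  fmt <- paste(c("GT", km("gq", "GQ"), km("dp", "DP"), km("cn", "CN"),
                 km("nsd", "NSD"), km("ad", "AD")), collapse = ":")
  per_sample <- vapply(seq_along(x$samples), function(j) {
    ad <- ifelse(is.na(x$indel_support[, j]) | is.na(x$indel_total[, j]), ".",
                 paste(x$indel_total[, j] - x$indel_support[, j],
                       x$indel_support[, j], sep = ","))
    paste(gt_code[x$geno[, j]],
          fmt_num(x$gq[, j]), fmt_num(x$dp[, j]),
          fmt_num(x$cn[, j], 4), fmt_num(x$nsd[, j]), ad, sep = ":")
  }, character(n))
  if (n == 1L) per_sample <- matrix(per_sample, nrow = 1L)
  body <- paste(x$sites$chrom, x$sites$pos, ".", x$sites$ref, x$sites$alt,
                ".", "PASS", ifelse(x$sites$in_dbsnp, "DB", "."), fmt,
                apply(per_sample, 1L, paste, collapse = "\t"), sep = "\t")
  ord <- order(x$sites$chrom, x$sites$pos, x$sites$ref, x$sites$alt)
  writeLines(c(hdr, body[ord]), path)
  invisible(path)
}
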