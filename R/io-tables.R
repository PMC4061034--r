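#' Read capture-target intervals from a BED file
#'
#' BED is 0-based half-open; intervals are converted to the 1-based
#' inclusive convention used throughout the package at this boundary
#' (`rtracklayer::import` performs the conversion).
#' @param path BED file path
#' @return a `GRanges` of target intervals (1-based inclusive)
#' @export
read_targets <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' Write 1-based inclusive intervals as BED (0-based half-open)
#' @param targets `GRanges` or data.frame with chrom/start/end (1-based)
#' @param path output path
#' @export
write_targets <- function(targets, path) {
  if (is.data.frame(targets)) {
    targets <- GenomicRanges::GRanges(
      targets$chrom, IRanges::IRanges(targets$start, targets$end))
  }
  rtracklayer::export(targets, path, format = "BED")
  invisible(path)
}

#' Read the per-variant annotation table
#'
#' Schema follows the candidate-mutation table convention: one row per
#' variant with gene symbol, consequence class, codon change, the four
#' predictor calls and the GERP conservation score.  Missing predictor
#' calls may be encoded as `-`, an en-dash, an empty field or `NA`.
#'
#' @param path TSV with columns `id` (chrom_pos_ref_alt), `gene`,
#'   `consequence`, and optionally `codons`, `sift`, `mutation_taster`,
#'   `polyphen2`, `pmut`, `gerp`.
#' @return data.frame with normalized predictor vocabularies
#' @export
read_annotations <- function(path) {
  ann <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("id", "gene", "consequence")
  if (!all(need %in% names(ann)))
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  for (col in c("sift", "mutation_taster", "polyphen2", "pmut"))
    if (!is.null(ann[[col]])) ann[[col]] <- normalize_predictor_call(ann[[col]], col)
  if (!is.null(ann$gerp)) ann$gerp <- suppressWarnings(as.numeric(ann$gerp))
  ann
}

#' Normalize a predictor-call column to its closed vocabulary
#'
#' @param x character vector of raw calls
#' @param predictor one of `sift`, `mutation_taster`, `polyphen2`, `pmut`
#' @return character vector with values from the predictor's vocabulary
#'   or `NA` for missing (`-`, en-dash, empty)
#' @export
normalize_predictor_call <- function(x, predictor) {
  vocab <- list(
    sift = c("DAMAGING", "TOLERATED"),
    mutation_taster = c("disease_causing", "polymorphism"),
    polyphen2 = c("damaging", "benign"),
    pmut = c("pathological", "neutral"))[[predictor]]
  y <- gsub("[ -]", "_", trimws(tolower(as.character(x))))
  y[y %in% c("", "_", "–", "—", "na", ".")] <- NA
  out <- vocab[match(y, tolower(vocab))]
  bad <- !is.na(y) & is.na(out)
  if (any(bad))
    stop("unknown ", predictor, " call(s): ", paste(unique(x[bad]), collapse = ", "))
  out
}

#' Read the population-database membership/frequency table
#'
#' @param path TSV with columns `chrom`, `pos`, `ref`, `alt`, `db`,
#'   `present` (logical or 0/1), `af` (fraction or NA when unknown)
#' @return data.frame with an added canonical `id` column
#' @export
read_popdb <- function(path) {
  pop <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", "", "."))
  need <- c("chrom", "pos", "ref", "alt", "db", "present")
  if (!all(need %in% names(pop)))
    stop("population table must have columns: ", paste(need, collapse = ", "))
  pop$present <- as.logical(pop$present)
  if (is.null(pop$af)) pop$af <- NA_real_
  pop$af <- suppressWarnings(as.numeric(pop$af))
  if (any(!is.na(pop$af) & (pop$af < 0 | pop$af > 1)))
    stop("allele frequencies must lie in [0, 1]")
  pop$id <- variant_id(pop$chrom, pop$pos, pop$ref, pop$alt)
  pop
}

#' Read a case-control genotype panel
#'
#' Long format: one row per (variant, subject).
#' @param path TSV with columns `id` (variant), `sample`, `group`
#'   (`case`, `control`, or any cohort label), `geno`
#'   (hom_ref/het/hom_alt/missing)
#' @return data.frame
#' @export
read_panel <- function(path) {
  panel <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "sample", "group", "geno")
  if (!all(need %in% names(panel)))
    stop("panel table must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(panel$geno), c("hom_ref", "het", "hom_alt", "missing"))
  if (length(bad)) stop("unknown panel genotype label(s): ", paste(bad, collapse = ", "))
  panel
}

#' Read pipeline configuration from JSON or YAML
#'
#' @param path `.json` (always supported) or `.yaml`/`.yml` (requires the
#'   `yaml` package) file of configuration overrides
#' @return a named list
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package; use JSON instead")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
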